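# Architecture descriptions: layer_spec / model_spec and their invariants.

#' Describe one hidden layer of a classifier
#'
#' A layer spec names the removal-unit granularity of structured pruning: a
#' dense layer's units are nodes, a convolutional layer's units are filters.
#'
#' @param kind `"dense"` or `"conv"`.
#' @param units Positive integer; nodes (dense) or filters (conv).
#' @param kernel Integer vector of length 2 (kernel height, width); conv only.
#' @param activation Activation function, `"relu"` or `"linear"`.
#' @param pool Optional pooling width (square max-pool, stride equal to
#'   width); conv only.
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(kind = c("dense", "conv"), units,
                       kernel = NULL, activation = c("relu", "linear"),
                       pool = NULL) {
  kind <- match.arg(kind)
  activation <- match.arg(activation)
  if (length(units) != 1L || is.na(units) || units < 1 || units != round(units)) {
    stop_jgrs("`units` must be a positive integer", "jgrs_config_error")
  }
  if (kind == "conv") {
    if (is.null(kernel)) kernel <- c(3L, 3L)
    if (length(kernel) == 1L) kernel <- rep(kernel, 2L)
    if (any(kernel < 1) || any(kernel != round(kernel))) {
      stop_jgrs("conv kernel dims must be positive integers", "jgrs_config_error")
    }
    if (!is.null(pool) && (length(pool) != 1L || pool < 1 || pool != round(pool))) {
      stop_jgrs("`pool` must be a positive integer width", "jgrs_config_error")
    }
  } else {
    if (!is.null(kernel)) {
      stop_jgrs("`kernel` applies only to conv layers", "jgrs_config_error")
    }
    if (!is.null(pool)) {
      stop_jgrs("`pool` applies only to conv layers", "jgrs_config_error")
    }
  }
  structure(
    list(layer_kind = kind, units = as.integer(units),
         kernel = if (kind == "conv") as.integer(kernel) else NULL,
         activation = activation,
         pool = if (!is.null(pool)) as.integer(pool) else NULL),
    class = "layer_spec"
  )
}

#' Describe an MLP or CNN classifier architecture
#'
#' @param kind `"mlp"` or `"cnn"`.
#' @param input_shape For an MLP, the feature count; for a CNN, an integer
#'   vector `c(channels, height, width)`.
#' @param hidden_layers A list of [layer_spec()] objects, ordered input to
#'   output. A CNN's convolutional layers must precede its dense layers; the
#'   output layer (a dense layer with `num_classes` units) is implicit and is
#'   never a pruning target.
#' @param num_classes Number of output classes (binary decoding uses 2).
#' @return A `model_spec` object.
#' @export
model_spec <- function(kind = c("mlp", "cnn"), input_shape, hidden_layers,
                       num_classes = 2L) {
  kind <- match.arg(kind)
  if (length(hidden_layers) < 1L) {
    stop_jgrs("a model needs at least one hidden layer", "jgrs_config_error")
  }
  if (!all(vapply(hidden_layers, inherits, logical(1), "layer_spec"))) {
    stop_jgrs("`hidden_layers` must be a list of layer_spec objects",
              "jgrs_config_error")
  }
  kinds <- vapply(hidden_layers, `[[`, character(1), "layer_kind")
  if (kind == "mlp") {
    if (length(input_shape) != 1L || input_shape < 1) {
      stop_jgrs("mlp input_shape is a single feature count", "jgrs_config_error")
    }
    if (any(kinds != "dense")) {
      stop_jgrs("mlp hidden layers must all be dense", "jgrs_config_error")
    }
  } else {
    if (length(input_shape) != 3L || any(input_shape < 1)) {
      stop_jgrs("cnn input_shape is c(channels, height, width)",
                "jgrs_config_error")
    }
    # conv layers must precede dense layers
    dense_seen <- FALSE
    for (k in kinds) {
      if (k == "dense") dense_seen <- TRUE
      if (k == "conv" && dense_seen) {
        stop_jgrs("conv layer after dense layer is not allowed",
                  "jgrs_config_error")
      }
    }
    if (kinds[1] != "conv") {
      stop_jgrs("a cnn must start with a conv layer", "jgrs_config_error")
    }
  }
  if (num_classes < 2) {
    stop_jgrs("`num_classes` must be at least 2", "jgrs_config_error")
  }
  structure(
    list(kind = kind, input_shape = as.integer(input_shape),
         hidden_layers = hidden_layers, num_classes = as.integer(num_classes)),
    class = "model_spec"
  )
}

#' Convenience constructor for an MLP spec
#'
#' @param input_dim Feature count.
#' @param hidden Integer vector of hidden-layer widths, e.g. `c(16, 16, 16)`.
#' @param num_classes Number of classes.
#' @param activation Hidden activation.
#' @return A `model_spec`.
#' @export
mlp_spec <- function(input_dim, hidden, num_classes = 2L, activation = "relu") {
  model_spec("mlp", input_dim,
             lapply(hidden, function(u) layer_spec("dense", u,
                                                   activation = activation)),
             num_classes)
}

#' Hidden-layer unit counts of a spec or model
#'
#' @param x A `model_spec` or `jgrs_model`.
#' @return Integer vector of removal-unit counts per hidden layer.
#' @export
hidden_units <- function(x) {
  spec <- if (inherits(x, "jgrs_model")) x$spec else x
  vapply(spec$hidden_layers, `[[`, integer(1), "units")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, input [%s], classes %d\n", x$kind,
              paste(x$input_shape, collapse = "x"), x$num_classes))
  for (i in seq_along(x$hidden_layers)) {
    l <- x$hidden_layers[[i]]
    extra <- if (l$layer_kind == "conv") {
      sprintf(" kernel %s%s", paste(l$kernel, collapse = "x"),
              if (!is.null(l$pool)) sprintf(", pool %d", l$pool) else "")
    } else ""
    cat(sprintf("  hidden %d: %s %d units (%s)%s\n", i, l$layer_kind,
                l$units, l$activation, extra))
  }
  invisible(x)
}

#' Serialize / read a model spec as JSON
#'
#' @param spec A `model_spec`.
#' @param path File path.
#' @return `read_model_spec_json()` returns a `model_spec`.
#' @export
write_model_spec_json <- function(spec, path) {
  obj <- list(kind = spec$kind, input_shape = spec$input_shape,
              num_classes = spec$num_classes,
              hidden_layers = lapply(spec$hidden_layers, function(l) {
                l[!vapply(l, is.null, logical(1))]
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec_json
#' @export
read_model_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(obj$hidden_layers, function(l) {
    layer_spec(l$layer_kind, l$units, kernel = l$kernel,
               activation = l$activation, pool = l$pool)
  })
  model_spec(obj$kind, obj$input_shape, layers, obj$num_classes)
}
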