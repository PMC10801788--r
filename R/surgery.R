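# Structured surgery: removal of whole nodes/filters with exact propagation
# of the deletion into the next layer's incoming weights, plus parameter and
# FLOP accounting.

#' Remove whole units (nodes or filters) from a hidden layer
#'
#' The atomic operation of structured pruning. Removing unit `u` of hidden
#' layer `l` deletes its incoming weights and bias, and the slices of the
#' next layer's weights that read from it: the matching input rows for a
#' dense successor, the matching input-channel slices for a conv successor,
#' and — at the conv-to-dense boundary — every flattened feature the removed
#' filter produces. Surviving weights are preserved verbatim, so removing a
#' unit whose outgoing weights are all zero leaves model predictions exactly
#' unchanged.
#'
#' @param model A `jgrs_model`.
#' @param layer Index into the hidden layers (the output layer is never a
#'   removal target).
#' @param unit_indices Distinct indices of units to delete; at least one unit
#'   must survive.
#' @return The edited `jgrs_model`.
#' @export
remove_units <- function(model, layer, unit_indices) {
  nh <- n_hidden(model)
  if (length(layer) != 1L || layer < 1 || layer > nh) {
    stop_jgrs("`layer` must index a hidden layer", "jgrs_index_error")
  }
  unit_indices <- as.integer(unit_indices)
  uc <- unit_count_layer(model, layer)
  if (anyDuplicated(unit_indices) || any(unit_indices < 1) ||
      any(unit_indices > uc)) {
    stop_jgrs("`unit_indices` must be distinct and within the layer",
              "jgrs_index_error")
  }
  if (length(unit_indices) >= uc) {
    stop_jgrs("cannot remove all units of a layer", "jgrs_structure_error")
  }
  keep <- setdiff(seq_len(uc), unit_indices)
  lay <- model$layers[[layer]]
  nxt <- model$layers[[layer + 1L]]
  if (lay$kind == "dense") {
    lay$W <- lay$W[, keep, drop = FALSE]
    lay$b <- lay$b[keep]
    # successor of a dense hidden layer is always dense
    nxt$W <- nxt$W[keep, , drop = FALSE]
  } else {
    lay$W <- lay$W[, , , keep, drop = FALSE]
    lay$b <- lay$b[keep]
    if (nxt$kind == "conv") {
      nxt$W <- nxt$W[, , keep, , drop = FALSE]
    } else {
      # conv -> dense boundary: filter f feeds the flattened block
      # (f-1)*H*W + 1 .. f*H*W of the dense input
      hw <- prod(lay$out_hw)
      keep_rows <- as.vector(outer(seq_len(hw), (keep - 1L) * hw, `+`))
      nxt$W <- nxt$W[keep_rows, , drop = FALSE]
    }
  }
  model$layers[[layer]] <- lay
  model$layers[[layer + 1L]] <- nxt
  model$spec$hidden_layers[[layer]]$units <- length(keep)
  model
}

#' Parameter count of a model
#'
#' Total number of stored scalar weights and biases across all layers
#' (biases count; they are removed together with their unit).
#'
#' @param model A `jgrs_model`.
#' @return Non-negative integer.
#' @export
param_count <- function(model) {
  sum(vapply(model$layers,
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Forward-pass FLOP count of a model
#'
#' Convention: a dense layer with `in` inputs and `out` units costs
#' `(2*in - 1) * out` multiply-adds plus `out` bias additions; a conv layer
#' costs `(2*kh*kw*cin - 1)` multiply-adds plus one bias addition per output
#' position per filter (valid padding, stride 1). Pooling and activations are
#' excluded.
#'
#' @param model A `jgrs_model`.
#' @return Non-negative integer.
#' @export
flop_count <- function(model) {
  total <- 0
  for (lay in model$layers) {
    if (lay$kind == "dense") {
      in_dim <- nrow(lay$W); out_dim <- ncol(lay$W)
      total <- total + (2 * in_dim - 1) * out_dim + out_dim
    } else {
      kh <- dim(lay$W)[1]; kw <- dim(lay$W)[2]
      cin <- dim(lay$W)[3]; nf <- dim(lay$W)[4]
      pos <- (lay$in_hw[1] - kh + 1) * (lay$in_hw[2] - kw + 1)
      total <- total + pos * nf * (2 * kh * kw * cin - 1) + pos * nf
    }
  }
  total
}
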