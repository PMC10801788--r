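# Seeded synthetic datasets with the statistical structure of the decoding
# inputs the pruning algorithms are designed for: calcium-trace matrices with
# binary behavior labels, balanced graph-embedding vectors, and
# teacher-network data whose labels genuinely require model capacity.

#' Parameters for the calcium-trace generator
#'
#' Defaults emulate a 5-minute single-subject recording: 3000 samples at
#' 10 Hz, `beta` neurons, binary behavior labels with temporal persistence.
#' A subset of neurons is label-coupled: they emit Poisson calcium events at
#' a state-dependent rate, convolved with a single-exponential decay kernel,
#' plus Gaussian noise; the remaining neurons fire at a state-independent
#' rate.
#'
#' @param beta Number of neurons (columns of the trace matrix).
#' @param n_samples Number of time samples (default 3000).
#' @param n_informative Number of label-coupled neurons (default 25% of
#'   `beta`, at least 1).
#' @param sampling_rate_hz Sampling rate (default 10).
#' @param transient_decay_s Calcium transient decay time constant in seconds.
#' @param event_rate_hz Length-2 vector: event rate (Hz) of informative
#'   neurons in behavior state 0 and state 1.
#' @param background_rate_hz Event rate of uninformative neurons (state
#'   independent).
#' @param noise_sd Gaussian noise standard deviation added to every trace.
#' @param label_persistence_s Mean dwell time of each behavior state in
#'   seconds (labels form a two-state Markov chain).
#' @param seed Integer seed.
#' @return An `msn_gen_params` list.
#' @export
msn_gen_params <- function(beta = 114L, n_samples = 3000L,
                           n_informative = max(1L, round(beta * 0.5)),
                           sampling_rate_hz = 10, transient_decay_s = 0.5,
                           event_rate_hz = c(0.2, 4.0),
                           background_rate_hz = 0.5,
                           noise_sd = 0.1, label_persistence_s = 3.0,
                           seed = 1L) {
  if (beta < 1 || n_samples < 1 || n_informative > beta ||
      n_informative < 0 || sampling_rate_hz <= 0 || transient_decay_s <= 0 ||
      any(event_rate_hz < 0) || length(event_rate_hz) != 2L ||
      background_rate_hz < 0 || noise_sd < 0 || label_persistence_s <= 0) {
    stop_jgrs("invalid calcium-trace generator parameters",
              "jgrs_config_error")
  }
  structure(list(beta = as.integer(beta), n_samples = as.integer(n_samples),
                 n_informative = as.integer(n_informative),
                 sampling_rate_hz = sampling_rate_hz,
                 transient_decay_s = transient_decay_s,
                 event_rate_hz = event_rate_hz,
                 background_rate_hz = background_rate_hz,
                 noise_sd = noise_sd,
                 label_persistence_s = label_persistence_s,
                 seed = seed),
            class = "msn_gen_params")
}

#' Generate a calcium-trace decoding dataset
#'
#' @param params An [msn_gen_params()] list.
#' @return A `labeled_dataset`: `features` (`n_samples` by `beta` trace
#'   matrix), binary `labels`, and the generator metadata.
#' @export
generate_msn_like <- function(params = msn_gen_params()) {
  if (!inherits(params, "msn_gen_params")) {
    stop_jgrs("`params` must come from msn_gen_params()", "jgrs_config_error")
  }
  with_seed(params$seed, {
    n <- params$n_samples
    fs <- params$sampling_rate_hz
    # two-state Markov chain labels with mean dwell time label_persistence_s
    switch_p <- min(1, 1 / (params$label_persistence_s * fs))
    labels <- integer(n)
    labels[1] <- stats::rbinom(1L, 1L, 0.5)
    flips <- stats::runif(n - 1L) < switch_p
    for (t in seq_len(n - 1L)) {
      labels[t + 1L] <- if (flips[t]) 1L - labels[t] else labels[t]
    }
    decay <- exp(-1 / (params$transient_decay_s * fs))
    traces <- matrix(0, n, params$beta)
    for (j in seq_len(params$beta)) {
      rate <- if (j <= params$n_informative) {
        ifelse(labels == 1L, params$event_rate_hz[2], params$event_rate_hz[1])
      } else {
        rep(params$background_rate_hz, n)
      }
      events <- stats::rpois(n, rate / fs)
      # recursive filter = exact convolution with exp(-t / tau) kernel
      ca <- as.numeric(stats::filter(events, decay, method = "recursive"))
      traces[, j] <- ca + stats::rnorm(n, sd = params$noise_sd)
    }
    labeled_dataset(traces, labels,
                    meta = list(kind = "msn_like", params = params))
  })
}

#' Generate a balanced embedding-vector dataset
#'
#' Two spherical unit-variance Gaussian clusters centred at
#' `+/- (separation / 2)` along a random unit direction, with exact class
#' balance. The Bayes accuracy is `pnorm(separation / 2)`, so `separation`
#' dials task difficulty directly.
#'
#' @param n Number of samples (even; default 1600).
#' @param dim Embedding dimension (default 80).
#' @param separation Distance between cluster centres in noise SD units.
#' @param seed Integer seed.
#' @return A `labeled_dataset` with `n / 2` samples per label.
#' @export
generate_embedding_like <- function(n = 1600L, dim = 80L, separation = 4,
                                    seed = 1L) {
  if (n < 2 || n %% 2 != 0) {
    stop_jgrs("`n` must be even for exact class balance", "jgrs_config_error")
  }
  with_seed(seed, {
    u <- stats::rnorm(dim)
    u <- u / sqrt(sum(u^2))
    labels <- sample(rep(0:1, each = n / 2))
    centers <- outer(ifelse(labels == 1L, separation / 2, -separation / 2), u)
    x <- centers + matrix(stats::rnorm(n * dim), n, dim)
    labeled_dataset(x, labels,
                    meta = list(kind = "embedding_like",
                                separation = separation, seed = seed))
  })
}

#' Generate data solvable only by a planted minimal subnetwork
#'
#' Gaussian inputs whose label is the parity of the sign bits of the first
#' `k_parity` coordinates (those coordinates are pushed `margin` away from
#' the decision planes so labels are clean). A `k`-bit parity is computable
#' by a small dedicated subnetwork, and an overparameterized model learns it
#' to near-perfect accuracy — but no layer narrower than `k_parity` units can
#' carry it, since parity is not recoverable from any lower-dimensional
#' linear projection. Accuracy therefore genuinely collapses as a model is
#' pruned toward a minimal structure, which is exactly the regime the
#' multi-phase sensitivity probe exercises.
#'
#' @param n Number of samples.
#' @param dim Input dimension (only the first `k_parity` carry label signal).
#' @param k_parity Number of parity bits (default 3).
#' @param margin Distance by which informative coordinates are pushed away
#'   from zero.
#' @param seed Integer seed.
#' @return A `labeled_dataset`.
#' @export
generate_planted_subnetwork <- function(n = 1600L, dim = 10L, k_parity = 3L,
                                        margin = 0.3, seed = 1L) {
  if (k_parity < 1 || k_parity > dim) {
    stop_jgrs("`k_parity` must be between 1 and `dim`", "jgrs_config_error")
  }
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * dim), n, dim)
    x[, seq_len(k_parity)] <- sign(x[, seq_len(k_parity)]) *
      (abs(x[, seq_len(k_parity)]) + margin)
    labels <- as.integer(rowSums(x[, seq_len(k_parity), drop = FALSE] > 0) %% 2L)
    labeled_dataset(x, labels,
                    meta = list(kind = "planted_subnetwork",
                                k_parity = k_parity, margin = margin,
                                seed = seed))
  })
}

# ---- dataset container ------------------------------------------------------

#' Construct a labeled dataset
#'
#' @param features Numeric matrix, samples by features.
#' @param labels Integer labels.
#' @param split Optional split from [split_8_1_1()].
#' @param meta Optional metadata list.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, split = NULL, meta = list()) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop_jgrs("feature rows and label length differ", "jgrs_data_error")
  }
  if (any(!is.finite(features))) {
    stop_jgrs("features contain non-finite values", "jgrs_data_error")
  }
  structure(list(features = features, labels = labels, split = split,
                 meta = meta),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features; labels {%s}%s\n",
              nrow(x$features), ncol(x$features),
              paste(sort(unique(x$labels)), collapse = ","),
              if (is.null(x$split)) "" else " (split attached)"))
  invisible(x)
}

#' Random 8:1:1 train/validation/test split
#'
#' Validation and test each receive `floor(n / 10)` samples; training takes
#' the remainder. The three index sets are disjoint and exhaustive.
#'
#' @param dataset A `labeled_dataset` (or sample count).
#' @param seed Integer seed.
#' @return The dataset with a `split` list (`train`, `validation`, `test`
#'   index vectors) attached; if `dataset` is a count, just the split list.
#' @export
split_8_1_1 <- function(dataset, seed = 1L) {
  n <- if (inherits(dataset, "labeled_dataset")) nrow(dataset$features)
       else as.integer(dataset)
  if (n < 10L) {
    stop_jgrs("need at least 10 samples for an 8:1:1 split", "jgrs_data_error")
  }
  split <- with_seed(seed, {
    perm <- sample.int(n)
    k <- n %/% 10L
    list(train = sort(perm[seq_len(n - 2L * k)]),
         validation = sort(perm[(n - 2L * k + 1L):(n - k)]),
         test = sort(perm[(n - k + 1L):n]))
  })
  if (inherits(dataset, "labeled_dataset")) {
    dataset$split <- split
    dataset
  } else {
    split
  }
}

#' Extract a split of a dataset as a data pair
#'
#' @param dataset A `labeled_dataset` with a split attached.
#' @param which `"train"`, `"validation"` or `"test"`.
#' @return A `data_pair`.
#' @export
dataset_split <- function(dataset, which = c("train", "validation", "test")) {
  which <- match.arg(which)
  if (is.null(dataset$split)) {
    stop_jgrs("dataset has no split; call split_8_1_1() first",
              "jgrs_data_error")
  }
  idx <- dataset$split[[which]]
  as_data_pair(dataset$features[idx, , drop = FALSE], dataset$labels[idx])
}

# ---- CSV IO -----------------------------------------------------------------

#' Write / read a labeled dataset as CSV
#'
#' Column `label` followed by feature columns `f1..fD`.
#'
#' @param dataset A `labeled_dataset`.
#' @param path File path.
#' @return `read_dataset_csv()` returns a `labeled_dataset` (no split).
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(label = dataset$labels, dataset$features)
  names(df) <- c("label", paste0("f", seq_len(ncol(dataset$features))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  labeled_dataset(as.matrix(df[, -1, drop = FALSE]), df$label)
}
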