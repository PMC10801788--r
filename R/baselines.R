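# Baseline pruning methods: RRS sensitivity probing and NWM magnitude
# pruning.

#' RRS pruning trace: random inter-layer order, random intra-layer selection
#'
#' Probes how sensitive accuracy is to unit removal as the model shrinks. At
#' each step one single-unit-removal candidate is built per prunable layer;
#' each candidate is retrained and validated `evals_per_structure` times
#' (averaging out retraining randomness), the mean accuracy across candidates
#' is recorded, and the walk continues from a uniformly random candidate.
#' Iterates until every layer reaches its minimum unit count. The default
#' tolerance of 0.5 is deliberately loose so the walk reaches the minimum
#' structure; the recorded trace is the object of interest, not the final
#' model.
#'
#' @param model A trained `jgrs_model`.
#' @param train_data,val_data `data_pair` splits.
#' @param mucv Minimum unit-count vector.
#' @param tolerance Accuracy-drop tolerance (floor is
#'   `tolerance * OriValAcc`); default 0.5.
#' @param evals_per_structure Retrain-validate repetitions per candidate
#'   (default 3).
#' @param train_cfg A [train_config()].
#' @param seed Optional seed for this call.
#' @param test_data Optional `data_pair`; if supplied, mean test accuracy is
#'   traced alongside validation accuracy.
#' @return A data frame with one row per removal step: `step`, `structure`
#'   (hidden widths after the step, e.g. `"15x16x16"`), `mean_val_acc`,
#'   `mean_test_acc`, `chosen_layer`, and `below_tolerance` flagging steps
#'   whose chosen candidate fell under `tolerance * OriValAcc`. The walk
#'   always continues to the minimum structure; the tolerance is recorded,
#'   not enforced, since the trace itself is the experiment's output.
#' @export
rrs_prune_trace <- function(model, train_data, val_data, mucv,
                            tolerance = 0.5, evals_per_structure = 3L,
                            train_cfg = train_config(), seed = NULL,
                            test_data = NULL) {
  mucv <- check_mucv(mucv, n_hidden(model))
  with_seed(seed, {
    ori_val_acc <- validate(model, val_data)
    val_acc_min <- ori_val_acc * tolerance
    cur <- model
    rows <- list()
    step <- 0L
    repeat {
      prunable <- which(hidden_units(cur) > mucv)
      if (length(prunable) == 0L) break
      cand_models <- list()
      cand_val <- numeric(0)
      cand_test <- numeric(0)
      for (lam in prunable) {
        cand0 <- random_cut_units(cur, lam, 1L)
        vs <- numeric(evals_per_structure)
        ts <- rep(NA_real_, evals_per_structure)
        m2 <- cand0
        for (e in seq_len(evals_per_structure)) {
          m2 <- fine_tune(cand0, train_data, train_cfg)
          vs[e] <- validate(m2, val_data)
          if (!is.null(test_data)) ts[e] <- validate(m2, test_data)
        }
        k <- length(cand_models) + 1L
        cand_models[[k]] <- m2
        cand_val[k] <- mean(vs)
        cand_test[k] <- mean(ts)
      }
      step <- step + 1L
      pick <- sample.int(length(cand_models), 1L)
      cur <- cand_models[[pick]]
      rows[[step]] <- data.frame(
        step = step,
        structure = paste(hidden_units(cur), collapse = "x"),
        mean_val_acc = mean(cand_val),
        mean_test_acc = if (is.null(test_data)) NA_real_ else mean(cand_test),
        chosen_layer = prunable[pick],
        below_tolerance = cand_val[pick] < val_acc_min)
    }
    do.call(rbind, rows)
  })
}

#' NWM pruning: natural layer order, weight-magnitude selection
#'
#' Structured adaptation of lower-half weight-magnitude pruning: hidden
#' layers are visited in natural input-to-output order; each round removes
#' the half of the current layer's removal units with the smallest L1 norm of
#' incoming weights (floor when odd, clamped so the layer keeps at least its
#' minimum unit count), then retrains and validates. Pruning stops when a
#' round's accuracy falls below the floor (the round is discarded) or when
#' the minimum structure is reached.
#'
#' @inheritParams far_subphase_1
#' @param val_acc_min Minimum acceptable validation accuracy; if `NULL`, it
#'   is computed as `tolerance * OriValAcc`.
#' @param tolerance Accuracy-drop tolerance used when `val_acc_min` is
#'   `NULL`; default 0.985.
#' @return A `prune_result`.
#' @export
nwm_prune <- function(model, train_data, val_data, mucv, val_acc_min = NULL,
                      tolerance = 0.985, train_cfg = train_config(),
                      seed = NULL) {
  mucv <- check_mucv(mucv, n_hidden(model))
  before <- call_counters()
  with_seed(seed, {
    ori_val_acc <- validate(model, val_data)
    if (is.null(val_acc_min)) val_acc_min <- ori_val_acc * tolerance
    cur <- model
    last_val_acc <- ori_val_acc
    steps <- list()
    round <- 0L
    stop_all <- FALSE
    for (lam in seq_along(mucv)) {
      while (!stop_all && unit_count_layer(cur, lam) > mucv[lam]) {
        uc <- unit_count_layer(cur, lam)
        n_cut <- min(uc %/% 2L, uc - mucv[lam])
        if (n_cut < 1L) break
        mags <- unit_magnitudes(cur, lam)
        idx <- order(mags)[seq_len(n_cut)]
        cand <- remove_units(cur, lam, idx)
        cand <- fine_tune(cand, train_data, train_cfg)
        acc <- validate(cand, val_data)
        accepted <- acc >= val_acc_min
        round <- round + 1L
        steps[[round]] <- trace_row("nwm", round, lam, idx, n_cut, TRUE,
                                    acc, accepted)
        if (accepted) {
          cur <- cand
          last_val_acc <- acc
        } else {
          stop_all <- TRUE
        }
      }
      if (stop_all) break
    }
    prune_result(cur, last_val_acc,
                 do.call(rbind, c(list(empty_trace()), steps)),
                 ori_val_acc, val_acc_min, counter_delta(before))
  })
}

# L1 norm of each removal unit's incoming weights (bias excluded).
unit_magnitudes <- function(model, layer) {
  lay <- model$layers[[layer]]
  if (lay$kind == "dense") {
    colSums(abs(lay$W))
  } else {
    apply(abs(lay$W), 4L, sum)
  }
}
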