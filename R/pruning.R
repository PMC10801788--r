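# Multi-phase structured pruning: the jump schedule (far subphase 1, far
# subphase 2) and the greedy-random near phase, driven by jgrs().

#' Pruning midpoint of a layer
#'
#' The batch size of units cut from a hidden layer during the far phase:
#' `max(floor((unit_count - mu) / 2), 1)`, i.e. half the distance from the
#' current width to the layer's minimum allowed width, never less than one.
#'
#' @param unit_count Current number of removal units in the layer (>= 1).
#' @param mu Minimum unit count for the layer (>= 1).
#' @return Positive integer.
#' @export
pruning_midpoint <- function(unit_count, mu) {
  if (any(unit_count < 1) || any(mu < 1)) {
    stop_jgrs("unit_count and mu must be >= 1", "jgrs_config_error")
  }
  pmax(floor((unit_count - mu) / 2), 1)
}

#' Compression rate of a pruning stage
#'
#' The number of removal units eliminated between successive
#' retrain-and-validate events: the sum of all layers' midpoints in far
#' subphase 1, one layer's midpoint in far subphase 2, and 1 in the near
#' phase.
#'
#' @param stage `"far1"`, `"far2"` or `"near"`.
#' @param model A `jgrs_model` (or anything [hidden_units()] accepts).
#' @param mucv Minimum unit-count vector, one entry per hidden layer.
#' @param layer Hidden-layer index; required for `"far2"`.
#' @return Positive integer.
#' @export
stage_compression_rate <- function(stage = c("far1", "far2", "near"),
                                   model, mucv, layer = NULL) {
  stage <- match.arg(stage)
  if (stage == "near") return(1L)
  units <- hidden_units(model)
  check_mucv(mucv, length(units))
  if (stage == "far1") {
    prunable <- units > mucv
    return(as.integer(sum(pruning_midpoint(units[prunable], mucv[prunable]))))
  }
  if (is.null(layer)) {
    stop_jgrs("`layer` is required for stage \"far2\"", "jgrs_config_error")
  }
  as.integer(pruning_midpoint(units[layer], mucv[layer]))
}

check_mucv <- function(mucv, nh) {
  if (length(mucv) != nh || any(mucv < 1) || any(mucv != round(mucv))) {
    stop_jgrs("`mucv` must hold one positive integer per hidden layer",
              "jgrs_config_error")
  }
  invisible(as.integer(mucv))
}

#' Randomly remove units from one layer
#'
#' Samples `n` units uniformly without replacement from hidden layer `layer`
#' and removes them via [remove_units()]. The removed indices are attached as
#' attribute `"removed_units"`.
#'
#' @param model A `jgrs_model`.
#' @param layer Hidden-layer index.
#' @param n Number of units to cut (must leave at least one unit).
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return The cut `jgrs_model`.
#' @export
random_cut_units <- function(model, layer, n, seed = NULL) {
  uc <- unit_count_layer(model, layer)
  if (n > uc - 1L) {
    stop_jgrs("cannot cut that many units from the layer", "jgrs_structure_error")
  }
  idx <- with_seed(seed, sort(sample.int(uc, n)))
  out <- remove_units(model, layer, idx)
  attr(out, "removed_units") <- idx
  out
}

#' Pruning configuration
#'
#' @param mucv Minimum unit-count vector (one positive integer per hidden
#'   layer); the hard floor below which no layer is pruned.
#' @param tolerance Accuracy-drop tolerance in `(0, 1]`: the minimum
#'   acceptable validation accuracy is `tolerance * OriValAcc`. Default
#'   0.985.
#' @param attempts Integer triple: attempts for far subphase 1, far subphase
#'   2, and the near phase. Default `c(3, 3, 3)`.
#' @param seed Master seed for the run.
#' @param train_cfg A [train_config()] used for all retraining.
#' @return A `pruning_config` list.
#' @export
pruning_config <- function(mucv, tolerance = 0.985, attempts = c(3L, 3L, 3L),
                           seed = 1L, train_cfg = train_config()) {
  if (any(mucv < 1) || any(mucv != round(mucv))) {
    stop_jgrs("`mucv` entries must be positive integers", "jgrs_config_error")
  }
  if (tolerance <= 0 || tolerance > 1) {
    stop_jgrs("`tolerance` must be in (0, 1]", "jgrs_config_error")
  }
  if (length(attempts) != 3L || any(attempts < 0)) {
    stop_jgrs("`attempts` must be three non-negative integers",
              "jgrs_config_error")
  }
  structure(list(mucv = as.integer(mucv), tolerance = tolerance,
                 attempts = as.integer(attempts), seed = seed,
                 train_cfg = train_cfg),
            class = "pruning_config")
}

# ---- trace / result helpers -------------------------------------------------

trace_row <- function(stage, round, layer, unit_indices, cr, retrained,
                      val_acc, accepted) {
  data.frame(stage = stage, round = round,
             layer = if (is.null(layer)) NA_integer_ else layer,
             units_cut = length(unit_indices),
             unit_indices = paste(unit_indices, collapse = ";"),
             cr = cr, retrained = retrained, val_acc = val_acc,
             accepted = accepted, stringsAsFactors = FALSE)
}

empty_trace <- function() {
  trace_row("none", 0L, NULL, integer(0), 0L, FALSE, NA_real_, FALSE)[0, ]
}

prune_result <- function(model, accuracy, trace, ori_val_acc, val_acc_min,
                         counters, runtime = NA_real_) {
  structure(
    list(model = model, accuracy = accuracy,
         n_flops = flop_count(model), n_params = param_count(model),
         trace = trace, ori_val_acc = ori_val_acc, val_acc_min = val_acc_min,
         counters = counters, runtime = runtime),
    class = "prune_result"
  )
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf(
    "<prune_result> hidden [%s]; acc %.4f (floor %.4f); %d params, %d FLOPs\n",
    paste(hidden_units(x$model), collapse = ","), x$accuracy, x$val_acc_min,
    x$n_params, x$n_flops))
  cat(sprintf("  %d trace steps; %d fine-tune, %d validate calls\n",
              nrow(x$trace), x$counters$fine_tune, x$counters$validate))
  invisible(x)
}

counter_delta <- function(before) {
  after <- call_counters()
  list(train = after$train - before$train,
       fine_tune = after$fine_tune - before$fine_tune,
       validate = after$validate - before$validate)
}

# ---- far subphase 1 ---------------------------------------------------------

#' Far subphase 1: jump across whole-network sweeps
#'
#' Repeatedly cuts `midpoint(lambda)` units from every still-prunable hidden
#' layer in a single sweep, then retrains once and validates once. A sweep is
#' accepted iff the resulting validation accuracy stays at or above
#' `val_acc_min`; the first rejected sweep (or reaching the minimum
#' structure) ends the subphase, returning the last accepted model.
#'
#' @param model A trained `jgrs_model`.
#' @param train_data,val_data `data_pair` splits for retraining/validation.
#' @param mucv Minimum unit-count vector.
#' @param val_acc_min Minimum acceptable validation accuracy.
#' @param train_cfg A [train_config()].
#' @param seed Optional seed for this call.
#' @return A `prune_result`.
#' @export
far_subphase_1 <- function(model, train_data, val_data, mucv, val_acc_min,
                           train_cfg = train_config(), seed = NULL) {
  mucv <- check_mucv(mucv, n_hidden(model))
  before <- call_counters()
  with_seed(seed, {
    ori_val_acc <- validate(model, val_data)
    m_start <- model
    last_val_acc <- ori_val_acc
    val_acc <- ori_val_acc
    steps <- list()
    round <- 0L
    while (val_acc >= val_acc_min) {
      ims <- m_start
      min_struct_reached <- TRUE
      cut_idx <- integer(0)
      for (lam in seq_along(mucv)) {
        uc <- unit_count_layer(ims, lam)
        if (uc > mucv[lam]) {
          min_struct_reached <- FALSE
          ud <- pruning_midpoint(uc, mucv[lam])
          ims <- random_cut_units(ims, lam, ud)
          cut_idx <- c(cut_idx, attr(ims, "removed_units"))
        }
      }
      if (min_struct_reached) {
        val_acc <- 0
      } else {
        round <- round + 1L
        ims <- fine_tune(ims, train_data, train_cfg)
        val_acc <- validate(ims, val_data)
        accepted <- val_acc >= val_acc_min
        steps[[round]] <- trace_row("far1", round, NULL, cut_idx,
                                    length(cut_idx), TRUE, val_acc, accepted)
        if (accepted) {
          last_val_acc <- val_acc
          m_start <- ims
        }
      }
    }
    prune_result(m_start, last_val_acc,
                 do.call(rbind, c(list(empty_trace()), steps)),
                 ori_val_acc, val_acc_min, counter_delta(before))
  })
}

# ---- far subphase 2 ---------------------------------------------------------

#' Far subphase 2: per-layer midpoint candidates, greedy selection
#'
#' Each round builds one candidate per prunable layer by cutting that layer's
#' midpoint from the current model, retrains and validates every candidate,
#' and greedily keeps the candidate with maximum validation accuracy (lowest
#' layer index wins ties). The round is accepted iff that maximum stays at or
#' above `val_acc_min`.
#'
#' @inheritParams far_subphase_1
#' @return A `prune_result`.
#' @export
far_subphase_2 <- function(model, train_data, val_data, mucv, val_acc_min,
                           train_cfg = train_config(), seed = NULL) {
  candidate_phase(model, train_data, val_data, mucv, val_acc_min, train_cfg,
                  seed, stage = "far2")
}

#' Near-phase greedy random selection (GRS)
#'
#' Identical control flow to [far_subphase_2()] but each candidate removes
#' exactly one randomly selected unit from its layer (compression rate 1):
#' candidates are chosen at random, selection among candidates is greedy by
#' validation accuracy. Iterates until a round is rejected or every layer
#' reaches its minimum unit count.
#'
#' @inheritParams far_subphase_1
#' @return A `prune_result`.
#' @export
grs_near_phase <- function(model, train_data, val_data, mucv, val_acc_min,
                           train_cfg = train_config(), seed = NULL) {
  candidate_phase(model, train_data, val_data, mucv, val_acc_min, train_cfg,
                  seed, stage = "near")
}

candidate_phase <- function(model, train_data, val_data, mucv, val_acc_min,
                            train_cfg, seed, stage) {
  mucv <- check_mucv(mucv, n_hidden(model))
  before <- call_counters()
  with_seed(seed, {
    ori_val_acc <- validate(model, val_data)
    m_start <- model
    last_val_acc <- ori_val_acc
    max_val_acc <- ori_val_acc
    steps <- list()
    round <- 0L
    while (max_val_acc >= val_acc_min) {
      cand_models <- list()
      cand_accs <- numeric(0)
      cand_layers <- integer(0)
      cand_idx <- list()
      for (lam in seq_along(mucv)) {
        uc <- unit_count_layer(m_start, lam)
        if (uc > mucv[lam]) {
          ud <- if (stage == "far2") pruning_midpoint(uc, mucv[lam]) else 1L
          ims <- random_cut_units(m_start, lam, ud)
          removed <- attr(ims, "removed_units")
          ims <- fine_tune(ims, train_data, train_cfg)
          acc <- validate(ims, val_data)
          k <- length(cand_models) + 1L
          cand_models[[k]] <- ims
          cand_accs[k] <- acc
          cand_layers[k] <- lam
          cand_idx[[k]] <- removed
        }
      }
      if (length(cand_accs) == 0L) {
        max_val_acc <- 0
      } else {
        max_val_acc <- max(cand_accs)
        pick <- which.max(cand_accs) # lowest layer index wins ties
        accepted <- max_val_acc >= val_acc_min
        round <- round + 1L
        steps[[round]] <- trace_row(stage, round, cand_layers[pick],
                                    cand_idx[[pick]],
                                    length(cand_idx[[pick]]), TRUE,
                                    max_val_acc, accepted)
        if (accepted) {
          last_val_acc <- max_val_acc
          m_start <- cand_models[[pick]]
        }
      }
    }
    prune_result(m_start, last_val_acc,
                 do.call(rbind, c(list(empty_trace()), steps)),
                 ori_val_acc, val_acc_min, counter_delta(before))
  })
}

# ---- driver -----------------------------------------------------------------

#' Jump greedy-random-selection structured pruning (JGRS)
#'
#' The full multi-phase schedule. The validation-accuracy floor
#' `ValAcc_min = OriValAcc * tolerance` is computed once from the input
#' model, then far subphase 1, far subphase 2 and the near-phase GRS are run
#' `attempts[1]`, `attempts[2]` and `attempts[3]` times respectively, each
#' attempt chaining on the model produced by the previous one.
#'
#' @param model A trained `jgrs_model`.
#' @param train_data,val_data `data_pair` splits.
#' @param config A [pruning_config()].
#' @return A `prune_result` with the merged trace of all stages. With all
#'   attempts zero the input model is returned unchanged with its counts.
#' @export
jgrs <- function(model, train_data, val_data, config) {
  if (!inherits(config, "pruning_config")) {
    stop_jgrs("`config` must be a pruning_config", "jgrs_config_error")
  }
  mucv <- check_mucv(config$mucv, n_hidden(model))
  before <- call_counters()
  t0 <- proc.time()[["elapsed"]]
  with_seed(config$seed, {
    ori_val_acc <- validate(model, val_data)
    val_acc_min <- ori_val_acc * config$tolerance
    acc <- ori_val_acc
    m <- model
    traces <- list(empty_trace())
    stage_fun <- list(far_subphase_1, far_subphase_2, grs_near_phase)
    for (stage_i in 1:3) {
      n_att <- config$attempts[stage_i]
      for (a in seq_len(n_att)) {
        res <- stage_fun[[stage_i]](m, train_data, val_data, mucv,
                                    val_acc_min, config$train_cfg)
        m <- res$model
        acc <- res$accuracy
        if (nrow(res$trace)) {
          res$trace$attempt <- a
          traces[[length(traces) + 1L]] <- res$trace
        }
      }
    }
    trace <- do.call(rbind, c(list(cbind(empty_trace(), attempt = integer(0))),
                              traces[-1]))
    prune_result(m, acc, trace, ori_val_acc = ori_val_acc,
                 val_acc_min = val_acc_min,
                 counters = counter_delta(before),
                 runtime = proc.time()[["elapsed"]] - t0)
  })
}
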