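# Pruning-method comparison metrics: signed, original-normalized differences
# between the GRS and JGRS pruned models, and the runtime ratio.

#' Accuracy-loss difference between GRS and JGRS
#'
#' `(acc_g - acc_j) / acc_o`, signed: positive means JGRS performed worse
#' than GRS on that dataset; negative means JGRS performed better.
#'
#' @param acc_g,acc_j Accuracy of the GRS- and JGRS-pruned models.
#' @param acc_o Accuracy of the original (unpruned) model; must be nonzero.
#' @return Signed real number.
#' @export
al_difference <- function(acc_g, acc_j, acc_o) {
  normalized_difference(acc_g, acc_j, acc_o)
}

#' FLOP- and parameter-count-improvement differences
#'
#' Same form as [al_difference()] with counts in place of accuracies:
#' `(count_g - count_j) / count_o`. Positive values mean the JGRS model is
#' smaller (better) than the GRS model.
#'
#' @param count_g,count_j FLOP or parameter counts of the pruned models.
#' @param count_o Count of the original model; must be nonzero.
#' @return Signed real number.
#' @export
fci_difference <- function(count_g, count_j, count_o) {
  normalized_difference(count_g, count_j, count_o)
}

#' @rdname fci_difference
#' @export
pci_difference <- function(count_g, count_j, count_o) {
  normalized_difference(count_g, count_j, count_o)
}

normalized_difference <- function(g, j, o) {
  if (any(o == 0)) {
    stop_jgrs("original-model reference value is zero", "jgrs_config_error")
  }
  (g - j) / o
}

#' Runtime ratio between GRS and JGRS
#'
#' `runtime_g / runtime_j`; values above 1 mean JGRS was faster.
#'
#' @param runtime_g,runtime_j Wall-clock pruning times; `runtime_j` must be
#'   positive.
#' @return Positive real number.
#' @export
time_ratio <- function(runtime_g, runtime_j) {
  if (any(runtime_j <= 0)) {
    stop_jgrs("`runtime_j` must be positive", "jgrs_config_error")
  }
  runtime_g / runtime_j
}

#' Percent of the initial count retained by a pruned model
#'
#' @param final,initial Counts after and before pruning.
#' @return Percentage (e.g. `27.80` for 2410 of 8669).
#' @export
percent_of_initial <- function(final, initial) {
  if (any(initial == 0)) {
    stop_jgrs("initial count is zero", "jgrs_config_error")
  }
  100 * final / initial
}

#' Summarize a method-comparison experiment
#'
#' Takes per-run records (one row per method x dataset, averaged over trials
#' beforehand or not) and reports the min/max/avg over datasets of the
#' accuracy-loss, FLOP-count and parameter-count differences and of the
#' runtime ratio between the two compared methods. Datasets missing either
#' compared method or the original-model row are excluded with a warning.
#'
#' @param records Data frame with columns `method` (`"original"` plus method
#'   names), `dataset`, `accuracy`, `flops`, `params`, `runtime`.
#' @param method_g,method_j The two methods compared (defaults `"grs"`,
#'   `"jgrs"`).
#' @return A `comparison_summary` data frame: one row per metric with
#'   columns `metric`, `min`, `max`, `avg`, `n_datasets`.
#' @export
summarize_comparison <- function(records, method_g = "grs", method_j = "jgrs") {
  needed <- c("method", "dataset", "accuracy", "flops", "params", "runtime")
  if (!all(needed %in% names(records))) {
    stop_jgrs("records are missing required columns", "jgrs_data_error")
  }
  agg <- stats::aggregate(records[c("accuracy", "flops", "params", "runtime")],
                          by = records[c("method", "dataset")], FUN = mean)
  datasets <- unique(agg$dataset)
  al <- fci <- pci <- tr <- numeric(0)
  used <- character(0)
  for (d in datasets) {
    g <- agg[agg$dataset == d & agg$method == method_g, ]
    j <- agg[agg$dataset == d & agg$method == method_j, ]
    o <- agg[agg$dataset == d & agg$method == "original", ]
    if (nrow(g) != 1L || nrow(j) != 1L || nrow(o) != 1L) {
      warning(sprintf("dataset '%s' lacks a complete method triple; excluded", d))
      next
    }
    al <- c(al, al_difference(g$accuracy, j$accuracy, o$accuracy))
    fci <- c(fci, fci_difference(g$flops, j$flops, o$flops))
    pci <- c(pci, pci_difference(g$params, j$params, o$params))
    tr <- c(tr, time_ratio(g$runtime, j$runtime))
    used <- c(used, d)
  }
  if (length(used) == 0L) {
    stop_jgrs("no dataset has both methods and an original-model record",
              "jgrs_data_error")
  }
  mk <- function(metric, v) {
    data.frame(metric = metric, min = min(v), max = max(v), avg = mean(v),
               n_datasets = length(v))
  }
  out <- rbind(mk("AL_difference", al), mk("FCI_difference", fci),
               mk("PCI_difference", pci), mk("Time_ratio", tr))
  class(out) <- c("comparison_summary", class(out))
  out
}

#' Per-model pruning summary row
#'
#' Mirrors the per-model reporting style of pruning experiments: accuracy
#' with relative loss percentage, and FLOP/parameter counts as a percentage
#' of the initial model. "Lost" percentages are relative
#' (`(orig - pruned) / orig`).
#'
#' @param label Row label (model or method name).
#' @param result A `prune_result`.
#' @param original The original `jgrs_model` before pruning.
#' @param test_acc,ori_test_acc Optional test accuracies of pruned and
#'   original model.
#' @return One-row data frame.
#' @export
pruning_summary_row <- function(label, result, original,
                                test_acc = NA_real_, ori_test_acc = NA_real_) {
  data.frame(
    model = label,
    test_acc = test_acc,
    test_acc_lost_pct = 100 * (ori_test_acc - test_acc) / ori_test_acc,
    val_acc = result$accuracy,
    val_acc_lost_pct = 100 * (result$ori_val_acc - result$accuracy) /
      result$ori_val_acc,
    flops = result$n_flops,
    flops_pct_of_initial = percent_of_initial(result$n_flops,
                                              flop_count(original)),
    params = result$n_params,
    params_pct_of_initial = percent_of_initial(result$n_params,
                                               param_count(original)),
    prune_time_s = result$runtime)
}
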