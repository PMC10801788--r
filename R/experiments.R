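# Canned experiments: single-method pruning runs, the JGRS-vs-GRS method
# comparison, and the multi-phase RRS sensitivity trace. These are the
# programmatic entry points behind the command-line script in inst/cli.

#' Train a model and prune it with one method
#'
#' Trains an initialized model on the dataset's training split, then runs the
#' selected pruning method. `method = "none"` performs an identity run that
#' reports the original model's counts.
#'
#' @param dataset A `labeled_dataset`; if it has no split, an 8:1:1 split is
#'   drawn from the run seed.
#' @param spec A [model_spec()] for the input overparameterized model.
#' @param method `"jgrs"`, `"grs"`, `"nwm"`, `"rrs"` or `"none"`.
#' @param config A [pruning_config()]; its `mucv`, `tolerance`, `attempts`,
#'   `seed` and `train_cfg` govern the run.
#' @param out_dir Optional directory; if given, the step trace (CSV), a run
#'   summary (JSON) and the pruned model (RDS plus spec sidecar JSON) are
#'   written there.
#' @return A list: `result` (`prune_result`, or RRS trace data frame),
#'   `record` (one-row data frame of method, accuracy, counts, runtime,
#'   fine-tune calls), `model0` (the trained input model), `ori_test_acc`.
#' @export
run_prune <- function(dataset, spec, method = c("jgrs", "grs", "nwm", "rrs",
                                                "none"),
                      config, out_dir = NULL) {
  method <- match.arg(method)
  seeds <- child_seeds(config$seed, 4L)
  if (is.null(dataset$split)) dataset <- split_8_1_1(dataset, seeds[[1]])
  tr <- dataset_split(dataset, "train")
  va <- dataset_split(dataset, "validation")
  te <- dataset_split(dataset, "test")
  model0 <- build_model(spec, seed = seeds[[2]])
  model0 <- with_seed(seeds[[3]], train_model(model0, tr, config$train_cfg))
  ori_val_acc <- validate(model0, va)
  ori_test_acc <- validate(model0, te)
  t0 <- proc.time()[["elapsed"]]
  before <- call_counters()
  run_cfg <- config
  run_cfg$seed <- seeds[[4]]
  result <- switch(
    method,
    jgrs = jgrs(model0, tr, va, run_cfg),
    grs = grs_near_phase(model0, tr, va, run_cfg$mucv,
                         ori_val_acc * run_cfg$tolerance,
                         run_cfg$train_cfg, seed = run_cfg$seed),
    nwm = nwm_prune(model0, tr, va, run_cfg$mucv,
                    tolerance = run_cfg$tolerance,
                    train_cfg = run_cfg$train_cfg, seed = run_cfg$seed),
    rrs = rrs_prune_trace(model0, tr, va, run_cfg$mucv,
                          tolerance = run_cfg$tolerance,
                          train_cfg = run_cfg$train_cfg,
                          seed = run_cfg$seed, test_data = te),
    none = prune_result(model0, ori_val_acc, empty_trace(), ori_val_acc,
                        ori_val_acc * run_cfg$tolerance,
                        counter_delta(before))
  )
  runtime <- proc.time()[["elapsed"]] - t0
  if (inherits(result, "prune_result")) {
    result$runtime <- runtime
    record <- data.frame(
      method = method,
      accuracy = result$accuracy,
      test_accuracy = validate(result$model, te),
      flops = result$n_flops, params = result$n_params,
      runtime = runtime, fine_tune_calls = result$counters$fine_tune)
  } else {
    record <- data.frame(method = method, accuracy = NA_real_,
                         test_accuracy = NA_real_, flops = NA_real_,
                         params = NA_real_, runtime = runtime,
                         fine_tune_calls = counter_delta(before)$fine_tune)
  }
  out <- list(result = result, record = record, model0 = model0,
              ori_val_acc = ori_val_acc, ori_test_acc = ori_test_acc)
  if (!is.null(out_dir)) write_run_artifacts(out, method, out_dir)
  out
}

write_run_artifacts <- function(run, method, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  result <- run$result
  if (inherits(result, "prune_result")) {
    utils::write.csv(result$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(method = method, accuracy = result$accuracy,
           ori_val_acc = result$ori_val_acc, val_acc_min = result$val_acc_min,
           n_flops = result$n_flops, n_params = result$n_params,
           hidden_units = hidden_units(result$model),
           counters = result$counters, runtime = result$runtime),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    saveRDS(result$model, file.path(out_dir, "pruned_model.rds"))
    write_model_spec_json(result$model$spec,
                          file.path(out_dir, "pruned_model_spec.json"))
  } else {
    utils::write.csv(result, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Compare pruning methods over datasets and trials
#'
#' Runs each method on each dataset for `trials` independent trials (each
#' trial re-splits, re-initializes and re-trains the input model under a
#' child seed), records accuracy, counts, runtime and fine-tune calls, and
#' summarizes JGRS against GRS.
#'
#' @param datasets Named list of `labeled_dataset` objects.
#' @param spec A [model_spec()].
#' @param methods Methods to run (default `c("jgrs", "grs")`).
#' @param trials Trials per method and dataset.
#' @param config A [pruning_config()].
#' @param out_dir Optional directory for `records.csv` and `summary.json`.
#' @return A list: `records` (one row per method x dataset x trial, plus the
#'   original-model rows) and `summary` (a `comparison_summary`, or `NULL`
#'   when jgrs and grs are not both present).
#' @export
run_compare <- function(datasets, spec, methods = c("jgrs", "grs"),
                        trials = 1L, config, out_dir = NULL) {
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("d", seq_along(datasets))
  }
  rows <- list()
  seeds <- child_seeds(config$seed, length(datasets) * trials)
  si <- 0L
  for (d in names(datasets)) {
    for (tri in seq_len(trials)) {
      si <- si + 1L
      trial_cfg <- config
      trial_cfg$seed <- seeds[[si]]
      for (m in methods) {
        run <- run_prune(datasets[[d]], spec, m, trial_cfg)
        rec <- run$record
        rec$dataset <- d
        rec$trial <- tri
        rows[[length(rows) + 1L]] <- rec
        if (m == methods[1]) {
          rows[[length(rows) + 1L]] <- data.frame(
            method = "original", accuracy = run$ori_val_acc,
            test_accuracy = run$ori_test_acc,
            flops = flop_count(run$model0), params = param_count(run$model0),
            runtime = run$record$runtime, fine_tune_calls = 0L,
            dataset = d, trial = tri)
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  summary <- if (all(c("jgrs", "grs") %in% methods)) {
    summarize_comparison(records)
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    if (!is.null(summary)) {
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           digits = NA)
    }
  }
  list(records = records, summary = summary)
}

#' Multi-phase sensitivity trace experiment
#'
#' Trains an MLP (default hidden structure 16x16x16) on the dataset and runs
#' the RRS random-walk pruning probe down to the minimum structure (default
#' 2x2x2) with a loose tolerance of 0.5 and three retrain-validate
#' evaluations per candidate structure, recording mean validation and test
#' accuracy at every removal step. The resulting trace exhibits the far/near
#' phase phenomenon: flat accuracy while the model is overparameterized, a
#' drop as it approaches the minimum structure.
#'
#' @param dataset A `labeled_dataset`.
#' @param hidden Hidden widths of the probe MLP.
#' @param mucv Minimum unit-count vector.
#' @param tolerance RRS tolerance (default 0.5).
#' @param evals_per_structure Retrain-validate repetitions per candidate.
#' @param train_cfg A [train_config()].
#' @param seed Master seed.
#' @param out_dir Optional directory for `phase_trace.csv`.
#' @return The RRS trace data frame (42 steps for the defaults).
#' @export
run_phase_trace <- function(dataset, hidden = c(16L, 16L, 16L),
                            mucv = c(2L, 2L, 2L), tolerance = 0.5,
                            evals_per_structure = 3L,
                            train_cfg = train_config(), seed = 1L,
                            out_dir = NULL) {
  seeds <- child_seeds(seed, 4L)
  if (is.null(dataset$split)) dataset <- split_8_1_1(dataset, seeds[[1]])
  tr <- dataset_split(dataset, "train")
  va <- dataset_split(dataset, "validation")
  te <- dataset_split(dataset, "test")
  spec <- mlp_spec(ncol(dataset$features), hidden)
  model0 <- build_model(spec, seed = seeds[[2]])
  model0 <- with_seed(seeds[[3]], train_model(model0, tr, train_cfg))
  trace <- rrs_prune_trace(model0, tr, va, mucv, tolerance = tolerance,
                           evals_per_structure = evals_per_structure,
                           train_cfg = train_cfg, seed = seeds[[4]],
                           test_data = te)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trace, file.path(out_dir, "phase_trace.csv"),
                     row.names = FALSE)
  }
  trace
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS of the full model plus a JSON sidecar of its
#' spec.
#'
#' @param model A `jgrs_model`.
#' @param path Path to the `.rds` checkpoint; the sidecar is written next to
#'   it with extension `.spec.json`.
#' @return `load_model()` returns the `jgrs_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  write_model_spec_json(model$spec, paste0(sub("\\.rds$", "", path),
                                           ".spec.json"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}
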