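.jgrs_state <- new.env(parent = emptyenv())

#' Reset the global training/validation call counters
#'
#' The package counts every call to [train_model()], [fine_tune()] and
#' [validate()] in a package-global tally. Retraining counts are the
#' hardware-independent proxy for pruning cost: the jump mechanism's speedup
#' is measured as a reduction in fine-tune invocations rather than wall-clock
#' time.
#'
#' @return Invisibly, the zeroed counter list.
#' @seealso [call_counters()]
#' @export
reset_call_counters <- function() {
  assign("counters", list(train = 0L, fine_tune = 0L, validate = 0L),
         envir = .jgrs_state)
  invisible(get("counters", envir = .jgrs_state))
}

#' Read the global training/validation call counters
#'
#' @return A list with integer elements `train`, `fine_tune` and `validate`.
#' @export
call_counters <- function() {
  if (!exists("counters", envir = .jgrs_state)) reset_call_counters()
  get("counters", envir = .jgrs_state)
}

bump_counter <- function(which) {
  cnt <- call_counters()
  cnt[[which]] <- cnt[[which]] + 1L
  assign("counters", cnt, envir = .jgrs_state)
  invisible(cnt[[which]])
}
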