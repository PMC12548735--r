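#' Emit a pipeline log message
#'
#' Lightweight logger used by every pipeline stage. Silenced by setting
#' `options(rdrpscreen.verbose = FALSE)` (the test suite does this).
#'
#' @param ... passed to [sprintf()].
#' @return invisibly, the formatted message.
#' @keywords internal
rs_log <- function(...) {
  msg <- sprintf(...)
  if (isTRUE(getOption("rdrpscreen.verbose", TRUE))) {
    message("[rdrpscreen] ", msg)
  }
  invisible(msg)
}

#' Log the record funnel of a pipeline stage
#'
#' Every stage reports how many records went in and came out, mirroring the
#' screening funnel style of reporting (e.g. 92741 gated, 9249 after the RT
#' purge, 3560 final calls).
#'
#' @param stage stage name.
#' @param n_in,n_out record counts.
#' @keywords internal
rs_log_funnel <- function(stage, n_in, n_out) {
  rs_log("%s: %d records in -> %d records out", stage, n_in, n_out)
}
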