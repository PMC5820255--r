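#' @keywords internal
#' @noRd
cs_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cranioshape_error")))
}

#' @keywords internal
#' @noRd
stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x)))
    cs_abort(sprintf("%s must be finite", what), "cranioshape_input_error")
  invisible(x)
}
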