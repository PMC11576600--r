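# Internal helpers: classed conditions and small numeric utilities.

stop_validation <- function(msg, class = "intakeval_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "intakeval_error")))
}

stop_format <- function(msg) {
  stop_validation(msg, class = c("intakeval_format_error"))
}

# %||% is not in base before 4.4
`%|||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("`%s` must be a single finite number", name))
  }
}

#' The measurement method labels the toolkit recognises
#'
#' `"weighing"` is the reference (gold-standard) channel; the other three are
#' the estimation channels compared against it.
#'
#' @return Character vector of the four method labels.
#' @export
intake_methods <- function() {
  c("weighing", "ai", "image_visual", "direct_visual")
}

estimation_methods <- function() setdiff(intake_methods(), "weighing")
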