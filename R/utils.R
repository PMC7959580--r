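#' @keywords internal
"_PACKAGE"

## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Length of the longest run of identical elements
#' @noRd
max_run_length <- function(x) {
  if (length(x) == 0L) return(0L)
  max(rle(as.character(x))$lengths)
}

#' z-score a numeric vector; returns NULL if the column is constant
#' @noRd
zscore_or_null <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NULL)
  (x - mean(x)) / s
}

#' Balanced left/right side assignment of length n (counts differ by <= 1),
#' in random order.
#' @noRd
balanced_sides <- function(n) {
  half <- n %/% 2L
  sides <- c(rep("left", half), rep("right", n - half))
  sample(sides)
}

stop_param <- function(...) stop(..., call. = FALSE)
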