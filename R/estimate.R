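#' Point estimate with 95% confidence bounds
#'
#' Lightweight container for a named metric. Any of the three numbers may
#' be `NA`: a zero denominator anywhere in a metric's formula yields the
#' missing value rather than an error or an infinity, and a metric whose
#' point value is missing always has missing bounds.
#'
#' @param value,lower,upper Numeric scalars or `NA`.
#' @param label Metric name (e.g. `"Se"`).
#' @return An object of class `dx_estimate`.
#' @export
dx_estimate <- function(value, lower = NA_real_, upper = NA_real_,
                        label = "") {
  if (is.na(value)) {
    lower <- NA_real_
    upper <- NA_real_
  }
  structure(
    list(value = as.numeric(value), lower = as.numeric(lower),
         upper = as.numeric(upper), label = as.character(label)),
    class = "dx_estimate"
  )
}

dx_estimate_na <- function(label) dx_estimate(NA_real_, label = label)

#' @export
print.dx_estimate <- function(x, ...) {
  cat(sprintf("%s: %s (95%% CI: %s to %s)\n",
              if (nzchar(x$label)) x$label else "estimate",
              dx_round(x$value), dx_round(x$lower), dx_round(x$upper)))
  invisible(x)
}

#' @export
format.dx_estimate <- function(x, ...) {
  sprintf("%s (%s, %s)", dx_round(x$value), dx_round(x$lower),
          dx_round(x$upper))
}

#' Half-up decimal rounding for display
#'
#' Rounds to `decimals` places with ties going away from zero (so 0.8055
#' displays as "0.806"), and renders missing values as `"NA"`. All internal
#' computation in the package is full precision; rounding happens only at
#' this display/export boundary.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param decimals Non-negative integer number of decimal places.
#' @return Character vector of fixed-width decimal strings.
#' @examples
#' dx_round(c(0.80556, 1, NA))
#' @export
dx_round <- function(x, decimals = DX_DECIMALS) {
  stopifnot(is.numeric(decimals), decimals >= 0)
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) return("NA")
    scale <- 10^decimals
    # small guard so decimal halves stored just under .5 in binary round up
    r <- sign(v) * floor(abs(v) * scale + 0.5 + sqrt(.Machine$double.eps)) /
      scale
    sprintf("%.*f", as.integer(decimals), r)
  }, character(1))
}
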