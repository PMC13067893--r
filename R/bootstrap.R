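# Run code under a temporary RNG state. Seeded runs are bit-reproducible
# and leave the caller's RNG untouched; unseeded runs use (and advance)
# the session RNG, matching interactive behaviour.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Sensitivity of an empirical ROC curve at given specificities, by linear
# interpolation on the curve's upper envelope (max Se at duplicated Sp).
roc_se_at_sp <- function(curve, sp_grid) {
  approx(curve$specificity, curve$sensitivity, xout = sp_grid,
         ties = max, rule = 2)$y
}

#' Bootstrap confidence band for ROC sensitivity
#'
#' Pointwise 95% percentile band for sensitivity over a specificity grid,
#' from a stratified nonparametric bootstrap: in each iteration the
#' diseased and non-diseased groups are resampled separately with
#' replacement (so no replicate ever loses a class), the empirical ROC
#' curve is rebuilt, and sensitivity is read off at each grid specificity
#' by linear interpolation. The band is the 2.5th and 97.5th percentile
#' across iterations at each grid point. A replicate with constant scores
#' degenerates to the diagonal ROC and contributes accordingly; it never
#' raises an error.
#'
#' The band is a graphical uncertainty display: with a seed it is
#' bit-reproducible, without one it varies slightly across runs.
#'
#' @inheritParams dx_direction
#' @param direction `"auto"`, `"higher"` or `"lower"` (fixed before
#'   resampling so all replicates share the orientation of the full data).
#' @param n_boot Number of bootstrap iterations (default 5000).
#' @param sp_grid Specificity grid, default `seq(0, 1, by = 0.01)`.
#' @param seed Optional integer seed; `NULL` (default) for fresh
#'   randomness.
#' @return A data frame of class `dx_band` with columns `specificity`,
#'   `se_lower`, `se_upper`; `n_boot` and the seed are stored as
#'   attributes.
#' @export
dx_bootstrap_band <- function(scores, labels,
                              direction = c("auto", "higher", "lower"),
                              n_boot = 5000,
                              sp_grid = seq(0, 1, by = 0.01),
                              seed = NULL) {
  direction <- match.arg(direction)
  check_scores_labels(scores, labels)
  if (!is.numeric(n_boot) || length(n_boot) != 1 || n_boot < 1) {
    stop("n_boot must be a positive integer", call. = FALSE)
  }
  stopifnot(all(sp_grid >= 0), all(sp_grid <= 1), !is.unsorted(sp_grid))
  if (direction == "auto") direction <- dx_direction(scores, labels)
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  m <- length(cases)
  n <- length(controls)
  labs <- rep.int(c(1L, 0L), c(m, n))

  draws <- with_rng(seed, {
    vapply(seq_len(n_boot), function(i) {
      s <- c(cases[sample.int(m, m, replace = TRUE)],
             controls[sample.int(n, n, replace = TRUE)])
      roc_se_at_sp(dx_roc(s, labs, direction = direction), sp_grid)
    }, numeric(length(sp_grid)))
  })
  draws <- matrix(draws, nrow = length(sp_grid))
  qs <- apply(draws, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(specificity = sp_grid,
                    se_lower = qs[1, ], se_upper = qs[2, ])
  attr(out, "n_boot") <- as.integer(n_boot)
  attr(out, "seed") <- seed
  class(out) <- c("dx_band", "data.frame")
  out
}
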