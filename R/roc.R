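#' Detect the positivity direction of a quantitative test
#'
#' Decides whether larger or smaller scores indicate disease by comparing
#' group medians: `"higher"` (higher score is test-positive) when the
#' median score of the diseased group is greater than or equal to the
#' median of the non-diseased group, otherwise `"lower"`. The tie goes to
#' `"higher"`, the common convention for biomarkers.
#'
#' @param scores Numeric vector, no missing values.
#' @param labels 0/1 reference vector; both classes must be present.
#' @return `"higher"` or `"lower"`.
#' @export
dx_direction <- function(scores, labels) {
  check_scores_labels(scores, labels)
  if (median(scores[labels == 1]) >= median(scores[labels == 0])) {
    "higher"
  } else {
    "lower"
  }
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must not contain missing values", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must contain only 0 and 1 values", call. = FALSE)
  }
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both reference classes (0 and 1) must be present", call. = FALSE)
  }
  invisible(NULL)
}

#' Candidate classification thresholds for a score vector
#'
#' Midpoints between consecutive distinct sorted values, flanked by -Inf
#' and +Inf sentinels so the ROC curve always reaches both corners. With
#' midpoint thresholds a strict `>` rule and a `>=` rule classify the
#' observed data identically, removing any boundary ambiguity.
#'
#' @param scores Numeric vector of length >= 1.
#' @return Increasing numeric vector of length `#distinct - 1 + 2`.
#' @examples
#' dx_thresholds(c(1, 2, 4)) # -Inf 1.5 3.0 Inf
#' @export
dx_thresholds <- function(scores) {
  stopifnot(length(scores) >= 1, !anyNA(scores))
  v <- sort(unique(scores))
  mids <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

#' Dichotomize a quantitative score at a cutoff
#'
#' Under `direction = "higher"` an observation is test-positive when its
#' score is strictly greater than the cutoff; under `"lower"`, strictly
#' smaller. With midpoint cutoffs from [dx_thresholds()] the strictness is
#' immaterial for observed values.
#'
#' @param scores Numeric vector.
#' @param cutoff Finite numeric cutoff.
#' @param direction `"higher"` or `"lower"`.
#' @return Integer 0/1 vector of the same length.
#' @export
dx_dichotomize <- function(scores, cutoff, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(cutoff))
  if (direction == "higher") {
    as.integer(scores > cutoff)
  } else {
    as.integer(scores < cutoff)
  }
}

#' Empirical ROC curve over all candidate thresholds
#'
#' One (threshold, sensitivity, specificity) point per candidate
#' threshold, including the -Inf/+Inf sentinels, so the curve always
#' contains the corner points (Se = 1, Sp = 0) and (Se = 0, Sp = 1).
#'
#' @inheritParams dx_direction
#' @param direction `"auto"` (default, detected by [dx_direction()]),
#'   `"higher"` or `"lower"`.
#' @return A data frame of class `dx_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`, ordered by threshold, and the direction
#'   stored in `attr(, "direction")`.
#' @examples
#' set.seed(1)
#' dx_roc(c(rnorm(5, 2), rnorm(5)), rep(c(1, 0), each = 5))
#' @export
dx_roc <- function(scores, labels, direction = c("auto", "higher", "lower")) {
  direction <- match.arg(direction)
  check_scores_labels(scores, labels)
  if (direction == "auto") direction <- dx_direction(scores, labels)
  tt <- dx_thresholds(scores)
  cases <- sort(scores[labels == 1])
  controls <- sort(scores[labels == 0])
  m <- length(cases)
  n <- length(controls)
  # thresholds are midpoints, never equal to an observed value, so counts
  # of (score <= t) and (score < t) coincide and findInterval suffices
  if (direction == "higher") {
    se <- (m - findInterval(tt, cases)) / m
    sp <- findInterval(tt, controls) / n
  } else {
    se <- findInterval(tt, cases) / m
    sp <- (n - findInterval(tt, controls)) / n
  }
  out <- data.frame(threshold = tt, sensitivity = se, specificity = sp)
  attr(out, "direction") <- direction
  class(out) <- c("dx_roc", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the (1 - specificity, sensitivity) points of an
#' empirical ROC curve. Equals the Mann-Whitney probability that a random
#' diseased score exceeds a random non-diseased score, with ties counted
#' one half.
#'
#' @param curve A `dx_roc` object from [dx_roc()].
#' @return AUC in \[0, 1\].
#' @export
dx_auc <- function(curve) {
  stopifnot(inherits(curve, "dx_roc"))
  fpr <- 1 - curve$specificity
  se <- curve$sensitivity
  ord <- order(fpr, se)
  fpr <- fpr[ord]
  se <- se[ord]
  sum(diff(fpr) * (se[-1] + se[-length(se)]) / 2)
}

#' AUC with DeLong's nonparametric confidence interval
#'
#' Computes the Mann-Whitney AUC (ties one half) and its variance from
#' DeLong's placement values: for case i the placement is the fraction of
#' controls its score beats (ties half), and symmetrically for controls.
#' The variance is `var(case placements)/m + var(control placements)/n`
#' with sample variances, and the 95% interval `AUC +/- 1.96 * sd` is
#' clipped to \[0, 1\]. With fewer than two cases or two controls the
#' variance is undefined and the bounds are missing while the AUC is still
#' returned.
#'
#' @inheritParams dx_direction
#' @param direction `"auto"`, `"higher"` or `"lower"`; scores are oriented
#'   so that higher values indicate disease before computing placements.
#' @return A list of class `dx_auc_ci` with elements `auc`, `lower`,
#'   `upper`, `se` (standard error) and `method = "delong"`.
#' @export
dx_delong <- function(scores, labels,
                      direction = c("auto", "higher", "lower")) {
  direction <- match.arg(direction)
  check_scores_labels(scores, labels)
  if (direction == "auto") direction <- dx_direction(scores, labels)
  x <- if (direction == "higher") scores else -scores
  cases <- x[labels == 1]
  controls <- x[labels == 0]
  m <- length(cases)
  n <- length(controls)
  # midranks give placement values in O((m+n) log(m+n)):
  # rank among all minus rank within own group, scaled by the other group
  r_all <- rank(c(cases, controls))
  v10 <- (r_all[seq_len(m)] - rank(cases)) / n        # case placements
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(controls)) / m # control placements
  auc <- mean(v10)
  if (m < 2 || n < 2) {
    res <- list(auc = auc, lower = NA_real_, upper = NA_real_,
                se = NA_real_, method = "delong")
  } else {
    v <- var(v10) / m + var(v01) / n
    half <- DX_Z * sqrt(v)
    res <- list(auc = auc, lower = max(0, auc - half),
                upper = min(1, auc + half), se = sqrt(v),
                method = "delong")
  }
  class(res) <- "dx_auc_ci"
  res
}

#' @export
print.dx_auc_ci <- function(x, ...) {
  cat(dx_auc_label(x), "\n")
  invisible(x)
}

#' Optimal cutoff closest to the top-left ROC corner
#'
#' Among the finite candidate thresholds, selects the one minimizing the
#' Euclidean distance `d(t) = sqrt((1 - Se(t))^2 + (1 - Sp(t))^2)` between
#' the curve point (1 - Sp, Se) and the top-left corner (0, 1) of ROC
#' space. Ties are broken by highest sensitivity (favouring case
#' detection), then by smallest threshold, making the choice
#' deterministic.
#'
#' @inheritParams dx_auc
#' @return A list of class `dx_cutoff` with `threshold`, `sensitivity`,
#'   `specificity` and `distance`, or `NULL` when the curve has no finite
#'   threshold (constant scores).
#' @export
dx_optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "dx_roc"))
  fin <- curve[is.finite(curve$threshold), , drop = FALSE]
  if (nrow(fin) == 0) return(NULL)
  d <- sqrt((1 - fin$sensitivity)^2 + (1 - fin$specificity)^2)
  ord <- order(d, -fin$sensitivity, fin$threshold)
  best <- ord[1]
  structure(
    list(threshold = fin$threshold[best],
         sensitivity = fin$sensitivity[best],
         specificity = fin$specificity[best],
         distance = d[best]),
    class = "dx_cutoff"
  )
}

#' @export
print.dx_cutoff <- function(x, ...) {
  cat(sprintf("optimal cutoff %s (Se = %s, Sp = %s, distance %s)\n",
              dx_round(x$threshold), dx_round(x$sensitivity),
              dx_round(x$specificity), dx_round(x$distance)))
  invisible(x)
}
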