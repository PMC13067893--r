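#' Wilson score interval for a binomial proportion
#'
#' The Wilson interval behaves better than the Wald interval for small
#' samples and for proportions near 0 or 1: its bounds always lie inside
#' \[0, 1\] and it never collapses to zero width at p = 0 or 1. With
#' p = successes/n the bounds are
#' \deqn{\frac{p + z^2/2n \pm z\sqrt{p(1-p)/n + z^2/4n^2}}{1 + z^2/n}.}
#'
#' @param successes,n Counts with `0 <= successes <= n`.
#' @param z Standard normal quantile; fixed at 1.96 (95% two-sided).
#' @return Numeric `c(lower, upper)`, both in \[0, 1\]; `c(NA, NA)` when
#'   `n` is zero.
#' @examples
#' dx_wilson(58, 72)
#' dx_wilson(0, 10) # lower bound exactly 0
#' @export
dx_wilson <- function(successes, n, z = DX_Z) {
  if (is.na(n) || n == 0) return(c(lower = NA_real_, upper = NA_real_))
  stopifnot(successes >= 0, successes <= n, z > 0)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  # clamp: the bounds lie in [0,1] and enclose p algebraically; this only
  # absorbs one-ulp sqrt noise so p = 0 gives a lower bound of exactly 0
  # and the interval always contains the raw proportion
  c(lower = min(p, max(0, (centre - half) / denom)),
    upper = max(p, min(1, (centre + half) / denom)))
}

wilson_estimate <- function(successes, n, label) {
  if (is.na(n) || n == 0) return(dx_estimate_na(label))
  ci <- dx_wilson(successes, n)
  dx_estimate(successes / n, ci[["lower"]], ci[["upper"]], label)
}

#' Sensitivity, specificity and accuracy
#'
#' Sensitivity is the probability that a diseased individual tests
#' positive, `TP / (TP + FN)`; specificity the probability that a
#' non-diseased individual tests negative, `TN / (TN + FP)`; accuracy the
#' overall proportion of correct classifications, `(TP + TN) / N`. Each
#' carries a 95% Wilson interval. A zero denominator (e.g. no diseased
#' subjects for sensitivity) yields a missing estimate.
#'
#' @param cm A [dx_confusion()] object.
#' @return A [dx_estimate()].
#' @examples
#' cm <- dx_confusion(58, 15, 14, 26)
#' dx_sensitivity(cm)
#' dx_specificity(cm)
#' dx_accuracy(cm)
#' @export
dx_sensitivity <- function(cm) {
  stopifnot(inherits(cm, "dx_confusion"))
  wilson_estimate(cm$tp, cm$n_diseased, "Se")
}

#' @rdname dx_sensitivity
#' @export
dx_specificity <- function(cm) {
  stopifnot(inherits(cm, "dx_confusion"))
  wilson_estimate(cm$tn, cm$n_nondiseased, "Sp")
}

#' @rdname dx_sensitivity
#' @export
dx_accuracy <- function(cm) {
  stopifnot(inherits(cm, "dx_confusion"))
  wilson_estimate(cm$tp + cm$tn, cm$n, "Acc")
}

#' Predictive values at a user-supplied population prevalence
#'
#' Positive and negative predictive values computed from Bayes' theorem
#' using the estimated sensitivity and specificity together with a
#' population prevalence `pr` supplied by the user (the sample prevalence
#' is deliberately not used; study samples are rarely representative of
#' the target population):
#' \deqn{PPV = \frac{Se \cdot pr}{Se \cdot pr + (1-Sp)(1-pr)}, \quad
#'       NPV = \frac{Sp (1-pr)}{Sp (1-pr) + (1-Se) \, pr}.}
#'
#' The 95% bounds are propagated from the sensitivity and specificity
#' bounds by evaluating the Bayes expression at all four combinations of
#' interval limits and taking the minimum and maximum — a conservative,
#' distribution-free propagation suited to small samples. Because both
#' expressions are monotone non-decreasing in Se and in Sp, the extremes
#' are attained at the (lower, lower) and (upper, upper) combinations.
#'
#' @param se,sp [dx_estimate()]s for sensitivity and specificity. If either
#'   point value is missing both outputs are fully missing.
#' @param prevalence Disease prevalence, strictly between 0 and 1.
#' @return A list with elements `ppv` and `npv`, each a [dx_estimate()].
#' @examples
#' cm <- dx_confusion(58, 15, 14, 26)
#' dx_predictive_values(dx_sensitivity(cm), dx_specificity(cm), 0.1)
#' @export
dx_predictive_values <- function(se, sp, prevalence) {
  stopifnot(inherits(se, "dx_estimate"), inherits(sp, "dx_estimate"))
  check_prevalence(prevalence)
  if (is.na(se$value) || is.na(sp$value)) {
    return(list(ppv = dx_estimate_na("PPV"), npv = dx_estimate_na("NPV")))
  }
  ppv_fun <- function(s, p) {
    d <- s * prevalence + (1 - p) * (1 - prevalence)
    if (d == 0) NA_real_ else s * prevalence / d
  }
  npv_fun <- function(s, p) {
    d <- p * (1 - prevalence) + (1 - s) * prevalence
    if (d == 0) NA_real_ else p * (1 - prevalence) / d
  }
  combo <- function(fun) {
    vals <- c(fun(se$lower, sp$lower), fun(se$lower, sp$upper),
              fun(se$upper, sp$lower), fun(se$upper, sp$upper))
    if (anyNA(vals)) c(NA_real_, NA_real_) else range(vals)
  }
  ppv_b <- if (is.na(se$lower) || is.na(sp$lower)) c(NA_real_, NA_real_)
           else combo(ppv_fun)
  npv_b <- if (is.na(se$lower) || is.na(sp$lower)) c(NA_real_, NA_real_)
           else combo(npv_fun)
  ppv <- ppv_fun(se$value, sp$value)
  npv <- npv_fun(se$value, sp$value)
  list(ppv = dx_estimate(ppv, ppv_b[1], ppv_b[2], "PPV"),
       npv = dx_estimate(npv, npv_b[1], npv_b[2], "NPV"))
}

check_prevalence <- function(prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1 ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  invisible(prevalence)
}

#' Likelihood ratios with log-scale confidence intervals
#'
#' `LR+ = Se / (1 - Sp)` quantifies how much a positive result raises the
#' odds of disease; `LR- = (1 - Se) / Sp` how much a negative result
#' lowers them. The 95% intervals are computed on the log scale (Simel's
#' approach): for LR+ the standard error of `log LR+` is
#' `sqrt(1/TP - 1/(TP+FN) + 1/FP - 1/(FP+TN))`, and for LR- it is
#' `sqrt(1/FN - 1/(TP+FN) + 1/TN - 1/(FP+TN))`.
#'
#' A zero denominator makes the point estimate missing (e.g. LR+ for a
#' perfectly specific test); a zero cell entering a reciprocal of the
#' standard error makes the interval missing while the point estimate, if
#' defined, is kept (no continuity correction is applied).
#'
#' @inheritParams dx_sensitivity
#' @return A list with elements `lr_pos` and `lr_neg`, each a
#'   [dx_estimate()] (bounds set directly, so a missing interval does not
#'   blank a defined point value).
#' @examples
#' dx_likelihood_ratios(dx_confusion(58, 15, 14, 26))
#' @export
dx_likelihood_ratios <- function(cm) {
  stopifnot(inherits(cm, "dx_confusion"))
  se <- if (cm$n_diseased > 0) cm$tp / cm$n_diseased else NA_real_
  sp <- if (cm$n_nondiseased > 0) cm$tn / cm$n_nondiseased else NA_real_

  lr_one <- function(num, den, a, b, label) {
    # num/den are the ratio's numerator and denominator probabilities;
    # a, b the cell counts entering the reciprocals of the log-scale SE
    if (is.na(num) || is.na(den) || den == 0) return(dx_estimate_na(label))
    value <- num / den
    est <- dx_estimate(value, label = label)
    if (a > 0 && b > 0 && value > 0) {
      se_log <- sqrt(1 / a - 1 / cm$n_diseased +
                     1 / b - 1 / cm$n_nondiseased)
      est$lower <- exp(log(value) - DX_Z * se_log)
      est$upper <- exp(log(value) + DX_Z * se_log)
    }
    est
  }
  list(
    lr_pos = lr_one(se, 1 - sp, cm$tp, cm$fp, "LR+"),
    lr_neg = lr_one(1 - se, sp, cm$fn, cm$tn, "LR-")
  )
}

#' Youden index with a binomial-variance confidence interval
#'
#' `J = Se + Sp - 1` summarises discriminative ability on \[0, 1\] for a
#' useful test (0 = uninformative, 1 = perfect). Treating sensitivity and
#' specificity as independent binomial proportions, the variance of J is
#' the sum of their binomial variances, giving the 95% interval
#' `J +/- 1.96 * sqrt(Se(1-Se)/n_d + Sp(1-Sp)/n_nd)`. Bounds are reported
#' unclipped: a bound slightly outside \[0, 1\] is a faithful consequence
#' of the normal approximation, not an error.
#'
#' @inheritParams dx_sensitivity
#' @return A [dx_estimate()]; missing when either margin is empty.
#' @examples
#' dx_youden(dx_confusion(58, 15, 14, 26))
#' @export
dx_youden <- function(cm) {
  stopifnot(inherits(cm, "dx_confusion"))
  if (cm$n_diseased == 0 || cm$n_nondiseased == 0) {
    return(dx_estimate_na("J"))
  }
  se <- cm$tp / cm$n_diseased
  sp <- cm$tn / cm$n_nondiseased
  j <- se + sp - 1
  se_j <- sqrt(se * (1 - se) / cm$n_diseased +
               sp * (1 - sp) / cm$n_nondiseased)
  dx_estimate(j, j - DX_Z * se_j, j + DX_Z * se_j, "J")
}

#' All confusion-matrix performance indicators
#'
#' Computes sensitivity, specificity, accuracy, predictive values at the
#' supplied prevalence, likelihood ratios and the Youden index, each with
#' its 95% confidence interval, and assembles them in a fixed-order table
#' (Se, Sp, Acc, PPV, NPV, LR+, LR-, J). The ROC module appends an AUC row
#' for quantitative tests. Values are kept at full precision; use
#' [print()] or the writers for the three-decimal display.
#'
#' @inheritParams dx_sensitivity
#' @inheritParams dx_predictive_values
#' @return A data frame of class `dx_metrics` with columns `metric`,
#'   `estimate`, `lower`, `upper`, and the prevalence recorded in
#'   `attr(, "prevalence")`.
#' @examples
#' dx_metrics(dx_confusion(58, 15, 14, 26), prevalence = 0.1)
#' @export
dx_metrics <- function(cm, prevalence) {
  stopifnot(inherits(cm, "dx_confusion"))
  check_prevalence(prevalence)
  se <- dx_sensitivity(cm)
  sp <- dx_specificity(cm)
  pv <- dx_predictive_values(se, sp, prevalence)
  lr <- dx_likelihood_ratios(cm)
  ests <- list(se, sp, dx_accuracy(cm), pv$ppv, pv$npv,
               lr$lr_pos, lr$lr_neg, dx_youden(cm))
  out <- data.frame(
    metric = vapply(ests, `[[`, character(1), "label"),
    estimate = vapply(ests, `[[`, numeric(1), "value"),
    lower = vapply(ests, `[[`, numeric(1), "lower"),
    upper = vapply(ests, `[[`, numeric(1), "upper"),
    stringsAsFactors = FALSE
  )
  attr(out, "prevalence") <- prevalence
  class(out) <- c("dx_metrics", "data.frame")
  out
}

#' @export
print.dx_metrics <- function(x, ...) {
  disp <- data.frame(metric = x$metric,
                     estimate = dx_round(x$estimate),
                     lower = dx_round(x$lower),
                     upper = dx_round(x$upper))
  print.data.frame(disp, row.names = FALSE)
  cat(sprintf("assumed prevalence: %s\n", attr(x, "prevalence")))
  invisible(x)
}
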