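#' Full diagnostic-test evaluation for one test column
#'
#' Runs the complete analysis on cleaned paired vectors. For a
#' quantitative test: build the ROC curve, estimate the AUC with its
#' DeLong interval, select the closest-to-top-left cutoff, dichotomize at
#' that cutoff, cross-tabulate against the reference, compute all
#' indicators, and (optionally) the bootstrap sensitivity band. For a
#' qualitative (0/1) test the values are used as-is: no cutoff search or
#' band, and the AUC degenerates to `(Se + Sp) / 2`, still computed by the
#' same Mann-Whitney machinery with a DeLong interval.
#'
#' @param test_values Numeric test results (0/1 when qualitative).
#' @param ref_values 0/1 reference vector; both classes present.
#' @param test_kind `"quantitative"` or `"qualitative"`.
#' @param prevalence Population disease prevalence in (0, 1), used for the
#'   predictive values.
#' @param direction `"auto"`, `"higher"` or `"lower"` (quantitative only).
#' @param n_boot Bootstrap iterations for the sensitivity band; `0`
#'   disables the band.
#' @param seed Optional integer seed for the bootstrap band.
#' @return A list of class `dx_analysis` with elements `test_kind`,
#'   `direction`, `curve` (`dx_roc`), `auc` (`dx_auc_ci`), `cutoff`
#'   (`dx_cutoff` or `NULL`), `cm` (`dx_confusion`), `metrics`
#'   (`dx_metrics` with an AUC row appended), `band` (`dx_band` or
#'   `NULL`), and `prevalence`.
#' @examples
#' d <- dx_simulate(seed = 7)
#' fit <- dx_analyze(d$Test1, d$Disease, "quantitative", prevalence = 0.1,
#'                   n_boot = 50, seed = 7)
#' fit$metrics
#' @export
dx_analyze <- function(test_values, ref_values,
                       test_kind = c("quantitative", "qualitative"),
                       prevalence,
                       direction = c("auto", "higher", "lower"),
                       n_boot = 5000, seed = NULL) {
  test_kind <- match.arg(test_kind)
  direction <- match.arg(direction)
  check_prevalence(prevalence)
  check_scores_labels(test_values, ref_values)

  if (test_kind == "qualitative") {
    if (!all(test_values %in% c(0, 1))) {
      stop("For qualitative tests, the test variable must contain only 0 and 1 values.",
           call. = FALSE)
    }
    direction <- "higher"
    curve <- dx_roc(test_values, ref_values, direction = "higher")
    auc <- dx_delong(test_values, ref_values, direction = "higher")
    cutoff <- NULL
    band <- NULL
    cm <- dx_confusion_matrix(test_values, ref_values)
  } else {
    curve <- dx_roc(test_values, ref_values, direction = direction)
    direction <- attr(curve, "direction")
    auc <- dx_delong(test_values, ref_values, direction = direction)
    cutoff <- dx_optimal_cutoff(curve)
    if (is.null(cutoff)) {
      stop("the test variable is constant; no classification threshold exists",
           call. = FALSE)
    }
    test_bin <- dx_dichotomize(test_values, cutoff$threshold, direction)
    cm <- dx_confusion_matrix(test_bin, ref_values)
    band <- if (n_boot > 0) {
      dx_bootstrap_band(test_values, ref_values, direction = direction,
                        n_boot = n_boot, seed = seed)
    }
  }

  metrics <- dx_metrics(cm, prevalence)
  auc_row <- data.frame(metric = "AUC", estimate = auc$auc,
                        lower = auc$lower, upper = auc$upper,
                        stringsAsFactors = FALSE)
  metrics <- rbind(as.data.frame(metrics), auc_row)
  attr(metrics, "prevalence") <- prevalence
  class(metrics) <- c("dx_metrics", "data.frame")

  structure(
    list(test_kind = test_kind, direction = direction, curve = curve,
         auc = auc, cutoff = cutoff, cm = cm, metrics = metrics,
         band = band, prevalence = prevalence),
    class = "dx_analysis"
  )
}

#' @export
print.dx_analysis <- function(x, ...) {
  cat(sprintf("Diagnostic test evaluation (%s test, direction: %s)\n\n",
              x$test_kind, x$direction))
  print(x$cm)
  if (!is.null(x$cutoff)) {
    cat("\n")
    print(x$cutoff)
  }
  cat("\n")
  print(x$metrics)
  invisible(x)
}
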