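#' Confusion matrix of a binary test against the reference standard
#'
#' @param tp,fp,fn,tn Non-negative integer counts of true positives, false
#'   positives, false negatives and true negatives.
#' @return An object of class `dx_confusion`: a list with the four counts
#'   plus the diseased margin `n_diseased = tp + fn`, the non-diseased
#'   margin `n_nondiseased = tn + fp`, and the total `n`.
#' @seealso [dx_confusion_matrix()] to cross-tabulate 0/1 vectors.
#' @export
dx_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("confusion matrix counts must be non-negative integers",
         call. = FALSE)
  }
  if (sum(counts) < 1) {
    stop("confusion matrix must contain at least one observation",
         call. = FALSE)
  }
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         tn = as.integer(tn),
         n_diseased = as.integer(tp + fn),
         n_nondiseased = as.integer(tn + fp),
         n = as.integer(tp + fp + fn + tn)),
    class = "dx_confusion"
  )
}

#' Cross-tabulate a dichotomous test against the reference
#'
#' Counts TP (test 1, reference 1), FP (test 1, reference 0), FN (test 0,
#' reference 1) and TN (test 0, reference 0).
#'
#' @param test,ref Equal-length vectors of 0/1 values, no missing values.
#' @return A [dx_confusion()] object whose counts sum to `length(test)`.
#' @examples
#' dx_confusion_matrix(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
dx_confusion_matrix <- function(test, ref) {
  if (length(test) != length(ref)) {
    stop("test and reference vectors must have equal length", call. = FALSE)
  }
  if (length(test) < 1) stop("empty input", call. = FALSE)
  if (anyNA(test) || anyNA(ref)) {
    stop("test and reference vectors must not contain missing values",
         call. = FALSE)
  }
  if (!all(test %in% c(0, 1)) || !all(ref %in% c(0, 1))) {
    stop("test and reference vectors must contain only 0 and 1 values",
         call. = FALSE)
  }
  dx_confusion(tp = sum(test == 1 & ref == 1),
               fp = sum(test == 1 & ref == 0),
               fn = sum(test == 0 & ref == 1),
               tn = sum(test == 0 & ref == 0))
}

#' @export
print.dx_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(c("Test positive", "Test negative"),
                              c("Disease present", "Disease absent")))
  print(m)
  cat(sprintf("n = %d (%d diseased, %d non-diseased)\n",
              x$n, x$n_diseased, x$n_nondiseased))
  invisible(x)
}
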