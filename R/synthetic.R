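#' Simulate a diagnostic-test dataset
#'
#' Generates a dataset with the structure used throughout the package's
#' examples and tests: a binary `Disease` reference, a right-skewed
#' positive quantitative marker `Test1`, and a binary test `Test2` with
#' known operating characteristics.
#'
#' Per row: `Disease ~ Bernoulli(p_disease)`;
#' `Test1 | Disease = 1 ~ chi-square(df_diseased)` and
#' `Test1 | Disease = 0 ~ chi-square(df_nondiseased)` (chi-square scores
#' are strictly positive and right-skewed, a common shape for biomarker
#' concentrations); `Test2 | Disease = 1 ~ Bernoulli(binary_se)` and
#' `Test2 | Disease = 0 ~ Bernoulli(1 - binary_sp)`, so `binary_se` and
#' `binary_sp` are the true sensitivity and specificity of the binary
#' test. With the default degrees of freedom (3 for diseased vs 1.5 for
#' non-diseased) the quantitative marker discriminates moderately: the
#' population AUC, `P(chisq(3) > chisq(1.5))`, is 0.730 by numerical
#' integration.
#'
#' Note that `p_disease` is the sampling fraction of diseased subjects in
#' the dataset and is distinct from the population prevalence supplied to
#' [dx_metrics()] for predictive values; study samples are typically
#' enriched for disease relative to the target population.
#'
#' @param n Number of rows (>= 2).
#' @param p_disease Probability a row is diseased, in (0, 1).
#' @param df_diseased,df_nondiseased Chi-square degrees of freedom for
#'   `Test1` in the diseased / non-diseased groups; both > 0.
#' @param binary_se,binary_sp True sensitivity and specificity of
#'   `Test2`, each in (0, 1).
#' @param seed Optional integer seed for bit-reproducible output; `NULL`
#'   for fresh randomness.
#' @return A data frame with integer column `Disease`, numeric `Test1`,
#'   integer `Test2`, and `n` rows.
#' @examples
#' head(dx_simulate(n = 10, seed = 1))
#' @export
dx_simulate <- function(n = 113, p_disease = 0.64,
                        df_diseased = 3, df_nondiseased = 1.5,
                        binary_se = 0.9, binary_sp = 0.7,
                        seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("n must be an integer >= 2", call. = FALSE)
  }
  for (p in c(p_disease = p_disease, binary_se = binary_se,
              binary_sp = binary_sp)) {
    if (!is.numeric(p) || is.na(p) || p <= 0 || p >= 1) {
      stop("p_disease, binary_se and binary_sp must lie strictly between 0 and 1",
           call. = FALSE)
    }
  }
  if (df_diseased <= 0 || df_nondiseased <= 0) {
    stop("chi-square degrees of freedom must be positive", call. = FALSE)
  }
  with_rng(seed, {
    disease <- rbinom(n, 1, p_disease)
    test1 <- numeric(n)
    test1[disease == 1] <- rchisq(sum(disease == 1), df = df_diseased)
    test1[disease == 0] <- rchisq(sum(disease == 0), df = df_nondiseased)
    test2 <- integer(n)
    test2[disease == 1] <- rbinom(sum(disease == 1), 1, binary_se)
    test2[disease == 0] <- rbinom(sum(disease == 0), 1, 1 - binary_sp)
    data.frame(Disease = as.integer(disease), Test1 = test1,
               Test2 = as.integer(test2))
  })
}

#' Simulate a dataset and persist it as an .xlsx workbook
#'
#' Convenience wrapper: [dx_simulate()] then [dx_write_dataset()]. The
#' written workbook round-trips through [dx_read_xlsx()] and [dx_clean()]
#' without error (provided both disease classes were drawn).
#'
#' @inheritParams dx_simulate
#' @param path Output .xlsx path.
#' @return The simulated data frame, invisibly.
#' @export
dx_simulate_xlsx <- function(path, n = 113, p_disease = 0.64,
                             df_diseased = 3, df_nondiseased = 1.5,
                             binary_se = 0.9, binary_sp = 0.7,
                             seed = NULL) {
  data <- dx_simulate(n = n, p_disease = p_disease,
                      df_diseased = df_diseased,
                      df_nondiseased = df_nondiseased,
                      binary_se = binary_se, binary_sp = binary_sp,
                      seed = seed)
  dx_write_dataset(data, path)
  invisible(data)
}
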