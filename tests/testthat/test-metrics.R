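# The worked 2x2 table used throughout: 72 diseased (58 detected),
# 41 non-diseased (26 correctly negative).
cm_ref <- dx_confusion(58, 15, 14, 26)

test_that("Wilson interval matches hand-evaluated values and edge algebra", {
  expect_equal(dx_wilson(58, 72), c(lower = 0.699670, upper = 0.880486),
               tolerance = 1e-6)
  expect_equal(dx_wilson(26, 41), c(lower = 0.481204, upper = 0.764104),
               tolerance = 1e-6)
  # algebraic collapse at p = 0 and p = 1
  expect_identical(dx_wilson(0, 10)[["lower"]], 0)
  expect_identical(dx_wilson(10, 10)[["upper"]], 1)
  # zero denominator follows the NA rule
  expect_true(all(is.na(dx_wilson(0, 0))))
})

test_that("Wilson interval contains the proportion and stays in [0,1]", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:80, 1)
    s <- sample(0:n, 1)
    ci <- dx_wilson(s, n)
    p <- s / n
    expect_gte(p, ci[["lower"]])
    expect_lte(p, ci[["upper"]])
    expect_gte(ci[["lower"]], 0)
    expect_lte(ci[["upper"]], 1)
  }
})

test_that("Wilson interval converges to the Wald interval for large n", {
  n <- 1e6
  s <- 3e5
  p <- s / n
  wald <- p + c(-1, 1) * 1.96 * sqrt(p * (1 - p) / n)
  expect_equal(unname(dx_wilson(s, n)), wald, tolerance = 1e-5)
})

test_that("sensitivity, specificity and accuracy match direct arithmetic", {
  se <- dx_sensitivity(cm_ref)
  sp <- dx_specificity(cm_ref)
  acc <- dx_accuracy(cm_ref)
  expect_equal(se$value, 58 / 72)
  expect_equal(sp$value, 26 / 41)
  expect_equal(acc$value, 84 / 113)
  expect_equal(c(se$lower, se$upper), unname(dx_wilson(58, 72)))
  # perfect and degenerate tests
  perfect <- dx_confusion(10, 0, 0, 10)
  expect_equal(dx_sensitivity(perfect)$value, 1)
  expect_equal(dx_specificity(perfect)$value, 1)
  expect_equal(dx_accuracy(perfect)$value, 1)
  expect_equal(dx_accuracy(dx_confusion(0, 10, 10, 0))$value, 0)
  no_diseased <- dx_confusion(0, 5, 0, 5)
  expect_true(is.na(dx_sensitivity(no_diseased)$value))
  expect_true(is.na(dx_specificity(dx_confusion(5, 0, 5, 0))$value))
})

test_that("predictive values follow Bayes' theorem with propagated bounds", {
  pv <- dx_predictive_values(dx_sensitivity(cm_ref),
                             dx_specificity(cm_ref), prevalence = 0.1)
  expect_equal(pv$ppv$value, 0.1965614, tolerance = 1e-6)
  expect_equal(c(pv$ppv$lower, pv$ppv$upper), c(0.1303208, 0.2931482),
               tolerance = 1e-6)
  expect_equal(pv$npv$value, 0.9670532, tolerance = 1e-6)
  expect_equal(c(pv$npv$lower, pv$npv$upper), c(0.9351503, 0.9829179),
               tolerance = 1e-6)
  # a perfect test gives certainty at any prevalence
  perfect <- dx_predictive_values(dx_estimate(1, 1, 1, "Se"),
                                  dx_estimate(1, 1, 1, "Sp"), 0.37)
  expect_equal(perfect$ppv$value, 1)
  expect_equal(perfect$npv$value, 1)
  expect_error(dx_predictive_values(dx_estimate(0.8, 0.7, 0.9, "Se"),
                                    dx_estimate(0.8, 0.7, 0.9, "Sp"), 1),
               "strictly between 0 and 1")
})

test_that("PPV/NPV are monotone in Se and Sp; bounds attained at matched corners", {
  ppv_fun <- function(se, sp, pr) se * pr / (se * pr + (1 - sp) * (1 - pr))
  npv_fun <- function(se, sp, pr) {
    sp * (1 - pr) / (sp * (1 - pr) + (1 - se) * pr)
  }
  set.seed(23)
  for (i in 1:200) {
    cm <- random_confusion()
    pr <- runif(1, 0.02, 0.98)
    se <- dx_sensitivity(cm)
    sp <- dx_specificity(cm)
    pv <- dx_predictive_values(se, sp, pr)
    # monotonicity implies the min/max over the four corner combinations
    # sit at (lower, lower) and (upper, upper)
    expect_equal(pv$ppv$lower, ppv_fun(se$lower, sp$lower, pr))
    expect_equal(pv$ppv$upper, ppv_fun(se$upper, sp$upper, pr))
    expect_equal(pv$npv$lower, npv_fun(se$lower, sp$lower, pr))
    expect_equal(pv$npv$upper, npv_fun(se$upper, sp$upper, pr))
    # the point estimate lies inside the propagated interval
    expect_gte(pv$ppv$value, pv$ppv$lower)
    expect_lte(pv$ppv$value, pv$ppv$upper)
    expect_gte(pv$npv$value, pv$npv$lower)
    expect_lte(pv$npv$value, pv$npv$upper)
  }
})

test_that("predictive values at the sample prevalence reduce to column proportions", {
  set.seed(29)
  for (i in 1:100) {
    cm <- random_confusion()
    pr <- cm$n_diseased / cm$n
    pv <- dx_predictive_values(dx_sensitivity(cm), dx_specificity(cm), pr)
    expect_equal(pv$ppv$value, cm$tp / (cm$tp + cm$fp), tolerance = 1e-12)
    expect_equal(pv$npv$value, cm$tn / (cm$tn + cm$fn), tolerance = 1e-12)
  }
})

test_that("likelihood ratios and log-scale intervals match hand evaluation", {
  lr <- dx_likelihood_ratios(cm_ref)
  expect_equal(lr$lr_pos$value, 2.201852, tolerance = 1e-6)
  expect_equal(c(lr$lr_pos$lower, lr$lr_pos$upper), c(1.448639, 3.346694),
               tolerance = 1e-6)
  expect_equal(lr$lr_neg$value, 0.3066239, tolerance = 1e-6)
  expect_equal(c(lr$lr_neg$lower, lr$lr_neg$upper), c(0.1814757, 0.5180763),
               tolerance = 1e-6)
  # the log-scale interval always contains the point LR when all cells > 0
  set.seed(31)
  for (i in 1:100) {
    cm <- random_confusion()
    lr <- dx_likelihood_ratios(cm)
    expect_lte(lr$lr_pos$lower, lr$lr_pos$value)
    expect_gte(lr$lr_pos$upper, lr$lr_pos$value)
    expect_lte(lr$lr_neg$lower, lr$lr_neg$value)
    expect_gte(lr$lr_neg$upper, lr$lr_neg$value)
  }
})

test_that("likelihood ratios follow the missing-value rule on zero cells", {
  perfect <- dx_likelihood_ratios(dx_confusion(10, 0, 0, 10))
  expect_true(is.na(perfect$lr_pos$value)) # 1 - Sp = 0
  expect_equal(perfect$lr_neg$value, 0)     # defined, but no interval
  expect_true(is.na(perfect$lr_neg$lower))
  no_diseased <- dx_likelihood_ratios(dx_confusion(0, 5, 0, 5))
  expect_true(is.na(no_diseased$lr_pos$value))
  expect_true(is.na(no_diseased$lr_neg$value))
})

test_that("Youden index and binomial-variance interval match hand evaluation", {
  j <- dx_youden(cm_ref)
  expect_equal(j$value, 0.4397019, tolerance = 1e-6)
  expect_equal(c(j$lower, j$upper), c(0.2662209, 0.6131829),
               tolerance = 1e-6)
  perfect <- dx_youden(dx_confusion(10, 0, 0, 10))
  expect_equal(perfect$value, 1)
  expect_equal(c(perfect$lower, perfect$upper), c(1, 1))
  expect_equal(dx_youden(dx_confusion(5, 5, 5, 5))$value, 0)
  expect_true(is.na(dx_youden(dx_confusion(0, 5, 0, 5))$value))
})

test_that("the metrics table composes the per-metric results in fixed order", {
  m <- dx_metrics(cm_ref, prevalence = 0.1)
  expect_equal(m$metric, c("Se", "Sp", "Acc", "PPV", "NPV", "LR+", "LR-", "J"))
  expect_equal(metric_value(m, "Se"), 58 / 72)
  expect_equal(metric_value(m, "PPV"), 0.1965614, tolerance = 1e-6)
  expect_equal(metric_value(m, "J"), 0.4397019, tolerance = 1e-6)
  # perfect test: LR+ missing, LR- zero
  mp <- dx_metrics(dx_confusion(10, 0, 0, 10), prevalence = 0.1)
  expect_true(is.na(metric_value(mp, "LR+")))
  expect_equal(metric_value(mp, "LR-"), 0)
  expect_equal(metric_value(mp, "Se"), 1)
  expect_equal(metric_value(mp, "PPV"), 1)
  # partial missingness propagates: Se missing drags PPV/NPV/LR/J with it
  mm <- dx_metrics(dx_confusion(0, 5, 0, 5), prevalence = 0.1)
  expect_true(is.na(metric_value(mm, "Se")))
  expect_equal(metric_value(mm, "Sp"), 0.5)
  expect_true(all(is.na(mm$estimate[mm$metric %in%
                                      c("PPV", "NPV", "LR+", "LR-", "J")])))
})
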