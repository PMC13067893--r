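# Brute-force oracles, deliberately naive and independent of the package's
# computation paths.

# Mann-Whitney AUC by explicit pair counting (ties one half); scores must
# already be oriented so that higher values indicate disease.
oracle_mw_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  total <- 0
  for (xi in x) {
    for (yj in y) {
      total <- total + (xi > yj) + 0.5 * (xi == yj)
    }
  }
  total / (length(x) * length(y))
}

# DeLong AUC variance from explicitly enumerated placement values.
oracle_delong_var <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x)
  n <- length(y)
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  sum((v10 - mean(v10))^2) / (m - 1) / m +
    sum((v01 - mean(v01))^2) / (n - 1) / n
}

# Exhaustive closest-to-top-left search over every candidate threshold,
# recomputing Se/Sp by direct classification at each.
oracle_best_cutoff <- function(scores, labels, direction) {
  tt <- dx_thresholds(scores)
  tt <- tt[is.finite(tt)]
  best <- NULL
  for (t in tt) {
    pos <- if (direction == "higher") scores > t else scores < t
    se <- sum(pos & labels == 1) / sum(labels == 1)
    sp <- sum(!pos & labels == 0) / sum(labels == 0)
    d <- sqrt((1 - se)^2 + (1 - sp)^2)
    cand <- list(threshold = t, se = se, sp = sp, d = d)
    if (is.null(best) || d < best$d - 1e-15 ||
        (abs(d - best$d) <= 1e-15 && se > best$se + 1e-15)) {
      best <- cand
    }
  }
  best
}

# Random classification instance with both classes guaranteed present.
random_instance <- function(max_cases = 20, max_controls = 20,
                            tie_prone = FALSE) {
  m <- sample(2:max_cases, 1)
  n <- sample(2:max_controls, 1)
  if (tie_prone) {
    scores <- sample(0:5, m + n, replace = TRUE)
  } else {
    scores <- c(rnorm(m, mean = runif(1, 0, 2)), rnorm(n))
  }
  list(scores = scores, labels = rep(c(1, 0), c(m, n)), m = m, n = n)
}

random_confusion <- function(max_cell = 30) {
  dx_confusion(tp = sample(1:max_cell, 1), fp = sample(1:max_cell, 1),
               fn = sample(1:max_cell, 1), tn = sample(1:max_cell, 1))
}

metric_value <- function(metrics, name) {
  metrics$estimate[metrics$metric == name]
}
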