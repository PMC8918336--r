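# Threshold reports, Mann-Whitney AUC, ROC staircase, univariate and risk tables.

test_that("confusion matrix reproduces printed sensitivity/specificity counts", {
  # 24 positives of whom 22 above threshold; 162 negatives, 126 at or below
  index <- c(rep(1.10, 22), rep(1.00, 2),    # positives
             rep(1.05, 36), rep(0.98, 126))  # negatives
  outcome <- c(rep(TRUE, 24), rep(FALSE, 162))
  rep <- confusion_at_threshold(index, outcome, 1.021)
  expect_identical(rep$tp, 22L); expect_identical(rep$fn, 2L)
  expect_identical(rep$fp, 36L); expect_identical(rep$tn, 126L)
  expect_equal(rep$sensitivity, 22 / 24)
  expect_equal(rep$specificity, 126 / 162)
  expect_equal(round(100 * rep$sensitivity, 1), 91.7)
  expect_equal(round(100 * rep$specificity, 1), 77.8)
})

test_that("threshold comparison is strict by default and switchable", {
  index <- c(1.021, 1.05); outcome <- c(TRUE, TRUE)
  expect_identical(confusion_at_threshold(index, outcome, 1.021)$tp, 1L)
  expect_identical(
    confusion_at_threshold(index, outcome, 1.021, strict = FALSE)$tp, 2L)
})

test_that("degenerate confusion inputs are flagged, not silent NaN", {
  rep <- confusion_at_threshold(c(1, 2), c(TRUE, TRUE), 1.5)
  expect_true(is.na(rep$specificity))
  expect_match(rep$notes, "no negatives", all = FALSE)
  expect_equal(rep$sensitivity, 0.5)
})

test_that("sensitivity falls and specificity rises with the threshold", {
  set.seed(21)
  index <- rnorm(300, 1, 0.1)
  outcome <- runif(300) < plogis(30 * (index - 1.05))
  ths <- seq(0.7, 1.3, by = 0.02)
  reps <- lapply(ths, function(t) confusion_at_threshold(index, outcome, t))
  sens <- vapply(reps, `[[`, numeric(1), "sensitivity")
  spec <- vapply(reps, `[[`, numeric(1), "specificity")
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
  expect_equal(sens[1], 1); expect_equal(spec[length(ths)], 1)
})

test_that("Mann-Whitney AUC equals the brute-force pair-counting oracle", {
  pair_auc <- function(x, y) {  # x positives, y negatives
    s <- 0
    for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
    s / (length(x) * length(y))
  }
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    # ties on purpose: scores on a coarse lattice
    x <- sample(seq(0, 2, by = 0.25), n1, replace = TRUE) +
      rbinom(n1, 1, 0.7) * 0.5
    y <- sample(seq(0, 2, by = 0.25), n2, replace = TRUE)
    res <- auc_mann_whitney(c(x, y), c(rep(TRUE, n1), rep(FALSE, n2)))
    expect_identical(res$auc, pair_auc(x, y))
  }
})

test_that("AUC edge cases: perfect separation and all ties", {
  expect_equal(auc_mann_whitney(c(2, 3, 0, 1),
                                c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(auc_mann_whitney(rep(1, 10),
                                rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(auc_mann_whitney(1:5, rep(TRUE, 5)),
               class = "km_degenerate_error")
})

test_that("Mann-Whitney p agrees with wilcox.test's normal approximation", {
  skip_if_not_installed("stats")
  set.seed(41)
  x <- rnorm(40, 1.05, 0.1); y <- rnorm(60, 1.0, 0.1)
  res <- auc_mann_whitney(c(x, y), c(rep(TRUE, 40), rep(FALSE, 60)))
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$u, unname(ref$statistic))
})

test_that("ROC staircase area equals the Mann-Whitney AUC to 1e-12", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    # mix of continuous and heavily tied scores
    idx <- if (i %% 2) rnorm(n) else sample(seq(0, 1, 0.1), n, replace = TRUE)
    out <- runif(n) < 0.4
    if (!any(out) || all(out)) out[1:2] <- c(TRUE, FALSE)
    roc <- roc_curve(idx, out)
    expect_equal(roc_auc_trapezoid(roc),
                 auc_mann_whitney(idx, out)$auc, tolerance = 1e-12)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  }
})

test_that("ROC mirrors under score reversal and hits (0,1) for a clean split", {
  idx <- c(5, 1, 2, 3); out <- c(TRUE, FALSE, FALSE, FALSE)
  roc <- roc_curve(idx, out)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  set.seed(61)
  idx2 <- rnorm(50); out2 <- runif(50) < 0.5
  if (!any(out2) || all(out2)) out2[1:2] <- c(TRUE, FALSE)
  expect_equal(auc_mann_whitney(-idx2, out2)$auc,
               1 - auc_mann_whitney(idx2, out2)$auc)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  idx <- rnorm(120, 1, 0.1); out <- runif(120) < plogis(20 * (idx - 1))
  if (!any(out) || all(out)) out[1:2] <- c(TRUE, FALSE)
  ref <- suppressMessages(pROC::auc(pROC::roc(out, idx, quiet = TRUE)))
  expect_equal(auc_mann_whitney(idx, out)$auc, as.numeric(ref),
               tolerance = 1e-12)
})

test_that("threshold selectors are labelled and behave as documented", {
  index <- c(rep(1.10, 22), rep(1.00, 2), rep(1.05, 36), rep(0.98, 126))
  outcome <- c(rep(TRUE, 24), rep(FALSE, 162))
  y <- select_threshold(index, outcome, method = "youden")
  s <- select_threshold(index, outcome, method = "sensitivity_first",
                        min_sensitivity = 0.9)
  expect_match(y$notes, "youden", all = FALSE)
  expect_gte(s$sensitivity, 0.9)
  # on this fixture the sensitivity-first cut keeps 22/24 sensitivity
  expect_equal(s$sensitivity, 22 / 24)
})

test_that("univariate table: identity factor, point-biserial oracle, NS marking", {
  set.seed(81)
  tbl <- dplyr::bind_rows(lapply(1:40, function(i)
    patient_row(sprintf("U%02d", i), rtpa = i %% 3 == 0,
                mls_max_mm = round(runif(1, 0, 10), 1))))
  co <- km_cohort(tbl)
  res <- univariate_table(co, list(
    self = function(t) t$mls_max_mm,
    lysis = function(t) t$rtpa,
    const = function(t) rep(1, nrow(t))))
  self_row <- res[res$factor == "self", ]
  expect_equal(self_row$r, 1)
  expect_equal(self_row$gradient, 1)
  expect_equal(self_row$intercept, 0, tolerance = 1e-12)
  # point-biserial closed form for the binary factor
  x <- as.numeric(tbl$rtpa); y <- tbl$mls_max_mm
  n1 <- sum(x == 1); n0 <- sum(x == 0); n <- n1 + n0
  rpb <- (mean(y[x == 1]) - mean(y[x == 0])) /
    (sd(y) * sqrt((n - 1) / n)) * sqrt(n1 * n0 / n^2)
  expect_equal(res[res$factor == "lysis", ]$r, rpb, tolerance = 1e-12)
  expect_match(res[res$factor == "const", ]$significance, "degenerate")
})

test_that("risk table reproduces printed class rates from constructed counts", {
  # class sizes 129 / 26 / 15 / 16 with event counts from the published table
  mk <- function(n, idx, mls_k, dhc_k, death_k)
    cohort_with_indices(rep(idx, n),
                        mls = c(rep(5, mls_k), rep(0, n - mls_k)),
                        dhc = c(rep(TRUE, dhc_k), rep(FALSE, n - dhc_k)),
                        death = c(rep(TRUE, death_k), rep(FALSE, n - death_k)))
  co <- km_cohort(dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(mk(129, 1.000, 2, 3, 2)),
                  id = sprintf("L%03d", 1:129)),
    dplyr::mutate(tibble::as_tibble(mk(26, 1.050, 5, 5, 1)),
                  id = sprintf("M%03d", 1:26)),
    dplyr::mutate(tibble::as_tibble(mk(15, 1.100, 4, 4, 1)),
                  id = sprintf("H%03d", 1:15)),
    dplyr::mutate(tibble::as_tibble(mk(16, 1.150, 13, 7, 3)),
                  id = sprintf("S%03d", 1:16))))
  rt <- risk_table(co)
  expect_equal(rt$n, c(129, 26, 15, 16))
  expect_equal(rt$mls, c(2, 5, 4, 13))
  expect_equal(rt$dhc, c(3, 5, 4, 7))
  expect_equal(rt$death, c(2, 1, 1, 3))
  expect_equal(rt$mls_rate, c(2 / 129, 5 / 26, 4 / 15, 13 / 16))
  expect_equal(round(100 * rt$mls_rate), c(2, 19, 27, 81))
  expect_equal(round(100 * rt$dhc_rate[4]), 44)
})

test_that("risk table conserves totals and marks empty classes", {
  co <- cohort_with_indices(rep(1.00, 10), mls = 0)
  rt <- risk_table(co)
  expect_equal(sum(rt$n), 10)
  expect_equal(rt$n[1], 10)
  expect_true(all(is.na(rt$mls_rate[rt$n == 0])))
  expect_true(all(rt$n[2:4] == 0))
})
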