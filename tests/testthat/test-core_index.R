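# Core index: weighting factor, time factor, KM/KMT indices, score, class.

test_that("weighting factor n follows the mTICI table, lysis multiplies by lambda", {
  p <- index_params()
  # grade -> (without rtPA, with rtPA at lambda = 0.7)
  expected <- list("0" = c(1.0, 0.70), "1" = c(0.9, 0.63),
                   "2a" = c(0.8, 0.56), "2b" = c(0.7, 0.49),
                   "2c" = c(0.6, 0.42), "3" = c(0.5, 0.35))
  for (g in names(expected)) {
    expect_equal(weighting_factor_n(treatment_record(TRUE, g), p),
                 expected[[g]][1])
    expect_equal(weighting_factor_n(treatment_record(TRUE, g, rtpa = TRUE), p),
                 expected[[g]][2])
  }
  expect_equal(weighting_factor_n(treatment_record(FALSE), p), 1.0)
  expect_equal(weighting_factor_n(treatment_record(FALSE, rtpa = TRUE), p),
               0.70)  # lysis weighting also applies without thrombectomy
})

test_that("treatment record validation: mtici present iff thrombectomy", {
  expect_error(treatment_record(TRUE), class = "km_validation_error")
  expect_error(treatment_record(FALSE, mtici = "3"),
               class = "km_validation_error")
  expect_error(treatment_record(TRUE, mtici = "4"),
               class = "km_validation_error")
  expect_error(treatment_record(TRUE, mtici = "3", onset_to_groin_hours = -1),
               class = "km_validation_error")
})

test_that("time factor bins onset-to-groin hours and defaults unknown to 1", {
  expect_identical(time_factor(3.0), 3L)
  expect_identical(time_factor(4.5), 3L)   # boundary belongs to the fast bin
  expect_identical(time_factor(6.0), 2L)
  expect_identical(time_factor(8.0), 2L)
  expect_identical(time_factor(10.0), 1L)
  expect_identical(time_factor(NA), 1L)
  expect_error(time_factor(-0.1), class = "km_validation_error")
})

test_that("KM index reproduces hand-computed values on cohort-mean volumes", {
  v <- mean_volumes()
  r1 <- km_index(v, treatment_record(TRUE, "3"))
  expect_equal(r1$index,
               (0.5 * (2.8 * 53.81 + 87.77) + 950.27) / 1086.26)
  expect_equal(r1$index, 0.9846, tolerance = 1e-4)
  r2 <- km_index(v, treatment_record(TRUE, "0"))
  expect_equal(r2$index, (2.8 * 53.81 + 87.77 + 950.27) / 1086.26)
  expect_equal(r2$index, 1.0943, tolerance = 1e-4)
  # component breakdown
  expect_equal(r1$components$B, 950.27 / 1086.26)
  expect_equal(r1$components$n, 0.5)
  expect_equal(r1$components$m_eff, 1.4)
})

test_that("healthy-brain limit: zero lesion gives index = B < 1", {
  v <- perfusion_volumes(0, 0, 1000, 900)
  for (tr in list(treatment_record(FALSE),
                  treatment_record(TRUE, "0", rtpa = TRUE),
                  treatment_record(TRUE, "3"))) {
    res <- km_index(v, tr)
    expect_equal(res$index, 0.9)
    expect_lt(res$index, 1)
  }
})

test_that("volume invariants are enforced", {
  expect_error(perfusion_volumes(10, 10, 0, 0), class = "km_validation_error")
  expect_error(perfusion_volumes(10, 10, 1000, 1001),
               class = "km_validation_error")
  expect_error(perfusion_volumes(600, 500, 1100, 1000),
               class = "km_validation_error")
  expect_error(perfusion_volumes(-1, 0, 1000, 900),
               class = "km_validation_error")
})

test_that("KMT index applies n^t with the core keeping its relative weight", {
  v <- mean_volumes()
  # t = 2 (6 h), mTICI 3 without rtPA: n = 0.5
  r <- kmt_index(v, treatment_record(TRUE, "3", onset_to_groin_hours = 6))
  expect_equal(r$index,
               (2.8 * 0.25 * 53.81 + 0.25 * 87.77 + 950.27) / 1086.26)
  expect_equal(r$index, 0.9296, tolerance = 1e-4)
  expect_identical(r$components$t, 2L)
  # zero lesion: index = B regardless of t
  v0 <- perfusion_volumes(0, 0, 1000, 900)
  for (h in c(2, 6, 12))
    expect_equal(kmt_index(v0, treatment_record(TRUE, "2b",
                                                onset_to_groin_hours = h))$index,
                 0.9)
})

test_that("KMT at t = 1 is floating-point identical to KM at lambda_t", {
  v <- mean_volumes()
  p <- index_params()
  p_swap <- index_params(lambda_lysis = p$lambda_lysis_time)
  for (g in MTICI_LEVELS) {
    for (rt in c(TRUE, FALSE)) {
      tr <- treatment_record(TRUE, g, rtpa = rt, onset_to_groin_hours = 10)
      expect_identical(kmt_index(v, tr, p)$index,
                       km_index(v, tr, p_swap)$index)
    }
  }
})

test_that("literal joint-scaling KMT form scales penumbra by m_ratio too", {
  v <- mean_volumes()
  tr <- treatment_record(TRUE, "3", onset_to_groin_hours = 6)
  r <- kmt_index(v, tr, literal_grouping = TRUE)
  expect_equal(r$index,
               (2.8 * 0.25 * (53.81 + 87.77) + 950.27) / 1086.26)
  expect_gt(r$index, kmt_index(v, tr)$index)
})

test_that("index is monotone: better reperfusion and lysis never raise it", {
  v <- mean_volumes()
  idx <- vapply(MTICI_LEVELS, function(g)
    km_index(v, treatment_record(TRUE, g))$index, numeric(1))
  expect_true(all(diff(idx) < 0))
  for (g in MTICI_LEVELS) {
    expect_lte(km_index(v, treatment_record(TRUE, g, rtpa = TRUE))$index,
               km_index(v, treatment_record(TRUE, g))$index)
  }
})

test_that("index respects its analytic bounds for random volumes", {
  set.seed(11)
  p <- index_params()
  for (i in 1:200) {
    mip <- runif(1, 800, 1400)
    mtt <- runif(1, 0.6, 0.99) * mip
    core <- runif(1, 0, mtt / 3)
    pen <- runif(1, 0, mtt - core)
    v <- perfusion_volumes(core, pen, mip, mtt)
    g <- sample(MTICI_LEVELS, 1)
    tr <- treatment_record(TRUE, g, rtpa = sample(c(TRUE, FALSE), 1))
    idx <- km_index(v, tr, p)$index
    expect_gte(idx, mtt / mip - 1e-12)
    expect_lte(idx, (p$m_ratio * core + pen + mtt) / mip + 1e-12)
  }
})

test_that("KM score discretization matches the published rules", {
  expect_identical(km_score(1.14), 14L)
  expect_identical(km_score(1.30), 20L)
  expect_identical(km_score(1.195), 20L)
  expect_identical(km_score(0.95), 0L)
  expect_identical(km_score(1.0049), 0L)
  expect_identical(km_score(1.006), 1L)   # half rounds away from zero
  expect_identical(km_score(1.194), 19L)
  expect_error(km_score(NaN), class = "km_validation_error")
  expect_error(km_score(Inf), class = "km_validation_error")
})

test_that("risk classes bin the score as 0-2 / 3-7 / 8-13 / 14-20", {
  expect_identical(risk_class(0), "low")
  expect_identical(risk_class(2), "low")
  expect_identical(risk_class(3), "moderate")
  expect_identical(risk_class(7), "moderate")
  expect_identical(risk_class(8), "high")
  expect_identical(risk_class(13), "high")
  expect_identical(risk_class(14), "severe")
  expect_identical(risk_class(20), "severe")
  expect_error(risk_class(21), class = "km_validation_error")
  expect_error(risk_class(-1), class = "km_validation_error")
})

test_that("score and class round-trip consistently over random indices", {
  set.seed(7)
  idx <- runif(20000, 0.8, 1.4)
  scores <- km_score_vec(idx)
  expect_true(all(scores >= 0 & scores <= 20))
  # vectorized and scalar paths agree
  k <- sample(length(idx), 500)
  expect_identical(scores[k],
                   vapply(idx[k], km_score, integer(1)))
  cls <- risk_class_vec(scores)
  expect_identical(as.character(cls),
                   vapply(scores, risk_class, character(1)))
  # class boundaries expressed on the index scale
  expect_true(all(cls[idx < 1.025] == "low"))
  expect_true(all(cls[idx >= 1.035 & idx < 1.075] == "moderate"))
  expect_true(all(cls[idx >= 1.075 & idx < 1.135] == "high"))
  expect_true(all(cls[idx >= 1.135] == "severe"))
})
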