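# Parameter calibration: recover the index parameters (m_ratio, lambda,
# lambda_t) by maximizing the Pearson correlation between the index and the
# maximum midline shift over a cohort. The search is fully deterministic — a
# fixed grid over m_ratio and bracketed successive grid refinement for the
# lysis weights — so a calibration is reproducible bit for bit.

#' Pearson correlation with t-test p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3), both non-constant.
#' @return A list with `r` and the two-sided `p` value from the t transform
#'   with n - 2 degrees of freedom.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) km_stop("x and y must have equal length")
  if (length(x) < 3L) km_stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) km_stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    km_stop("degenerate input: constant series", class = "km_degenerate_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# Correlation between the cohort index and maximum MLS, the calibration
# objective. Missing MLS is treated as 0 mm by default: the outcome is the
# *maximum* shift over follow-up, and a patient in whom no shift was ever
# observed contributes 0, not a missing value. brain_term = FALSE drops the
# parenchyma summand from the numerator (for sensitivity analyses).

#' Correlation between index and midline shift over a cohort
#'
#' The calibration objective: Pearson r between the per-patient index at the
#' given parameters and the maximum midline shift.
#'
#' @param cohort A `km_cohort` or compatible data frame.
#' @param params An [index_params()].
#' @param variant `"km"` or `"kmt"`.
#' @param mls_missing `"zero"` (default) treats an absent MLS measurement as
#'   0 mm; `"drop"` restricts to patients with a recorded value.
#' @param brain_term Set `FALSE` to drop the parenchyma term `v_mtt` from
#'   the index numerator (sensitivity analysis of the atrophy contribution).
#' @return A list with `r` and `p` as in [pearson_r()].
#' @export
km_mls_correlation <- function(cohort, params = index_params(),
                               variant = c("km", "kmt"),
                               mls_missing = c("zero", "drop"),
                               brain_term = TRUE) {
  variant <- match.arg(variant)
  mls_missing <- match.arg(mls_missing)
  tbl <- cohort_indices(cohort, params, variant = variant)
  if (!brain_term)
    tbl$index <- tbl$index - tbl$v_mtt / tbl$v_mip
  mls <- tbl$mls_max_mm
  if (mls_missing == "zero") {
    mls[is.na(mls)] <- 0
  } else {
    keep <- !is.na(mls)
    tbl <- tbl[keep, ]
    mls <- mls[keep]
  }
  pearson_r(tbl$index, mls)
}

calibration_result <- function(m_ratio, lambda, lambda_time, r, trace,
                               notes = character(0)) {
  structure(
    list(m_ratio = m_ratio, lambda = lambda, lambda_time = lambda_time,
         r = r, trace = trace, notes = notes),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result\n")
  cat(sprintf("  m_ratio = %.3f   lambda = %.4f   lambda_t = %s\n",
              x$m_ratio, x$lambda,
              if (is.na(x$lambda_time)) "-" else sprintf("%.4f", x$lambda_time)))
  cat(sprintf("  achieved Pearson r = %.4f  (%d objective evaluations)\n",
              x$r, nrow(x$trace)))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

new_trace <- function() {
  tibble::tibble(parameter = character(0), value = numeric(0),
                 m_ratio = numeric(0), lambda = numeric(0), r = numeric(0))
}

#' Grid search over the core weighting m_ratio
#'
#' Evaluates the index-MLS correlation on a fixed grid of `m_ratio` values
#' at a fixed lysis weight and returns the maximizer. Ties are broken toward
#' the smaller `m_ratio` (the weaker core weighting).
#'
#' @param cohort A `km_cohort` with at least 3 patients carrying an MLS
#'   value under the chosen missing-value policy.
#' @param m_grid Grid of candidate `m_ratio` values; the default spans 0.1
#'   to 5.0 in steps of 0.1 (a core swelling potential of up to 500%).
#' @param lambda Fixed lysis weight during the search.
#' @param params Baseline [index_params()] (supplies `n_base`).
#' @inheritParams km_mls_correlation
#' @return A `calibration_result` with the search trace.
#' @export
grid_search_m <- function(cohort, m_grid = seq(0.1, 5.0, by = 0.1),
                          lambda = 0.70, params = index_params(),
                          mls_missing = c("zero", "drop")) {
  mls_missing <- match.arg(mls_missing)
  if (!length(m_grid) || any(m_grid <= 0))
    km_stop("m_grid must contain positive values")
  m_grid <- sort(m_grid)
  rs <- vapply(m_grid, function(m) {
    p <- index_params(m_ratio = m, lambda_lysis = lambda,
                      lambda_lysis_time = params$lambda_lysis_time,
                      n_base = params$n_base,
                      n_no_thrombectomy = params$n_no_thrombectomy)
    km_mls_correlation(cohort, p, variant = "km", mls_missing = mls_missing)$r
  }, numeric(1))
  best <- which.max(rs)  # first max = smallest m on the sorted grid
  trace <- tibble::tibble(parameter = "m_ratio", value = m_grid,
                          m_ratio = m_grid, lambda = lambda, r = rs)
  calibration_result(m_grid[best], lambda, NA_real_, rs[best], trace,
                     notes = "ties in r broken toward smaller m_ratio")
}

# Deterministic 1-D maximization of f over [lo, hi] by successive grid
# refinement: evaluate `points` equally spaced values, keep the best (ties
# toward the larger argument), shrink the bracket to its neighbours, repeat
# until the bracket is narrower than tol. Returns list(x, f, trace_x, trace_f).
refine_1d <- function(f, lo, hi, tol = 1e-3, points = 21L) {
  stopifnot(hi >= lo)
  trace_x <- numeric(0); trace_f <- numeric(0)
  if (hi - lo < tol) {
    x <- (lo + hi) / 2
    return(list(x = x, f = f(x), trace_x = x, trace_f = f(x)))
  }
  while (hi - lo >= tol) {
    xs <- seq(lo, hi, length.out = points)
    fs <- vapply(xs, f, numeric(1))
    trace_x <- c(trace_x, xs); trace_f <- c(trace_f, fs)
    best <- length(fs) + 1L - which.max(rev(fs))  # last max: larger argument
    lo2 <- xs[max(1L, best - 1L)]
    hi2 <- xs[min(length(xs), best + 1L)]
    if (hi2 - lo2 >= hi - lo) break  # no shrink possible (degenerate grid)
    lo <- lo2; hi <- hi2
  }
  x <- (lo + hi) / 2
  list(x = x, f = f(x), trace_x = c(trace_x, x), trace_f = c(trace_f, f(x)))
}

#' Optimize the lysis weight lambda at fixed m_ratio
#'
#' Maximizes the index-MLS correlation over the lysis weight by bracketed
#' successive grid refinement to the given tolerance. The cohort must
#' contain both rtPA and non-rtPA patients, otherwise lambda does not enter
#' the objective identifiably. Ties are broken toward the larger lambda
#' (the weaker lysis effect).
#'
#' @inheritParams grid_search_m
#' @param m_ratio Fixed core weighting during the search.
#' @param interval Search interval for lambda, a sub-interval of (0, 1].
#' @param tol Bracket width at which the search stops; the midpoint of the
#'   final bracket is returned.
#' @param variant `"km"` optimizes `lambda_lysis`; `"kmt"` optimizes the
#'   time-variant weight `lambda_lysis_time` under the KMT index.
#' @return A `calibration_result`.
#' @export
optimize_lambda <- function(cohort, m_ratio = 2.8,
                            interval = c(0.01, 1), tol = 1e-3,
                            params = index_params(),
                            mls_missing = c("zero", "drop"),
                            variant = c("km", "kmt")) {
  mls_missing <- match.arg(mls_missing)
  variant <- match.arg(variant)
  tbl <- tibble::as_tibble(cohort)
  if (all(tbl$rtpa) || !any(tbl$rtpa))
    km_stop("lambda is unidentifiable: cohort must contain both rtPA and non-rtPA patients",
            class = "km_unidentifiable_error")
  if (variant == "kmt" && all(is.na(tbl$onset_to_groin_hours)))
    km_stop("no patients with known onset-to-groin time",
            class = "km_unidentifiable_error")
  if (interval[1] <= 0 || interval[2] > 1 || interval[1] > interval[2])
    km_stop("interval must lie within (0, 1]")
  obj <- function(lam) {
    p <- if (variant == "km")
      index_params(m_ratio = m_ratio, lambda_lysis = lam,
                   lambda_lysis_time = params$lambda_lysis_time,
                   n_base = params$n_base,
                   n_no_thrombectomy = params$n_no_thrombectomy)
    else
      index_params(m_ratio = m_ratio, lambda_lysis = params$lambda_lysis,
                   lambda_lysis_time = lam, n_base = params$n_base,
                   n_no_thrombectomy = params$n_no_thrombectomy)
    km_mls_correlation(cohort, p, variant = variant,
                       mls_missing = mls_missing)$r
  }
  res <- refine_1d(obj, interval[1], interval[2], tol = tol)
  trace <- tibble::tibble(
    parameter = if (variant == "km") "lambda" else "lambda_time",
    value = res$trace_x,
    m_ratio = m_ratio,
    lambda = if (variant == "km") res$trace_x else params$lambda_lysis,
    r = res$trace_f)
  calibration_result(
    m_ratio,
    lambda = if (variant == "km") res$x else params$lambda_lysis,
    lambda_time = if (variant == "kmt") res$x else NA_real_,
    r = res$f, trace = trace,
    notes = "ties in r broken toward larger lambda")
}

#' Calibrate the time-variant lysis weight lambda_t
#'
#' Repeats the lysis-weight optimization under the time-weighted KMT index
#' (where n is raised to the time factor t). On a cohort in which every
#' patient has t = 1 this coincides with [optimize_lambda()].
#'
#' @inheritParams optimize_lambda
#' @return A `calibration_result` with `lambda_time` set.
#' @export
calibrate_time_variant <- function(cohort, m_ratio = 2.8,
                                   interval = c(0.01, 1), tol = 1e-3,
                                   params = index_params(),
                                   mls_missing = c("zero", "drop")) {
  optimize_lambda(cohort, m_ratio = m_ratio, interval = interval, tol = tol,
                  params = params, mls_missing = mls_missing,
                  variant = "kmt")
}

#' Full coordinate calibration of m_ratio and lambda
#'
#' Alternates the m_ratio grid search and the lambda refinement for a fixed
#' number of sweeps (two by default), then optionally calibrates the
#' time-variant weight lambda_t at the selected m_ratio. Deterministic: the
#' same cohort always yields the same result, and the full evaluation trace
#' is returned for audit.
#'
#' @inheritParams grid_search_m
#' @inheritParams optimize_lambda
#' @param sweeps Number of alternating (m, lambda) sweeps.
#' @param time_variant Also calibrate `lambda_time` under the KMT index.
#' @return A `calibration_result`.
#' @export
calibrate_index <- function(cohort, m_grid = seq(0.1, 5.0, by = 0.1),
                            interval = c(0.01, 1), tol = 1e-3, sweeps = 2L,
                            params = index_params(),
                            mls_missing = c("zero", "drop"),
                            time_variant = FALSE) {
  mls_missing <- match.arg(mls_missing)
  lambda <- params$lambda_lysis
  trace <- new_trace()
  m_best <- params$m_ratio; r_best <- NA_real_
  for (s in seq_len(sweeps)) {
    gm <- grid_search_m(cohort, m_grid = m_grid, lambda = lambda,
                        params = params, mls_missing = mls_missing)
    m_best <- gm$m_ratio
    ol <- optimize_lambda(cohort, m_ratio = m_best, interval = interval,
                          tol = tol, params = params,
                          mls_missing = mls_missing, variant = "km")
    lambda <- ol$lambda
    r_best <- ol$r
    trace <- dplyr::bind_rows(trace, gm$trace, ol$trace)
  }
  lambda_time <- NA_real_
  if (time_variant) {
    ct <- calibrate_time_variant(cohort, m_ratio = m_best,
                                 interval = interval, tol = tol,
                                 params = params, mls_missing = mls_missing)
    lambda_time <- ct$lambda_time
    trace <- dplyr::bind_rows(trace, ct$trace)
  }
  calibration_result(m_best, lambda, lambda_time, r_best, trace,
                     notes = c("ties broken toward smaller m_ratio and larger lambda"))
}

#' Serialize a calibration result to JSON
#'
#' Writes the fitted parameters, the achieved correlation and the full
#' search trace, for audit and reproduction.
#'
#' @param result A `calibration_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(m_ratio = result$m_ratio, lambda = result$lambda,
         lambda_time = result$lambda_time, r = result$r,
         notes = result$notes, trace = result$trace),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
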