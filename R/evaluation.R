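# Threshold and discrimination analysis: confusion matrices at an index
# cut-off, ROC/AUC via the Mann-Whitney construction, univariate
# correlation tables and risk-class outcome tables.

#' Confusion matrix at an index threshold
#'
#' Classifies patients as test-positive when their index exceeds the
#' threshold (strict `>` by default, matching the usual reading of
#' "index above x"; set `strict = FALSE` for `>=`).
#'
#' @param index Numeric index values.
#' @param outcome Logical outcome flags (e.g. midline shift observed).
#' @param threshold Index cut-off.
#' @param strict Use strict `>` (default) rather than `>=`.
#' @return A list with `threshold`, the counts `tp`, `fp`, `tn`, `fn`, and
#'   `sensitivity` / `specificity`. A rate with an empty denominator is
#'   returned as `NA` and flagged in `notes`.
#' @examples
#' confusion_at_threshold(c(1.1, 1.0, 0.9), c(TRUE, FALSE, FALSE), 1.021)
#' @export
confusion_at_threshold <- function(index, outcome, threshold,
                                   strict = TRUE) {
  if (length(index) != length(outcome))
    km_stop("index and outcome must have equal length")
  if (anyNA(index) || anyNA(outcome)) km_stop("missing values not allowed")
  if (!is.logical(outcome)) km_stop("outcome must be logical")
  pos <- if (strict) index > threshold else index >= threshold
  tp <- sum(pos & outcome); fn <- sum(!pos & outcome)
  fp <- sum(pos & !outcome); tn <- sum(!pos & !outcome)
  notes <- character(0)
  if (tp + fn == 0) notes <- c(notes, "no positives: sensitivity undefined")
  if (tn + fp == 0) notes <- c(notes, "no negatives: specificity undefined")
  structure(
    list(threshold = threshold,
         tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         notes = notes),
    class = "km_threshold_report")
}

#' @export
print.km_threshold_report <- function(x, ...) {
  cat(sprintf("Threshold %g: TP %d  FP %d  TN %d  FN %d\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %s  specificity %s\n",
              if (is.na(x$sensitivity)) "undefined"
              else sprintf("%.1f%% (%d/%d)", 100 * x$sensitivity, x$tp, x$tp + x$fn),
              if (is.na(x$specificity)) "undefined"
              else sprintf("%.1f%% (%d/%d)", 100 * x$specificity, x$tn, x$tn + x$fp)))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' AUC via the Mann-Whitney U statistic
#'
#' Computes the area under the ROC curve as `U / (n1 * n2)` from the
#' rank-sum U statistic, counting ties as 1/2, together with a two-sided p
#' value from the normal approximation with tie correction and continuity
#' correction. Identical to the fraction of (positive, negative) pairs in
#' which the positive scores higher (ties half).
#'
#' @param index Numeric index values.
#' @param outcome Logical outcome flags; both classes must be non-empty.
#' @return A list with `auc`, `u` and `p`.
#' @export
auc_mann_whitney <- function(index, outcome) {
  if (length(index) != length(outcome))
    km_stop("index and outcome must have equal length")
  if (anyNA(index) || anyNA(outcome)) km_stop("missing values not allowed")
  n1 <- sum(outcome); n2 <- sum(!outcome)
  if (n1 == 0 || n2 == 0)
    km_stop("both outcome classes must be non-empty",
            class = "km_degenerate_error")
  r <- rank(index)  # midranks handle ties
  u <- sum(r[outcome]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  n <- n1 + n2
  ties <- table(index)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  p <- if (sigma2 <= 0) 1 else {
    z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-max(z, 0))
  }
  list(auc = auc, u = u, p = min(p, 1))
}

#' Empirical ROC curve
#'
#' Returns the ROC staircase as ordered (fpr, tpr) points from (0, 0) to
#' (1, 1); tied index values produce diagonal segments, so the trapezoidal
#' area under the returned curve equals the Mann-Whitney AUC exactly.
#'
#' @inheritParams auc_mann_whitney
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(index, outcome) {
  if (length(index) != length(outcome))
    km_stop("index and outcome must have equal length")
  if (anyNA(index) || anyNA(outcome)) km_stop("missing values not allowed")
  n1 <- sum(outcome); n2 <- sum(!outcome)
  if (n1 == 0 || n2 == 0)
    km_stop("both outcome classes must be non-empty",
            class = "km_degenerate_error")
  thr <- sort(unique(index), decreasing = TRUE)
  tp <- vapply(thr, function(th) sum(outcome & index >= th), numeric(1))
  fp <- vapply(thr, function(th) sum(!outcome & index >= th), numeric(1))
  tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n2),
    tpr = c(0, tp / n1)
  )
}

#' Area under a ROC staircase by the trapezoidal rule
#'
#' @param roc A tibble from [roc_curve()].
#' @return The trapezoidal area.
#' @export
roc_auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Pick an operating threshold from a ROC analysis
#'
#' Two labelled selectors are provided: `"youden"` maximizes
#' sensitivity + specificity - 1, and `"sensitivity_first"` picks the
#' smallest threshold whose sensitivity still reaches `min_sensitivity`
#' (screening-test logic: preserve sensitivity, then take the best
#' specificity available). Candidate thresholds are midpoints between
#' adjacent distinct index values.
#'
#' @inheritParams auc_mann_whitney
#' @param method `"youden"` or `"sensitivity_first"`.
#' @param min_sensitivity Floor for the `"sensitivity_first"` selector.
#' @return A `km_threshold_report` at the selected threshold, with the
#'   selector recorded in `notes`.
#' @export
select_threshold <- function(index, outcome,
                             method = c("youden", "sensitivity_first"),
                             min_sensitivity = 0.9) {
  method <- match.arg(method)
  v <- sort(unique(index))
  cand <- (utils::head(v, -1) + utils::tail(v, -1)) / 2
  if (!length(cand)) km_stop("need at least two distinct index values")
  reports <- lapply(cand, function(th)
    confusion_at_threshold(index, outcome, th))
  sens <- vapply(reports, `[[`, numeric(1), "sensitivity")
  spec <- vapply(reports, `[[`, numeric(1), "specificity")
  best <- if (method == "youden") {
    which.max(sens + spec - 1)
  } else {
    ok <- which(sens >= min_sensitivity)
    if (!length(ok)) km_stop("no threshold attains the requested sensitivity")
    ok[which.max(spec[ok])]
  }
  rep <- reports[[best]]
  rep$notes <- c(rep$notes, paste("selector:", method))
  rep
}

#' Univariate correlation table of MLS predictors
#'
#' For each candidate factor, reports the Pearson correlation with the
#' maximum midline shift, the least-squares regression line of the factor
#' on MLS (reported as intercept + gradient * MLS), the p value, and a
#' significance marker (`"NS"` for p > 0.05). Logical factors are encoded
#' 0/1, for which the Pearson r coincides with the point-biserial
#' correlation. Constant factors are marked degenerate instead of erroring.
#'
#' @param cohort A `km_cohort` or compatible data frame.
#' @param factors Named list mapping a display name to either a column name
#'   or a function of the cohort table returning a numeric/logical vector.
#' @param mls_missing `"zero"` or `"drop"`, as in [km_mls_correlation()].
#' @return A tibble with columns `factor`, `r`, `intercept`, `gradient`,
#'   `p`, `significance`.
#' @export
univariate_table <- function(cohort, factors,
                             mls_missing = c("zero", "drop")) {
  mls_missing <- match.arg(mls_missing)
  tbl <- tibble::as_tibble(cohort)
  mls <- tbl$mls_max_mm
  if (mls_missing == "zero") mls[is.na(mls)] <- 0
  rows <- lapply(names(factors), function(nm) {
    spec <- factors[[nm]]
    x <- if (is.function(spec)) spec(tbl) else tbl[[spec]]
    x <- as.numeric(x)
    keep <- !is.na(x) & !is.na(mls)
    x <- x[keep]; y <- mls[keep]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(factor = nm, r = NA_real_,
                            intercept = NA_real_, gradient = NA_real_,
                            p = NA_real_, significance = "NS (degenerate)"))
    }
    ct <- pearson_r(x, y)
    fit <- stats::lm(x ~ y)  # factor as a function of MLS
    tibble::tibble(
      factor = nm, r = ct$r,
      intercept = unname(stats::coef(fit)[1]),
      gradient = unname(stats::coef(fit)[2]),
      p = ct$p,
      significance = if (ct$p > 0.05) "NS" else "< 0.05")
  })
  dplyr::bind_rows(rows)
}

# Standard factor set for the univariate analysis of a cohort table.
default_mls_factors <- function(params = index_params()) {
  list(
    P = function(tbl) tbl$v_penumbra / tbl$v_mip,
    I = function(tbl) tbl$v_core / tbl$v_mip,
    `MTT/MIP` = function(tbl) tbl$v_mtt / tbl$v_mip,
    lysis = function(tbl) tbl$rtpa,
    n_without_lysis = function(tbl)
      ifelse(tbl$thrombectomy, unname(params$n_base[tbl$mtici]),
             params$n_no_thrombectomy),
    n_with_lysis = function(tbl)
      cohort_indices(tbl, params)$n,
    t = function(tbl) {
      h <- tbl$onset_to_groin_hours
      ifelse(is.na(h), 1, ifelse(h <= 4.5, 3, ifelse(h <= 8, 2, 1)))
    },
    DHC = function(tbl) tbl$dhc
  )
}

#' Outcome rates by risk class
#'
#' Computes the index, score and risk class for every patient and tabulates
#' counts and rates of midline shift, decompressive hemicraniectomy and
#' death within 7 days per class. Classes with no patients are reported
#' with `n = 0` and `NA` rates rather than dropped.
#'
#' @param cohort A `km_cohort` or compatible data frame.
#' @param params An [index_params()].
#' @param mls_threshold_mm A midline shift strictly greater than this counts
#'   as an MLS event; default 0 (any recorded shift).
#' @param variant `"km"` or `"kmt"`.
#' @return A tibble with one row per risk class: `risk_class`, `n`,
#'   `mls`, `mls_rate`, `dhc`, `dhc_rate`, `death`, `death_rate`.
#' @export
risk_table <- function(cohort, params = index_params(),
                       mls_threshold_mm = 0, variant = c("km", "kmt")) {
  variant <- match.arg(variant)
  tbl <- cohort_indices(cohort, params, variant = variant)
  tbl$mls_event <- !is.na(tbl$mls_max_mm) & tbl$mls_max_mm > mls_threshold_mm
  out <- lapply(RISK_CLASSES, function(cl) {
    sub <- tbl[tbl$risk_class == cl, ]
    n <- nrow(sub)
    rate <- function(k) if (n > 0) k / n else NA_real_
    tibble::tibble(
      risk_class = cl, n = n,
      mls = sum(sub$mls_event), mls_rate = rate(sum(sub$mls_event)),
      dhc = sum(sub$dhc), dhc_rate = rate(sum(sub$dhc)),
      death = sum(sub$death_7d), death_rate = rate(sum(sub$death_7d)))
  })
  dplyr::bind_rows(out)
}

#' ROC plot
#'
#' @inheritParams auc_mann_whitney
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_roc <- function(index, outcome, title = "Receiver operating characteristic") {
  roc <- roc_curve(index, outcome)
  auc <- auc_mann_whitney(index, outcome)$auc
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::labs(title = title,
                  subtitle = sprintf("AUC = %.1f%%", 100 * auc),
                  x = "1 - specificity", y = "Sensitivity") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Index versus midline-shift scatter plot
#'
#' @param cohort A `km_cohort` or compatible data frame.
#' @param params An [index_params()].
#' @return A ggplot object.
#' @export
plot_index_mls <- function(cohort, params = index_params()) {
  tbl <- cohort_indices(cohort, params)
  tbl$mls <- ifelse(is.na(tbl$mls_max_mm), 0, tbl$mls_max_mm)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$index, y = .data$mls)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$dhc), alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::labs(x = "KM index", y = "Maximum midline shift (mm)",
                  shape = "DHC") +
    ggplot2::theme_minimal()
}
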