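# KM / KMT index computation for a single patient.
#
# The index relates the expected space-occupying burden (swollen core,
# penumbra at risk, perfused parenchyma) to the scanned intracranial volume:
#
#   KM  = (n * (m_ratio * v_core + v_penumbra) + v_mtt) / v_mip
#   KMT = (m_ratio * n^t * v_core + n^t * v_penumbra + v_mtt) / v_mip
#
# n depends on the reperfusion result (mTICI) and lysis, t on the
# onset-to-groin time. Values above 1 indicate that the predicted burden
# exceeds the intracranial capacity, i.e. herniation risk.

RISK_CLASSES <- c("low", "moderate", "high", "severe")

#' Penumbra weighting factor n from the treatment record
#'
#' n models the probability that the penumbra proceeds to infarction. Without
#' thrombectomy n is 1; after thrombectomy it decreases linearly with the
#' mTICI grade (1.0 at grade 0 down to 0.5 at grade 3). Intravenous rtPA
#' multiplies n by the lysis weight lambda.
#'
#' @param treatment A [treatment_record()].
#' @param params An [index_params()].
#' @param use_time_lambda Use the KMT-refitted lysis weight
#'   `lambda_lysis_time` instead of `lambda_lysis`.
#' @return The weighting factor n, a number in (0, 1].
#' @examples
#' weighting_factor_n(treatment_record(TRUE, "3", rtpa = FALSE))   # 0.5
#' weighting_factor_n(treatment_record(TRUE, "2b", rtpa = TRUE))   # 0.49
#' @export
weighting_factor_n <- function(treatment, params = index_params(),
                               use_time_lambda = FALSE) {
  stopifnot(inherits(treatment, "treatment_record"),
            inherits(params, "index_params"))
  n <- if (treatment$thrombectomy) {
    unname(params$n_base[[treatment$mtici]])
  } else {
    params$n_no_thrombectomy
  }
  if (treatment$rtpa) {
    n <- n * (if (use_time_lambda) params$lambda_lysis_time
              else params$lambda_lysis)
  }
  n
}

#' Time factor t from the onset-to-groin interval
#'
#' Discretizes the delay between symptom onset and groin puncture into the
#' exponent t of the KMT index: 3 for up to 4.5 h, 2 for more than 4.5 up to
#' 8 h, 1 beyond 8 h. An unknown onset (wake-up stroke, unclear onset) maps
#' to t = 1, the most conservative choice: it leaves n unshrunk and so never
#' understates the index.
#'
#' @param onset_to_groin_hours Hours from onset to groin puncture, or `NA`.
#' @return Integer time factor in `{1, 2, 3}`.
#' @examples
#' time_factor(3)    # 3
#' time_factor(6)    # 2
#' time_factor(NA)   # 1
#' @export
time_factor <- function(onset_to_groin_hours) {
  h <- onset_to_groin_hours
  if (length(h) != 1L) km_stop("onset_to_groin_hours must be a single value")
  if (is.na(h)) return(1L)
  if (!is.numeric(h) || !is.finite(h) || h < 0)
    km_stop("onset_to_groin_hours must be non-negative or NA")
  if (h <= 4.5) 3L else if (h <= 8) 2L else 1L
}

#' KM index for a single patient
#'
#' @param volumes A [perfusion_volumes()].
#' @param treatment A [treatment_record()].
#' @param params An [index_params()].
#' @return A `km_result`: list with `index`, `score` (0-20 integer),
#'   `risk_class`, and a `components` record (the dimensionless ratios I, P
#'   and B, the applied n, effective m and, for the KMT variant, t).
#' @examples
#' v <- perfusion_volumes(53.81, 87.77, 1086.26, 950.27)
#' km_index(v, treatment_record(TRUE, "3", rtpa = FALSE))
#' @seealso [kmt_index()] for the time-weighted variant.
#' @export
km_index <- function(volumes, treatment, params = index_params()) {
  stopifnot(inherits(volumes, "perfusion_volumes"))
  n <- weighting_factor_n(treatment, params)
  idx <- (n * (params$m_ratio * volumes$v_core + volumes$v_penumbra) +
            volumes$v_mtt) / volumes$v_mip
  km_result(idx, volumes, n = n, m_eff = params$m_ratio * n, t = NA_integer_,
            variant = "KM")
}

#' Time-weighted KMT index for a single patient
#'
#' Raises the penumbra weight n to the time factor t, so that early
#' successful reperfusion shrinks the predicted burden more strongly. The
#' core keeps its relative weight: m^t = m_ratio * n^t (equivalently
#' m = t-th root of m_ratio times n). n is computed with the KMT-refitted
#' lysis weight. With t = 1 the KMT index coincides exactly with the KM index
#' at that lysis weight.
#'
#' `literal_grouping = TRUE` selects an alternative published rendering that
#' scales core and penumbra jointly by `m_ratio * n^t`; it inflates the
#' penumbra term and is provided for comparison only.
#'
#' @inheritParams km_index
#' @param literal_grouping Use the joint-scaling form (see Details).
#' @return A `km_result`.
#' @export
kmt_index <- function(volumes, treatment, params = index_params(),
                      literal_grouping = FALSE) {
  stopifnot(inherits(volumes, "perfusion_volumes"))
  n <- weighting_factor_n(treatment, params, use_time_lambda = TRUE)
  t <- time_factor(treatment$onset_to_groin_hours)
  nt <- n^t
  num <- if (literal_grouping) {
    params$m_ratio * nt * (volumes$v_core + volumes$v_penumbra) + volumes$v_mtt
  } else {
    params$m_ratio * nt * volumes$v_core + nt * volumes$v_penumbra +
      volumes$v_mtt
  }
  km_result(num / volumes$v_mip, volumes, n = n,
            m_eff = params$m_ratio * nt, t = t, variant = "KMT")
}

km_result <- function(index, volumes, n, m_eff, t, variant) {
  structure(
    list(
      index = index,
      score = km_score(index),
      risk_class = risk_class(km_score(index)),
      components = list(
        I = volumes$v_core / volumes$v_mip,
        P = volumes$v_penumbra / volumes$v_mip,
        B = volumes$v_mtt / volumes$v_mip,
        n = n, m_eff = m_eff, t = t
      ),
      variant = variant
    ),
    class = "km_result"
  )
}

#' Discretize a KM index value into the 0-20 KM score
#'
#' Indices below 1.005 score 0; indices at or above 1.195 score 20; in
#' between, the score is `100 * (index - 1)` rounded half away from zero
#' (so an index of 1.14 scores 14). Half-away-from-zero rounding is used
#' deliberately instead of `round()`'s round-half-even, so .5 boundaries
#' always move up.
#'
#' @param index A finite KM or KMT index value.
#' @return Integer score in `[0, 20]`.
#' @examples
#' km_score(1.14)  # 14
#' km_score(0.95)  # 0
#' km_score(1.30)  # 20
#' @export
km_score <- function(index) {
  if (length(index) != 1L || !is.numeric(index) || !is.finite(index))
    km_stop("index must be a single finite number")
  if (index < 1.005) return(0L)
  if (index >= 1.195) return(20L)
  as.integer(floor(100 * (index - 1) + 0.5))
}

#' Risk class from the KM score
#'
#' Scores 0-2 are low risk, 3-7 moderate, 8-13 high and 14-20 severe. The
#' class keys off the integer score (not the raw index) so that the class
#' boundaries are gap-free.
#'
#' @param score Integer KM score in `[0, 20]`.
#' @return One of `"low"`, `"moderate"`, `"high"`, `"severe"` (factor level).
#' @examples
#' risk_class(2)   # low
#' risk_class(14)  # severe
#' @export
risk_class <- function(score) {
  if (length(score) != 1L || !is.numeric(score) || is.na(score) ||
      score != as.integer(score) || score < 0 || score > 20)
    km_stop("score must be an integer in [0, 20]")
  if (score <= 2) "low" else if (score <= 7) "moderate"
  else if (score <= 13) "high" else "severe"
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("%s index: %.4f  (score %d, %s risk)\n",
              x$variant, x$index, x$score, x$risk_class))
  cm <- x$components
  cat(sprintf("  I = %.4f  P = %.4f  B = %.4f  n = %.3f  m_eff = %.3f%s\n",
              cm$I, cm$P, cm$B, cm$n, cm$m_eff,
              if (is.na(cm$t)) "" else sprintf("  t = %d", cm$t)))
  invisible(x)
}
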