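# Domain objects shared by all modules: perfusion volumes, treatment record,
# index parameters. All constructors validate eagerly so downstream code can
# assume the invariants.

km_stop <- function(msg, class = "km_validation_error") {
  stop(structure(
    class = c(class, "km_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

MTICI_LEVELS <- c("0", "1", "2a", "2b", "2c", "3")

EXCLUSION_REASONS <- c(
  "large_hemorrhage",       # large intracranial hemorrhage on initial imaging
  "iatrogenic_bleed_gt20ml",# serious iatrogenic complication (bleed > 20 ml)
  "ctp_technical_failure",  # perfusion scan not diagnostic
  "no_followup_imaging"     # no control scan within the follow-up window
)

#' Perfusion volume summary for one patient
#'
#' Bundles the four volumes (in cm\eqn{^3}) extracted from a CT perfusion
#' study: infarct core, penumbra, the scanned partial intracranial volume
#' (from the maximum-intensity projection, used as the intracranial-volume
#' proxy) and the perfused brain parenchyma volume (from the mean-transit-time
#' map).
#'
#' @param v_core Infarct core volume, cm^3.
#' @param v_penumbra Penumbra volume, cm^3 (disjoint from the core).
#' @param v_mip Partial intracranial volume, cm^3; must be positive.
#' @param v_mtt Perfused brain parenchyma volume, cm^3; at most `v_mip`.
#' @return An object of class `perfusion_volumes`.
#' @examples
#' perfusion_volumes(53.81, 87.77, 1086.26, 950.27)
#' @export
perfusion_volumes <- function(v_core, v_penumbra, v_mip, v_mtt) {
  vals <- c(v_core = v_core, v_penumbra = v_penumbra,
            v_mip = v_mip, v_mtt = v_mtt)
  if (!all(is.finite(vals))) km_stop("all volumes must be finite numbers")
  if (any(vals < 0)) km_stop("volumes must be non-negative")
  if (v_mip <= 0) km_stop("v_mip must be positive")
  if (v_mtt > v_mip + 1e-9)
    km_stop(sprintf("v_mtt (%.2f) exceeds v_mip (%.2f)", v_mtt, v_mip))
  if (v_core + v_penumbra > v_mtt + 1e-9)
    km_stop(sprintf("v_core + v_penumbra (%.2f) exceeds v_mtt (%.2f)",
                    v_core + v_penumbra, v_mtt))
  structure(as.list(vals), class = "perfusion_volumes")
}

#' Treatment record for one patient
#'
#' Captures the therapy actually delivered: mechanical thrombectomy with its
#' mTICI reperfusion grade, intravenous thrombolysis (rtPA), and the time
#' from symptom onset to groin puncture. The mTICI grade must be present
#' exactly when a thrombectomy was performed.
#'
#' @param thrombectomy Logical; was a mechanical thrombectomy performed?
#' @param mtici mTICI reperfusion grade, one of `"0"`, `"1"`, `"2a"`, `"2b"`,
#'   `"2c"`, `"3"`; required iff `thrombectomy` is `TRUE`, otherwise `NA`.
#' @param rtpa Logical; was intravenous rtPA given?
#' @param onset_to_groin_hours Hours from symptom onset to groin puncture;
#'   `NA` for wake-up strokes or unclear onset.
#' @return An object of class `treatment_record`.
#' @examples
#' treatment_record(TRUE, mtici = "2b", rtpa = TRUE, onset_to_groin_hours = 3)
#' treatment_record(FALSE, rtpa = FALSE)
#' @export
treatment_record <- function(thrombectomy, mtici = NA_character_,
                             rtpa = FALSE, onset_to_groin_hours = NA_real_) {
  if (!is.logical(thrombectomy) || length(thrombectomy) != 1L || is.na(thrombectomy))
    km_stop("thrombectomy must be TRUE or FALSE")
  if (!is.logical(rtpa) || length(rtpa) != 1L || is.na(rtpa))
    km_stop("rtpa must be TRUE or FALSE")
  mtici <- as.character(mtici)
  if (thrombectomy) {
    if (is.na(mtici))
      km_stop("mtici grade is required when a thrombectomy was performed")
    if (!mtici %in% MTICI_LEVELS)
      km_stop(sprintf("unknown mTICI grade '%s' (expected one of %s)",
                      mtici, paste(MTICI_LEVELS, collapse = ", ")))
  } else if (!is.na(mtici)) {
    km_stop("mtici must be NA when no thrombectomy was performed")
  }
  if (!is.na(onset_to_groin_hours)) {
    if (!is.numeric(onset_to_groin_hours) || !is.finite(onset_to_groin_hours))
      km_stop("onset_to_groin_hours must be a finite number or NA")
    if (onset_to_groin_hours < 0)
      km_stop("onset_to_groin_hours must be non-negative")
  }
  structure(
    list(thrombectomy = thrombectomy, mtici = mtici, rtpa = rtpa,
         onset_to_groin_hours = as.numeric(onset_to_groin_hours)),
    class = "treatment_record"
  )
}

#' Index parameters
#'
#' The tunable parameters of the KM and KMT indices. Defaults are the values
#' fitted on the original 186-patient derivation cohort; with other perfusion
#' post-processing software the core weighting `m_ratio` in particular may
#' need recalibration (see [calibrate_index()]).
#'
#' @param m_ratio Swelling weight of the infarct core relative to the
#'   penumbra weight n, i.e. m = `m_ratio` * n. Default 2.8.
#' @param lambda_lysis Multiplicative reduction of n when rtPA was given,
#'   used by the plain KM index. Default 0.70.
#' @param lambda_lysis_time As `lambda_lysis` but refitted for the
#'   time-weighted KMT index. Default 0.87.
#' @param n_base Named numeric vector mapping mTICI grade to the base
#'   weighting factor n (probability that the penumbra proceeds to
#'   infarction). Must be strictly decreasing from grade 0 to 3, all in (0, 1].
#' @param n_no_thrombectomy n used when no thrombectomy was performed.
#'   Default 1.0 (untreated penumbra is assumed lost).
#' @return An object of class `index_params`.
#' @examples
#' index_params()                  # published defaults
#' index_params(m_ratio = 2.0)     # e.g. for software with less core bias
#' @export
index_params <- function(m_ratio = 2.8,
                         lambda_lysis = 0.70,
                         lambda_lysis_time = 0.87,
                         n_base = c("0" = 1.0, "1" = 0.9, "2a" = 0.8,
                                    "2b" = 0.7, "2c" = 0.6, "3" = 0.5),
                         n_no_thrombectomy = 1.0) {
  if (!is.numeric(m_ratio) || length(m_ratio) != 1L ||
      !is.finite(m_ratio) || m_ratio <= 0)
    km_stop("m_ratio must be a positive number")
  for (lam in list(lambda_lysis = lambda_lysis,
                   lambda_lysis_time = lambda_lysis_time)) {
    if (!is.numeric(lam) || length(lam) != 1L || lam <= 0 || lam > 1)
      km_stop("lysis weights lambda must lie in (0, 1]")
  }
  if (!setequal(names(n_base), MTICI_LEVELS))
    km_stop("n_base must be named by the six mTICI grades")
  n_base <- n_base[MTICI_LEVELS]
  if (any(n_base <= 0 | n_base > 1))
    km_stop("n_base values must lie in (0, 1]")
  if (any(diff(n_base) >= 0))
    km_stop("n_base must be strictly decreasing from mTICI 0 to 3")
  if (n_no_thrombectomy <= 0 || n_no_thrombectomy > 1)
    km_stop("n_no_thrombectomy must lie in (0, 1]")
  structure(
    list(m_ratio = m_ratio, lambda_lysis = lambda_lysis,
         lambda_lysis_time = lambda_lysis_time, n_base = n_base,
         n_no_thrombectomy = n_no_thrombectomy),
    class = "index_params"
  )
}

#' @export
print.perfusion_volumes <- function(x, ...) {
  cat(sprintf(
    "Perfusion volumes (cm^3): core %.2f | penumbra %.2f | MTT %.2f | MIP %.2f\n",
    x$v_core, x$v_penumbra, x$v_mtt, x$v_mip))
  invisible(x)
}

#' @export
print.treatment_record <- function(x, ...) {
  cat(sprintf(
    "Treatment: thrombectomy %s%s | rtPA %s | onset-to-groin %s\n",
    if (x$thrombectomy) "yes" else "no",
    if (x$thrombectomy) paste0(" (mTICI ", x$mtici, ")") else "",
    if (x$rtpa) "yes" else "no",
    if (is.na(x$onset_to_groin_hours)) "unknown"
    else sprintf("%.1f h", x$onset_to_groin_hours)))
  invisible(x)
}

#' @export
print.index_params <- function(x, ...) {
  cat("KM index parameters\n")
  cat(sprintf("  m_ratio: %.3g   lambda (lysis): %.3g   lambda_t: %.3g\n",
              x$m_ratio, x$lambda_lysis, x$lambda_lysis_time))
  cat("  n by mTICI: ",
      paste(sprintf("%s=%.2g", names(x$n_base), x$n_base), collapse = "  "),
      "\n", sep = "")
  cat(sprintf("  n (no thrombectomy): %.2g\n", x$n_no_thrombectomy))
  invisible(x)
}
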