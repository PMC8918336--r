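# Shared fixtures, all built in code at test time.

# Cohort-mean perfusion volumes used in the worked examples.
mean_volumes <- function() perfusion_volumes(53.81, 87.77, 1086.26, 950.27)

# Minimal single-patient cohort row with sensible defaults, overridable.
patient_row <- function(id = "P1", v_core = 30, v_penumbra = 80,
                        v_mip = 1100, v_mtt = 950,
                        thrombectomy = FALSE, mtici = NA_character_,
                        rtpa = FALSE, onset_to_groin_hours = NA_real_,
                        mls_max_mm = 0, dhc = FALSE, death_7d = FALSE,
                        exclusion_flags = "") {
  tibble::tibble(
    id = id, age = 70, sex = "female", occluded_vessel = "M1",
    nihss = 10L, v_core = v_core, v_penumbra = v_penumbra,
    v_mip = v_mip, v_mtt = v_mtt, thrombectomy = thrombectomy,
    mtici = mtici, rtpa = rtpa,
    onset_to_groin_hours = onset_to_groin_hours,
    mls_max_mm = mls_max_mm, dhc = dhc, death_7d = death_7d,
    exclusion_flags = exclusion_flags)
}

# A cohort in which each patient's index can be dialed in exactly:
# no treatment weighting (n = 1), zero core, v_mip = 1000, v_mtt = 950,
# so index = (penumbra + 950) / 1000 and penumbra = 1000*index - 950.
cohort_with_indices <- function(indices, mls = 0, dhc = FALSE,
                                death = FALSE) {
  k <- length(indices)
  mls <- rep_len(mls, k); dhc <- rep_len(dhc, k); death <- rep_len(death, k)
  rows <- lapply(seq_len(k), function(i) {
    pen <- 1000 * indices[i] - 950
    stopifnot(pen >= 0, pen <= 950)
    patient_row(id = sprintf("IX%03d", i), v_core = 0, v_penumbra = pen,
                v_mip = 1000, v_mtt = 950, mls_max_mm = mls[i],
                dhc = dhc[i], death_7d = death[i])
  })
  km_cohort(dplyr::bind_rows(rows))
}

# Nested-box label map: outer MIP box 10x10x10 cm, MTT 9x9x9, a 3x3x3
# penumbra block with a 2x2x2 core carved from it (1 mm spacing).
nested_box_map <- function() {
  lab <- array(0L, dim = c(120, 120, 120))
  lab[11:110, 11:110, 11:110] <- 1L              # 100^3 voxels = 1000 cm^3
  lab[16:105, 16:105, 16:105] <- 2L              # 90^3 = 729 cm^3
  lab[41:70, 41:70, 41:70] <- 3L                 # 30^3 = 27 cm^3 lesion
  lab[41:60, 41:60, 41:60] <- 4L                 # 20^3 = 8 cm^3 core
  label_map(lab, spacing = c(1, 1, 1))
}
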