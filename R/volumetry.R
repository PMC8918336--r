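# Voxel-based volumetry: turn 3-D label maps into perfusion volumes.
#
# A label map is a single integer array with nested coverage semantics:
#   0 = outside the scanned volume
#   1 = scanned intracranial coverage (MIP) outside the perfused parenchyma
#   2 = perfused brain parenchyma (MTT) outside any lesion
#   3 = penumbra
#   4 = infarct core
# Coverage regions are the label-at-least sets: MIP = labels >= 1,
# MTT = labels >= 2, lesion = labels >= 3. Volumes count voxels times the
# voxel size; no partial-volume weighting is applied (clinical perfusion
# software counts voxels the same way).

LABEL_NAMES <- c("0" = "outside", "1" = "mip", "2" = "mtt",
                 "3" = "penumbra", "4" = "core")

#' Construct a label map
#'
#' @param voxels 3-D integer array with labels 0-4 (see the label scheme in
#'   the package overview: 1 = MIP coverage, 2 = MTT parenchyma,
#'   3 = penumbra, 4 = infarct core; higher labels nest inside lower
#'   coverage by the label-at-least convention).
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm, all positive.
#' @return An object of class `label_map`.
#' @export
label_map <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    km_stop("voxels must be a 3-D array")
  if (anyNA(voxels) || !all(voxels %in% 0:4))
    km_stop("labels must be integers in 0..4")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    km_stop("spacing must be three positive numbers (mm)")
  structure(list(voxels = array(as.integer(voxels), dim = dim(voxels)),
                 spacing = as.numeric(spacing)),
            class = "label_map")
}

#' Read a label map from a NIfTI file
#'
#' Voxel spacing is taken from the header (`pixdim`); orientation metadata
#' is ignored, as volumes are orientation-invariant.
#'
#' @param path Path to a NIfTI-1 file holding the integer label volume.
#' @return A `label_map`.
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  label_map(array(as.integer(round(img)), dim = dim(img)[1:3]), spacing = sp)
}

#' Write a label map to a NIfTI file
#'
#' @param map A `label_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  img <- RNifti::asNifti(map$voxels)
  RNifti::pixdim(img) <- map$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Volume of a label set
#'
#' @param map A `label_map`.
#' @param labels Integer labels to count (e.g. `3:4` for the whole lesion).
#' @return Volume in cm^3: voxel count times voxel volume / 1000.
#' @examples
#' m <- label_map(array(1L, dim = c(10, 10, 10)))
#' mask_volume(m, 1)  # 1000 voxels at 1 mm^3 = 1 cm^3
#' @export
mask_volume <- function(map, labels) {
  stopifnot(inherits(map, "label_map"))
  sum(map$voxels %in% labels) * prod(map$spacing) / 1000
}

#' Extract perfusion volumes from a label map
#'
#' Computes the four volumes under the coverage convention:
#' `v_mip` = labels >= 1, `v_mtt` = labels >= 2, `v_penumbra` = label 3,
#' `v_core` = label 4. By construction the output satisfies the
#' [perfusion_volumes()] invariants.
#'
#' @param map A `label_map`.
#' @return A [perfusion_volumes()].
#' @export
extract_volumes <- function(map) {
  stopifnot(inherits(map, "label_map"))
  perfusion_volumes(
    v_core = mask_volume(map, 4L),
    v_penumbra = mask_volume(map, 3L),
    v_mip = mask_volume(map, 1:4),
    v_mtt = mask_volume(map, 2:4)
  )
}

#' Merge separate binary masks into one label map
#'
#' Accepts the four coverage masks as logical arrays and verifies strict
#' nesting (core inside lesion inside MTT inside MIP) before merging; a
#' violation is reported with the offending pair of labels.
#'
#' @param mip,mtt,penumbra,core Logical 3-D arrays of identical dimensions.
#'   `penumbra` and `core` are the disjoint lesion compartments; `core`
#'   voxels may be marked in `penumbra` too (they are reassigned to core).
#' @param spacing Voxel spacing in mm.
#' @return A `label_map`.
#' @export
merge_masks <- function(mip, mtt, penumbra, core, spacing = c(1, 1, 1)) {
  dims <- dim(mip)
  for (m in list(mtt, penumbra, core))
    if (!identical(dim(m), dims)) km_stop("mask dimensions differ")
  check_nested <- function(inner, outer, what) {
    if (any(inner & !outer))
      km_stop(paste0("nesting violation: ", what))
  }
  lesion <- penumbra | core
  check_nested(core, lesion, "core outside penumbra/core region")
  check_nested(lesion, mtt, "penumbra/core outside MTT coverage")
  check_nested(mtt, mip, "MTT outside MIP coverage")
  lab <- array(0L, dim = dims)
  lab[mip] <- 1L
  lab[mtt] <- 2L
  lab[penumbra] <- 3L
  lab[core] <- 4L
  label_map(lab, spacing)
}

#' Dimensionless brain-occupancy ratios
#'
#' The conceptual form of the index components, defined on true anatomical
#' volumes: the brain-parenchyma fraction `B = 1 - (vs + vv) / iv` (one
#' minus the cerebrospinal-fluid fraction, reflecting protective atrophy),
#' and the core and penumbra fractions `I = vc / iv`, `P = vp / iv`. In
#' practice the scanned partial volumes stand in for these (B as
#' v_mtt / v_mip); this function keeps the anatomical definition available.
#'
#' @param iv Intracranial volume, cm^3 (> 0).
#' @param vs Subarachnoid-space volume, cm^3.
#' @param vv Ventricle volume, cm^3.
#' @param vc Infarct core volume, cm^3.
#' @param vp Penumbra volume, cm^3.
#' @return A list with the input volumes and the ratios `B`, `I`, `P`.
#' @examples
#' conceptual_ratios(iv = 1400, vs = 100, vv = 40, vc = 30, vp = 80)
#' @export
conceptual_ratios <- function(iv, vs, vv, vc, vp) {
  vals <- c(iv = iv, vs = vs, vv = vv, vc = vc, vp = vp)
  if (!all(is.finite(vals)) || any(vals < 0))
    km_stop("all volumes must be finite and non-negative")
  if (iv <= 0) km_stop("iv must be positive")
  if (vs + vv > iv + 1e-9) km_stop("vs + vv exceeds iv")
  c(as.list(vals),
    list(B = 1 - (vs + vv) / iv, I = vc / iv, P = vp / iv))
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Label map %dx%dx%d voxels, spacing %.2gx%.2gx%.2g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  counts <- table(factor(x$voxels, levels = 0:4))
  cat("  voxels:",
      paste(sprintf("%s=%d", LABEL_NAMES, as.integer(counts)),
            collapse = "  "), "\n")
  invisible(x)
}
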