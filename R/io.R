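# Shared I/O: design YAML, NIfTI maps, serialized k-space/coefficients.

#' Write an acquisition design to YAML
#'
#' @param design A [acquisition_design()].
#' @param file Output path.
#' @export
design_to_yaml <- function(design, file) {
  yaml::write_yaml(list(flip_deg = design$flip_deg,
                        phase_deg = design$phase_deg, TR_ms = design$TR,
                        TE_ms = design$TE, slice_mm = design$d,
                        invert = design$invert, N = design$N,
                        inversion_ms = design$inversion_ms), file)
  invisible(file)
}

#' Read an acquisition design from YAML
#'
#' Accepts either an explicit `flip_deg` list or a ramp specification
#' (`ramp: {alpha_a, alpha_b}`) with `N`.
#'
#' @param file YAML path.
#' @return A [acquisition_design()].
#' @export
design_from_yaml <- function(file) {
  cfg <- yaml::read_yaml(file)
  flip <- if (!is.null(cfg$flip_deg)) unlist(cfg$flip_deg)
  else if (!is.null(cfg$ramp))
    seq(cfg$ramp$alpha_a, cfg$ramp$alpha_b, length.out = cfg$N)
  else stop("design YAML needs flip_deg or ramp")
  acquisition_design(flip, TR = cfg$TR_ms, TE = cfg$TE_ms,
                     d = if (is.null(cfg$slice_mm)) 2 else cfg$slice_mm,
                     invert = isTRUE(cfg$invert),
                     phase_deg = if (is.null(cfg$phase_deg)) 0
                     else unlist(cfg$phase_deg),
                     inversion_ms = if (is.null(cfg$inversion_ms)) 20
                     else cfg$inversion_ms)
}

#' Write parameter or frame maps as NIfTI
#'
#' Real maps are written as-is; complex inputs are written as magnitude
#' (keep complex data in the serialized exports). Voxel spacing is
#' derived from the field of view.
#'
#' @param img 2D/3D array.
#' @param file Output path (`.nii` / `.nii.gz`).
#' @param fov_mm In-plane field of view, mm.
#' @param slice_mm Through-plane spacing, mm.
#' @export
write_map_nifti <- function(img, file, fov_mm = 225, slice_mm = 2) {
  if (is.complex(img)) img <- Mod(img)
  pix <- fov_mm / dim(img)[1]
  img <- RNifti::asNifti(img)
  RNifti::pixdim(img) <- if (length(dim(img)) >= 3) c(pix, pix, slice_mm)
  else c(pix, pix)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Serialize simulated k-space (or any QTI object) to disk
#'
#' Raw k-space and subspace coefficients are complex-valued and are
#' stored with R's native serialization, with geometry and design carried
#' inside the object.
#'
#' @param x Object (e.g. `qti_kspace`, `qti_subspace`).
#' @param file Output path (`.rds`).
#' @export
export_qti <- function(x, file) {
  if (inherits(x, "qti_kspace")) x$sampling$cache <- NULL
  saveRDS(x, file)
  invisible(file)
}

#' Load a serialized QTI object
#'
#' @param file Path written by [export_qti()].
#' @return The object, with caches re-initialized.
#' @export
import_qti <- function(file) {
  x <- readRDS(file)
  if (inherits(x, "qti_kspace") && is.null(x$sampling$cache))
    x$sampling$cache <- new.env(parent = emptyenv())
  x
}
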