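# Variable-density spiral sampling with golden-angle rotation.

GOLDEN_ANGLE_DEG <- 180 * (3 - sqrt(5))  # 111.2461...

#' Variable-density spiral sampling scheme
#'
#' Builds an analytic variable-density Archimedean spiral arm reaching
#' `k_max = matrix/2` cycles/FOV (i.e. `1/(2*resolution)` in physical
#' units), whose inner region (a fraction of `k_max`) is fully sampled by
#' the dense-core interleaf count while the periphery is sampled by the
#' full interleaf count. The azimuthal pitch follows `dphi/dk =
#' 2*pi/nu(k)` with `nu(k)` the effective arm count, so consecutive turns
#' of the rotated arm set are Nyquist-spaced in each regime. Per
#' repetition the readout is the base arm rotated either continuously by
#' the golden angle (default) or through a golden-ratio permutation of
#' the interleaf set.
#'
#' @param fov_mm Field of view, mm.
#' @param resolution_mm In-plane resolution, mm; `fov/resolution` sets the
#'   (possibly fractional) nominal matrix size.
#' @param n_interleaves Total interleaves covering k-space.
#' @param n_dense Interleaves sufficient to cover the dense center.
#' @param samples_per_readout Samples along one arm.
#' @param dense_frac Radius fraction of `k_max` treated as the dense core.
#' @param schedule `"golden"` (continuous golden-angle rotation) or
#'   `"permute"` (golden-ratio stepping through the interleaf set).
#' @param arms_per_repetition Interleaves played per repetition (evenly
#'   spaced rotations of the base arm, concatenated into one readout).
#'   The transient-state default is 1; set it to `n_interleaves` for a
#'   fully sampled repetition (calibration / sanity studies).
#' @return An object of class `qti_spiral`. Use [spiral_traj()] for the
#'   per-repetition coordinates (cycles/FOV).
#' @export
make_spiral <- function(fov_mm = 225, resolution_mm = fov_mm / 64,
                        n_interleaves = 89, n_dense = 18,
                        samples_per_readout = 256, dense_frac = 0.2,
                        schedule = c("golden", "permute"),
                        arms_per_repetition = 1) {
  schedule <- match.arg(schedule)
  stopifnot(n_dense <= n_interleaves, n_dense >= 1)
  if (resolution_mm <= 0 || resolution_mm > fov_mm)
    stop("resolution incompatible with the field of view")
  msize <- fov_mm / resolution_mm         # may be fractional
  kmax <- msize / 2                       # cycles/FOV = fov/(2*resolution)
  r <- kmax * seq(0, 1, length.out = samples_per_readout)
  nu <- ifelse(r <= dense_frac * kmax, n_dense, n_interleaves)
  dphi <- 2 * pi / nu * c(0, diff(r))
  phi <- cumsum(dphi)
  base <- r * exp(1i * phi)
  if (arms_per_repetition > 1) {
    rots <- exp(2i * pi * (seq_len(arms_per_repetition) - 1) /
                  arms_per_repetition)
    base <- as.vector(outer(base, rots))
    samples_per_readout <- length(base)
  }
  structure(list(base = base, n_interleaves = as.integer(n_interleaves),
                 n_dense = as.integer(n_dense), kmax = kmax,
                 matrix_size = msize, fov_mm = fov_mm,
                 resolution_mm = resolution_mm, dense_frac = dense_frac,
                 samples_per_readout = as.integer(samples_per_readout),
                 schedule = schedule, cache = new.env(parent = emptyenv())),
            class = "qti_spiral")
}

#' Interleaf index used at a repetition
#'
#' @param sampling A [make_spiral()].
#' @param t Repetition index (1-based).
#' @return Integer interleaf index in `1..n_interleaves` (`"permute"`
#'   schedule) or 1 (the continuously rotated base arm).
#' @export
spiral_interleaf <- function(sampling, t) {
  if (sampling$schedule == "permute") {
    phi <- (sqrt(5) - 1) / 2
    as.integer(floor((t - 1) * phi * sampling$n_interleaves) %%
                 sampling$n_interleaves) + 1L
  } else 1L
}

#' Readout coordinates of one repetition
#'
#' @param sampling A [make_spiral()].
#' @param t Repetition index (1-based).
#' @return Two-column matrix `(kx, ky)` in cycles/FOV.
#' @export
spiral_traj <- function(sampling, t) {
  ang <- if (sampling$schedule == "golden") {
    (t - 1) * GOLDEN_ANGLE_DEG * pi / 180
  } else {
    2 * pi * (spiral_interleaf(sampling, t) - 1) / sampling$n_interleaves
  }
  k <- sampling$base * exp(1i * ang)
  cbind(kx = Re(k), ky = Im(k))
}

# All base interleaves (rotations by 2*pi/n): geometry checks and display.
spiral_interleaf_set <- function(sampling) {
  lapply(seq_len(sampling$n_interleaves), function(j) {
    k <- sampling$base * exp(2i * pi * (j - 1) / sampling$n_interleaves)
    cbind(kx = Re(k), ky = Im(k))
  })
}

# Memoised per-repetition NUFFT plans on an n x n reconstruction grid.
spiral_plans <- function(sampling, N, n, osf = 2, width = 8) {
  key <- sprintf("p_%d_%d_%g_%d", N, n, osf, width)
  if (!is.null(sampling$cache[[key]])) return(sampling$cache[[key]])
  if (sampling$kmax > n / 2 + 1e-9)
    stop("spiral reaches beyond the Nyquist limit of the reconstruction grid")
  plans <- lapply(seq_len(N), function(t) {
    tr <- spiral_traj(sampling, t)
    nufft_plan(tr[, 1], tr[, 2], n, osf, width)
  })
  sampling$cache[[key]] <- plans
  plans
}
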