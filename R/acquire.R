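# Forward acquisition: phantom -> transient-state multi-coil spiral
# k-space.

# Signals for every voxel in the support, computed once per unique
# (T1, T2, v) combination (exact caching, no interpolation) and scaled by
# the per-voxel proton density. Returns list(mask, X) with X an
# nvox_masked x N complex matrix.
phantom_signals <- function(phantom, design, K = design$N + 1L) {
  mask <- phantom$rho > 0
  key <- paste(phantom$T1[mask], phantom$T2[mask], phantom$v[mask])
  uniq <- !duplicated(key)
  pm <- cbind(phantom$T1[mask][uniq], phantom$T2[mask][uniq],
              phantom$v[mask][uniq])
  S <- signal_batch(design, pm, K)               # N x n_unique
  idx <- match(key, key[uniq])
  X <- t(S[, idx, drop = FALSE]) * phantom$rho[mask]
  list(mask = mask, X = X)
}

#' Simulate a transient-state spiral acquisition
#'
#' For every repetition the phantom's instantaneous image (per-voxel
#' transient signal times proton density) is weighted by each coil map
#' and evaluated with the non-uniform Fourier transform on that
#' repetition's spiral arm; circular complex Gaussian noise is added.
#' Per-voxel signals are computed once per unique (T1, T2, v) tuple.
#'
#' @param phantom A [make_phantom()].
#' @param design A [acquisition_design()].
#' @param sampling A [make_spiral()] whose `k_max` fits the phantom grid.
#' @param coils A [make_coils()] on the same grid.
#' @param noise_sd Standard deviation of the complex Gaussian noise per
#'   sample (real and imaginary parts each `noise_sd/sqrt(2)`).
#' @param seed Noise seed; the data are bit-identical for identical
#'   inputs.
#' @return An object of class `qti_kspace`: complex array `y` indexed
#'   `[repetition, coil, sample]`, plus `noise_sd` and references to the
#'   generating design/sampling/coils geometry.
#' @export
acquire <- function(phantom, design, sampling, coils, noise_sd = 0,
                    seed = 1) {
  n <- phantom$shape[1]
  if (!all(dim(coils$sens)[1:2] == n)) stop("coil/phantom geometry mismatch")
  ps <- phantom_signals(phantom, design)
  plans <- spiral_plans(sampling, design$N, n)
  nsamp <- sampling$samples_per_readout
  y <- array(0 + 0i, c(design$N, coils$n_coils, nsamp))
  frame <- matrix(0 + 0i, n, n)
  for (t in seq_len(design$N)) {
    frame[ps$mask] <- ps$X[, t]
    for (c1 in seq_len(coils$n_coils))
      y[t, c1, ] <- nufft_forward(plans[[t]], frame * coils$sens[, , c1])
  }
  if (noise_sd > 0) {
    y <- y + with_local_seed(seed, {
      m <- length(y)
      complex(real = stats::rnorm(m, 0, noise_sd / sqrt(2)),
              imaginary = stats::rnorm(m, 0, noise_sd / sqrt(2)))
    })
  }
  structure(list(y = y, noise_sd = noise_sd, design = design,
                 sampling = sampling, coils = coils, shape = c(n, n),
                 seed = seed),
            class = "qti_kspace")
}

#' Noise level matching a target signal-to-noise ratio
#'
#' @param y Noiseless k-space (`qti_kspace` or complex array).
#' @param snr_db Target SNR in decibel (RMS signal over noise sd).
#' @return Per-sample complex noise standard deviation.
#' @export
noise_sd_for_snr <- function(y, snr_db) {
  if (inherits(y, "qti_kspace")) y <- y$y
  sqrt(mean(Mod(y)^2)) / 10^(snr_db / 20)
}
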