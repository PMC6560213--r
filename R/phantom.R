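# Digital phantoms and simulated coil sensitivities.

#' Digital phantom
#'
#' Builds per-voxel T1/T2/proton-density/velocity maps with a class-label
#' map on a single slice.
#'
#' `"brain2d"` is a head-like ellipse with a white-matter interior, a
#' grey-matter ribbon, CSF-filled ventricles, and small vessel disks
#' carrying blood relaxation times and a through-plane velocity.
#' Relaxation times are the class means used throughout the package
#' (GM 1450/85, WM 900/60, CSF 3600/1750, blood 1740/275 ms).
#' `"tubes"` is a ring of uniform disks spanning a range of (T1, T2) on an
#' empty background, loosely emulating a multi-compartment relaxometry
#' phantom.
#'
#' @param kind `"brain2d"` or `"tubes"`.
#' @param shape Matrix size (single integer, >= 32).
#' @param fov_mm Field of view, mm.
#' @param vessel_v Through-plane speed assigned to vessel voxels, mm/s
#'   (brain2d only).
#' @param seed Seed controlling the small random jitter of vessel
#'   positions; the same seed always yields the identical phantom.
#' @return An object of class `qti_phantom`: list of `n x n` maps `T1`,
#'   `T2`, `rho`, `v`, integer `labels` (with a `classes` attribute), plus
#'   `fov_mm` and `shape`.
#' @export
make_phantom <- function(kind = c("brain2d", "tubes"), shape = 64,
                         fov_mm = 225, vessel_v = 50, seed = 1) {
  kind <- match.arg(kind)
  n <- as.integer(shape[1])
  if (n < 32) stop("phantom needs shape >= 32")
  xg <- (seq_len(n) - (n + 1) / 2) / (n / 2)   # [-1, 1] coordinates
  X <- matrix(xg, n, n); Y <- matrix(xg, n, n, byrow = TRUE)
  T1 <- T2 <- rho <- v <- matrix(0, n, n)
  labels <- matrix(0L, n, n)
  set_region <- function(m, lab, t1, t2, r, vel = 0) {
    T1[m] <<- t1; T2[m] <<- t2; rho[m] <<- r; v[m] <<- vel
    labels[m] <<- lab
  }
  if (kind == "brain2d") {
    classes <- c("background", "GM", "WM", "CSF", "vessel")
    head_m <- (X / 0.78)^2 + (Y / 0.9)^2 <= 1
    wm_m <- (X / 0.56)^2 + (Y / 0.68)^2 <= 1
    set_region(head_m, 1L, 1450, 85, 0.8)                 # GM ribbon
    set_region(wm_m, 2L, 900, 60, 0.7)                    # WM interior
    for (s in c(-1, 1)) {                                  # ventricles
      vent <- ((X - s * 0.16) / 0.1)^2 + (Y / 0.32)^2 <= 1
      set_region(vent, 3L, 3600, 1750, 1.0)
    }
    centers <- with_local_seed(seed, {
      base <- cbind(c(-0.45, 0.45, 0.0, -0.3), c(-0.45, -0.4, 0.62, 0.45))
      base + matrix(stats::runif(8, -0.03, 0.03), 4, 2)
    })
    for (i in seq_len(nrow(centers))) {
      ves <- (X - centers[i, 1])^2 + (Y - centers[i, 2])^2 <= 0.05^2
      set_region(ves, 4L, 1740, 275, 0.9, vessel_v)
    }
  } else {
    classes <- c("tube")
    t1s <- exp(seq(log(300), log(3000), length.out = 9))
    t2s <- exp(seq(log(40), log(800), length.out = 9))
    ang <- 2 * pi * (seq_len(8) - 1) / 8
    cx <- c(0, 0.55 * cos(ang)); cy <- c(0, 0.55 * sin(ang))
    for (i in seq_len(9)) {
      tube <- (X - cx[i])^2 + (Y - cy[i])^2 <= 0.14^2
      set_region(tube, 1L, t1s[i], t2s[i], 1.0)
    }
  }
  attr(labels, "classes") <- classes
  structure(list(T1 = T1, T2 = T2, rho = rho, v = v, labels = labels,
                 fov_mm = fov_mm, shape = c(n, n), kind = kind, seed = seed),
            class = "qti_phantom")
}

#' Simulated receive-coil sensitivities
#'
#' Smooth complex sensitivity maps from Gaussian lobes placed around the
#' field of view with slowly varying phase, normalized so the
#' root-sum-of-squares across coils is 1 at every voxel.
#'
#' @param shape Matrix size.
#' @param n_coils Number of coils (>= 1); a single coil has constant unit
#'   magnitude.
#' @param seed Seed for the small random perturbations of lobe positions
#'   and phases.
#' @return An object of class `qti_coils`: complex array
#'   `n x n x n_coils`.
#' @export
make_coils <- function(shape = 64, n_coils = 8, seed = 1) {
  n <- as.integer(shape[1])
  stopifnot(n_coils >= 1)
  if (n_coils == 1) {
    sens <- array(1 + 0i, c(n, n, 1))
    return(structure(list(sens = sens, n_coils = 1L), class = "qti_coils"))
  }
  xg <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  X <- matrix(xg, n, n); Y <- matrix(xg, n, n, byrow = TRUE)
  sens <- with_local_seed(seed, {
    a <- array(0 + 0i, c(n, n, n_coils))
    ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils +
      stats::runif(n_coils, -0.1, 0.1)
    for (c1 in seq_len(n_coils)) {
      cx <- 1.25 * cos(ang[c1]); cy <- 1.25 * sin(ang[c1])
      mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * 0.8^2))
      ph <- stats::runif(1, 0, 2 * pi) +
        0.5 * (stats::runif(1, -1, 1) * X + stats::runif(1, -1, 1) * Y)
      a[, , c1] <- mag * exp(1i * ph)
    }
    a
  })
  rss <- sqrt(apply(Mod(sens)^2, c(1, 2), sum))
  for (c1 in seq_len(n_coils)) sens[, , c1] <- sens[, , c1] / rss
  structure(list(sens = sens, n_coils = as.integer(n_coils)),
            class = "qti_coils")
}
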