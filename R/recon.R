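# Temporal-subspace reconstruction: rank-R coefficient images fitted to
# undersampled multi-coil spiral data by ADMM with local low-rank
# regularization.

#' Temporal subspace basis from prior signal draws
#'
#' Simulates an ensemble of transient-state signal evolutions for tissue
#' parameters drawn from the class prior (optionally mixing in flowing
#' spins over a velocity range) and takes the top left singular vectors
#' as an orthonormal temporal basis.
#'
#' @param design A [acquisition_design()].
#' @param prior A [tissue_class_prior()].
#' @param n_signals Ensemble size (>= R).
#' @param R Subspace rank (default 10).
#' @param seed Draw seed.
#' @param include_flow Mix flowing-spin signals into the ensemble?
#' @param flow_frac Fraction of draws given a velocity when
#'   `include_flow`.
#' @param v_max Velocities drawn uniformly on (0, v_max] mm/s.
#' @return An object of class `qti_basis`: complex `N x R` matrix `phi`
#'   with orthonormal columns, the singular values of the ensemble and
#'   the generating configuration.
#' @export
build_subspace <- function(design, prior, n_signals = 1000, R = 10,
                           seed = 1, include_flow = TRUE, flow_frac = 0.2,
                           v_max = 100) {
  stopifnot(n_signals >= R)
  theta <- with_local_seed(seed, {
    th <- sample_tissue_prior(prior, n_signals)
    v <- numeric(n_signals)
    if (include_flow) {
      fl <- stats::runif(n_signals) < flow_frac
      v[fl] <- stats::runif(sum(fl), 0, v_max)
    }
    cbind(th, v)
  })
  S <- signal_batch(design, theta)
  sv <- svd(S, nu = R, nv = 0)
  if (sv$d[R] <= 1e-12 * sv$d[1])
    stop(sprintf("signal ensemble is rank deficient below R = %d", R))
  structure(list(phi = sv$u, R = as.integer(R), N = design$N, d = sv$d,
                 design = design, n_signals = n_signals, seed = seed,
                 include_flow = include_flow),
            class = "qti_basis")
}

#' Reconstruction configuration
#'
#' @param lambda Local low-rank weight, expressed relative to the largest
#'   patch singular value of the adjoint (zero-filled) reconstruction.
#' @param patch Spatial patch edge length (patches span the full temporal
#'   dimension through the subspace coefficients).
#' @param admm_rho ADMM penalty parameter.
#' @param n_iters Outer ADMM iterations.
#' @param cg_iters Conjugate-gradient iterations per data-consistency
#'   step.
#' @param tol Relative primal-residual stopping tolerance.
#' @param random_shifts Cyclically shift the patch grid at random each
#'   outer iteration (avoids blocking artifacts). Disable for a fixed
#'   partition, under which the ADMM objective is monotone.
#' @return An object of class `qti_recon_config`.
#' @export
recon_config <- function(lambda = 0.005, patch = 8, admm_rho = 0.05,
                         n_iters = 10, cg_iters = 6, tol = 1e-4,
                         random_shifts = TRUE) {
  stopifnot(lambda >= 0, patch >= 1, admm_rho > 0, n_iters >= 1,
            cg_iters >= 1, tol > 0)
  structure(list(lambda = lambda, patch = patch, admm_rho = admm_rho,
                 n_iters = n_iters, cg_iters = cg_iters, tol = tol,
                 random_shifts = isTRUE(random_shifts)),
            class = "qti_recon_config")
}

#' Subspace forward model (coefficients to k-space)
#'
#' Applies, per repetition, the temporal basis weights to the coefficient
#' images, the coil sensitivities, and the non-uniform Fourier transform
#' on that repetition's spiral arm.
#'
#' @param coeffs Complex `n x n x R` coefficient array (or `qti_subspace`).
#' @param sampling A [make_spiral()].
#' @param coils A [make_coils()].
#' @param basis A [build_subspace()] basis.
#' @return Complex array `[repetition, coil, sample]`.
#' @export
subspace_forward <- function(coeffs, sampling, coils, basis) {
  if (inherits(coeffs, "qti_subspace")) coeffs <- coeffs$coeffs
  n <- dim(coeffs)[1]
  N <- basis$N
  C <- matrix(coeffs, n * n, basis$R)
  TS <- C %*% t(basis$phi)                 # nvox x N frame stack
  plans <- spiral_plans(sampling, N, n)
  y <- array(0 + 0i, c(N, coils$n_coils, sampling$samples_per_readout))
  for (t in seq_len(N)) {
    frame <- matrix(TS[, t], n, n)
    for (c1 in seq_len(coils$n_coils))
      y[t, c1, ] <- nufft_forward(plans[[t]], frame * coils$sens[, , c1])
  }
  y
}

#' Adjoint of the subspace forward model
#'
#' Exact adjoint of [subspace_forward()]:
#' `<forward(c), y> = <c, adjoint(y)>` for all inputs.
#'
#' @param y Complex `[repetition, coil, sample]` array (or `qti_kspace`).
#' @inheritParams subspace_forward
#' @return Complex `n x n x R` coefficient array.
#' @export
subspace_adjoint <- function(y, sampling, coils, basis, n = NULL) {
  if (inherits(y, "qti_kspace")) {
    if (is.null(n)) n <- y$shape[1]
    y <- y$y
  }
  if (is.null(n)) stop("reconstruction grid size n required")
  N <- basis$N
  plans <- spiral_plans(sampling, N, n)
  G <- matrix(0 + 0i, n * n, N)
  for (t in seq_len(N)) {
    g <- matrix(0 + 0i, n, n)
    for (c1 in seq_len(coils$n_coils))
      g <- g + Conj(coils$sens[, , c1]) *
        nufft_adjoint(plans[[t]], y[t, c1, ])
    G[, t] <- as.vector(g)
  }
  array(G %*% Conj(basis$phi), c(n, n, basis$R))
}

#' Local low-rank singular-value shrinkage
#'
#' Partitions the coefficient images into square spatial patches (after
#' an optional cyclic shift), forms each patch's (voxels x R) matrix, and
#' soft-thresholds its singular values.
#'
#' @param coeffs Complex `n x n x R` array.
#' @param patch Patch edge; must not exceed the grid.
#' @param threshold Soft threshold (>= 0) on singular values.
#' @param shift Length-2 cyclic shift applied before patching.
#' @return Array of the same shape.
#' @export
llr_shrink <- function(coeffs, patch, threshold, shift = c(0, 0)) {
  d <- dim(coeffs); n1 <- d[1]; n2 <- d[2]; R <- d[3]
  if (patch > n1 || patch > n2) stop("patch larger than the image grid")
  if (threshold < 0) stop("threshold must be >= 0")
  if (threshold == 0 && all(shift == 0)) return(coeffs)
  i1 <- ((seq_len(n1) - 1 + shift[1]) %% n1) + 1
  i2 <- ((seq_len(n2) - 1 + shift[2]) %% n2) + 1
  x <- coeffs[i1, i2, , drop = FALSE]
  for (p1 in seq(1, n1 - patch + 1, by = patch)) {
    for (p2 in seq(1, n2 - patch + 1, by = patch)) {
      r1 <- p1:min(p1 + patch - 1, n1); r2 <- p2:min(p2 + patch - 1, n2)
      M <- matrix(x[r1, r2, , drop = FALSE], length(r1) * length(r2), R)
      sv <- svd(M)
      dshr <- pmax(sv$d - threshold, 0)
      x[r1, r2, ] <- sv$u %*% (dshr * Conj(t(sv$v)))
    }
  }
  x[order(i1), order(i2), , drop = FALSE]
}

# Sum of singular values over the (shifted) patch partition.
llr_nuclear <- function(coeffs, patch, shift = c(0, 0)) {
  d <- dim(coeffs)
  i1 <- ((seq_len(d[1]) - 1 + shift[1]) %% d[1]) + 1
  i2 <- ((seq_len(d[2]) - 1 + shift[2]) %% d[2]) + 1
  x <- coeffs[i1, i2, , drop = FALSE]
  tot <- 0
  for (p1 in seq(1, d[1] - patch + 1, by = patch))
    for (p2 in seq(1, d[2] - patch + 1, by = patch)) {
      r1 <- p1:min(p1 + patch - 1, d[1]); r2 <- p2:min(p2 + patch - 1, d[2])
      M <- matrix(x[r1, r2, , drop = FALSE], length(r1) * length(r2), d[3])
      tot <- tot + sum(svd(M, nu = 0, nv = 0)$d)
    }
  tot
}

# Largest singular value over the unshifted patch partition.
llr_max_sv <- function(coeffs, patch) {
  d <- dim(coeffs); m <- 0
  for (p1 in seq(1, d[1] - patch + 1, by = patch))
    for (p2 in seq(1, d[2] - patch + 1, by = patch)) {
      M <- matrix(coeffs[p1:(p1 + patch - 1), p2:(p2 + patch - 1), ,
                         drop = FALSE], patch * patch, d[3])
      m <- max(m, svd(M, nu = 0, nv = 0)$d[1])
    }
  m
}

cplx_dot <- function(a, b) sum(Re(Conj(a) * b))

# Largest eigenvalue of A^H A by power iteration; used to normalize the
# encoding operator to unit spectral norm so that the regularization
# weight and ADMM penalty live on the image scale.
operator_norm_sq <- function(sampling, coils, basis, n, iters = 8,
                             seed = 1) {
  x <- with_local_seed(seed, array(
    complex(real = stats::rnorm(n * n * basis$R),
            imaginary = stats::rnorm(n * n * basis$R)), c(n, n, basis$R)))
  ev <- 1
  for (i in seq_len(iters)) {
    x <- subspace_adjoint(subspace_forward(x, sampling, coils, basis),
                          sampling, coils, basis, n = n)
    ev <- sqrt(cplx_dot(x, x))
    x <- x / ev
  }
  ev
}

# CG for (A^H A / L2 + rho I) x = b with A the subspace encoding operator.
cg_solve <- function(b, x0, sampling, coils, basis, rho, iters, n, inv_L2) {
  AHA <- function(x) {
    inv_L2 * subspace_adjoint(subspace_forward(x, sampling, coils, basis),
                              sampling, coils, basis, n = n) + rho * x
  }
  x <- x0
  r <- b - AHA(x)
  p <- r
  rs <- cplx_dot(r, r)
  if (rs < 1e-300) return(x)
  for (i in seq_len(iters)) {
    Ap <- AHA(p)
    alpha <- rs / cplx_dot(p, Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- cplx_dot(r, r)
    if (rs_new < 1e-30) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

#' ADMM reconstruction with local low-rank regularization
#'
#' Solves `min_c 0.5 * ||forward(c) - y||^2 + lambda * sum_patches ||P c||_*`
#' by the alternating direction method of multipliers: a
#' conjugate-gradient data-consistency step, singular-value
#' soft-thresholding on local patches (with a random cyclic patch shift
#' per outer iteration), and a dual update. The encoding operator is
#' first normalized to unit spectral norm (power iteration), so the
#' penalty `admm_rho` and the threshold — `config$lambda` times the
#' largest patch singular value of the normalized adjoint reconstruction
#' — both live on the image scale.
#'
#' @param y A `qti_kspace` or raw `[repetition, coil, sample]` array.
#' @inheritParams subspace_forward
#' @param config A [recon_config()].
#' @param seed Seed for the per-iteration patch shifts.
#' @param n Reconstruction grid (needed when `y` is a raw array).
#' @param verbose Print the objective per iteration?
#' @return An object of class `qti_subspace`: coefficient array `coeffs`
#'   (`n x n x R`), the `basis`, and a per-iteration `objective` log.
#' @export
admm_reconstruct <- function(y, sampling, coils, basis,
                             config = recon_config(), seed = 1, n = NULL,
                             verbose = FALSE) {
  if (inherits(y, "qti_kspace")) {
    if (is.null(n)) n <- y$shape[1]
    y <- y$y
  }
  if (is.null(n)) stop("reconstruction grid size n required")
  # normalize the encoding operator to unit spectral norm: lambda, rho and
  # the CG system then all live on the image scale
  L2 <- operator_norm_sq(sampling, coils, basis, n, seed = seed)
  inv_L2 <- 1 / L2
  b <- inv_L2 * subspace_adjoint(y, sampling, coils, basis, n = n)
  lam <- config$lambda * llr_max_sv(b, config$patch)
  rho <- config$admm_rho
  shifts <- with_local_seed(seed, matrix(
    sample.int(config$patch, 2 * config$n_iters, replace = TRUE) - 1L,
    ncol = 2))
  x <- array(0 + 0i, dim(b)); z <- x; u <- x
  obj <- numeric(0)
  for (it in seq_len(config$n_iters)) {
    x <- cg_solve(b + rho * (z - u), x, sampling, coils, basis, rho,
                  config$cg_iters, n, inv_L2)
    sh <- if (config$lambda > 0 && config$random_shifts) shifts[it, ]
    else c(0L, 0L)
    z <- llr_shrink(x + u, config$patch, lam / rho, sh)
    u <- u + x - z
    resid <- subspace_forward(x, sampling, coils, basis) - y
    o <- 0.5 * inv_L2 * sum(Mod(resid)^2) +
      (if (lam > 0) lam * llr_nuclear(x, config$patch, sh) else 0)
    if (!is.finite(o)) stop("ADMM diverged: non-finite objective")
    obj <- c(obj, o)
    if (verbose)
      message(sprintf("ADMM iter %d: objective %.6g", it, o))
    if (sqrt(cplx_dot(x - z, x - z)) <=
        config$tol * max(sqrt(cplx_dot(x, x)), 1e-30) && it > 1) break
  }
  structure(list(coeffs = z, basis = basis, objective = obj,
                 config = config, n = n),
            class = "qti_subspace")
}

#' Back-project subspace coefficients to the time series
#'
#' @param coeffs A `qti_subspace` or complex `n x n x R` array.
#' @param basis Basis (taken from the object when omitted).
#' @return Complex `n x n x N` array of time frames.
#' @export
project_to_time <- function(coeffs, basis = NULL) {
  if (inherits(coeffs, "qti_subspace")) {
    if (is.null(basis)) basis <- coeffs$basis
    coeffs <- coeffs$coeffs
  }
  n <- dim(coeffs)[1]
  array(matrix(coeffs, n * n, basis$R) %*% t(basis$phi),
        c(n, n, basis$N))
}
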