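# Bayesian experimental design: Fisher-information utility marginalized
# over a tissue-class prior, plus per-class contrast terms, combined into
# a single cost evaluated over flip-angle ramp control points.

#' Tissue-class prior
#'
#' A Gaussian-mixture prior over (T1, T2) built from named tissue classes,
#' together with per-class contrast weights. The default classes are the
#' brain values used throughout the package: grey matter 1450/85 ms, white
#' matter 900/60 ms, cerebrospinal fluid 3600/1750 ms and stationary blood
#' 1740/275 ms, with contrast weights 0.05, 0.05, 0.1 and 0.3 (so the
#' information-utility weight is 1 - 0.5 = 0.5).
#'
#' @param classes Data frame with columns `name`, `T1`, `T2` (ms).
#' @param weights Per-class contrast weights `mu_c >= 0`, `sum(mu_c) <= 1`.
#' @param cv Coefficient of variation of the per-class Gaussian on each
#'   parameter (dispersion = `cv * mean`), truncated at zero.
#' @return An object of class `qti_prior`.
#' @export
tissue_class_prior <- function(classes = data.frame(
                                 name = c("GM", "WM", "CSF", "SB"),
                                 T1 = c(1450, 900, 3600, 1740),
                                 T2 = c(85, 60, 1750, 275)),
                               weights = c(0.05, 0.05, 0.1, 0.3),
                               cv = 0.1) {
  stopifnot(nrow(classes) >= 1, length(weights) == nrow(classes))
  if (any(weights < 0) || sum(weights) > 1 + 1e-12)
    stop("need mu_c >= 0 and sum(mu_c) <= 1")
  if (cv <= 0) stop("dispersion must be positive")
  structure(list(classes = classes, weights = weights, cv = cv,
                 utility_weight = 1 - sum(weights)),
            class = "qti_prior")
}

# Draw n (T1, T2) samples from the class mixture (equal class
# probabilities), Gaussian per class with sd = cv * mean, truncated at
# zero by redrawing.
sample_tissue_prior <- function(prior, n, seed = NULL) {
  draw <- function() {
    cls <- sample.int(nrow(prior$classes), n, replace = TRUE)
    mu <- as.matrix(prior$classes[cls, c("T1", "T2")])
    th <- mu * (1 + prior$cv * matrix(stats::rnorm(2 * n), n, 2))
    bad <- th[, 1] <= 0 | th[, 2] <= 0
    while (any(bad)) {
      th[bad, ] <- mu[bad, , drop = FALSE] *
        (1 + prior$cv * matrix(stats::rnorm(2 * sum(bad)), sum(bad), 2))
      bad <- th[, 1] <= 0 | th[, 2] <= 0
    }
    colnames(th) <- c("T1", "T2")
    th
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Ramp specification
#'
#' Two control points (initial and final flip angle) define a linear
#' flip-angle ramp; all other acquisition variables are carried along.
#'
#' @param alpha_a,alpha_b Initial and final flip angles, degrees,
#'   `0 < alpha_a <= alpha_b <= 180`.
#' @param N Repetitions. @param TR,TE Repetition/echo time, ms.
#' @param d Slice thickness, mm. @param invert Inversion-prepared?
#' @return An object of class `qti_ramp`.
#' @export
ramp_spec <- function(alpha_a, alpha_b, N = 260, TR = 14, TE = 2, d = 2,
                      invert = TRUE) {
  if (!(alpha_a > 0 && alpha_a <= alpha_b && alpha_b <= 180))
    stop("need 0 < alpha_a <= alpha_b <= 180")
  structure(list(alpha_a = alpha_a, alpha_b = alpha_b, N = N, TR = TR,
                 TE = TE, d = d, invert = invert),
            class = "qti_ramp")
}

#' Build the acquisition design of a flip-angle ramp
#'
#' Linearly interpolates N flip angles between the two control points of a
#' [ramp_spec()]. The reference design of the package is the 7/70 degree
#' ramp with 260 repetitions, TE/TR = 2/14 ms, 2 mm slices and an initial
#' inversion, lasting 3.66 s per slice.
#'
#' @param spec A [ramp_spec()].
#' @return A [acquisition_design()].
#' @export
make_ramp_design <- function(spec) {
  stopifnot(inherits(spec, "qti_ramp"))
  acquisition_design(seq(spec$alpha_a, spec$alpha_b, length.out = spec$N),
                     TR = spec$TR, TE = spec$TE, d = spec$d,
                     invert = spec$invert)
}

# Central finite-difference Jacobian of a vector-valued function f(theta)
# at a named positive parameter vector; step = rel_step * theta[i].
fd_central <- function(f, theta, rel_step = 1e-3) {
  if (rel_step <= 0) stop("rel_step must be positive")
  p <- length(theta)
  J <- NULL
  for (i in seq_len(p)) {
    step <- rel_step * theta[i]
    if (step == 0) stop("degenerate finite-difference step")
    up <- theta; up[i] <- up[i] + step
    dn <- theta; dn[i] <- dn[i] - step
    col <- (f(up) - f(dn)) / (2 * step)
    J <- cbind(J, col)
  }
  colnames(J) <- names(theta)
  J
}

#' Sensitivity (Jacobian) of the signal to tissue parameters
#'
#' Central finite differences of [simulate_signal()] with respect to the
#' selected parameters, with per-parameter step `rel_step * value`. The
#' signal is linear in `rho`, so its column equals `s / rho` to rounding.
#'
#' @param design A [acquisition_design()].
#' @param params A [tissue_params()] strictly inside the parameter domain.
#' @param which Parameters to differentiate; subset of
#'   `c("T1", "T2", "rho", "v")`.
#' @param rel_step Relative step (> 0).
#' @return Complex `N x length(which)` matrix.
#' @export
signal_jacobian <- function(design, params, which = c("T1", "T2", "rho"),
                            rel_step = 1e-3) {
  which <- match.arg(which, c("T1", "T2", "rho", "v"), several.ok = TRUE)
  th <- c(T1 = params$T1, T2 = params$T2, rho = Re(params$rho), v = params$v)[which]
  f <- function(t) {
    pp <- params
    for (nm in names(t)) pp[[nm]] <- t[[nm]]
    simulate_signal(design, pp)$s
  }
  fd_central(f, th, rel_step)
}

#' Fisher-information utility of a design at one parameter point
#'
#' Under additive Gaussian noise the information carried about the tissue
#' parameters is the determinant of the Fisher information matrix
#' `M[i, j] = Re(sum_t dS_t/dtheta_i * Conj(dS_t/dtheta_j)) / noise_sd^2`,
#' assembled here from first-derivative sensitivities.
#'
#' @inheritParams signal_jacobian
#' @param noise_sd Gaussian noise standard deviation (same scale as the
#'   signal).
#' @return Non-negative scalar; 0 for a singular information matrix.
#' @export
information_utility <- function(design, params, noise_sd = 1,
                                which = c("T1", "T2", "rho"),
                                rel_step = 1e-3) {
  J <- signal_jacobian(design, params, which, rel_step)
  fisher_det(J, noise_sd)
}

fisher_det <- function(J, noise_sd) {
  M <- Re(t(J) %*% Conj(J)) / noise_sd^2
  u <- det(M)
  if (!is.finite(u) || u < 0) 0 else u
}

# Fast utility for a (T1, T2) sample matrix: one batched EPG call covering
# base and perturbed parameter rows. rho enters linearly so its
# sensitivity column is the base signal itself (the exact value of its
# central difference). Returns the vector u(theta_i).
utility_batch <- function(design, theta, noise_sd = 1, rel_step = 1e-3) {
  n <- nrow(theta)
  T1 <- theta[, 1]; T2 <- theta[, 2]
  h1 <- rel_step * T1; h2 <- rel_step * T2
  pm <- cbind(c(T1, T1 + h1, T1 - h1, T1, T1),
              c(T2, T2, T2, T2 + h2, T2 - h2),
              0)
  S <- signal_batch(design, pm)
  base <- S[, seq_len(n), drop = FALSE]
  dT1 <- (S[, n + seq_len(n), drop = FALSE] -
          S[, 2 * n + seq_len(n), drop = FALSE]) / rep(2 * h1, each = nrow(S))
  dT2 <- (S[, 3 * n + seq_len(n), drop = FALSE] -
          S[, 4 * n + seq_len(n), drop = FALSE]) / rep(2 * h2, each = nrow(S))
  vapply(seq_len(n), function(i)
    fisher_det(cbind(T1 = dT1[, i], T2 = dT2[, i], rho = base[, i]), noise_sd),
    numeric(1))
}

#' Marginalized information utility of a design
#'
#' Monte-Carlo average of `log u(design; theta)` over tissue parameters
#' drawn from the class-mixture prior. Draws with a singular information
#' matrix contribute `log(eps)`.
#'
#' @param design A [acquisition_design()].
#' @param prior A [tissue_class_prior()].
#' @param n_samples Monte-Carlo sample count (>= 1).
#' @param seed RNG seed making the estimate deterministic.
#' @param noise_sd Noise level entering the information matrix.
#' @param eps Floor inserted for zero utility draws.
#' @param theta_samples Optional precomputed `n x 2` (T1, T2) sample
#'   matrix; overrides `n_samples`/`seed` (used to share one draw across a
#'   design grid).
#' @return Scalar utility `U(design)`.
#' @export
marginal_utility <- function(design, prior, n_samples = 200, seed = 1,
                             noise_sd = 1, eps = 1e-300,
                             theta_samples = NULL) {
  if (is.null(theta_samples)) {
    stopifnot(n_samples >= 1)
    theta_samples <- sample_tissue_prior(prior, n_samples, seed)
  }
  u <- utility_batch(design, theta_samples, noise_sd)
  mean(log(pmax(u, eps)))
}

#' Per-class tissue contrast of a design
#'
#' For each class the contrast is the worst-case (over competing classes)
#' of the best (over echoes) absolute complex signal separation,
#' `min_{d != c} max_t |s_t(theta_c) - s_t(theta_d)|`, evaluated at the
#' class means with unit proton density and no flow.
#'
#' @param design A [acquisition_design()].
#' @param prior A [tissue_class_prior()] with at least two classes.
#' @param aggregate `"min"` (worst-case, default) or `"mean"` over
#'   competing classes.
#' @return Named per-class contrast vector.
#' @export
contrast_term <- function(design, prior, aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  cl <- prior$classes
  if (nrow(cl) < 2) stop("contrast needs at least two classes")
  S <- signal_batch(design, cbind(cl$T1, cl$T2, 0))
  n <- nrow(cl)
  D <- matrix(0, n, n)
  for (c1 in seq_len(n - 1)) for (c2 in (c1 + 1):n) {
    D[c1, c2] <- D[c2, c1] <- max(Mod(S[, c1] - S[, c2]))
  }
  agg <- if (aggregate == "min") function(x) min(x) else function(x) mean(x)
  out <- vapply(seq_len(n), function(c1) agg(D[c1, -c1]), numeric(1))
  names(out) <- cl$name
  out
}

#' Design cost combining encoding utility and tissue contrast
#'
#' `cost = -((1 - sum(mu_c)) * U + sum_c mu_c * contrast_c)`; lower is
#' better, so minimizing the cost maximizes both the marginal information
#' utility and the weighted per-class contrasts.
#'
#' @inheritParams marginal_utility
#' @return A list of class `qti_cost` with elements `utility`, `contrast`
#'   (named per-class), and `total_cost`.
#' @export
design_cost <- function(design, prior, n_samples = 200, seed = 1,
                        noise_sd = 1, theta_samples = NULL) {
  U <- marginal_utility(design, prior, n_samples, seed, noise_sd,
                        theta_samples = theta_samples)
  ct <- contrast_term(design, prior)
  structure(list(utility = U, contrast = ct,
                 total_cost = -(prior$utility_weight * U +
                                  sum(prior$weights * ct))),
            class = "qti_cost")
}

#' Exhaustive ramp optimization over a control-point grid
#'
#' Evaluates [design_cost()] for every admissible pair of initial/final
#' flip angles on a grid, sharing one Monte-Carlo parameter draw across
#' all points, and returns the minimizer (ties broken toward smaller
#' `alpha_a`, then smaller `alpha_b`) together with the full cost
#' landscape.
#'
#' @param grid_a,grid_b Candidate initial/final flip angles, degrees.
#' @param prior A [tissue_class_prior()].
#' @param n_samples,seed,noise_sd Passed to the shared prior draw and
#'   utility.
#' @param N,TR,TE,d,invert Acquisition variables of every candidate ramp.
#' @return List with `best` (a [ramp_spec()]) and `landscape` (data frame
#'   with one row per grid point: `alpha_a`, `alpha_b`, `utility`,
#'   `contrast_<class>` columns and `cost`).
#' @export
optimize_ramp <- function(grid_a = 1:15, grid_b = seq(40, 90, by = 5),
                          prior = tissue_class_prior(), n_samples = 200,
                          seed = 1, noise_sd = 1, N = 260, TR = 14, TE = 2,
                          d = 2, invert = TRUE) {
  pts <- expand.grid(alpha_a = grid_a, alpha_b = grid_b)
  pts <- pts[pts$alpha_a <= pts$alpha_b, , drop = FALSE]
  if (nrow(pts) == 0) stop("empty admissible grid")
  pts <- pts[order(pts$alpha_a, pts$alpha_b), , drop = FALSE]
  theta <- sample_tissue_prior(prior, n_samples, seed)
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    spec <- ramp_spec(pts$alpha_a[i], pts$alpha_b[i], N = N, TR = TR,
                      TE = TE, d = d, invert = invert)
    cb <- design_cost(make_ramp_design(spec), prior, theta_samples = theta,
                      noise_sd = noise_sd)
    c(alpha_a = pts$alpha_a[i], alpha_b = pts$alpha_b[i],
      utility = cb$utility, stats::setNames(cb$contrast,
        paste0("contrast_", names(cb$contrast))), cost = cb$total_cost)
  })
  landscape <- as.data.frame(do.call(rbind, rows))
  best <- which.min(landscape$cost)  # rows sorted lexicographically
  list(best = ramp_spec(landscape$alpha_a[best], landscape$alpha_b[best],
                        N = N, TR = TR, TE = TE, d = d, invert = invert),
       landscape = landscape)
}
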