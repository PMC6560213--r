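test_that("ramp design interpolates control points and reports duration", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 260, TR = 14, TE = 2))
  expect_equal(design_duration(des), 3.66)                 # 0.02 + 260*0.014
  expect_equal(des$flip_deg[1], 7)
  expect_equal(des$flip_deg[260], 70)
  expect_equal(make_ramp_design(ramp_spec(10, 80, N = 2))$flip_deg, c(10, 80))
  expect_equal(unique(make_ramp_design(ramp_spec(30, 30, N = 5))$flip_deg), 30)
  expect_error(ramp_spec(70, 7), "alpha")
})

test_that("finite differences are second order and exact for linear terms", {
  # closed-form check on a mono-exponential toy signal
  f <- function(th) exp(-(1:50) / th[["T2"]])
  J <- qti:::fd_central(f, c(T2 = 80), rel_step = 1e-4)
  expect_lt(max(abs(J - (1:50) / 80^2 * exp(-(1:50) / 80))), 1e-6)
  # halving the step shrinks the error ~4x (central differences)
  g <- function(th) th[["a"]]^3
  e1 <- abs(qti:::fd_central(g, c(a = 2), 1e-3) - 12)
  e2 <- abs(qti:::fd_central(g, c(a = 2), 5e-4) - 12)
  expect_gt(e1 / e2, 3.5); expect_lt(e1 / e2, 4.5)

  des <- make_ramp_design(ramp_spec(7, 70, N = 30))
  p <- tissue_params(1450, 85, rho = 2)
  J <- signal_jacobian(des, p, which = c("T1", "rho"))
  s <- simulate_signal(des, p)$s
  expect_lt(max(Mod(J[, "rho"] - s / 2)), 1e-12)          # linearity in rho
  expect_error(signal_jacobian(des, p, rel_step = 0), "rel_step")
})

test_that("information utility behaves like a Fisher determinant", {
  des0 <- acquisition_design(rep(0, 16), TR = 14, TE = 2, invert = FALSE)
  p <- tissue_params(1450, 85)
  expect_equal(information_utility(des0, p), 0)            # no signal

  # orthogonal-sensitivity toy case: det equals the product of the
  # per-parameter sums of squared derivatives
  J <- cbind(c(1 + 2i, 0, 0, 3i), c(0, 2, -1i, 0))
  expect_equal(qti:::fisher_det(J, 1),
               sum(Mod(J[, 1])^2) * sum(Mod(J[, 2])^2), tolerance = 1e-12)

  # additivity over echoes: stacked designs = summed information matrices
  des <- make_ramp_design(ramp_spec(7, 70, N = 24))
  J1 <- signal_jacobian(des, p); J2 <- signal_jacobian(des0, p)
  M <- function(J) Re(t(J) %*% Conj(J))
  expect_equal(det(M(rbind(J1, J2))), det(M(J1) + M(J2)), tolerance = 1e-9)

  # duplicating every repetition doubles each entry, scaling u by 2^p
  u1 <- qti:::fisher_det(J1, 1)
  expect_equal(qti:::fisher_det(rbind(J1, J1), 1) / u1, 2^3,
               tolerance = 1e-9)

  # noise scaling: u / s^(2p) exactly
  expect_equal(information_utility(des, p, noise_sd = 3),
               information_utility(des, p, noise_sd = 1) / 3^6,
               tolerance = 1e-10)
})

test_that("marginal utility reduces to a point evaluation and floors zeros", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 24))
  prior <- small_prior()
  th <- matrix(c(1450, 85), 1)
  U <- marginal_utility(des, prior, theta_samples = th)
  # fast-path consistency with the public per-point utility
  expect_equal(U, log(information_utility(des, tissue_params(1450, 85))),
               tolerance = 1e-6)
  des0 <- acquisition_design(rep(0, 24), TR = 14, TE = 2, invert = FALSE)
  expect_equal(marginal_utility(des0, prior, theta_samples = th), log(1e-300))
  # noise rescaling shifts U by -2p log s for every draw
  th2 <- qti:::sample_tissue_prior(prior, 25, seed = 3)
  expect_equal(marginal_utility(des, prior, theta_samples = th2, noise_sd = 2),
               marginal_utility(des, prior, theta_samples = th2) -
                 6 * log(2), tolerance = 1e-9)
})

test_that("Monte-Carlo utility estimates are consistent across sample sizes", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 24))
  prior <- small_prior()
  u_small <- marginal_utility(des, prior, n_samples = 100, seed = 5)
  u_big <- marginal_utility(des, prior, n_samples = 1000, seed = 6)
  reps <- vapply(11:18, function(s)
    marginal_utility(des, prior, n_samples = 100, seed = s), numeric(1))
  se <- stats::sd(reps)
  expect_lt(abs(u_big - u_small), 3 * se + 1e-12)
  # determinism given the seed
  expect_identical(u_small, marginal_utility(des, prior, 100, seed = 5))
})

test_that("contrast term measures worst-case class separation", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 40))
  two_same <- tissue_class_prior(
    classes = data.frame(name = c("a", "b"), T1 = c(900, 900),
                         T2 = c(60, 60)), weights = c(0.2, 0.2))
  expect_equal(unname(contrast_term(des, two_same)), c(0, 0))
  two <- tissue_class_prior(
    classes = data.frame(name = c("a", "b"), T1 = c(900, 1450),
                         T2 = c(60, 85)), weights = c(0.2, 0.2))
  ct <- contrast_term(des, two)
  expect_equal(ct[["a"]], ct[["b"]])                      # symmetric pair
  expect_true(all(contrast_term(des, small_prior()) <= 2))  # |f| <= 1 bound
  one <- tissue_class_prior(classes = data.frame(name = "a", T1 = 900,
                                                 T2 = 60), weights = 0.2)
  expect_error(contrast_term(des, one), "two classes")
})

test_that("blood separates best late in the designed ramp", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 260))
  cl <- small_prior()$classes
  S <- qti:::signal_batch(des, cbind(cl$T1, cl$T2, 0))
  sb <- which(cl$name == "SB")
  sep <- do.call(pmin, lapply(setdiff(seq_len(nrow(cl)), sb),
                              function(d) Mod(S[, sb] - S[, d])))
  expect_gt(which.max(sep), 130)                          # latter half
})

test_that("design cost combines utility and contrast exactly", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 40))
  prior <- small_prior()
  th <- qti:::sample_tissue_prior(prior, 20, seed = 2)
  cb <- design_cost(des, prior, theta_samples = th)
  expect_equal(cb$total_cost,
               -(prior$utility_weight * cb$utility +
                   sum(prior$weights * cb$contrast)), tolerance = 1e-12)
  # mu = 0: pure encoding design
  p0 <- tissue_class_prior(weights = rep(0, 4))
  cb0 <- design_cost(des, p0, theta_samples = th)
  expect_equal(cb0$total_cost, -cb0$utility, tolerance = 1e-12)
  # sum(mu) = 1: utility ignored
  p1 <- tissue_class_prior(weights = c(0.25, 0.25, 0.25, 0.25))
  cb1 <- design_cost(des, p1, theta_samples = th)
  expect_equal(cb1$total_cost, -sum(0.25 * cb1$contrast), tolerance = 1e-12)
})

test_that("exhaustive ramp search returns the landscape minimizer", {
  prior <- small_prior()
  one <- optimize_ramp(grid_a = 7, grid_b = 70, prior = prior,
                       n_samples = 10, seed = 1, N = 24)
  expect_equal(one$best$alpha_a, 7)
  expect_equal(one$best$alpha_b, 70)
  expect_equal(nrow(one$landscape), 1)

  res <- optimize_ramp(grid_a = c(2, 8), grid_b = c(50, 80), prior = prior,
                       n_samples = 25, seed = 4, N = 24)
  L <- res$landscape
  expect_equal(nrow(L), 4)
  expect_true(all(c("utility", "contrast_SB", "cost") %in% names(L)))
  best <- which.min(L$cost)
  expect_equal(res$best$alpha_a, L$alpha_a[best])
  # identical seed reproduces the landscape bit for bit
  res2 <- optimize_ramp(grid_a = c(2, 8), grid_b = c(50, 80), prior = prior,
                        n_samples = 25, seed = 4, N = 24)
  expect_identical(res$landscape, res2$landscape)
  # admissibility: candidate pairs with alpha_a > alpha_b are dropped
  tri <- optimize_ramp(grid_a = c(30, 60), grid_b = c(45, 75),
                       prior = prior, n_samples = 10, seed = 1, N = 24)
  expect_equal(nrow(tri$landscape), 3)
})

test_that("contrast-only preference is for small initial flip angles", {
  prior <- small_prior()
  grid <- expand.grid(alpha_a = c(1, 5, 10, 15), alpha_b = c(40, 70, 90))
  ct <- vapply(seq_len(nrow(grid)), function(i) {
    des <- make_ramp_design(ramp_spec(grid$alpha_a[i], grid$alpha_b[i],
                                      N = 260))
    sum(prior$weights * contrast_term(des, prior))
  }, numeric(1))
  expect_lt(grid$alpha_a[which.max(ct)], 10)
})
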