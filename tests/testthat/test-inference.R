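test_that("profiled likelihood is scale invariant and exact at truth", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 60))
  p <- tissue_params(1450, 85, rho = 1.3 - 0.4i)
  s <- simulate_signal(des, p)$s
  ll <- log_likelihood(s, p, des, noise_sd = 0.01)
  expect_equal(ll, 0)                                     # zero residual
  expect_equal(log_likelihood(s * (2 + 1i), p, des, 0.01), 0)
  # ordering matches direct least-squares residuals on a two-point grid
  cand <- list(tissue_params(900, 60), tissue_params(2000, 150))
  res <- vapply(cand, function(q) {
    f <- simulate_signal(des, q)$s
    rho <- sum(Conj(f) * s) / sum(Mod(f)^2)
    sum(Mod(s - rho * f)^2)
  }, numeric(1))
  lls <- vapply(cand, log_likelihood, numeric(1), signal = s, design = des,
                noise_sd = 0.01)
  expect_equal(order(lls), order(-res))
  zero <- tissue_params(1000, 100)
  expect_equal(log_likelihood(s, zero,
                              acquisition_design(rep(0, 60), 14, 2,
                                                 invert = FALSE), 0.01),
               -Inf)
})

test_that("posterior sampling recovers noiseless parameters within 1%", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 260))
  truth <- tissue_params(1450, 85, rho = 0.8)
  s <- simulate_signal(des, truth)$s
  ps <- posterior_sample(s, des, noise_sd = 0.002, n_stages = 6,
                         n_particles = 300, seed = 12)
  expect_lt(abs(ps$ml[["T1"]] / 1450 - 1), 0.01)
  expect_lt(abs(ps$ml[["T2"]] / 85 - 1), 0.01)
  expect_lt(Mod(ps$rho_ml) / 0.8 - 1, 0.01)
  pr <- inference_prior()
  expect_true(all(ps$samples[, "T1"] >= pr$lower["T1"] &
                    ps$samples[, "T1"] <= pr$upper["T1"]))
  expect_true(all(ps$samples[, "T2"] >= pr$lower["T2"] &
                    ps$samples[, "T2"] <= pr$upper["T2"]))
  expect_true(all(ps$sd >= 0))
  expect_true(all(ps$mean >= ps$q025 & ps$mean <= ps$q975))
  expect_error(posterior_sample(s * 0, des, noise_sd = 0.01), "zero")
})

test_that("posterior width shrinks as the noise level decreases", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 260))
  s <- simulate_signal(des, tissue_params(900, 60))$s
  sds <- vapply(c(0.05, 0.01, 0.002), function(ns)
    posterior_sample(s, des, noise_sd = ns, n_stages = 6,
                     n_particles = 250, seed = 3)$sd[["T1"]], numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("sampler agrees with the analytic posterior on a linear model", {
  # one-parameter Gaussian sub-problem embedded in the same machinery:
  # direct numerical posterior vs particle summaries
  des <- make_ramp_design(ramp_spec(7, 70, N = 260))
  ns <- 0.02
  s <- simulate_signal(des, tissue_params(1200, 85))$s
  ps <- posterior_sample(s, des, noise_sd = ns, n_stages = 8,
                         n_particles = 500, seed = 5)
  # numerical reference posterior on a fine T1 x T2 grid
  T1g <- seq(ps$mean[["T1"]] - 5 * ps$sd[["T1"]],
             ps$mean[["T1"]] + 5 * ps$sd[["T1"]], length.out = 101)
  T2g <- seq(ps$mean[["T2"]] - 5 * ps$sd[["T2"]],
             ps$mean[["T2"]] + 5 * ps$sd[["T2"]], length.out = 101)
  grid <- as.matrix(expand.grid(T1 = T1g, T2 = T2g))
  lw <- qti:::loglik_batch(s, grid, des, ns)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  ref_mean <- colSums(grid * w)
  ref_sd <- sqrt(colSums(sweep(grid, 2, ref_mean)^2 * w))
  mc_se <- ref_sd / sqrt(ps$ess)
  expect_lt(abs(ps$mean[["T1"]] - ref_mean[["T1"]]), 3 * mc_se[["T1"]])
  expect_lt(abs(ps$mean[["T2"]] - ref_mean[["T2"]]), 3 * mc_se[["T2"]])
  expect_lt(abs(ps$sd[["T1"]] / ref_sd[["T1"]] - 1), 0.35)
})

test_that("dictionary matching finds atoms and ignores complex scale", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 60))
  dict <- build_dictionary(des, n_T1 = 30, n_T2 = 30)
  expect_equal(max(abs(colSums(Mod(dict$atoms)^2) - 1)), 0,
               tolerance = 1e-12)
  j <- 217
  hit <- dictionary_match(dict$atoms[, j], dict)
  expect_equal(unname(hit$params[1, ]), unname(dict$params[j, ]))
  expect_equal(hit$correlation, 1, tolerance = 1e-9)
  scaled <- dictionary_match(dict$atoms[, j] * (0.3 - 2i), dict)
  expect_equal(unname(scaled$params[1, ]), unname(dict$params[j, ]))
  expect_equal(scaled$correlation, 1, tolerance = 1e-9)
})

test_that("matching and posterior ML agree at high SNR", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 260))
  dict <- build_dictionary(des, T1_range = c(400, 4000),
                           T2_range = c(30, 2000), n_T1 = 120, n_T2 = 160)
  step_T1 <- exp(log(4000 / 400) / 119) - 1
  step_T2 <- exp(log(2000 / 30) / 159) - 1
  set.seed(61)
  for (i in 1:5) {
    T1 <- exp(runif(1, log(600), log(3000)))
    T2 <- exp(runif(1, log(50), log(min(T1, 1200))))
    s <- simulate_signal(des, tissue_params(T1, T2))$s
    s <- s + 0.001 * complex(real = rnorm(260), imaginary = rnorm(260))
    dm <- dictionary_match(s, dict)
    ps <- posterior_sample(s, des, noise_sd = 0.001, n_stages = 6,
                           n_particles = 250, seed = i)
    expect_lt(abs(dm$params[1, "T1"] / ps$ml[["T1"]] - 1), 2 * step_T1)
    expect_lt(abs(dm$params[1, "T2"] / ps$ml[["T2"]] - 1), 2 * step_T2)
  }
})

test_that("map fitting recovers a noiseless phantom and masks correctly", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 120))
  ph <- make_phantom("brain2d", 32, seed = 2)
  ps <- qti:::phantom_signals(ph, des)
  frames <- array(0 + 0i, c(32, 32, 120))
  fm <- matrix(frames, 32 * 32, 120)
  fm[as.vector(ps$mask), ] <- ps$X
  frames <- array(fm, c(32, 32, 120))
  dict <- build_dictionary(des, T1_range = c(500, 4500),
                           T2_range = c(30, 2200), n_T1 = 120, n_T2 = 220)
  stationary <- ps$mask & ph$v == 0
  maps <- fit_maps(frames, stationary, des, method = "dict", dict = dict)
  cls <- attr(ph$labels, "classes")
  for (lab in c("GM", "WM", "CSF")) {
    m <- ph$labels == which(cls == lab) - 1
    expect_lt(abs(stats::median(maps$T1[m]) / ph$T1[m][1] - 1), 0.02)
    expect_lt(abs(stats::median(maps$T2[m]) / ph$T2[m][1] - 1), 0.02)
  }
  expect_true(all(maps$PD[!stationary] == 0))             # background zero
  expect_true(all(maps$PD[stationary] > 0))
  # single-voxel mask reduces to the per-voxel operation
  one <- matrix(FALSE, 32, 32)
  vox <- which(ph$labels == which(cls == "WM") - 1)[5]
  one[vox] <- TRUE
  m1 <- fit_maps(frames, one, des, method = "dict", dict = dict)
  dm <- dictionary_match(fm[vox, ], dict)
  expect_equal(m1$T1[vox], unname(dm$params[1, "T1"]))
  expect_error(fit_maps(frames, matrix(FALSE, 32, 32), des), "mask")
})

test_that("least-squares refinement stays within the dictionary cell", {
  des <- make_ramp_design(ramp_spec(7, 70, N = 120))
  truth <- tissue_params(1111, 71)
  s <- simulate_signal(des, truth)$s
  frames <- array(s, c(1, 1, 120))
  dict <- build_dictionary(des, n_T1 = 60, n_T2 = 60)
  maps <- fit_maps(frames, matrix(TRUE, 1, 1), des, method = "lsq",
                   dict = dict, noise_sd = 0.01)
  expect_lt(abs(maps$T1[1, 1] / 1111 - 1), 0.01)
  expect_lt(abs(maps$T2[1, 1] / 71 - 1), 0.01)
})
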