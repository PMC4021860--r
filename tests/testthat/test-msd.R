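test_that("MSD of the elbow trajectory matches hand enumeration", {
  curve <- compute_msd(elbow_ensemble(), max_lag = 2)
  expect_equal(curve$msd, c(1, 2))
  expect_equal(curve$n_pairs, c(2L, 1L))
  expect_equal(curve$t, c(0.01, 0.02))
})

test_that("a stationary trajectory has identically zero MSD", {
  e <- make_ensemble(list(data.frame(frame = 0:9, x = rep(0, 10),
                                     y = rep(3, 10))), dt = 0.01)
  curve <- compute_msd(e, max_lag = 4)
  expect_equal(curve$msd, rep(0, 4))
  expect_equal(curve$sd, rep(0, 4))
})

test_that("compute_msd equals the brute-force double-loop oracle", {
  set.seed(77)
  for (rep in 1:20) {
    tr <- random_traj(50)
    e <- make_ensemble(list(tr), dt = 0.01)
    curve <- compute_msd(e, max_lag = 12)
    for (k in seq_len(nrow(curve))) {
      vals <- oracle_msd_one(tr$frame, tr$x, tr$y, curve$lag[k])
      expect_equal(curve$msd[k], mean(vals), tolerance = 1e-10)
      expect_equal(curve$n_pairs[k], length(vals))
    }
  }
})

test_that("ensemble MSD pools displacements and counts independent pairs", {
  set.seed(78)
  trs <- list(random_traj(15), random_traj(25))
  e <- make_ensemble(trs, dt = 0.01)
  curve <- compute_msd(e, max_lag = 5)
  for (k in 1:5) {
    vals <- c(oracle_msd_one(trs[[1]]$frame, trs[[1]]$x, trs[[1]]$y, k),
              oracle_msd_one(trs[[2]]$frame, trs[[2]]$x, trs[[2]]$y, k))
    expect_equal(curve$msd[k], mean(vals), tolerance = 1e-10)
    expect_equal(curve$n_indep[k], floor(14 / k) + floor(24 / k))
    expect_equal(curve$sem[k],
                 sqrt(mean((vals - mean(vals))^2)) / sqrt(curve$n_indep[k]),
                 tolerance = 1e-12)
  }
})

test_that("gapped trajectories only pair frames truly lag apart", {
  tr <- data.frame(frame = c(0L, 1L, 3L), x = c(0, 1, 5), y = 0)
  e <- make_ensemble(list(tr), dt = 0.01)
  curve <- compute_msd(e, max_lag = 3)
  expect_equal(curve$lag, c(1L, 2L, 3L))   # lag 1: 0->1; lag 2: 1->3; lag 3: 0->3
  expect_equal(curve$msd, c(1, 16, 25))
})

test_that("a noiseless line fits back exactly (r2 = 1, zero intercept)", {
  curve <- make_msd_curve(t = (1:10) * 0.01, msd = 4 * 1.0 * (1:10) * 0.01)
  fit <- fit_msd(curve, "brownian")
  expect_equal(fit$D, 1.0, tolerance = 1e-12)
  expect_equal(unname(fit$params["a"]), 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
})

test_that("weighted and unweighted Brownian fits coincide for equal sems", {
  set.seed(80)
  t <- (1:8) * 0.01
  msd <- 0.02 + 4 * 1.5 * t + rnorm(8, 0, 1e-3)
  curve <- make_msd_curve(t, msd, sem = rep(2e-3, 8))
  fw <- fit_msd(curve, "brownian", weighted = TRUE)
  fu <- fit_msd(curve, "brownian", weighted = FALSE)
  expect_equal(fw$params, fu$params, tolerance = 1e-10)
})

test_that("nonlinear models recover their own forward curves", {
  t <- (1:10) * 0.01
  # flow: D = 0.5, v = 2.0
  flow <- make_msd_curve(t, 4 * 0.5 * t + (2.0 * t)^2)
  ff <- fit_msd(flow, "flow")
  expect_equal(unname(ff$params["D"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(ff$params["v"]), 2.0, tolerance = 1e-6)
  # anomalous: Gamma = 0.8, alpha = 0.6
  anom <- make_msd_curve(t, 0.8 * t^0.6)
  fa <- fit_msd(anom, "anomalous")
  expect_equal(unname(fa$params["alpha"]), 0.6, tolerance = 1e-6)
  expect_equal(unname(fa$params["Gamma"]), 0.8, tolerance = 1e-6)
  # confined: plateau 0.25 um^2, D = 1
  conf <- make_msd_curve(t, 0.25 * (1 - exp(-4 * 1 * t / 0.25)))
  fc <- fit_msd(conf, "confined")
  expect_equal(unname(fc$params["R_inf2"]), 0.25, tolerance = 1e-6)
  expect_equal(unname(fc$params["D"]), 1, tolerance = 1e-6)
})

test_that("localization formulas match hand-computed values", {
  # exact curve msd = a + 4 D t with a = 4 (0.1 um)^2, D = 1, dt = 0.01:
  # sigma_static = 0.1 um, x = 1.0, p_b = floor(2 + 2.3) = 4
  t <- (1:20) * 0.01
  curve <- make_msd_curve(t, 0.04 + 4 * t)
  loc <- localization_analysis(curve, exposure = 0)
  expect_equal(loc$sigma_static, 0.1, tolerance = 1e-10)
  expect_equal(loc$sigma_dynamic, 0.1, tolerance = 1e-10)
  expect_equal(loc$x_reduced, 1.0, tolerance = 1e-10)
  expect_equal(loc$p_b_opt, 4L)
  expect_equal(loc$p_a_opt, 4L)
  expect_equal(loc$R_blur, 0)
})

test_that("the noise-free limit gives zero errors and the minimal two lags", {
  t <- (1:20) * 0.01
  curve <- make_msd_curve(t, 4 * t)   # a = 0, exposure = 0
  loc <- localization_analysis(curve, exposure = 0)
  expect_equal(loc$sigma_static, 0, tolerance = 1e-6)
  expect_equal(loc$sigma_dynamic, 0, tolerance = 1e-6)
  expect_equal(loc$x_reduced, 0, tolerance = 1e-6)
  expect_equal(loc$p_b_opt, 2L)
})

test_that("finite exposure raises the blur coefficient to 1/6", {
  t <- (1:20) * 0.01
  curve <- make_msd_curve(t, 0.04 + 4 * t)
  loc <- localization_analysis(curve, exposure = 0.01, dt = 0.01)
  expect_equal(loc$R_blur, 1 / 6, tolerance = 1e-12)
  # static error now includes the blur term: sqrt(a/4 + 2 R D dt)
  expect_equal(loc$sigma_static,
               sqrt(0.01 + 2 * (1 / 6) * 1 * 0.01), tolerance = 1e-8)
})

test_that("fitted D lands within 3 sigma_D of the simulated truth", {
  failures <- 0L
  cases <- expand.grid(D = c(0.2, 2), sigma = c(0, 0.05), seed = 1:5)
  for (i in seq_len(nrow(cases))) {
    e <- simulate_simple(40, 300, 0.01, D1 = cases$D[i],
                         sigma_loc = cases$sigma[i],
                         seed = 1000L + i)
    loc <- localization_analysis(compute_msd(e, max_lag = 30), exposure = 0)
    if (abs(loc$D - cases$D[i]) > 3 * loc$sigma_D) failures <- failures + 1L
  }
  expect_lte(failures, 1L)   # 3-sigma band: ~99.7% nominal coverage
})

test_that("sigma_D shrinks as the ensemble grows", {
  sds <- sapply(c(10, 40, 160), function(n) {
    e <- simulate_simple(n, 200, 0.01, D1 = 1, seed = 42)
    localization_analysis(compute_msd(e, max_lag = 20), exposure = 0)$sigma_D
  })
  expect_true(all(diff(sds) < 0))
})
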