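test_that("simulations are bit-reproducible and prefix-stable in n_traj", {
  e1 <- simulate_simple(5, 50, 0.01, D1 = 1, sigma_loc = 0.05, seed = 7)
  e2 <- simulate_simple(5, 50, 0.01, D1 = 1, sigma_loc = 0.05, seed = 7)
  expect_identical(e1$points, e2$points)
  # growing n_traj appends; existing trajectories are unchanged
  e3 <- simulate_simple(8, 50, 0.01, D1 = 1, sigma_loc = 0.05, seed = 7)
  expect_identical(e3$points[e3$points$trajectory <= 5, ], e1$points)
  e4 <- simulate_simple(5, 50, 0.01, D1 = 1, sigma_loc = 0.05, seed = 8)
  expect_false(identical(e4$points, e1$points))
})

test_that("frozen particles stay put when D and noise are zero", {
  e <- simulate_simple(3, 20, 0.01, D1 = 0, D2 = 0, fraction1 = 0.5,
                       sigma_loc = 0, seed = 1)
  expect_true(all(e$points$x == 0) && all(e$points$y == 0))
})

test_that("per-axis squared steps match the 2 D dt Gaussian law", {
  e <- simulate_simple(1, 1e5, 0.01, D1 = 2, seed = 21)
  dx <- diff(e$points$x)
  target <- 2 * 2 * 0.01          # 0.04 um^2 per axis
  se <- stats::sd(dx^2) / sqrt(length(dx))
  expect_lt(abs(mean(dx^2) - target), 3 * se)
})

test_that("localization noise adds 4 sigma^2 to the MSD intercept", {
  e <- simulate_simple(60, 400, 0.01, D1 = 1, sigma_loc = 0.05, seed = 31)
  loc <- localization_analysis(compute_msd(e, max_lag = 30), exposure = 0)
  expect_lt(abs(loc$a - 4 * 0.05^2), 3 * loc$a_err)
})

test_that("switching is off when both rates are zero", {
  res <- simulate_switch(3, 100, 0.01, D1 = 2, D2 = 0.2, k12 = 0, k21 = 0,
                         seed = 2)
  expect_true(all(res$states$state == 1L))
})

test_that("state occupancy and dwell times follow the two-state Markov law", {
  res <- simulate_switch(20, 5000, 0.01, D1 = 1, D2 = 1, k12 = 5, k21 = 5,
                         seed = 3)
  st <- res$states$state
  # symmetric rates: occupancy 1/2; SE from the number of dwell segments
  runs <- rle(paste(res$states$trajectory, st))$lengths
  expect_lt(abs(mean(st == 1L) - 0.5), 3 * 0.5 / sqrt(length(runs)))
  # dwell mean ~ 1 / (1 - exp(-k dt)) ~ 20.5 frames at k dt = 0.05
  dwell <- mean(runs)
  expected <- 1 / (1 - exp(-5 * 0.01))
  expect_lt(abs(dwell - expected), 3 * expected / sqrt(length(runs)))
})

test_that("asymmetric rates reach the k21/(k12+k21) equilibrium", {
  res <- simulate_switch(20, 4000, 0.01, D1 = 1, D2 = 1, k12 = 15, k21 = 5,
                         seed = 4)
  st <- res$states$state
  runs <- rle(paste(res$states$trajectory, st))$lengths
  expect_lt(abs(mean(st == 1L) - 0.25), 3 * 0.5 / sqrt(length(runs)))
})

test_that("equal-D switching is indistinguishable from simple diffusion", {
  res <- simulate_switch(10, 2000, 0.01, D1 = 1.5, D2 = 1.5, k12 = 2, k21 = 2,
                         seed = 5)
  e_simple <- simulate_simple(10, 2000, 0.01, D1 = 1.5, seed = 6)
  v1 <- unlist(lapply(split(res$ensemble$points$x,
                            res$ensemble$points$trajectory), diff))^2
  v2 <- unlist(lapply(split(e_simple$points$x,
                            e_simple$points$trajectory), diff))^2
  se <- sqrt(stats::var(v1) / length(v1) + stats::var(v2) / length(v2))
  expect_lt(abs(mean(v1) - mean(v2)), 3 * se)
})

test_that("domain maps follow the Poisson/Gaussian generator law", {
  expect_length(generate_domain_map(c(10, 10), density = 0,
                                    mean_diameter = 1, seed = 1)$r, 0L)
  counts <- diams <- numeric(200)
  for (s in 1:200) {
    m <- generate_domain_map(c(10, 10), density = 1, mean_diameter = 0.5,
                             diameter_sd = 0.1, seed = s)
    counts[s] <- length(m$r)
    diams[s] <- mean(2 * m$r)
  }
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 200))   # Poisson mean
  expect_lt(abs(mean(diams) - 0.5), 3 * stats::sd(diams) / sqrt(200))
})

test_that("raster import reproduces the drawn circle exactly", {
  # 100x100 binary image, filled circle of radius 20 px at (50, 50)
  px <- matrix(0, 100, 100)
  for (i in 1:100) for (j in 1:100)
    if ((i - 50.5)^2 + (j - 50.5)^2 <= 20^2) px[i, j] <- 1
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(px, path)
  map <- import_domain_map(path, pixel_size = 0.05)
  expect_equal(map$box, c(5, 5))
  # membership equals the rasterization oracle at every pixel center
  centers <- expand.grid(col = 1:100, row = 1:100)
  got <- domain_membership(map, (centers$col - 0.5) * 0.05,
                           (centers$row - 0.5) * 0.05)
  expect_identical(got, px[cbind(centers$row, centers$col)] > 0)
  # interior area ~ pi (1 um)^2 within rasterization error
  area <- sum(px) * 0.05^2
  expect_lt(abs(area - pi) / pi, 0.03)
  expect_equal(domain_area_fraction(map), sum(px) / 1e4)
})

test_that("an all-background image yields a map nothing ever enters", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0, 20, 20), path)
  expect_message(map <- import_domain_map(path, pixel_size = 0.1),
                 "no domain interior")
  res <- simulate_domains(3, 50, 0.01, D1 = 1, D2 = 0.1, k12 = 5, k21 = 5,
                          map = map, seed = 1)
  expect_true(all(res$states$state == 1L))
})

test_that("impermeable domains are never entered (k12 = 0)", {
  map <- generate_domain_map(c(10, 10), density = 1, mean_diameter = 0.7,
                             seed = 11)
  # start every particle outside a domain
  set.seed(99)
  starts <- matrix(NA_real_, 20, 2)
  for (i in 1:20) {
    repeat {
      p <- stats::runif(2, 0, 10)
      if (!domain_membership(map, p[1], p[2])) break
    }
    starts[i, ] <- p
  }
  res <- simulate_domains(20, 100, 0.01, D1 = 2, D2 = 2, k12 = 0, k21 = 5,
                          map = map, seed = 12, start = starts)
  expect_true(all(res$states$state == 1L))
})

test_that("trapping domains confine inside-starting particles (k21 = 0)", {
  map <- structure(list(type = "circles", x = 5, y = 5, r = 0.5,
                        box = c(10, 10)), class = "spt_domain_map")
  starts <- matrix(rep(c(5, 5), each = 10), ncol = 2)
  res <- simulate_domains(10, 300, 0.01, D1 = 2, D2 = 2, k12 = 5, k21 = 0,
                          map = map, seed = 13, start = starts)
  expect_true(all(res$states$state == 2L))
  curve <- compute_msd(res$ensemble, max_lag = 75)
  # MSD saturates below the geometric bound for a disc of radius 0.5 um
  expect_lt(max(curve$msd), 4 * 0.5^2)
  # and the long-lag tail is flat compared to free diffusion 4 D t
  expect_lt(curve$msd[75], 0.1 * 4 * 2 * curve$t[75])
})

test_that("an empty map reduces domain mode to simple diffusion", {
  map <- structure(list(type = "circles", x = numeric(0), y = numeric(0),
                        r = numeric(0), box = c(10, 10)),
                   class = "spt_domain_map")
  res <- simulate_domains(10, 1000, 0.01, D1 = 1.2, D2 = 0.1, k12 = 3,
                          k21 = 3, map = map, seed = 14)
  v <- unlist(lapply(split(res$ensemble$points$x,
                           res$ensemble$points$trajectory), diff))^2
  target <- 2 * 1.2 * 0.01
  expect_lt(abs(mean(v) - target), 3 * stats::sd(v) / sqrt(length(v)))
  expect_true(all(res$states$state == 1L))
})

test_that("G(r) of a two-point pattern concentrates in the distance bin", {
  map <- structure(list(type = "circles", x = c(2, 8), y = c(5, 5),
                        r = c(0.3, 0.3), box = c(10, 10)),
                   class = "spt_domain_map")
  # periodic minimum image: |2 - 8| = 6 wraps to 4
  pc <- pair_correlation(map, r_max = 5, n_bins = 25)
  hit <- pc$r > 3.8 & pc$r < 4.2
  expect_true(all(pc$G[!hit] == 0))
  expect_true(any(pc$G[hit] > 0))
})

test_that("G(r) of a CSR pattern is 1 at long range", {
  map <- generate_domain_map(c(20, 20), density = 5, mean_diameter = 0.2,
                             seed = 15)   # ~2000 centers
  pc <- pair_correlation(map, r_max = 8, n_bins = 40)
  upper <- pc$G[pc$r > 4]
  expect_lt(abs(mean(upper) - 1), 0.05)
  expect_error(pair_correlation(
    structure(list(type = "circles", x = 1, y = 1, r = 0.1, box = c(5, 5)),
              class = "spt_domain_map")), "at least 2")
})

test_that("raster maps contribute connected-component centers to G(r)", {
  skip_if_not_installed("EBImage")
  px <- matrix(0, 60, 60)
  for (c0 in list(c(15, 15), c(45, 45), c(15, 45), c(45, 15)))
    for (i in -3:3) for (j in -3:3)
      if (i^2 + j^2 <= 9) px[c0[1] + i, c0[2] + j] <- 1
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(px, path)
  map <- import_domain_map(path, pixel_size = 0.1)
  pc <- pair_correlation(map, r_max = 2.9, n_bins = 29)
  expect_equal(attr(pc, "n_centers"), 4L)
  # neighbors at 3 um exceed r_max; diagonal wraps shorter? no: all pairs
  # are at 3 um or 3*sqrt(2) um, so every evaluated bin is empty
  expect_true(all(pc$G == 0))
})
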