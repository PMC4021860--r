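# Independent brute-force oracles and fixture builders shared by the tests.
# The oracles deliberately use explicit double loops and closed-form algebra
# so they share no code with the package implementation.

# Brute-force time-averaged MSD of one trajectory: explicit double loop over
# all localization pairs, matched on frame difference.
oracle_msd_one <- function(frame, x, y, lag) {
  vals <- c()
  n <- length(frame)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (frame[j] - frame[i] == lag)
        vals <- c(vals, (x[j] - x[i])^2 + (y[j] - y[i])^2)
    }
  }
  vals
}

# Closed-form unweighted least-squares line (slope, intercept) on (t, y).
oracle_line <- function(t, y) {
  b <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  a <- mean(y) - b * mean(t)
  c(a = a, b = b)
}

# Random gapless trajectory of a pure Brownian walker.
random_traj <- function(n, D = 1, dt = 0.01) {
  s <- sqrt(2 * D * dt)
  data.frame(frame = 0:(n - 1L),
             x = cumsum(c(0, rnorm(n - 1L, 0, s))),
             y = cumsum(c(0, rnorm(n - 1L, 0, s))))
}

# Ensemble from a list of trajectory data frames (frame/x/y[/intensity]).
make_ensemble <- function(trajs, dt = 0.01, ...) {
  pts <- do.call(rbind, lapply(seq_along(trajs), function(i)
    cbind(trajectory = i, trajs[[i]])))
  spt_ensemble(pts, dt = dt, ...)
}

# Hand-built MSD curve object (for fitting tests on exact model curves).
make_msd_curve <- function(t, msd, sem = rep(1e-4, length(t)),
                           n_pairs = rep(1000L, length(t))) {
  out <- data.frame(lag = seq_along(t), t = t, msd = msd,
                    sd = sem * sqrt(n_pairs), sem = sem,
                    n_pairs = n_pairs, n_indep = n_pairs)
  attr(out, "dt") <- t[1]
  class(out) <- c("spt_msd", "data.frame")
  out
}

# Hand-built empirical-CPD curve from explicit (r2, p) points.
make_cpd_curve <- function(r2, p, lag = 1L, dt = 0.01) {
  out <- data.frame(r2 = r2, p = p)
  attr(out, "lag") <- lag
  attr(out, "t") <- lag * dt
  attr(out, "n") <- length(r2)
  class(out) <- c("spt_cpd", "data.frame")
  out
}

# Minimal converged CPD-fit stub (for F-test formula checks).
make_cpdfit_stub <- function(order, rss, n, lag = 1L) {
  structure(list(lag = lag, t = 0.01 * lag, order = order,
                 r2_pop = rev(seq_len(order)) * 0.01,
                 F = rep(1 / order, order), errors = NULL, rss = rss,
                 n_points = n, converged = TRUE, diagnostics = character(0)),
            class = "spt_cpdfit")
}

# The three-point elbow trajectory used across modules:
# (0,0) -> (1,0) -> (1,1) um; MSD(1) = 1, MSD(2) = 2.
elbow_ensemble <- function(dt = 0.01) {
  make_ensemble(list(data.frame(frame = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))),
                dt = dt)
}
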