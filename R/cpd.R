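#' Pooled squared displacements at one time-lag
#'
#' Collects the overlapping squared displacements
#' `(x_{i+lag} - x_i)^2 + (y_{i+lag} - y_i)^2` from every trajectory long
#' enough, pooled over the ensemble.
#'
#' @param e an [spt_ensemble].
#' @param lag frame lag (>= 1).
#' @return An object of class `spt_sqdisp`: `lag`, `t` (s), `values` (um^2),
#'   `n`.
#' @export
squared_displacements <- function(e, lag) {
  stopifnot(inherits(e, "spt_ensemble"))
  if (!is.numeric(lag) || lag < 1L) stop("lag must be >= 1")
  lag <- as.integer(lag)
  vals <- unlist(lapply(.traj_list(e), .sq_disp_one, lag = lag),
                 use.names = FALSE)
  if (length(vals) == 0L)
    stop("no trajectory long enough for lag ", lag)
  structure(list(lag = lag, t = lag * e$dt, values = vals, n = length(vals)),
            class = "spt_sqdisp")
}

#' Empirical cumulative probability distribution of squared displacements
#'
#' Sorts the squared displacements and assigns plotting positions `i/n`, so
#' the curve is monotone nondecreasing and ends at 1.
#'
#' @param sd_set an [squared_displacements()] result.
#' @return A data frame of class `spt_cpd` with columns `r2` (sorted squared
#'   displacement, um^2) and `p` (cumulative probability); attributes `lag`,
#'   `t`, `n`. Fewer than 10 values triggers a warning (downstream fits skip
#'   such lags).
#' @export
empirical_cpd <- function(sd_set) {
  stopifnot(inherits(sd_set, "spt_sqdisp"))
  n <- sd_set$n
  if (n < 10L)
    warning("only ", n, " squared displacements at lag ", sd_set$lag,
            "; CPD fit will be skipped for this lag")
  out <- data.frame(r2 = sort(sd_set$values), p = seq_len(n) / n)
  attr(out, "lag") <- sd_set$lag
  attr(out, "t") <- sd_set$t
  attr(out, "n") <- n
  class(out) <- c("spt_cpd", "data.frame")
  out
}

# Deterministic even subsample of CPD points (for fit speed on huge lags).
.cpd_subsample <- function(curve, cap) {
  n <- nrow(curve)
  if (n <= cap) return(curve)
  curve[unique(round(seq(1L, n, length.out = cap))), , drop = FALSE]
}

# Multi-exponential CDF: P(r2) = 1 - sum_i F_i exp(-r2 / s_i)
.cpd_model <- function(r2, scales, fracs) {
  acc <- 0
  for (i in seq_along(scales)) acc <- acc + fracs[i] * exp(-r2 / scales[i])
  1 - acc
}

#' Multi-exponential CPD fit at one lag
#'
#' Fits the mixture CDF `P(r2) = 1 - sum_i F_i exp(-r2 / r_i^2)` (fractions
#' summing to 1; `order` components) to the empirical CPD by
#' Levenberg-Marquardt least squares. Initialization is a deterministic
#' multi-start around the mean squared displacement `m`: order 1 starts at
#' `m`; order 2 at `(4m, m/4, F1 = 0.7)` and `(2m, m/2, F1 = 0.5)`; order 3
#' adds the geometric-middle scale. The first convergent start with the
#' lowest residual sum of squares wins. Populations are reported fast to
#' slow (`r1^2 >= r2^2 >= ...`).
#'
#' @param curve an [empirical_cpd()] result.
#' @param order number of populations (1, 2 or 3).
#' @param cap fit at most this many CPD points (deterministic even
#'   subsample), for speed at large lags.
#' @return An object of class `spt_cpdfit`: `lag`, `t`, `order`, `r2_pop`
#'   (scale parameters, um^2, sorted decreasing), `F` (fractions summing to
#'   1), `errors` (one-sigma, for the free parameters), `rss`, `n_points`,
#'   `converged`, `diagnostics`.
#' @export
fit_cpd <- function(curve, order, cap = 10000L) {
  stopifnot(inherits(curve, "spt_cpd"))
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  d <- .cpd_subsample(curve, cap)
  m <- mean(d$r2)
  if (m <= 0) stop("degenerate CPD: all squared displacements are zero")
  n <- nrow(d)

  fail <- function(msg) structure(
    list(lag = attr(curve, "lag"), t = attr(curve, "t"), order = order,
         r2_pop = rep(NA_real_, order), F = rep(NA_real_, order),
         errors = NULL, rss = NA_real_, n_points = n, converged = FALSE,
         diagnostics = msg),
    class = "spt_cpdfit")

  # Parameters: log scales (positivity for free) and stick-breaking
  # fractions g_i in [0,1] (F1 = g1, F2 = (1-g1) g2, ...), so fractions
  # always sum to 1 without a sum constraint.
  unpack <- function(par) {
    ls <- par[seq_len(order)]
    g <- par[-seq_len(order)]
    fr <- numeric(order)
    rest <- 1
    if (order > 1L) for (i in seq_len(order - 1L)) {
      fr[i] <- rest * g[i]; rest <- rest - fr[i]
    }
    fr[order] <- rest
    list(scales = exp(ls), fracs = fr)
  }
  resid_fn <- function(par) {
    u <- unpack(par)
    .cpd_model(d$r2, u$scales, u$fracs) - d$p
  }
  starts <- switch(order,
    `1` = list(c(log(m))),
    `2` = list(c(log(4 * m), log(m / 4), 0.7),
               c(log(2 * m), log(m / 2), 0.5)),
    `3` = list(c(log(4 * m), log(m), log(m / 4), 0.5, 0.6),
               c(log(2 * m), log(m), log(m / 2), 0.4, 0.5)))
  n_g <- order - 1L
  lower <- c(rep(-Inf, order), rep(0, n_g))
  upper <- c(rep(Inf, order), rep(1, n_g))

  best <- NULL
  msgs <- character(0)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(err) err)
    if (inherits(fit, "error")) { msgs <- c(msgs, conditionMessage(fit)); next }
    if (!fit$info %in% 1:4) { msgs <- c(msgs, fit$message); next }
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(fail(msgs))

  fit <- best$fit
  u <- unpack(fit$par)
  # one-sigma errors via the Gauss-Newton covariance, delta method back to
  # the natural scale parameters; fraction errors for F1 only (= g1).
  se_nat <- rep(NA_real_, 2L * order - 1L)
  names(se_nat) <- c(paste0("r2_pop", seq_len(order)),
                     if (order > 1L) paste0("F", seq_len(order - 1L)))
  cov <- tryCatch(solve(fit$hessian) * best$rss / max(1L, n - length(fit$par)),
                  error = function(e) NULL)
  if (!is.null(cov)) {
    se_par <- sqrt(pmax(diag(cov), 0))
    se_nat[seq_len(order)] <- se_par[seq_len(order)] * u$scales  # d exp(l)/dl
    if (order > 1L) se_nat[order + 1L] <- se_par[order + 1L]
  }
  ord <- order(u$scales, decreasing = TRUE)   # fast to slow
  se_scales <- se_nat[seq_len(order)][ord]
  structure(list(
    lag = attr(curve, "lag"), t = attr(curve, "t"), order = order,
    r2_pop = unname(u$scales[ord]), F = unname(u$fracs[ord]),
    errors = c(se_scales, se_nat[-seq_len(order)]), rss = best$rss,
    n_points = n, converged = TRUE, diagnostics = character(0)),
    class = "spt_cpdfit")
}

#' @export
print.spt_cpdfit <- function(x, ...) {
  cat(sprintf("CPD fit, lag %d (t = %g s), %d population(s)\n",
              x$lag, x$t, x$order))
  if (!x$converged) {
    cat("  DID NOT CONVERGE:", paste(x$diagnostics, collapse = "; "), "\n")
    return(invisible(x))
  }
  for (i in seq_len(x$order))
    cat(sprintf("  population %d: r^2 = %.5g um^2, F = %.3f\n",
                i, x$r2_pop[i], x$F[i]))
  cat(sprintf("  rss = %.4g over %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' F-test between nested CPD model orders
#'
#' An order-k mixture has `2k - 1` free parameters (k scales, k - 1
#' fractions). With `df = n - parameters`,
#' `F = ((rss_low - rss_high) / (df_low - df_high)) / (rss_high / df_high)`;
#' the higher order is accepted iff the upper-tail p-value is below `alpha`.
#' If the higher-order fit has the larger RSS, F is clamped at 0 and the
#' lower order retained.
#'
#' @param fit_low,fit_high [fit_cpd()] results of increasing order on the
#'   same curve.
#' @param n number of fitted points (default taken from `fit_high`).
#' @param alpha significance level.
#' @return A list: `F`, `p`, `accepted_order`, `df1`, `df2`.
#' @export
compare_models_ftest <- function(fit_low, fit_high, n = fit_high$n_points,
                                 alpha = 0.05) {
  stopifnot(inherits(fit_low, "spt_cpdfit"), inherits(fit_high, "spt_cpdfit"))
  if (fit_low$order >= fit_high$order)
    stop("fit_low must have the lower model order")
  if (!isTRUE(fit_low$converged) || !isTRUE(fit_high$converged))
    stop("both fits must have converged")
  p_low <- 2L * fit_low$order - 1L
  p_high <- 2L * fit_high$order - 1L
  df_low <- n - p_low
  df_high <- n - p_high
  dnum <- df_low - df_high
  # a fit that already reproduces the curve to numerical precision cannot be
  # meaningfully improved: clamp F at 0 rather than divide rounding noise
  numerically_perfect <- fit_low$rss < n * 1e-20
  Fstat <- if (fit_high$rss > fit_low$rss || numerically_perfect) 0 else
    ((fit_low$rss - fit_high$rss) / dnum) / (fit_high$rss / df_high)
  pval <- stats::pf(Fstat, dnum, df_high, lower.tail = FALSE)
  list(F = Fstat, p = pval,
       accepted_order = if (pval < alpha) fit_high$order else fit_low$order,
       df1 = dnum, df2 = df_high)
}

# Draw squared displacements from a fitted exponential mixture
# (component i contributes Exp(mean = r2_pop_i) with probability F_i).
.sample_mixture <- function(n, scales, fracs) {
  comp <- sample.int(length(scales), n, replace = TRUE, prob = fracs)
  stats::rexp(n) * scales[comp]
}

#' Bootstrap-calibrated F-test between CPD model orders
#'
#' The analytic F-test of [compare_models_ftest()] assumes independent
#' residuals, but neighboring points of an empirical CDF are strongly
#' correlated (the empirical process is a Brownian bridge), which makes the
#' analytic test anticonservative on large samples: a spare mixture
#' component can always absorb part of the smooth sampling wiggle. This
#' version calibrates the observed F statistic against its null
#' distribution, obtained by refitting both orders on `n_boot` synthetic
#' datasets of `n_full` squared displacements drawn from the fitted
#' lower-order mixture (a parametric bootstrap). The higher order is
#' accepted iff the rank-based p-value `(1 + #(F* >= F)) / (n_boot + 1)` is
#' at most `alpha`; with the default `n_boot = 19` and `alpha = 0.05` this
#' accepts only when the observed F exceeds every bootstrap replicate.
#'
#' @inheritParams compare_models_ftest
#' @param n_full number of squared displacements behind the curve.
#' @param cap CPD point cap used for the fits.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap draws.
#' @return A list: `F`, `p` (rank-based), `accepted_order`, `F_null`
#'   (the bootstrap F statistics).
#' @export
compare_models_boot <- function(fit_low, fit_high, n_full, cap = 10000L,
                                n_boot = 19L, seed = 1L, alpha = 0.05) {
  F_obs <- compare_models_ftest(fit_low, fit_high)$F
  set.seed(as.integer(seed))
  Fs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    vals <- .sample_mixture(n_full, fit_low$r2_pop, fit_low$F)
    sdset <- structure(list(lag = fit_low$lag, t = fit_low$t,
                            values = vals, n = n_full),
                       class = "spt_sqdisp")
    curve <- suppressWarnings(empirical_cpd(sdset))
    f_lo <- fit_cpd(curve, fit_low$order, cap = cap)
    f_hi <- fit_cpd(curve, fit_high$order, cap = cap)
    if (f_lo$converged && f_hi$converged)
      Fs[b] <- compare_models_ftest(f_lo, f_hi)$F
  }
  Fs <- Fs[!is.na(Fs)]
  p <- (1 + sum(Fs >= F_obs)) / (length(Fs) + 1)
  list(F = F_obs, p = p,
       accepted_order = if (p <= alpha) fit_high$order else fit_low$order,
       F_null = Fs)
}

#' Per-population diffusion coefficients from per-lag CPD fits
#'
#' For each population i, fits an unweighted line to the per-lag scale
#' parameter `r_i^2` against lag time; `D_i = slope / 4` with the slope's
#' standard error divided by 4. The fast fraction is the mean of the
#' per-lag `F1` values with its standard error over lags.
#'
#' @param fits list of converged [fit_cpd()] results, all of the same order,
#'   at distinct lags (>= 3 of them).
#' @param weighted weight each lag by the inverse squared parameter error
#'   (default unweighted).
#' @return An object of class `spt_populations`: per population `D`,
#'   `D_err`, `intercept`, `intercept_err` (um^2); `F1`, `F1_err`; `lags`
#'   used; `order`.
#' @export
population_diffusion <- function(fits, weighted = FALSE) {
  fits <- Filter(function(f) inherits(f, "spt_cpdfit") && isTRUE(f$converged), fits)
  if (length(fits) < 3L) stop("need at least 3 successful per-lag CPD fits")
  orders <- vapply(fits, function(f) f$order, 1L)
  if (length(unique(orders)) != 1L)
    stop("mixed CPD model orders: ", paste(unique(orders), collapse = ", "))
  k <- orders[1L]
  t <- vapply(fits, function(f) f$t, 1)
  D <- D_err <- icpt <- icpt_err <- numeric(k)
  for (i in seq_len(k)) {
    y <- vapply(fits, function(f) f$r2_pop[i], 1)
    fit <- stats::lm(y ~ t)
    sm <- suppressWarnings(summary(fit))$coefficients
    D[i] <- sm["t", "Estimate"] / 4
    D_err[i] <- sm["t", "Std. Error"] / 4
    icpt[i] <- sm["(Intercept)", "Estimate"]
    icpt_err[i] <- sm["(Intercept)", "Std. Error"]
  }
  F1v <- vapply(fits, function(f) f$F[1L], 1)
  structure(list(order = k, D = D, D_err = D_err,
                 intercept = icpt, intercept_err = icpt_err,
                 F1 = mean(F1v), F1_err = stats::sd(F1v) / sqrt(length(F1v)),
                 F1_per_lag = F1v,
                 lags = vapply(fits, function(f) f$lag, 1L)),
            class = "spt_populations")
}

#' @export
print.spt_populations <- function(x, ...) {
  cat("Population decomposition (", x$order, " population(s), lags ",
      min(x$lags), "-", max(x$lags), ")\n", sep = "")
  for (i in seq_len(x$order))
    cat(sprintf("  D%d = %.4g +/- %.2g um^2/s (intercept %.3g +/- %.2g um^2)\n",
                i, x$D[i], x$D_err[i], x$intercept[i], x$intercept_err[i]))
  if (x$order > 1L)
    cat(sprintf("  F1 = %.1f%% +/- %.1f%%\n", 100 * x$F1, 100 * x$F1_err))
  invisible(x)
}

#' Full CPD decomposition pipeline
#'
#' For each lag in `1..max_lag`: pools squared displacements, builds the
#' empirical CPD and fits every candidate order. Unless `order` is fixed, a
#' sequential test ladder (1 vs 2, then the winner vs 3) is run per lag —
#' bootstrap-calibrated by default (see [compare_models_boot()]; `"analytic"`
#' uses [compare_models_ftest()] directly) — and the dataset-level order is
#' the highest order accepted on a strict majority of lags. Per-population
#' diffusion coefficients are then derived from the fits of that order via
#' [population_diffusion()]. Lags with fewer than `min_n` squared
#' displacements, or whose fit failed, are skipped with a warning.
#'
#' @param e an [spt_ensemble].
#' @param max_lag number of leading lags to analyze.
#' @param orders candidate model orders (subset of 1:3).
#' @param alpha significance level for order selection.
#' @param cap CPD point cap per lag (see [fit_cpd()]).
#' @param min_n minimum squared displacements per lag.
#' @param order fix the model order instead of selecting (skips all tests).
#' @param select order-selection method: `"bootstrap"` (default) or
#'   `"analytic"`.
#' @param n_boot,seed bootstrap replicates and RNG seed (bootstrap only).
#' @return An object of class `spt_cpd_analysis`: `populations`
#'   ([population_diffusion()] result), `order` (selected), `fits` (list of
#'   per-lag fits by order), `ftests` (per-lag test results),
#'   `order_votes` (accepted order per lag).
#' @export
cpd_analysis <- function(e, max_lag = 10L, orders = 1:3, alpha = 0.05,
                         cap = 10000L, min_n = 10L, order = NULL,
                         select = c("bootstrap", "analytic"),
                         n_boot = 19L, seed = 1L) {
  stopifnot(inherits(e, "spt_ensemble"))
  select <- match.arg(select)
  fit_orders <- if (!is.null(order)) as.integer(order) else
    sort(unique(as.integer(orders)))
  fits <- list(); ftests <- list(); votes <- integer(0)
  for (lag in seq_len(max_lag)) {
    sdset <- tryCatch(squared_displacements(e, lag), error = function(err) NULL)
    if (is.null(sdset) || sdset$n < min_n) {
      warning("lag ", lag, " skipped: too few squared displacements")
      next
    }
    curve <- suppressWarnings(empirical_cpd(sdset))
    lag_fits <- lapply(fit_orders, function(k) fit_cpd(curve, k, cap = cap))
    names(lag_fits) <- paste0("order", fit_orders)
    fits[[as.character(lag)]] <- lag_fits
    if (!is.null(order)) next
    # sequential ladder over converged fits
    conv <- vapply(lag_fits, function(f) isTRUE(f$converged), TRUE)
    if (!any(conv)) next
    accepted <- fit_orders[conv][1L]
    tests <- list()
    for (k in fit_orders[-1L]) {
      lo <- paste0("order", accepted); hi <- paste0("order", k)
      if (!isTRUE(conv[[hi]]) || k <= accepted) next
      ft <- if (select == "analytic")
        compare_models_ftest(lag_fits[[lo]], lag_fits[[hi]], alpha = alpha)
      else
        compare_models_boot(lag_fits[[lo]], lag_fits[[hi]], n_full = sdset$n,
                            cap = cap, n_boot = n_boot,
                            seed = seed + 7L * lag + k, alpha = alpha)
      tests[[paste0(accepted, "v", k)]] <- ft
      accepted <- ft$accepted_order
    }
    ftests[[as.character(lag)]] <- tests
    votes <- c(votes, accepted)
  }
  if (length(fits) == 0L) stop("no lag produced a usable CPD")
  if (is.null(order)) {
    majority <- vapply(fit_orders, function(k)
      sum(votes >= k) > length(votes) / 2, TRUE)
    order <- max(fit_orders[majority], fit_orders[1L])
  }
  chosen <- lapply(fits, function(lf) lf[[paste0("order", order)]])
  pops <- population_diffusion(chosen)
  structure(list(populations = pops, order = order, fits = fits,
                 ftests = ftests, order_votes = votes),
            class = "spt_cpd_analysis")
}

#' @export
print.spt_cpd_analysis <- function(x, ...) {
  cat("CPD analysis: selected order ", x$order,
      if (length(x$order_votes))
        paste0(" (per-lag votes: ", paste(x$order_votes, collapse = " "), ")"),
      "\n", sep = "")
  print(x$populations)
  invisible(x)
}

#' @export
plot.spt_cpdfit <- function(x, curve, ...) {
  stopifnot(inherits(curve, "spt_cpd"))
  d <- .cpd_subsample(curve, 2000L)
  fitted <- .cpd_model(d$r2, x$r2_pop, x$F)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  plot(d$r2, d$p, pch = ".", xlab = "squared displacement (um^2)",
       ylab = "cumulative probability", ...)
  graphics::lines(d$r2, fitted, col = "red3")
  plot(d$r2, d$p - fitted, pch = ".", xlab = "squared displacement (um^2)",
       ylab = "residual")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
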