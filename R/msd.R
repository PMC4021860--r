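#' Mean square displacement curve
#'
#' Time-averaged MSD over overlapping displacement pairs. For an ensemble the
#' squared displacements of all trajectories are pooled per lag. The per-lag
#' dispersion `sd` is the population standard deviation of the pooled squared
#' displacements; because overlapping pairs are serially correlated, the
#' standard error uses the non-overlapping pair count:
#' `sem = sd / sqrt(n_indep)` with `n_indep = sum floor((L-1)/lag)` over
#' trajectories of length L.
#'
#' @param e an [spt_ensemble] (use [get_trajectory()] for a single track).
#' @param max_lag largest frame lag to evaluate; default one quarter of the
#'   longest trajectory. Lags with no contributing pair are omitted.
#' @return A data frame of class `spt_msd` with columns `lag`, `t` (s),
#'   `msd` (um^2), `sd`, `sem`, `n_pairs`, `n_indep`; attribute `dt`.
#' @examples
#' e <- simulate_simple(n_traj = 5, n_steps = 100, dt = 0.01, D1 = 1, seed = 1)
#' curve <- compute_msd(e)
#' fit_msd(curve, "brownian", n_points = 4)
#' @export
compute_msd <- function(e, max_lag = NULL) {
  stopifnot(inherits(e, "spt_ensemble"))
  trs <- .traj_list(e)
  lens <- vapply(trs, function(tr) length(tr$frame), 1L)
  if (length(trs) == 0L || max(lens) < 2L)
    stop("need at least one trajectory with more than one localization")
  if (is.null(max_lag)) max_lag <- max(1L, floor(max(lens) / 4))
  if (!is.numeric(max_lag) || max_lag < 1L) stop("max_lag must be >= 1")
  max_lag <- as.integer(max_lag)

  lag_v <- integer(0); msd_v <- sd_v <- sem_v <- numeric(0)
  np_v <- ni_v <- integer(0)
  for (lag in seq_len(max_lag)) {
    vals <- unlist(lapply(trs, .sq_disp_one, lag = lag), use.names = FALSE)
    n <- length(vals)
    if (n == 0L) next
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    n_indep <- sum(pmax(0L, (lens - 1L) %/% lag))
    lag_v <- c(lag_v, lag); msd_v <- c(msd_v, m); sd_v <- c(sd_v, s)
    sem_v <- c(sem_v, s / sqrt(max(1L, n_indep)))
    np_v <- c(np_v, n); ni_v <- c(ni_v, n_indep)
  }
  out <- data.frame(lag = lag_v, t = lag_v * e$dt, msd = msd_v, sd = sd_v,
                    sem = sem_v, n_pairs = np_v, n_indep = ni_v)
  attr(out, "dt") <- e$dt
  class(out) <- c("spt_msd", "data.frame")
  out
}

#' @export
plot.spt_msd <- function(x, log = "", sem_bars = TRUE, ...) {
  plot(x$t, x$msd, log = log, xlab = "time lag (s)", ylab = "MSD (um^2)", ...)
  if (sem_bars && any(x$sem > 0))
    graphics::arrows(x$t, x$msd - x$sem, x$t, x$msd + x$sem,
                     angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' Fit a diffusion model to an MSD curve
#'
#' Model forms (2-D diffusion):
#' \describe{
#'   \item{brownian}{`msd(t) = a + b t`, `D = b/4`; solved in closed form.
#'     The weighted fit uses weights `1/sem^2` and reports known-variance
#'     (generalized least squares) parameter errors, so a two-point fit still
#'     carries an error estimate; the unweighted fit reports ordinary
#'     residual-based errors.}
#'   \item{anomalous}{`msd(t) = Gamma t^alpha` (subdiffusion for alpha < 1);
#'     an apparent `D_app = Gamma/4` is also reported.}
#'   \item{flow}{`msd(t) = 4 D t + (v t)^2` (diffusion plus drift).}
#'   \item{confined}{`msd(t) = R_inf2 (1 - exp(-4 D t / R_inf2))`, saturating
#'     at the plateau `R_inf2`.}
#' }
#' Nonlinear models are solved by Levenberg-Marquardt least squares from
#' slope-based initializations; non-convergence yields a result with
#' `converged = FALSE` carrying diagnostics, never an error.
#'
#' @param curve an [compute_msd()] result.
#' @param model one of `"brownian"`, `"anomalous"`, `"flow"`, `"confined"`.
#' @param n_points number of leading MSD points to fit (`NULL` = all).
#' @param weighted weight by `1/sem^2`? Falls back to unweighted (with a
#'   flag in `$diagnostics`) if any used `sem` is zero.
#' @return An object of class `spt_msdfit`: `model`, `params` (named),
#'   `errors` (one-sigma, named), `D`, `D_err`, `r2`, `weighted`,
#'   `n_points_used`, `fitted`, `converged`, `diagnostics`.
#' @export
fit_msd <- function(curve, model = c("brownian", "anomalous", "flow", "confined"),
                    n_points = NULL, weighted = FALSE) {
  stopifnot(inherits(curve, "spt_msd"))
  model <- match.arg(model)
  n_free <- switch(model, brownian = 2L, anomalous = 2L, flow = 2L, confined = 2L)
  n_avail <- nrow(curve)
  if (is.null(n_points)) n_points <- n_avail
  n_points <- min(as.integer(n_points), n_avail)
  if (n_points < n_free)
    stop("need at least ", n_free, " MSD points for the ", model, " model")
  d <- curve[seq_len(n_points), , drop = FALSE]
  t <- d$t; y <- d$msd
  diagnostics <- character(0)

  w <- NULL
  if (weighted) {
    if (any(d$sem <= 0)) {
      diagnostics <- c(diagnostics, "zero sem encountered; fell back to unweighted")
      weighted <- FALSE
    } else w <- 1 / d$sem^2
  }

  r2_of <- function(fitted) {
    tss <- sum((y - mean(y))^2)
    if (tss > 0) 1 - sum((y - fitted)^2) / tss else NA_real_
  }

  if (model == "brownian") {
    X <- cbind(a = 1, b = t)
    if (weighted) {
      XtWX <- crossprod(X, X * w)
      beta <- drop(solve(XtWX, crossprod(X, y * w)))
      cov <- solve(XtWX)          # known-variance GLS covariance
      se <- sqrt(diag(cov))
    } else {
      fit <- stats::lm(y ~ t)
      beta <- stats::coef(fit)
      se <- if (n_points > 2L) suppressWarnings(sqrt(diag(stats::vcov(fit)))) else rep(NA_real_, 2L)
      if (n_points == 2L)
        diagnostics <- c(diagnostics, "two-point unweighted fit: errors undefined")
    }
    names(beta) <- names(se) <- c("a", "b")
    fitted <- drop(X %*% beta)
    return(structure(list(
      model = model, params = beta, errors = se,
      D = unname(beta["b"]) / 4, D_err = unname(se["b"]) / 4,
      r2 = r2_of(fitted), weighted = weighted, n_points_used = n_points,
      fitted = fitted, converged = TRUE, diagnostics = diagnostics),
      class = "spt_msdfit"))
  }

  # nonlinear models: slope-based starts
  slope0 <- max((y[n_points] - y[1L]) / (t[n_points] - t[1L]), .Machine$double.eps)
  df_fit <- data.frame(t = t, y = y)
  # anomalous: initialize from the log-log line (exact when y is a power law)
  ll_ok <- all(y > 0)
  alpha0 <- if (ll_ok) {
    lt <- log(t); ly <- log(y)
    sum((lt - mean(lt)) * (ly - mean(ly))) / sum((lt - mean(lt))^2)
  } else 1
  Gamma0 <- if (ll_ok) exp(mean(log(y) - alpha0 * log(t))) else
    max(y[1L] / t[1L], 1e-12)
  spec <- switch(model,
    anomalous = list(
      formula = y ~ Gamma * t^alpha,
      start = list(Gamma = Gamma0, alpha = alpha0)),
    flow = list(
      formula = y ~ 4 * D * t + (v * t)^2,
      start = list(D = slope0 / 4, v = sqrt(slope0))),
    confined = list(
      formula = y ~ R_inf2 * (1 - exp(-4 * D * t / R_inf2)),
      start = list(R_inf2 = max(y), D = slope0 / 4)))
  fit_args <- list(spec$formula, data = df_fit, start = spec$start,
                   control = minpack.lm::nls.lm.control(maxiter = 200))
  if (weighted) fit_args$weights <- w
  fit <- tryCatch(do.call(minpack.lm::nlsLM, fit_args),
                  error = function(err) err)
  if (inherits(fit, "error")) {
    return(structure(list(
      model = model, params = unlist(spec$start), errors = NULL,
      D = NA_real_, D_err = NA_real_, r2 = NA_real_, weighted = weighted,
      n_points_used = n_points, fitted = NULL, converged = FALSE,
      diagnostics = c(diagnostics, conditionMessage(fit))),
      class = "spt_msdfit"))
  }
  beta <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(beta)))
  fitted <- stats::fitted(fit)
  D <- switch(model,
    anomalous = unname(beta["Gamma"]) / 4,  # apparent D at unit lag time
    flow = unname(beta["D"]),
    confined = unname(beta["D"]))
  D_err <- switch(model,
    anomalous = unname(se["Gamma"]) / 4,
    flow = unname(se["D"]),
    confined = unname(se["D"]))
  structure(list(
    model = model, params = beta, errors = se, D = D, D_err = D_err,
    r2 = r2_of(fitted), weighted = weighted, n_points_used = n_points,
    fitted = fitted, converged = TRUE, diagnostics = diagnostics),
    class = "spt_msdfit")
}

#' @export
print.spt_msdfit <- function(x, ...) {
  cat("MSD fit:", x$model,
      if (x$weighted) "(weighted)" else "(unweighted)",
      "over", x$n_points_used, "points\n")
  if (!x$converged) {
    cat("  DID NOT CONVERGE:", paste(x$diagnostics, collapse = "; "), "\n")
    return(invisible(x))
  }
  for (p in names(x$params))
    cat(sprintf("  %-7s %.6g +/- %.3g\n", p, x$params[p],
                if (is.null(x$errors)) NA else x$errors[p]))
  cat(sprintf("  D = %.6g um^2/s; r2 = %.5f\n", x$D, x$r2))
  invisible(x)
}

#' Localization-error analysis of a Brownian MSD fit
#'
#' Decomposes the MSD intercept into localization errors and selects the
#' optimal number of time-lags for fitting, iterating the weighted Brownian
#' fit until the optimum stabilizes (at most 10 rounds). With the motion-blur
#' coefficient `R = exposure/(6 dt)` (uniform illumination: 1/6 at full-frame
#' exposure, 0 for instantaneous sampling, as in simulated data):
#' \itemize{
#'   \item dynamic (apparent) localization error `sigma_dyn = sqrt(a)/2`
#'     for intercept `a > 0` (0 with a flag otherwise);
#'   \item static error `sigma_static = sqrt(a/4 + 2 R D dt)`;
#'   \item reduced error `x = sigma_static^2/(D dt) - 2R`;
#'   \item optimal lags `p_b = max(2, floor(2 + 2.3 x^0.52))` for the slope,
#'     `p_a = max(2, floor(2 + 2.7 x^0.5))` for the intercept;
#'   \item `sigma_D` = slope error of the weighted fit over `p_b` lags,
#'     divided by 4.
#' }
#' The power-law constants are standard optimal-lag calibrations and may be
#' overridden.
#'
#' @param curve an [compute_msd()] result.
#' @param exposure camera exposure (s).
#' @param dt frame interval (s); defaults to the curve's own.
#' @param coef_b,coef_a optimal-lag constants `(multiplier, exponent)`.
#' @return An object of class `spt_locerr`: `sigma_static`, `sigma_dynamic`
#'   (um), `x_reduced`, `R_blur`, `sigma_D` (um^2/s), `p_a_opt`, `p_b_opt`,
#'   `D`, `a`, `fit` (the final [fit_msd()] result), `flags`.
#' @export
localization_analysis <- function(curve, exposure = 0, dt = attr(curve, "dt"),
                                  coef_b = c(2.3, 0.52), coef_a = c(2.7, 0.5)) {
  stopifnot(inherits(curve, "spt_msd"))
  R <- exposure / (6 * dt)
  flags <- character(0)
  p_b <- p_a <- nrow(curve)   # start from all points
  fit_b <- fit_msd(curve, "brownian", n_points = p_b, weighted = TRUE)
  fit_a <- fit_b
  if (fit_b$params["b"] <= 0) {
    return(structure(list(sigma_static = NA_real_, sigma_dynamic = NA_real_,
                          x_reduced = NA_real_, R_blur = R, sigma_D = NA_real_,
                          p_a_opt = NA_integer_, p_b_opt = NA_integer_,
                          D = fit_b$D, a = unname(fit_b$params["a"]), fit = fit_b,
                          flags = "non-positive MSD slope: localization analysis undefined"),
                     class = "spt_locerr"))
  }
  for (round in seq_len(10L)) {
    a <- unname(fit_a$params["a"]); D <- fit_b$D
    var_static <- a / 4 + 2 * R * D * dt
    x <- if (D > 0) max(var_static, 0) / (D * dt) - 2 * R else 0
    xp <- max(x, 0)   # estimation noise can push x slightly below its bound
    p_b_new <- min(nrow(curve), max(2L, as.integer(floor(2 + coef_b[1] * xp^coef_b[2]))))
    p_a_new <- min(nrow(curve), max(2L, as.integer(floor(2 + coef_a[1] * xp^coef_a[2]))))
    if (p_b_new == p_b && p_a_new == p_a) break
    p_b <- p_b_new; p_a <- p_a_new
    fit_b <- fit_msd(curve, "brownian", n_points = p_b, weighted = TRUE)
    fit_a <- if (p_a == p_b) fit_b else
      fit_msd(curve, "brownian", n_points = p_a, weighted = TRUE)
    if (fit_b$params["b"] <= 0) { flags <- c(flags, "slope went non-positive during iteration"); break }
  }
  a <- unname(fit_a$params["a"]); D <- fit_b$D
  var_static <- a / 4 + 2 * R * D * dt
  if (var_static < 0) { flags <- c(flags, "negative static variance clamped to 0"); var_static <- 0 }
  sigma_static <- sqrt(var_static)
  if (a > 0) sigma_dynamic <- sqrt(a) / 2
  else { sigma_dynamic <- 0; flags <- c(flags, "non-positive intercept: dynamic error set to 0") }
  x <- if (D > 0) var_static / (D * dt) - 2 * R else NA_real_
  structure(list(sigma_static = sigma_static, sigma_dynamic = sigma_dynamic,
                 x_reduced = x, R_blur = R, sigma_D = fit_b$D_err,
                 p_a_opt = p_a, p_b_opt = p_b, D = D, a = a, fit = fit_b,
                 fit_intercept = fit_a, a_err = unname(fit_a$errors["a"]),
                 flags = flags),
            class = "spt_locerr")
}

#' @export
print.spt_locerr <- function(x, ...) {
  cat("Localization-error analysis (R_blur =", format(x$R_blur), ")\n")
  cat(sprintf("  D            = %.5g +/- %.3g um^2/s (over %d lags)\n",
              x$D, x$sigma_D, x$p_b_opt))
  cat(sprintf("  sigma_static = %.4g um; sigma_dynamic = %.4g um\n",
              x$sigma_static, x$sigma_dynamic))
  cat(sprintf("  reduced error x = %.4g; optimal lags: slope %d, intercept %d\n",
              x$x_reduced, x$p_b_opt, x$p_a_opt))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
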