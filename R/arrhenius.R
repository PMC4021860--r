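#' Arrhenius analysis of temperature-dependent diffusion
#'
#' Fits `ln(D)` against `1/T` by least squares; the effective activation
#' energy is `Ea = -slope * R_gas` with `R_gas = 8.314 J/(mol K)`, reported
#' in kJ/mol. When diffusion-coefficient errors are supplied the fit is
#' weighted by the inverse squared fractional error (`sigma_lnD = D_err/D`);
#' with equal weights this coincides with the unweighted fit. With exactly
#' two points the line is exact and the parameter errors are undefined
#' (flagged `NA`).
#'
#' @param temperature temperatures (kelvin unless `celsius = TRUE`).
#' @param D diffusion coefficients (um^2/s, all > 0).
#' @param D_err optional one-sigma errors on `D`.
#' @param celsius are temperatures in degrees Celsius?
#' @return An object of class `spt_arrhenius`: `Ea`, `Ea_err` (kJ/mol),
#'   `ln_prefactor`, `ln_prefactor_err`, `r2`, `points` (data frame `T_K`,
#'   `D`, `D_err`), `weighted`.
#' @examples
#' arrhenius_fit(c(298.15, 313.15), c(1, 2))
#' @export
arrhenius_fit <- function(temperature, D, D_err = NULL, celsius = FALSE) {
  R_gas <- 8.314
  if (celsius) temperature <- temperature + 273.15
  if (length(temperature) != length(D))
    stop("temperature and D must have equal length")
  if (length(unique(temperature)) < 2L)
    stop("need at least 2 distinct temperatures")
  if (any(!is.finite(D)) || any(D <= 0))
    stop("all diffusion coefficients must be positive")
  x <- 1 / temperature
  y <- log(D)
  w <- NULL
  if (!is.null(D_err)) {
    if (length(D_err) != length(D)) stop("D_err must match D in length")
    if (any(!is.finite(D_err)) || any(D_err <= 0))
      stop("all D errors must be positive")
    w <- (D / D_err)^2
  }
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  beta <- stats::coef(fit)
  n <- length(y)
  se <- if (n > 2L) suppressWarnings(sqrt(diag(stats::vcov(fit)))) else rep(NA_real_, 2L)
  r2 <- if (n > 2L) suppressWarnings(summary(fit))$r.squared else 1
  structure(list(
    Ea = -unname(beta[2L]) * R_gas / 1000,
    Ea_err = unname(se[2L]) * R_gas / 1000,
    ln_prefactor = unname(beta[1L]),
    ln_prefactor_err = unname(se[1L]),
    r2 = r2,
    points = data.frame(T_K = temperature, D = D,
                        D_err = if (is.null(D_err)) NA_real_ else D_err),
    weighted = !is.null(w)),
    class = "spt_arrhenius")
}

#' @export
print.spt_arrhenius <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures (%s)\n",
              nrow(x$points), if (x$weighted) "weighted" else "unweighted"))
  cat(sprintf("  Ea = %.4g +/- %.3g kJ/mol; ln prefactor = %.4g; r2 = %.4f\n",
              x$Ea, x$Ea_err, x$ln_prefactor, x$r2))
  invisible(x)
}

#' @export
plot.spt_arrhenius <- function(x, ...) {
  invT <- 1 / x$points$T_K
  plot(invT, log(x$points$D), xlab = "1/T (1/K)", ylab = "ln D", ...)
  graphics::abline(x$ln_prefactor, -x$Ea * 1000 / 8.314, col = "red3")
  invisible(x)
}
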