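#' Quick per-trajectory diffusion estimates
#'
#' For each trajectory, computes the time-averaged MSD over frame lags
#' `1..n_lags` (overlapping pairs) and fits an unweighted line
#' `msd = a + b t`; the apparent diffusion coefficient is `D = b/4`, clamped
#' at zero (D is nonnegative by definition; a negative-slope fit reflects
#' noise or an immobile spot). Trajectories too short to yield at least two
#' MSD points are flagged with `D = NA` rather than dropped.
#'
#' @param e an [spt_ensemble].
#' @param n_lags number of time-lags for the per-trajectory fit (>= 2);
#'   short-lag fits are least biased, hence the small default.
#' @return A data frame with one row per trajectory: `trajectory`, `length`,
#'   `D` (um^2/s, `NA` when undefined), `r2` (`NA` when the MSD has zero
#'   variance), `mean_intensity` (`NA` when intensities are absent).
#' @export
individual_diffusion_estimates <- function(e, n_lags = 4L) {
  stopifnot(inherits(e, "spt_ensemble"))
  if (!is.numeric(n_lags) || n_lags < 2L)
    stop("n_lags must be >= 2")
  n_lags <- as.integer(n_lags)
  trs <- .traj_list(e)
  ids <- as.integer(names(trs))
  dt <- e$dt
  out <- data.frame(trajectory = ids,
                    length = vapply(trs, function(tr) length(tr$frame), 1L),
                    D = NA_real_, r2 = NA_real_, mean_intensity = NA_real_)
  for (i in seq_along(trs)) {
    tr <- trs[[i]]
    if (!is.null(tr$intensity))
      out$mean_intensity[i] <- mean(tr$intensity, na.rm = TRUE)
    if (length(tr$frame) <= n_lags) next   # undefined D, flagged via NA
    msd <- rep(NA_real_, n_lags)
    for (lag in seq_len(n_lags)) {
      v <- .sq_disp_one(tr, lag)
      if (length(v) > 0L) msd[lag] <- mean(v)
    }
    ok <- !is.na(msd)
    if (sum(ok) < 2L) next
    t <- (seq_len(n_lags) * dt)[ok]
    y <- msd[ok]
    fit <- stats::lm.fit(cbind(1, t), y)
    slope <- fit$coefficients[2L]
    out$D[i] <- max(0, slope / 4)
    tss <- sum((y - mean(y))^2)
    out$r2[i] <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Exclusion criteria for trajectory filtering
#'
#' Any criterion left `NA` is skipped. Intensity bounds refer to the mean
#' over the trajectory of the mean-normalized spot intensity.
#'
#' @param min_frames minimum trajectory length in frames.
#' @param min_D,max_D bounds on the per-trajectory diffusion coefficient
#'   (um^2/s) from [individual_diffusion_estimates()].
#' @param min_r2 minimum R-squared of the per-trajectory linear MSD fit.
#' @param min_intensity,max_intensity bounds on mean trajectory intensity.
#' @return An object of class `spt_filter_criteria`.
#' @export
filter_criteria <- function(min_frames = NA, min_D = NA, max_D = NA,
                            min_r2 = NA, min_intensity = NA,
                            max_intensity = NA) {
  if (!is.na(min_D) && !is.na(max_D) && min_D > max_D)
    stop("min_D must be <= max_D")
  if (!is.na(min_intensity) && !is.na(max_intensity) &&
      min_intensity > max_intensity)
    stop("min_intensity must be <= max_intensity")
  if (!is.na(min_r2) && (min_r2 < 0 || min_r2 > 1))
    stop("min_r2 must lie in [0, 1]")
  structure(list(min_frames = min_frames, min_D = min_D, max_D = max_D,
                 min_r2 = min_r2, min_intensity = min_intensity,
                 max_intensity = max_intensity),
            class = "spt_filter_criteria")
}

#' Filter spurious trajectories by exclusion criteria
#'
#' A trajectory survives if and only if it passes every criterion that is
#' set: `length >= min_frames`; `min_D <= D <= max_D`; `r2 >= min_r2`;
#' `min_intensity <= mean intensity <= max_intensity`. A trajectory whose
#' `D` or `r2` is undefined (too short for the requested lags, or a
#' zero-variance MSD) fails any set criterion on that quantity. When the
#' ensemble carries no intensities, intensity criteria are skipped with a
#' warning. The input ensemble is never modified.
#'
#' @param e an [spt_ensemble].
#' @param criteria an [filter_criteria()] object.
#' @param n_lags lags for the per-trajectory D estimates (see
#'   [individual_diffusion_estimates()]).
#' @return A list of class `spt_filter_result`: `ensemble` (the filtered
#'   [spt_ensemble]), `report` (named integer vector of per-criterion
#'   failure counts; one trajectory may count under several criteria),
#'   `n_input`, `n_kept`, `kept_ids`.
#' @export
apply_filters <- function(e, criteria, n_lags = 4L) {
  stopifnot(inherits(e, "spt_ensemble"), inherits(criteria, "spt_filter_criteria"))
  est <- individual_diffusion_estimates(e, n_lags = n_lags)
  cr <- criteria
  report <- c(min_frames = 0L, min_D = 0L, max_D = 0L, min_r2 = 0L,
              min_intensity = 0L, max_intensity = 0L)
  keep <- rep(TRUE, nrow(est))

  fail <- function(cond) { cond[is.na(cond)] <- TRUE; cond }
  if (!is.na(cr$min_frames)) {
    f <- est$length < cr$min_frames
    report["min_frames"] <- sum(f); keep <- keep & !f
  }
  if (!is.na(cr$min_D)) {
    f <- fail(est$D < cr$min_D)
    report["min_D"] <- sum(f); keep <- keep & !f
  }
  if (!is.na(cr$max_D)) {
    f <- fail(est$D > cr$max_D)
    report["max_D"] <- sum(f); keep <- keep & !f
  }
  if (!is.na(cr$min_r2)) {
    f <- fail(est$r2 < cr$min_r2)
    report["min_r2"] <- sum(f); keep <- keep & !f
  }
  has_int <- !is.null(e$points$intensity)
  if ((!is.na(cr$min_intensity) || !is.na(cr$max_intensity)) && !has_int) {
    warning("ensemble carries no intensities; intensity criteria skipped")
  } else {
    if (!is.na(cr$min_intensity)) {
      f <- fail(est$mean_intensity < cr$min_intensity)
      report["min_intensity"] <- sum(f); keep <- keep & !f
    }
    if (!is.na(cr$max_intensity)) {
      f <- fail(est$mean_intensity > cr$max_intensity)
      report["max_intensity"] <- sum(f); keep <- keep & !f
    }
  }

  kept_ids <- est$trajectory[keep]
  out <- e
  out$points <- e$points[e$points$trajectory %in% kept_ids, , drop = FALSE]
  rownames(out$points) <- NULL
  structure(list(ensemble = out, report = report,
                 n_input = nrow(est), n_kept = sum(keep),
                 kept_ids = kept_ids),
            class = "spt_filter_result")
}

#' @export
print.spt_filter_result <- function(x, ...) {
  cat("Trajectory filtering:", x$n_input, "->", x$n_kept, "trajectories\n")
  cat("Failures by criterion (a trajectory may count more than once):\n")
  for (nm in names(x$report))
    if (x$report[nm] > 0L) cat(sprintf("  %-14s %d\n", nm, x$report[nm]))
  if (all(x$report == 0L)) cat("  (none)\n")
  invisible(x)
}

#' Dataset summary statistics
#'
#' Counts, mean trajectory length, mean individual diffusion coefficient,
#' and histograms of trajectory length, mean intensity, and individual D
#' (log10 scale by default, matching how broad D distributions are usually
#' displayed).
#'
#' @param e an [spt_ensemble].
#' @param n_lags lags for the per-trajectory D estimates.
#' @param breaks passed to [graphics::hist()] for the histograms.
#' @param log10_D histogram individual D on the log10 scale?
#' @return An object of class `spt_summary`: `n_coordinates`,
#'   `n_trajectories`, `mean_length`, `mean_D`, and `hist_length`,
#'   `hist_intensity`, `hist_D` (each a list with `breaks` and `counts`,
#'   or `NULL` when there is nothing to bin).
#' @export
summarize_ensemble <- function(e, n_lags = 4L, breaks = "Sturges",
                               log10_D = TRUE) {
  stopifnot(inherits(e, "spt_ensemble"))
  n_traj <- n_trajectories(e)
  if (n_traj == 0L) {
    return(structure(list(n_coordinates = 0L, n_trajectories = 0L,
                          mean_length = NA_real_, mean_D = NA_real_,
                          hist_length = NULL, hist_intensity = NULL,
                          hist_D = NULL),
                     class = "spt_summary"))
  }
  est <- individual_diffusion_estimates(e, n_lags = n_lags)
  hist_of <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NULL)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  }
  Dv <- est$D
  if (log10_D) Dv <- log10(Dv[!is.na(Dv) & Dv > 0])
  structure(list(
    n_coordinates = n_coordinates(e),
    n_trajectories = n_traj,
    mean_length = n_coordinates(e) / n_traj,
    mean_D = mean(est$D, na.rm = TRUE),
    hist_length = hist_of(est$length),
    hist_intensity = hist_of(est$mean_intensity),
    hist_D = hist_of(Dv)),
    class = "spt_summary")
}

#' @export
print.spt_summary <- function(x, ...) {
  cat("Coordinates:              ", x$n_coordinates, "\n")
  cat("Trajectories:             ", x$n_trajectories, "\n")
  cat("Average trajectory length:",
      if (is.na(x$mean_length)) "NA" else sprintf("%.1f", x$mean_length), "\n")
  cat("Mean individual D:        ",
      if (is.na(x$mean_D)) "NA" else sprintf("%.3g um^2/s", x$mean_D), "\n")
  invisible(x)
}
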