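#' Trajectory ensemble
#'
#' An `spt_ensemble` bundles a set of single-molecule trajectories with the
#' acquisition metadata every downstream analysis needs: the frame interval
#' `dt` (s), the camera `pixel_size` (um/pixel, `NA` when positions were never
#' in pixels), the `exposure` time (s, at most `dt`), and optionally the
#' sample `temperature` (K).
#'
#' Localizations live in a single data frame with columns `trajectory`
#' (integer id), `frame` (0-based integer, strictly increasing within a
#' trajectory), `x`, `y` (um, origin at the image top-left, y pointing down)
#' and optionally `intensity` (dimensionless, mean-normalized spot
#' brightness).
#'
#' @param points data frame with columns `trajectory`, `frame`, `x`, `y` and
#'   optionally `intensity`. May have zero rows.
#' @param dt frame interval in seconds (> 0).
#' @param pixel_size pixel size in um/pixel, or `NA` if not applicable.
#' @param exposure camera exposure in seconds, `0 <= exposure <= dt`.
#' @param temperature sample temperature in kelvin, or `NA`.
#' @param source free-form provenance string.
#' @return An object of class `spt_ensemble`.
#' @examples
#' pts <- data.frame(trajectory = c(1, 1, 1), frame = 0:2,
#'                   x = c(0, 1, 1), y = c(0, 0, 1))
#' e <- spt_ensemble(pts, dt = 0.01)
#' n_trajectories(e)
#' @export
spt_ensemble <- function(points, dt, pixel_size = NA_real_, exposure = 0,
                         temperature = NA_real_, source = "memory") {
  stopifnot(is.data.frame(points))
  required <- c("trajectory", "frame", "x", "y")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0L)
    stop("points is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)")
  if (!is.numeric(exposure) || length(exposure) != 1L || is.na(exposure) ||
      exposure < 0 || exposure > dt)
    stop("exposure must satisfy 0 <= exposure <= dt")

  points$trajectory <- as.integer(points$trajectory)
  points$frame <- as.integer(points$frame)
  points$x <- as.numeric(points$x)
  points$y <- as.numeric(points$y)
  if (!is.null(points$intensity)) points$intensity <- as.numeric(points$intensity)
  points <- points[order(points$trajectory, points$frame), , drop = FALSE]
  rownames(points) <- NULL

  if (nrow(points) > 0L) {
    if (any(!is.finite(points$x)) || any(!is.finite(points$y)))
      stop("positions must be finite")
    same <- points$trajectory[-1L] == points$trajectory[-nrow(points)]
    dup <- same & (points$frame[-1L] <= points$frame[-nrow(points)])
    if (any(dup)) {
      bad <- points$trajectory[-1L][dup][1L]
      stop("frames must be strictly increasing within trajectory ", bad)
    }
  }

  structure(
    list(points = points, dt = dt, pixel_size = pixel_size,
         exposure = exposure, temperature = temperature, source = source),
    class = "spt_ensemble")
}

#' @export
print.spt_ensemble <- function(x, ...) {
  cat("spt_ensemble:", n_trajectories(x), "trajectories,",
      n_coordinates(x), "localizations\n")
  cat("  dt =", x$dt, "s; exposure =", x$exposure, "s",
      if (!is.na(x$pixel_size)) paste0("; pixel size = ", x$pixel_size, " um"),
      "\n")
  if (!is.na(x$temperature)) cat("  temperature =", x$temperature, "K\n")
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Ensemble accessors
#'
#' @param e an [spt_ensemble].
#' @return `n_trajectories()`/`n_coordinates()` return integer counts;
#'   `trajectory_lengths()` a named integer vector (names are trajectory
#'   ids); `trajectory_ids()` the integer ids.
#' @export
n_trajectories <- function(e) length(unique(e$points$trajectory))

#' @rdname n_trajectories
#' @export
n_coordinates <- function(e) nrow(e$points)

#' @rdname n_trajectories
#' @export
trajectory_lengths <- function(e) {
  if (nrow(e$points) == 0L) return(integer(0))
  tab <- table(e$points$trajectory)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @rdname n_trajectories
#' @export
trajectory_ids <- function(e) unique(e$points$trajectory)

#' Extract one trajectory as a single-trajectory ensemble
#'
#' @param e an [spt_ensemble].
#' @param id trajectory id.
#' @return An [spt_ensemble] holding only trajectory `id`.
#' @export
get_trajectory <- function(e, id) {
  keep <- e$points$trajectory == id
  if (!any(keep)) stop("no trajectory with id ", id)
  out <- e
  out$points <- e$points[keep, , drop = FALSE]
  rownames(out$points) <- NULL
  out
}

#' @export
plot.spt_ensemble <- function(x, max_traj = 50L, col = NULL, asp = 1, ...) {
  ids <- trajectory_ids(x)
  if (length(ids) > max_traj) ids <- ids[seq_len(max_traj)]
  pts <- x$points[x$points$trajectory %in% ids, , drop = FALSE]
  if (nrow(pts) == 0L) stop("nothing to plot: empty ensemble")
  if (is.null(col)) col <- grDevices::hcl.colors(length(ids), "Dark 3")
  plot(NA, xlim = range(pts$x), ylim = rev(range(pts$y)), asp = asp,
       xlab = "x (um)", ylab = "y (um)", ...)
  for (i in seq_along(ids)) {
    tr <- pts[pts$trajectory == ids[i], ]
    graphics::lines(tr$x, tr$y, col = col[(i - 1L) %% length(col) + 1L])
  }
  invisible(x)
}

# Internal: split ensemble into a list of per-trajectory lists
# (frame/x/y/intensity vectors), ordered by id. Used by the MSD and CPD code.
.traj_list <- function(e) {
  pts <- e$points
  if (nrow(pts) == 0L) return(list())
  idx <- split(seq_len(nrow(pts)), pts$trajectory)
  has_int <- !is.null(pts$intensity)
  lapply(idx, function(i) {
    list(frame = pts$frame[i], x = pts$x[i], y = pts$y[i],
         intensity = if (has_int) pts$intensity[i] else NULL)
  })
}

# Internal: squared displacements of one trajectory at a frame lag.
# Pairs are overlapping and matched on frame index difference, so gapped
# trajectories contribute only pairs truly `lag` frames apart.
.sq_disp_one <- function(tr, lag) {
  j <- match(tr$frame + lag, tr$frame)
  ok <- !is.na(j)
  if (!any(ok)) return(numeric(0))
  i <- which(ok)
  (tr$x[j[i]] - tr$x[i])^2 + (tr$y[j[i]] - tr$y[i])^2
}
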