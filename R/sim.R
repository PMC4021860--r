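# Monte-Carlo diffusion simulators.
#
# All modes share one RNG discipline: the run seed initializes a master
# stream used only to derive one sub-seed per trajectory, so growing n_traj
# appends trajectories without reshuffling existing ones. Per-trajectory
# draws (population/state assignment, steps, localization noise) come from
# the trajectory's own substream.

.traj_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n, replace = TRUE)
}

.check_sim_args <- function(n_traj, n_steps, dt, D1, D2, sigma_loc) {
  if (!is.numeric(n_traj) || n_traj < 1L) stop("n_traj must be >= 1")
  if (!is.numeric(n_steps) || n_steps < 1L) stop("n_steps must be >= 1")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (D1 < 0 || D2 < 0) stop("diffusion coefficients must be >= 0")
  if (sigma_loc < 0) stop("sigma_loc must be >= 0")
}

.points_df <- function(xs, ys, ints = NULL) {
  n_traj <- length(xs)
  len <- length(xs[[1L]])
  data.frame(trajectory = rep(seq_len(n_traj), each = len),
             frame = rep.int(0:(len - 1L), n_traj),
             x = unlist(xs, use.names = FALSE),
             y = unlist(ys, use.names = FALSE))
}

#' Simulate simple (constant-D) Brownian diffusion
#'
#' Each particle diffuses with a constant coefficient for its whole lifetime:
#' with probability `fraction1` it belongs to population 1 (`D1`), otherwise
#' to population 2 (`D2`). Per-frame displacements are drawn independently
#' per axis from a zero-mean Gaussian with variance `2 D dt`; independent
#' Gaussian localization noise of standard deviation `sigma_loc` is then
#' added to every reported coordinate (re-drawn each frame; true positions
#' propagate noise-free). The plane is unbounded. A run is bit-reproducible
#' under a fixed `seed`.
#'
#' @param n_traj number of trajectories.
#' @param n_steps displacements per trajectory (each trajectory has
#'   `n_steps + 1` localizations, frames `0..n_steps`).
#' @param dt frame interval (s).
#' @param D1,D2 diffusion coefficients (um^2/s).
#' @param fraction1 probability of belonging to population 1.
#' @param sigma_loc localization noise standard deviation (um).
#' @param seed integer RNG seed.
#' @return An [spt_ensemble] with attribute `"population"` (integer 1/2 per
#'   trajectory).
#' @examples
#' e <- simulate_simple(n_traj = 4, n_steps = 1000, dt = 0.01, D1 = 2, seed = 1)
#' @export
simulate_simple <- function(n_traj, n_steps, dt, D1, D2 = D1, fraction1 = 1,
                            sigma_loc = 0, seed = 1L) {
  .check_sim_args(n_traj, n_steps, dt, D1, D2, sigma_loc)
  if (fraction1 < 0 || fraction1 > 1) stop("fraction1 must lie in [0, 1]")
  seeds <- .traj_seeds(seed, n_traj)
  xs <- ys <- vector("list", n_traj)
  pop <- integer(n_traj)
  len <- n_steps + 1L
  for (i in seq_len(n_traj)) {
    set.seed(seeds[i])
    pop[i] <- if (stats::runif(1) < fraction1) 1L else 2L
    D <- if (pop[i] == 1L) D1 else D2
    s <- sqrt(2 * D * dt)
    x <- c(0, cumsum(stats::rnorm(n_steps, 0, s)))
    y <- c(0, cumsum(stats::rnorm(n_steps, 0, s)))
    if (sigma_loc > 0) {
      x <- x + stats::rnorm(len, 0, sigma_loc)
      y <- y + stats::rnorm(len, 0, sigma_loc)
    }
    xs[[i]] <- x; ys[[i]] <- y
  }
  e <- spt_ensemble(.points_df(xs, ys), dt = dt,
                    source = sprintf("sim:simple(seed=%d)", as.integer(seed)))
  attr(e, "population") <- pop
  e
}

#' Simulate two-state switching diffusion
#'
#' Particles alternate between a fast state 1 (`D1`, exit rate `k12`) and a
#' slow state 2 (`D2`, exit rate `k21`). The initial state is drawn from the
#' equilibrium occupancy `k21/(k12 + k21)` for state 1 (state 1 when both
#' rates are zero), which avoids transient bias in fraction estimates. At
#' each frame the particle leaves its state with probability
#' `1 - exp(-k dt)` (exact exponential-dwell discretization, valid for large
#' `k dt`). The displacement over a frame uses the state at the frame's
#' start. Noise as in [simulate_simple()].
#'
#' @inheritParams simulate_simple
#' @param k12,k21 switch rates (1/s) out of states 1 and 2.
#' @return A list: `ensemble` (an [spt_ensemble]) and `states` (data frame
#'   `trajectory`, `frame`, `state` with state 1 = fast, 2 = slow, one row
#'   per localization).
#' @export
simulate_switch <- function(n_traj, n_steps, dt, D1, D2, k12, k21,
                            sigma_loc = 0, seed = 1L) {
  .check_sim_args(n_traj, n_steps, dt, D1, D2, sigma_loc)
  if (k12 < 0 || k21 < 0) stop("switch rates must be >= 0")
  seeds <- .traj_seeds(seed, n_traj)
  p_eq1 <- if (k12 + k21 > 0) k21 / (k12 + k21) else 1
  p_exit <- c(1 - exp(-k12 * dt), 1 - exp(-k21 * dt))
  len <- n_steps + 1L
  xs <- ys <- st <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(seeds[i])
    s0 <- if (stats::runif(1) < p_eq1) 1L else 2L
    states <- integer(0)
    cur <- s0
    while (length(states) < len) {
      p <- p_exit[cur]
      dwell <- if (p <= 0) len else stats::rgeom(1L, p) + 1L
      states <- c(states, rep.int(cur, min(dwell, len - length(states))))
      cur <- 3L - cur
    }
    sd_step <- sqrt(2 * ifelse(states[seq_len(n_steps)] == 1L, D1, D2) * dt)
    x <- c(0, cumsum(stats::rnorm(n_steps, 0, sd_step)))
    y <- c(0, cumsum(stats::rnorm(n_steps, 0, sd_step)))
    if (sigma_loc > 0) {
      x <- x + stats::rnorm(len, 0, sigma_loc)
      y <- y + stats::rnorm(len, 0, sigma_loc)
    }
    xs[[i]] <- x; ys[[i]] <- y; st[[i]] <- states
  }
  pts <- .points_df(xs, ys)
  e <- spt_ensemble(pts, dt = dt,
                    source = sprintf("sim:switch(seed=%d)", as.integer(seed)))
  states <- data.frame(trajectory = pts$trajectory, frame = pts$frame,
                       state = unlist(st, use.names = FALSE))
  list(ensemble = e, states = states)
}

#' Generate a random circular-domain map
#'
#' Places `Poisson(density x area)` immobile circular domains with centers
#' uniform in the box (complete spatial randomness) and diameters drawn from
#' a Gaussian truncated to positive values. Overlaps are permitted; a point
#' is "inside" when it falls inside any circle.
#'
#' @param box simulation region `c(width, height)` in um.
#' @param density expected domains per um^2.
#' @param mean_diameter,diameter_sd domain diameter distribution (um).
#' @param seed integer RNG seed.
#' @return An object of class `spt_domain_map` (`type = "circles"`).
#' @export
generate_domain_map <- function(box, density, mean_diameter, diameter_sd = 0,
                                seed = 1L) {
  stopifnot(length(box) == 2L, all(box > 0))
  if (density < 0) stop("density must be >= 0")
  if (mean_diameter <= 0) stop("mean_diameter must be > 0")
  if (diameter_sd < 0) stop("diameter_sd must be >= 0")
  set.seed(as.integer(seed))
  n <- stats::rpois(1L, density * box[1] * box[2])
  cx <- stats::runif(n, 0, box[1])
  cy <- stats::runif(n, 0, box[2])
  d <- stats::rnorm(n, mean_diameter, diameter_sd)
  while (any(d <= 0)) d[d <= 0] <- stats::rnorm(sum(d <= 0), mean_diameter, diameter_sd)
  structure(list(type = "circles", x = cx, y = cy, r = d / 2, box = box),
            class = "spt_domain_map")
}

#' Import a domain map from a binary raster image
#'
#' Reads a single-channel PNG or TIFF; pixels above `threshold` (default one
#' half of the normalized intensity range) are domain interior. Membership
#' queries resolve by pixel lookup at `floor(position / pixel_size)`, with
#' row 1 at the image top (y increases downward, matching the coordinate
#' convention of [spt_ensemble()]).
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param pixel_size physical pixel size in um.
#' @param threshold foreground threshold on the normalized `[0, 1]` scale.
#' @return An object of class `spt_domain_map` (`type = "raster"`).
#' @export
import_domain_map <- function(path, pixel_size, threshold = 0.5) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)"))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask <- img > threshold
  if (all(mask)) message("imported domain map is all foreground")
  if (!any(mask)) message("imported domain map has no domain interior")
  structure(list(type = "raster", mask = mask, pixel_size = pixel_size,
                 box = c(ncol(mask), nrow(mask)) * pixel_size),
            class = "spt_domain_map")
}

#' @export
print.spt_domain_map <- function(x, ...) {
  if (x$type == "circles")
    cat("spt_domain_map: ", length(x$r), " circular domains in ",
        x$box[1], " x ", x$box[2], " um box\n", sep = "")
  else
    cat("spt_domain_map: ", nrow(x$mask), " x ", ncol(x$mask),
        " raster, pixel ", x$pixel_size, " um\n", sep = "")
  cat(sprintf("  domain area fraction ~ %.3f\n", domain_area_fraction(x)))
  invisible(x)
}

#' Domain membership query
#'
#' Deterministically reports whether points lie inside a domain. Circle maps
#' use minimum-image distances on the periodic box; raster maps use pixel
#' lookup (coordinates wrapped into the box).
#'
#' @param map an `spt_domain_map`.
#' @param x,y coordinates in um (vectors of equal length).
#' @return Logical vector.
#' @export
domain_membership <- function(map, x, y) {
  stopifnot(inherits(map, "spt_domain_map"), length(x) == length(y))
  W <- map$box[1]; H <- map$box[2]
  x <- x %% W; y <- y %% H
  if (map$type == "circles") {
    inside <- rep(FALSE, length(x))
    for (k in seq_along(map$r)) {
      dx <- abs(x - map$x[k]); dx <- pmin(dx, W - dx)
      dy <- abs(y - map$y[k]); dy <- pmin(dy, H - dy)
      inside <- inside | (dx * dx + dy * dy <= map$r[k]^2)
    }
    inside
  } else {
    nr <- nrow(map$mask); nc <- ncol(map$mask)
    col <- pmin(nc, floor(x / map$pixel_size) + 1L)
    row <- pmin(nr, floor(y / map$pixel_size) + 1L)
    map$mask[cbind(row, col)]
  }
}

#' Area fraction covered by domains
#'
#' Monte-Carlo-free grid estimate of the covered area fraction (exact for
#' raster maps; rasterization at `n_grid^2` cells for circle maps).
#'
#' @param map an `spt_domain_map`.
#' @param n_grid grid resolution per axis for circle maps.
#' @return A number in `[0, 1]`.
#' @export
domain_area_fraction <- function(map, n_grid = 256L) {
  if (map$type == "raster") return(mean(map$mask))
  gx <- (seq_len(n_grid) - 0.5) / n_grid * map$box[1]
  gy <- (seq_len(n_grid) - 0.5) / n_grid * map$box[2]
  g <- expand.grid(x = gx, y = gy)
  mean(domain_membership(map, g$x, g$y))
}

#' Simulate diffusion among immobile domains
#'
#' Particles diffuse in a periodic box containing the domains of `map`:
#' outside a domain the step is drawn with `D1`, inside with `D2`. When a
#' candidate step would cross a domain boundary, the crossing is accepted
#' with probability `min(1, k dt)` (`k12` for entering, `k21` for leaving);
#' on rejection the step is re-drawn, up to 10 attempts, after which the
#' particle stays in place for that frame (this keeps the distribution of
#' non-crossing steps unbiased). Setting `k12 = 0` makes domains impermeable
#' obstacles (subdiffusion); `k21 = 0` traps inside-starting particles
#' (confined diffusion). Reported coordinates are continuous (unwrapped), so
#' MSD analysis is unaffected by the periodic box; membership uses wrapped
#' positions. Noise as in [simulate_simple()].
#'
#' @inheritParams simulate_switch
#' @param map an `spt_domain_map`; its box defines the simulation region.
#' @param start optional `n_traj x 2` matrix of start positions in um
#'   (default: uniform in the box, drawn per trajectory).
#' @return A list: `ensemble` ([spt_ensemble], unwrapped coordinates) and
#'   `states` (data frame `trajectory`, `frame`, `state`; 1 = outside,
#'   2 = inside).
#' @export
simulate_domains <- function(n_traj, n_steps, dt, D1, D2, k12, k21, map,
                             sigma_loc = 0, seed = 1L, start = NULL) {
  .check_sim_args(n_traj, n_steps, dt, D1, D2, sigma_loc)
  if (k12 < 0 || k21 < 0) stop("rates must be >= 0")
  stopifnot(inherits(map, "spt_domain_map"))
  if (!is.null(start)) {
    start <- as.matrix(start)
    if (nrow(start) != n_traj || ncol(start) != 2L)
      stop("start must be an n_traj x 2 matrix")
  }
  seeds <- .traj_seeds(seed, n_traj)
  len <- n_steps + 1L
  sd1 <- sqrt(2 * D1 * dt); sd2 <- sqrt(2 * D2 * dt)
  p_enter <- min(1, k12 * dt); p_leave <- min(1, k21 * dt)
  xs <- ys <- st <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(seeds[i])
    pos <- if (is.null(start)) stats::runif(2L, 0, map$box) else start[i, ]
    x <- y <- numeric(len); s <- integer(len)
    x[1L] <- pos[1L]; y[1L] <- pos[2L]
    inside <- domain_membership(map, pos[1L], pos[2L])
    s[1L] <- if (inside) 2L else 1L
    for (step in seq_len(n_steps)) {
      sd_step <- if (inside) sd2 else sd1
      moved <- FALSE
      for (attempt in 1:10) {
        dxy <- stats::rnorm(2L, 0, sd_step)
        cand <- pos + dxy
        inside_c <- domain_membership(map, cand[1L], cand[2L])
        if (inside_c == inside) { moved <- TRUE; break }
        p_acc <- if (inside) p_leave else p_enter
        if (p_acc >= 1 || stats::runif(1) < p_acc) {
          moved <- TRUE; inside <- inside_c; break
        }
      }
      if (moved) pos <- cand
      x[step + 1L] <- pos[1L]; y[step + 1L] <- pos[2L]
      s[step + 1L] <- if (inside) 2L else 1L
    }
    if (sigma_loc > 0) {
      x <- x + stats::rnorm(len, 0, sigma_loc)
      y <- y + stats::rnorm(len, 0, sigma_loc)
    }
    xs[[i]] <- x; ys[[i]] <- y; st[[i]] <- s
  }
  pts <- .points_df(xs, ys)
  e <- spt_ensemble(pts, dt = dt,
                    source = sprintf("sim:domains(seed=%d)", as.integer(seed)))
  states <- data.frame(trajectory = pts$trajectory, frame = pts$frame,
                       state = unlist(st, use.names = FALSE))
  list(ensemble = e, states = states)
}

#' Pair correlation function of domain centers
#'
#' Radial distribution `G(r)` of domain center-to-center distances with
#' periodic (minimum-image) wrapping: the count of ordered pairs in each
#' annulus `[r, r + dr)` is normalized by `N rho 2 pi r dr`, so a completely
#' spatially random pattern gives `G ~ 1` beyond small r. For raster maps
#' the centers are the centroids of connected foreground components
#' (labelled via the EBImage package).
#'
#' @param map an `spt_domain_map` with at least 2 domain centers.
#' @param r_max largest distance evaluated (um); default half the shorter
#'   box side.
#' @param n_bins number of radial bins.
#' @return A data frame of class `spt_paircorr` with columns `r` (bin
#'   centers, um) and `G`; attributes `rho` (center density, um^-2) and
#'   `n_centers`.
#' @export
pair_correlation <- function(map, r_max = NULL, n_bins = 50L) {
  stopifnot(inherits(map, "spt_domain_map"))
  if (map$type == "circles") {
    cx <- map$x; cy <- map$y
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("pair_correlation on raster maps requires the EBImage package")
    lab <- EBImage::bwlabel(t(map$mask) * 1)  # EBImage images are x-major
    labv <- as.integer(EBImage::imageData(lab))
    idx <- which(labv > 0L)
    xpix <- (idx - 1L) %% dim(lab)[1L]
    ypix <- (idx - 1L) %/% dim(lab)[1L]
    cx <- tapply(xpix + 0.5, labv[idx], mean) * map$pixel_size
    cy <- tapply(ypix + 0.5, labv[idx], mean) * map$pixel_size
  }
  n <- length(cx)
  if (n < 2L) stop("pair correlation needs at least 2 domain centers")
  if (is.null(r_max)) r_max <- min(map$box) / 2
  if (r_max <= 0) stop("r_max must be > 0")
  W <- map$box[1]; H <- map$box[2]
  dx <- abs(outer(cx, cx, "-")); dx <- pmin(dx, W - dx)
  dy <- abs(outer(cy, cy, "-")); dy <- pmin(dy, H - dy)
  d <- sqrt(dx^2 + dy^2)
  d <- d[row(d) != col(d)]          # ordered pairs, diagonal excluded
  breaks <- seq(0, r_max, length.out = n_bins + 1L)
  counts <- graphics::hist(d[d < r_max], breaks = breaks, plot = FALSE)$counts
  r_mid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  dr <- breaks[2L] - breaks[1L]
  rho <- n / (W * H)
  G <- counts / (n * rho * 2 * pi * r_mid * dr)
  out <- data.frame(r = r_mid, G = G)
  attr(out, "rho") <- rho
  attr(out, "n_centers") <- n
  class(out) <- c("spt_paircorr", "data.frame")
  out
}

#' @export
plot.spt_paircorr <- function(x, ...) {
  plot(x$r, x$G, type = "l", xlab = "r (um)", ylab = "G(r)", ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}
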