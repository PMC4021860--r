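#' Read particle-tracking trajectories
#'
#' Imports trajectories from either an ImageJ Mosaic Particle Tracker text
#' report (`dialect = "mosaic"`) or a generic delimited trajectory table
#' (`dialect = "table"`).
#'
#' The Mosaic dialect consists of blocks headed `%% Trajectory N` followed by
#' whitespace-separated rows `frame x y z m0 m2 ...`; `x` and `y` are in
#' pixels and are converted to um using `pixel_size`; the `m0` column, when
#' present, is taken as spot intensity and mean-normalized over the whole
#' dataset. Unknown columns are ignored.
#'
#' The table dialect is delimited text (comma or tab, auto-detected) with
#' header `trajectory,frame,x,y[,intensity]`, positions already in um.
#'
#' @param path path to the trajectory file.
#' @param dialect `"mosaic"` or `"table"`.
#' @param dt frame interval in seconds (required).
#' @param pixel_size pixel size in um/pixel; required for the mosaic dialect.
#' @param exposure camera exposure in seconds.
#' @param temperature sample temperature in kelvin (optional).
#' @return An [spt_ensemble].
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path, dialect = c("table", "mosaic"), dt,
                              pixel_size = NA_real_, exposure = 0,
                              temperature = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(dt) || is.null(dt) || is.na(dt))
    stop("configuration error: dt (frame interval, s) must be provided")
  pts <- switch(dialect,
    mosaic = .read_mosaic(path, pixel_size),
    table  = .read_table(path))
  spt_ensemble(pts, dt = dt, pixel_size = pixel_size, exposure = exposure,
               temperature = temperature, source = paste0(dialect, ":", path))
}

.read_mosaic <- function(path, pixel_size) {
  if (is.na(pixel_size) || pixel_size <= 0)
    stop("configuration error: pixel_size (um/pixel) must be provided for the mosaic dialect")
  lines <- readLines(path, warn = FALSE)
  header <- grepl("^%+\\s*Trajectory\\s+\\d+", lines)
  cur_id <- NA_integer_
  recs <- vector("list", sum(header))
  acc_frame <- acc_x <- acc_y <- acc_int <- acc_id <- list()
  k <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") next
    if (header[ln]) {
      cur_id <- as.integer(sub("^%+\\s*Trajectory\\s+(\\d+).*", "\\1", lines[ln]))
      next
    }
    if (startsWith(line, "%")) next   # other comment lines
    if (is.na(cur_id))
      stop("parse error at line ", ln, ": data row before any '%% Trajectory' header")
    fields <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1]]))
    if (length(fields) < 3L || anyNA(fields[1:3]))
      stop("parse error at line ", ln, ": expected numeric 'frame x y ...' row")
    k <- k + 1L
    acc_id[[k]] <- cur_id
    acc_frame[[k]] <- fields[1L]
    acc_x[[k]] <- fields[2L]
    acc_y[[k]] <- fields[3L]
    acc_int[[k]] <- if (length(fields) >= 5L && !is.na(fields[5L])) fields[5L] else NA_real_
  }
  if (k == 0L)
    return(data.frame(trajectory = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0)))
  pts <- data.frame(trajectory = unlist(acc_id), frame = unlist(acc_frame),
                    x = unlist(acc_x) * pixel_size,
                    y = unlist(acc_y) * pixel_size,
                    intensity = unlist(acc_int))
  if (all(is.na(pts$intensity))) {
    pts$intensity <- NULL
  } else {
    m <- mean(pts$intensity, na.rm = TRUE)
    if (is.finite(m) && m > 0) pts$intensity <- pts$intensity / m
  }
  pts
}

.read_table <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    stop("parse error at line 1: empty file (expected a header)")
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  names(tab) <- tolower(names(tab))
  need <- c("trajectory", "frame", "x", "y")
  if (!all(need %in% names(tab)))
    stop("parse error at line 1: header must contain ",
         paste(need, collapse = ","))
  keep <- intersect(c(need, "intensity"), names(tab))
  tab <- tab[, keep, drop = FALSE]
  if (nrow(tab) == 0L) {
    for (cn in keep) tab[[cn]] <- numeric(0)
    return(tab)
  }
  for (cn in keep) {
    if (!is.numeric(tab[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[cn]]))) & !is.na(tab[[cn]]))
      stop("parse error at line ", if (length(bad)) bad[1L] + 1L else "?",
           ": non-numeric value in column '", cn, "'")
    }
  }
  tab
}

#' Write trajectories as a generic delimited table
#'
#' Writes the table dialect understood by [read_trajectories()]: header
#' `trajectory,frame,x,y[,intensity]`, comma-separated, positions in um
#' serialized with 17 significant digits so a read/write round trip
#' reproduces positions exactly. The intensity column is omitted when the
#' ensemble carries no intensities.
#'
#' @param e an [spt_ensemble].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return Invisibly, `path`.
#' @export
write_trajectories <- function(e, path, sep = ",") {
  stopifnot(inherits(e, "spt_ensemble"))
  pts <- e$points
  has_int <- !is.null(pts$intensity)
  header <- paste(c("trajectory", "frame", "x", "y",
                    if (has_int) "intensity"), collapse = sep)
  fmt_num <- function(v) sprintf("%.17g", v)
  cols <- list(as.character(pts$trajectory), as.character(pts$frame),
               fmt_num(pts$x), fmt_num(pts$y))
  if (has_int) cols <- c(cols, list(fmt_num(pts$intensity)))
  rows <- do.call(paste, c(cols, sep = sep))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Write a state trace table
#'
#' Serializes the per-localization diffusion state returned by
#' [simulate_switch()] or [simulate_domains()] as a delimited table with
#' header `trajectory,frame,state`.
#'
#' @param states data frame with columns `trajectory`, `frame`, `state`.
#' @param path output file path.
#' @param sep field separator.
#' @return Invisibly, `path`.
#' @export
write_state_trace <- function(states, path, sep = ",") {
  stopifnot(is.data.frame(states),
            all(c("trajectory", "frame", "state") %in% names(states)))
  utils::write.table(states[, c("trajectory", "frame", "state")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Accepts either YAML or flat `key = value` text. Recognized keys mirror the
#' acquisition metadata ([spt_ensemble()]), the exclusion criteria
#' ([filter_criteria()]) and analysis/simulation options; unknown keys are
#' kept so callers can extend the schema.
#'
#' @param path path to the config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  looks_flat <- all(grepl("^\\s*($|#|[A-Za-z_.][A-Za-z0-9_.]*\\s*=)", txt))
  if (looks_flat && any(grepl("=", txt, fixed = TRUE))) {
    txt <- txt[grepl("=", txt, fixed = TRUE)]
    keys <- trimws(sub("=.*", "", txt))
    vals <- trimws(sub("^[^=]*=", "", txt))
    num <- suppressWarnings(as.numeric(vals))
    out <- lapply(seq_along(vals), function(i)
      if (!is.na(num[i])) num[i] else vals[i])
    names(out) <- keys
    return(out)
  }
  yaml::read_yaml(path)
}
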