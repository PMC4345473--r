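#' @title Cell-track behaviour responses
#'
#' @description
#' Tracks are timed 2-D positions of individual cells, as produced by
#' time-lapse imaging of *ex vivo* cultures or by an agent-based
#' simulation, held in a data frame with columns `track_id`, `t_min`
#' (minutes), `x_um`, `y_um` (micrometres) and optionally `cell_type`
#' (e.g. `LTin`, `LTi`). Sampling must be uniform within a track. Two
#' behaviour responses are derived per track: *velocity*, the total path
#' length divided by the total duration (um/min), and *displacement*, the
#' straight-line distance from the first to the last position (um).
#'
#' @name gsn-tracks
NULL

TRACK_COLUMNS <- c("track_id", "t_min", "x_um", "y_um")

check_tracks <- function(tracks) {
  if (!is.data.frame(tracks) || !all(TRACK_COLUMNS %in% names(tracks))) {
    abort_format(paste0("tracks must be a data frame with columns ",
                        paste(TRACK_COLUMNS, collapse = ", ")))
  }
  if (nrow(tracks) == 0) return(tracks)
  if (!is.numeric(tracks$t_min) || !is.numeric(tracks$x_um) ||
      !is.numeric(tracks$y_um) || anyNA(tracks[TRACK_COLUMNS])) {
    abort_format("track coordinates and times must be numeric and complete")
  }
  tracks <- tracks[order(tracks$track_id, tracks$t_min), , drop = FALSE]
  rownames(tracks) <- NULL
  for (id in unique(tracks$track_id)) {
    t <- tracks$t_min[tracks$track_id == id]
    if (length(t) < 2) {
      abort_invalid(sprintf("track '%s' has fewer than 2 positions", id))
    }
    dt <- diff(t)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * max(dt)) {
      abort_format(sprintf("track '%s' is not uniformly sampled", id))
    }
  }
  tracks
}

#' Read cell tracks from CSV
#'
#' Expects the dialect `track_id,t_min,x_um,y_um[,cell_type]`; rows are
#' sorted by (track_id, t_min) and each track must be uniformly sampled in
#' time.
#'
#' @param path CSV file path.
#' @return A validated track data frame.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) abort_not_found(sprintf("file '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_tracks(df)
}

#' Write cell tracks to CSV
#'
#' @param tracks A track data frame (see [read_tracks()] for the dialect).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- check_tracks(tracks)
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-track behaviour summaries: velocity and displacement
#'
#' @param tracks A track data frame.
#' @return Data frame with one row per track: `track_id`, `cell_type`
#'   (`NA` when absent), `n_positions`, `duration_min`, `path_length_um`,
#'   `velocity_um_min` (path length / duration) and `displacement_um`
#'   (straight-line first-to-last distance). Displacement never exceeds
#'   path length.
#' @examples
#' tr <- data.frame(track_id = "a", t_min = 0:1, x_um = c(0, 3), y_um = c(0, 4))
#' track_summaries(tr) # velocity 5 um/min, displacement 5 um
#' @export
track_summaries <- function(tracks) {
  tracks <- check_tracks(tracks)
  ids <- unique(tracks$track_id)
  has_type <- "cell_type" %in% names(tracks)
  res <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    seg <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    duration <- tr$t_min[nrow(tr)] - tr$t_min[1]
    data.frame(
      track_id = id,
      cell_type = if (has_type) tr$cell_type[1] else NA_character_,
      n_positions = nrow(tr),
      duration_min = duration,
      path_length_um = sum(seg),
      velocity_um_min = sum(seg) / duration,
      displacement_um = sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                             (tr$y_um[nrow(tr)] - tr$y_um[1])^2),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Partition tracks by proximity to a forming aggregation
#'
#' Tracks are classified by the Euclidean distance of their *first*
#' position to the aggregation centre: strictly less than the threshold is
#' *near*, at or beyond it is *far* (50 um by default, the conventional
#' split between cells close to and far from a forming aggregation).
#' Classification at observation start keeps group membership fixed over
#' the tracking period.
#'
#' @param tracks A track data frame.
#' @param centre Numeric `c(x, y)` of the aggregation centre, in um.
#' @param threshold_um Positive distance threshold in um (default 50).
#' @return A list of class `gsn_partition`: `near` and `far` (track id
#'   vectors), `threshold_um`, `centre`.
#' @export
partition_tracks <- function(tracks, centre, threshold_um = 50) {
  if (!is.numeric(centre) || length(centre) != 2 || anyNA(centre)) {
    abort_invalid("centre must be numeric c(x, y)")
  }
  if (!is.numeric(threshold_um) || length(threshold_um) != 1 ||
      threshold_um <= 0) {
    abort_invalid("threshold_um must be a single positive number")
  }
  tracks <- check_tracks(tracks)
  near <- character()
  far <- character()
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    d <- sqrt((tr$x_um[1] - centre[1])^2 + (tr$y_um[1] - centre[2])^2)
    if (d < threshold_um) near <- c(near, id) else far <- c(far, id)
  }
  structure(list(near = near, far = far, threshold_um = threshold_um,
                 centre = centre), class = "gsn_partition")
}

#' Generate synthetic cell tracks
#'
#' Each track is an independent 2-D random walk:
#' `position[t+1] = position[t] + drift + N(0, step_sd^2)` per axis, with
#' the start position drawn uniformly from a bounding box. The generator
#' stands in for *ex vivo* culture tracking data in examples and tests and
#' is fully reproducible from `seed`.
#'
#' @param n Number of tracks (>= 1).
#' @param start_region Bounding box `c(xmin, ymin, xmax, ymax)` in um for
#'   start positions.
#' @param drift Per-step deterministic displacement `c(dx, dy)` in um.
#' @param step_sd Standard deviation of the per-axis Gaussian step noise
#'   (um, >= 0).
#' @param n_steps Number of steps per track (>= 1), giving `n_steps + 1`
#'   positions.
#' @param interval_min Minutes between consecutive positions.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param cell_type Optional cell-type tag recorded on every track.
#' @return A track data frame (see [read_tracks()]).
#' @export
synthesize_tracks <- function(n, start_region = c(0, 0, 100, 100),
                              drift = c(0, 0), step_sd = 1, n_steps = 20,
                              interval_min = 1, seed = NULL,
                              cell_type = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort_invalid("n must be a positive integer")
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 1 ||
      n_steps != round(n_steps)) {
    abort_invalid("n_steps must be a positive integer")
  }
  if (!is.numeric(step_sd) || length(step_sd) != 1 || step_sd < 0) {
    abort_invalid("step_sd must be a single non-negative number")
  }
  if (!is.numeric(start_region) || length(start_region) != 4) {
    abort_invalid("start_region must be c(xmin, ymin, xmax, ymax)")
  }
  if (!is.numeric(interval_min) || length(interval_min) != 1 ||
      interval_min <= 0) {
    abort_invalid("interval_min must be a single positive number")
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
  }
  out <- vector("list", n)
  width_id <- max(3L, nchar(as.character(n)))
  for (i in seq_len(n)) {
    x <- numeric(n_steps + 1)
    y <- numeric(n_steps + 1)
    x[1] <- stats::runif(1, start_region[1], start_region[3])
    y[1] <- stats::runif(1, start_region[2], start_region[4])
    for (s in seq_len(n_steps)) {
      x[s + 1] <- x[s] + drift[1] + stats::rnorm(1, 0, step_sd)
      y[s + 1] <- y[s] + drift[2] + stats::rnorm(1, 0, step_sd)
    }
    df <- data.frame(
      track_id = sprintf(paste0("t%0", width_id, "d"), i),
      t_min = (0:n_steps) * interval_min,
      x_um = x, y_um = y, stringsAsFactors = FALSE
    )
    if (!is.null(cell_type)) df$cell_type <- cell_type
    out[[i]] <- df
  }
  do.call(rbind, out)
}
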