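#' A single fly's head-coordinate track
#'
#' Time-stamped head coordinates of one fly at a nominal 25 frames/s. Frames
#' whose coordinates fall outside the arena (or are missing) are kept but
#' flagged invalid rather than clamped; all downstream metrics integrate `dt`
#' between valid frames rather than counting frames, so irregular sampling
#' and dropouts degrade gracefully.
#'
#' @param fly_id Fly identifier (character scalar).
#' @param t Frame times, seconds, strictly increasing.
#' @param x,y Head coordinates, mm (`x` along the long axis).
#' @param valid Optional logical vector; frames additionally failing the
#'   range checks against `arena` are set invalid.
#' @param arena Optional [arena_spec()] used to range-check coordinates.
#' @return An object of class `fly_track`.
#' @export
fly_track <- function(fly_id, t, x, y, valid = NULL, arena = NULL) {
  stopifnot(is.character(fly_id), length(fly_id) == 1L, nzchar(fly_id))
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (length(x) != n || length(y) != n)
    stop("t, x, y must have equal length", call. = FALSE)
  if (n == 0L) stop("track must contain at least one frame", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop(sprintf("non-monotone timestamps for fly '%s'", fly_id), call. = FALSE)
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- as.logical(valid) & is.finite(x) & is.finite(y)
  if (!is.null(arena)) {
    in_range <- x >= 0 & x <= arena$length & y >= 0 & y <= arena$width
    in_range[is.na(in_range)] <- FALSE
    if (any(valid & !in_range))
      warning(sprintf("fly '%s': %d frame(s) outside the arena marked invalid",
                      fly_id, sum(valid & !in_range)), call. = FALSE)
    valid <- valid & in_range
  }
  structure(list(fly_id = fly_id, t = t, x = x, y = y, valid = valid),
            class = "fly_track")
}

#' @export
print.fly_track <- function(x, ...) {
  cat(sprintf("<fly_track> '%s': %d frames over [%g, %g] s (%d valid)\n",
              x$fly_id, length(x$t), min(x$t), max(x$t), sum(x$valid)))
  invisible(x)
}

#' A genotype group's experiment record
#'
#' Bundles one group's tracks with the arena geometry, the illumination
#' schedule they share, and free-form metadata (driver, effector,
#' intervention, replicate id, ...).
#'
#' @param tracks List of [fly_track()] objects.
#' @param arena An [arena_spec()].
#' @param schedule An [illumination_schedule()] (or list of epochs).
#' @param group_label Non-empty group label, e.g. `"test"`,
#'   `"driver-control"`, `"responder-control"`.
#' @param metadata Named list of free-form metadata.
#' @return An object of class `experiment_record`.
#' @export
experiment_record <- function(tracks, arena, schedule, group_label,
                              metadata = list()) {
  stopifnot(inherits(arena, "arena_spec"),
            is.character(group_label), length(group_label) == 1L,
            nzchar(group_label), is.list(metadata))
  if (!inherits(schedule, "illumination_schedule"))
    schedule <- illumination_schedule(schedule)
  ok <- vapply(tracks, inherits, logical(1), "fly_track")
  if (length(tracks) == 0L || !all(ok))
    stop("tracks must be a non-empty list of fly_track objects", call. = FALSE)
  ids <- vapply(tracks, `[[`, character(1), "fly_id")
  if (anyDuplicated(ids)) stop("duplicate fly_id in tracks", call. = FALSE)
  structure(list(tracks = tracks, arena = arena, schedule = schedule,
                 group_label = group_label, metadata = metadata),
            class = "experiment_record")
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf("<experiment_record> '%s': %d flies, %d epochs\n",
              x$group_label, length(x$tracks), length(x$schedule)))
  invisible(x)
}

#' Read a track table into an experiment record
#'
#' The track table is comma-separated text with a header row and columns
#' `fly_id`, `t_s`, `x_mm`, `y_mm` — one row per fly per frame. Rows are
#' sorted by time within each fly; coordinates outside the arena are flagged
#' invalid with a warning, never clamped.
#'
#' @param path Path to the track table.
#' @param arena An [arena_spec()].
#' @param schedule An [illumination_schedule()].
#' @param group_label Group label for the record.
#' @param metadata Named list of metadata.
#' @return An [experiment_record()].
#' @export
load_tracks <- function(path, arena, schedule, group_label = "test",
                        metadata = list()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "t_s", "x_mm", "y_mm")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop(sprintf("track table '%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  tracks <- lapply(split(tab, tab$fly_id), function(d) {
    d <- d[order(d$t_s), , drop = FALSE]
    if (anyDuplicated(d$t_s))
      stop(sprintf("non-monotone timestamps for fly '%s'", d$fly_id[1]),
           call. = FALSE)
    fly_track(as.character(d$fly_id[1]), d$t_s, d$x_mm, d$y_mm, arena = arena)
  })
  names(tracks) <- NULL
  experiment_record(tracks, arena, schedule, group_label, metadata)
}

#' Write an experiment record's tracks as a track table
#'
#' Inverse of [load_tracks()]; invalid frames are written with empty
#' coordinates so the round trip preserves the valid mask.
#'
#' @param record An [experiment_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(record, path) {
  stopifnot(inherits(record, "experiment_record"))
  rows <- lapply(record$tracks, function(tr) {
    data.frame(fly_id = tr$fly_id, t_s = tr$t,
               x_mm = ifelse(tr$valid, tr$x, NA_real_),
               y_mm = ifelse(tr$valid, tr$y, NA_real_))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Smooth a track with a centered triangular window
#'
#' Applies rolling-window smoothing to the head coordinates using a centered
#' triangular window spanning `window` seconds (25 frames at the nominal
#' 25 frames/s). Weights are renormalized at the track edges and across
#' invalid frames, so valid frames are never contaminated by missing data and
#' the kernel remains a convex combination (output never leaves the input's
#' min-max envelope). Gaps of invalid frames no longer than `max_gap` seconds
#' are linearly interpolated first, for smoothing continuity; longer gaps
#' leave their frames invalid. The valid mask is preserved.
#'
#' @param track A [fly_track()].
#' @param window Full window width, seconds.
#' @param max_gap Longest invalid gap, seconds, bridged by linear
#'   interpolation before smoothing.
#' @return A smoothed [fly_track()].
#' @export
smooth_track <- function(track, window = 1.0, max_gap = 0.2) {
  stopifnot(inherits(track, "fly_track"), window > 0)
  if (!any(track$valid)) stop("track has no valid frames", call. = FALSE)
  n <- length(track$t)
  if (n == 1L) return(track)
  dt <- stats::median(diff(track$t))
  # 25 taps for a 1 s window at 25 fps; floor guards against float fuzz in dt
  half <- max(1L, floor(window / dt / 2 + 1e-9))
  # symmetric triangular weights, peak 1 at lag 0, linear to 0 beyond +/- half
  w <- 1 - abs(seq.int(-half, half)) / (half + 1)

  xs <- interpolate_short_gaps(track$t, track$x, track$valid, max_gap)
  ys <- interpolate_short_gaps(track$t, track$y, track$valid, max_gap)
  usable <- !is.na(xs) & !is.na(ys)

  track$x <- masked_convolve(xs, usable, w)
  track$y <- masked_convolve(ys, usable, w)
  # frames that were invalid and not bridged keep their raw values
  track$x[is.na(track$x)] <- xs[is.na(track$x)]
  track$y[is.na(track$y)] <- ys[is.na(track$y)]
  track
}

# linear interpolation of runs of invalid frames whose duration <= max_gap s;
# returns values with NA where frames stay unusable
interpolate_short_gaps <- function(t, v, valid, max_gap) {
  out <- ifelse(valid, v, NA_real_)
  if (all(valid) || !any(valid)) return(out)
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == length(v)) next          # edge gaps stay invalid
    if (t[i1 + 1L] - t[i0 - 1L] > max_gap + 1e-9) next
    out[i0:i1] <- stats::approx(x = t[c(i0 - 1L, i1 + 1L)],
                                y = v[c(i0 - 1L, i1 + 1L)],
                                xout = t[i0:i1])$y
  }
  out
}

# weighted moving average with per-position renormalization over usable frames
masked_convolve <- function(v, usable, w) {
  n <- length(v)
  half <- (length(w) - 1L) %/% 2L
  vv <- ifelse(usable, v, 0)
  mm <- as.numeric(usable)
  num <- rep(0, n); den <- rep(0, n)
  for (k in seq_along(w)) {
    lag <- k - half - 1L
    src <- seq_len(n) + lag
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w[k] * vv[src[ok]]
    den[ok] <- den[ok] + w[k] * mm[src[ok]]
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!usable] <- NA_real_
  out
}

#' Annotate a track's frames with zone and light state
#'
#' For the frames of `track` falling inside `epoch`, derives the quadrant
#' index (half-open intervals on `x`), the binary light state (lit iff the
#' quadrant is in the epoch's lit set; every frame of a dark epoch is unlit),
#' and the choice-zone id (the border index when the head is within
#' `choice_halfwidth` of that border, else `NA`). Occupancy is scored by the
#' nominal border position; the physical light gradient does not create a
#' third state.
#'
#' @param track A [fly_track()].
#' @param arena An [arena_spec()].
#' @param epoch An [illumination_epoch()].
#' @return A tibble with columns `t`, `x`, `y`, `valid`, `quadrant`,
#'   `lit`, `zone` (class `zone_annotation`).
#' @export
annotate_zones <- function(track, arena, epoch) {
  stopifnot(inherits(track, "fly_track"), inherits(arena, "arena_spec"),
            inherits(epoch, "illumination_epoch"))
  sel <- track$t >= epoch$start & track$t < epoch$end
  t <- track$t[sel]; x <- track$x[sel]; y <- track$y[sel]
  valid <- track$valid[sel]
  q <- quadrant_of(x, arena)
  lit <- q %in% epoch$lit_quadrants & length(epoch$lit_quadrants) > 0L
  d <- abs(outer(x, arena$border_positions, "-"))
  nearest <- max.col(-d, ties.method = "first")
  zone <- ifelse(d[cbind(seq_along(x), nearest)] <= arena$choice_halfwidth,
                 nearest - 1L, NA_integer_)
  out <- tibble::tibble(t = t, x = x, y = y, valid = valid,
                        quadrant = as.integer(q), lit = lit,
                        zone = as.integer(zone))
  class(out) <- c("zone_annotation", class(out))
  out
}
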