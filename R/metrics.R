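# Per-fly preference and speed metrics with the assay's censoring rules.
#
# All metrics integrate dt between frames (dt attributed to the frame at the
# start of each inter-frame step) over valid frames only, so dropped frames
# and irregular sampling shrink the integrated time instead of biasing it.

# dt per frame within an annotation: step duration to the next frame, last
# frame closed by the epoch end; invalid frames contribute 0
frame_dt <- function(ann, epoch) {
  n <- nrow(ann)
  if (n == 0L) return(numeric(0))
  dt <- c(diff(ann$t), max(epoch$end - ann$t[n], 0))
  dt[!ann$valid] <- 0
  dt
}

# path length over valid adjacent frame pairs, mm
path_length <- function(ann) {
  v <- ann$valid
  if (sum(v) < 2L) return(0)
  keep <- v[-length(v)] & v[-1]
  sum(sqrt(diff(ann$x)^2 + diff(ann$y)^2)[keep])
}

#' Preference index of one fly for one epoch
#'
#' PI = (time in light - time in dark) / total time, integrated over the
#' valid frames of the analysis window (by default the last 30 s of the
#' epoch). A fly that stayed on one side of the lit/unlit banding for the
#' whole epoch but still moved within it (total path length above
#' `move_threshold`) is assigned an extreme PI of +1 (light side) or -1
#' (dark side) with `pi_source = "extreme_assigned"`. A fly with no valid
#' frames in the window is censored (PI `NA`), never an error.
#'
#' @param track A [fly_track()] (smoothing is not required for occupancy).
#' @param arena An [arena_spec()].
#' @param epoch An [illumination_epoch()].
#' @param window Analysis window length, seconds, anchored at the epoch end.
#' @param move_threshold Path length (mm) over the epoch above which a
#'   single-side fly counts as having moved within its zone.
#' @return A one-row tibble: `fly_id`, `pi`, `pi_source`, `time_in_light`,
#'   `time_in_dark`, `censor_pi`.
#' @export
compute_pi <- function(track, arena, epoch, window = 30, move_threshold = 2) {
  ann <- annotate_zones(track, arena, epoch)
  win_start <- max(epoch$start, epoch$end - window)
  win <- ann[ann$t >= win_start, , drop = FALSE]
  dt <- frame_dt(win, epoch)
  t_light <- sum(dt[win$lit])
  t_dark <- sum(dt[!win$lit])
  total <- t_light + t_dark

  if (total <= 0) {
    return(tibble::tibble(fly_id = track$fly_id, pi = NA_real_,
                          pi_source = NA_character_, time_in_light = 0,
                          time_in_dark = 0, censor_pi = TRUE))
  }
  pi_val <- (t_light - t_dark) / total
  src <- "measured"
  lit_epoch <- ann$lit[ann$valid]
  if (length(lit_epoch) > 0 && (all(lit_epoch) || all(!lit_epoch)) &&
      path_length(ann) > move_threshold) {
    pi_val <- if (all(lit_epoch)) 1.0 else -1.0
    src <- "extreme_assigned"
  }
  tibble::tibble(fly_id = track$fly_id, pi = pi_val, pi_source = src,
                 time_in_light = t_light, time_in_dark = t_dark,
                 censor_pi = FALSE)
}

#' Light/dark speed ratio of one fly for one epoch
#'
#' LSR = log2(mean speed while lit / mean speed while unlit), with per-frame
#' speed = step displacement / dt, each step attributed to the light state of
#' its starting frame, over the analysis window. Censoring follows the
#' assay's rules: a fly that stayed stationary for the entire epoch is
#' censored with flag `no_movement`; a fly that did not move in both the lit
#' and unlit regions is censored with flag `single_zone` (PI remains
#' defined). Speeds should be computed on smoothed coordinates — pass the
#' track through [smooth_track()] first.
#'
#' @inheritParams compute_pi
#' @param track A smoothed [fly_track()].
#' @param move_threshold Minimum per-zone path length (mm) within the window
#'   for the fly to count as having moved in that zone.
#' @return A one-row tibble: `fly_id`, `lsr`, `mean_speed_light`,
#'   `mean_speed_dark`, `censor_lsr`, `censor_reason`.
#' @export
compute_lsr <- function(track, arena, epoch, window = 30, move_threshold = 0) {
  ann <- annotate_zones(track, arena, epoch)
  win_start <- max(epoch$start, epoch$end - window)
  win <- ann[ann$t >= win_start, , drop = FALSE]
  n <- nrow(win)
  censored <- function(reason) {
    tibble::tibble(fly_id = track$fly_id, lsr = NA_real_,
                   mean_speed_light = NA_real_, mean_speed_dark = NA_real_,
                   censor_lsr = TRUE, censor_reason = reason)
  }
  if (n < 2L || sum(win$valid) < 2L) return(censored("no_movement"))

  # steps between consecutive valid frames; attributed to the starting frame
  i0 <- seq_len(n - 1L); i1 <- i0 + 1L
  ok <- win$valid[i0] & win$valid[i1]
  dt <- (win$t[i1] - win$t[i0])[ok]
  disp <- sqrt((win$x[i1] - win$x[i0])^2 + (win$y[i1] - win$y[i0])^2)[ok]
  lit0 <- win$lit[i0][ok]

  dist_light <- sum(disp[lit0]); dist_dark <- sum(disp[!lit0])
  if (dist_light + dist_dark <= 0) return(censored("no_movement"))
  if (!any(lit0) || dist_light <= move_threshold) return(censored("single_zone"))
  if (all(lit0) || dist_dark <= move_threshold) return(censored("single_zone"))

  v_light <- dist_light / sum(dt[lit0])
  v_dark <- dist_dark / sum(dt[!lit0])
  if (!is.finite(v_light) || !is.finite(v_dark) || v_light <= 0 || v_dark <= 0)
    return(censored("single_zone"))
  tibble::tibble(fly_id = track$fly_id, lsr = log2(v_light / v_dark),
                 mean_speed_light = v_light, mean_speed_dark = v_dark,
                 censor_lsr = FALSE, censor_reason = NA_character_)
}

#' Conditioned-odor preference score from two test phases
#'
#' Position-based memory score for the two-odor test: in each test phase the
#' chamber holds the CS+ odor on one side and the CS- odor on the other, with
#' sides swapped between phases. Each half PI is
#' (time on the CS+ side - time on the CS- side) / total time over the last
#' `window` seconds of its phase; the full PI is the mean of the two halves,
#' so any fixed side bias cancels. Positive full PI means preference for the
#' CS+ odor.
#'
#' @param phase_a,phase_b Data frames with columns `t` (s) and `x` (mm) for
#'   the two test phases (per fly or pooled cohort positions).
#' @param midline Chamber midline position, mm.
#' @param cs_plus_side_a,cs_plus_side_b Side (`"left"` or `"right"`) holding
#'   the CS+ odor in each phase; must differ between phases.
#' @param window Scoring window, seconds, anchored at each phase's end.
#' @return A list of class `conditioning_result` with `half_pi_a`,
#'   `half_pi_b`, `full_pi`.
#' @export
conditioning_pi <- function(phase_a, phase_b, midline,
                            cs_plus_side_a = "left",
                            cs_plus_side_b = "right", window = 30) {
  if (is.null(phase_a) || is.null(phase_b) ||
      nrow(phase_a) == 0L || nrow(phase_b) == 0L)
    stop("both test phases are required", call. = FALSE)
  if (cs_plus_side_a == cs_plus_side_b)
    stop("the CS+ side must swap between phases", call. = FALSE)
  half <- function(ph, side) {
    ph <- ph[order(ph$t), , drop = FALSE]
    keep <- ph$t >= max(ph$t) - window
    ph <- ph[keep, , drop = FALSE]
    dt <- c(diff(ph$t), stats::median(diff(ph$t)))
    on_left <- ph$x < midline
    t_plus <- sum(dt[if (side == "left") on_left else !on_left])
    t_minus <- sum(dt) - t_plus
    (t_plus - t_minus) / (t_plus + t_minus)
  }
  a <- half(phase_a, cs_plus_side_a)
  b <- half(phase_b, cs_plus_side_b)
  structure(list(half_pi_a = a, half_pi_b = b, full_pi = mean(c(a, b))),
            class = "conditioning_result")
}

#' Per-fly metric table for a group and epoch
#'
#' Computes PI, LSR and the choice-zone metrics for every fly of a record
#' over one epoch and returns a tidy table, one row per fly, with explicit
#' censoring flags. Tracks are smoothed with [smooth_track()] before speed
#' computation; occupancy (PI) uses the same smoothed coordinates, matching
#' the smoothing-then-metrics order of the assay.
#'
#' @param record An [experiment_record()].
#' @param epoch An [illumination_epoch()] from the record's schedule (or its
#'   index in the schedule).
#' @param window Analysis window, seconds (PI and LSR).
#' @param smooth Smooth tracks before computing metrics.
#' @return A tibble with one row per fly: identity, `pi`, `pi_source`,
#'   `lsr`, speeds, `chi`, `pedl`, `peld`, transit counts and censor flags.
#' @export
summarize_group <- function(record, epoch, window = 30, smooth = TRUE) {
  stopifnot(inherits(record, "experiment_record"))
  if (is.numeric(epoch)) epoch <- record$schedule[[epoch]]
  rows <- lapply(record$tracks, function(tr) {
    trs <- if (smooth) smooth_track(tr) else tr
    p <- compute_pi(trs, record$arena, epoch, window = window)
    s <- compute_lsr(trs, record$arena, epoch, window = window)
    transits <- segment_transits(trs, record$arena, epoch)
    ch <- choice_metrics(transits)
    tibble::tibble(
      fly_id = tr$fly_id, group = record$group_label,
      pi = p$pi, pi_source = p$pi_source,
      time_in_light = p$time_in_light, time_in_dark = p$time_in_dark,
      censor_pi = p$censor_pi,
      lsr = s$lsr, mean_speed_light = s$mean_speed_light,
      mean_speed_dark = s$mean_speed_dark,
      censor_lsr = s$censor_lsr, censor_reason = s$censor_reason,
      chi = ch$chi, pedl = ch$pedl, peld = ch$peld,
      n_transits = ch$n_transits,
      n_entries_from_dark = ch$n_entries_from_dark,
      n_entries_from_light = ch$n_entries_from_light,
      censor_choice = ch$censor_choice)
  })
  do.call(rbind, rows)
}

#' Group mean and SD over non-censored values
#'
#' @param metrics A table from [summarize_group()].
#' @param columns Metric columns to summarize.
#' @return A tibble with one row per metric: `metric`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(metrics, columns = c("pi", "lsr", "chi", "pedl", "peld")) {
  rows <- lapply(columns, function(cl) {
    v <- metrics[[cl]]
    v <- v[!is.na(v)]
    tibble::tibble(metric = cl, n = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  do.call(rbind, rows)
}
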