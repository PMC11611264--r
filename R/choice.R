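# Choice-zone transit segmentation and boundary statistics.

#' Segment choice-zone transits of one fly over one epoch
#'
#' A transit opens when the head enters a choice zone (the 3 mm band either
#' side of a border) from outside and closes at the first frame outside that
#' zone again. Entry and exit sides are the light state of the quadrant just
#' outside the zone on the respective side, under the epoch's lit set. A
#' transit whose outcome would straddle the epoch end is discarded, as is a
#' partial transit already in progress at the epoch start (its entry side is
#' unknown). A re-entry into the same zone within `merge_frames` frames of
#' the previous exit is merged into the prior transit, suppressing
#' pixel-noise chatter at the zone edge.
#'
#' @param track A [fly_track()] (typically smoothed).
#' @param arena An [arena_spec()].
#' @param epoch An [illumination_epoch()].
#' @param merge_frames Chatter-merge threshold, frames.
#' @return A tibble of transits: `fly_id`, `border` (0-based), `t_entry`,
#'   `t_exit`, `entry_side`, `exit_side` (`"dark"`/`"light"`), `x_min`,
#'   `x_max`, `outcome` (`"crossing"`/`"reversal"`).
#' @export
segment_transits <- function(track, arena, epoch, merge_frames = 2L) {
  ann <- annotate_zones(track, arena, epoch)
  ann <- ann[ann$valid, , drop = FALSE]
  empty <- tibble::tibble(fly_id = character(0), border = integer(0),
                          t_entry = numeric(0), t_exit = numeric(0),
                          entry_side = character(0), exit_side = character(0),
                          x_min = numeric(0), x_max = numeric(0),
                          outcome = character(0))
  n <- nrow(ann)
  if (n < 2L) return(empty)

  # light state of the quadrant adjacent to border b (0-based) on one side
  side_state <- function(border, left) {
    q <- if (left) border else border + 1L     # 0-based quadrant index
    if (length(epoch$lit_quadrants) > 0L && q %in% epoch$lit_quadrants)
      "light" else "dark"
  }

  zone <- ann$zone
  res <- list()
  open <- NULL              # list(border, i_entry, entry_left)
  skip_initial <- !is.na(zone[1])   # partial transit at epoch start
  i <- 1L
  while (i <= n) {
    z <- zone[i]
    if (skip_initial) {
      if (is.na(z)) skip_initial <- FALSE
      i <- i + 1L
      next
    }
    if (is.null(open)) {
      if (!is.na(z)) {
        b <- arena$border_positions[z + 1L]
        # merge with the immediately preceding transit at the same border?
        last <- if (length(res)) res[[length(res)]] else NULL
        if (!is.null(last) && last$border == z &&
            (i - last$i_exit) <= merge_frames) {
          open <- list(border = z, i_entry = last$i_entry,
                       entry_left = last$entry_left)
          res[[length(res)]] <- NULL
        } else {
          open <- list(border = z, i_entry = i, entry_left = ann$x[i] < b)
        }
      }
    } else if (is.na(z) || z != open$border) {
      b <- arena$border_positions[open$border + 1L]
      res[[length(res) + 1L]] <- list(
        border = open$border, i_entry = open$i_entry, i_exit = i,
        entry_left = open$entry_left, exit_left = ann$x[i] < b)
      open <- NULL
      next        # re-examine frame i: it may itself enter an adjacent zone
    }
    i <- i + 1L
  }
  # an open transit at the epoch end straddles it: discarded
  if (length(res) == 0L) return(empty)

  rows <- lapply(res, function(tr) {
    idx <- tr$i_entry:tr$i_exit
    tibble::tibble(
      fly_id = track$fly_id, border = as.integer(tr$border),
      t_entry = ann$t[tr$i_entry], t_exit = ann$t[tr$i_exit],
      entry_side = side_state(tr$border, tr$entry_left),
      exit_side = side_state(tr$border, tr$exit_left),
      x_min = min(ann$x[idx]), x_max = max(ann$x[idx]))
  })
  out <- do.call(rbind, rows)
  out$outcome <- ifelse(out$entry_side == out$exit_side, "reversal", "crossing")
  out
}

#' Choice metrics from a fly's transits
#'
#' ChI = (transits exiting to light - transits exiting to dark) / total
#' transits; PEDL = proportion of entries from the dark side exiting to
#' light; PELD = proportion of entries from the light side exiting to dark.
#' A fly with no transits during the epoch is censored entirely; PEDL / PELD
#' are additionally censored when their respective entry count is zero.
#'
#' @param transits A transit table from [segment_transits()] (one fly).
#' @return A one-row tibble: `chi`, `pedl`, `peld`, `n_transits`,
#'   `n_entries_from_dark`, `n_entries_from_light`, `censor_choice`.
#' @export
choice_metrics <- function(transits) {
  n <- nrow(transits)
  if (n == 0L) {
    return(tibble::tibble(chi = NA_real_, pedl = NA_real_, peld = NA_real_,
                          n_transits = 0L, n_entries_from_dark = 0L,
                          n_entries_from_light = 0L, censor_choice = TRUE))
  }
  to_light <- sum(transits$exit_side == "light")
  to_dark <- n - to_light
  from_dark <- transits$entry_side == "dark"
  n_dark <- sum(from_dark); n_light <- n - n_dark
  pedl <- if (n_dark > 0) sum(from_dark & transits$exit_side == "light") / n_dark
          else NA_real_
  peld <- if (n_light > 0) sum(!from_dark & transits$exit_side == "dark") / n_light
          else NA_real_
  tibble::tibble(chi = (to_light - to_dark) / n, pedl = pedl, peld = peld,
                 n_transits = as.integer(n),
                 n_entries_from_dark = as.integer(n_dark),
                 n_entries_from_light = as.integer(n_light),
                 censor_choice = FALSE)
}

#' Boundary-aligned transit trajectories
#'
#' Re-expresses transit paths in border-relative coordinates for
#' approach-behavior plots: time is re-zeroed at zone entry and `x` is
#' re-signed so the side the fly entered from is negative (for the default
#' dark-to-light filter, the dark side is negative). Borders whose dark side
#' lies to the right are mirrored, so trajectories from all borders overlay.
#'
#' @param transits Transit table from [segment_transits()].
#' @param track The matching [fly_track()].
#' @param arena An [arena_spec()].
#' @param direction Entry-side filter: `"dark_to_any"` keeps entries from
#'   the dark side (the standard approach-from-dark view), `"light_to_any"`
#'   entries from the light side, `"all"` everything.
#' @param t_after Seconds of trajectory kept after zone entry.
#' @return A tibble: `fly_id`, `border`, `transit`, `rel_t` (s from entry),
#'   `rel_x` (signed mm from the border, entry side negative).
#' @export
align_boundary_trajectories <- function(transits, track, arena,
                                        direction = c("dark_to_any",
                                                      "light_to_any", "all"),
                                        t_after = 5) {
  direction <- match.arg(direction)
  keep <- switch(direction,
                 dark_to_any = transits$entry_side == "dark",
                 light_to_any = transits$entry_side == "light",
                 all = rep(TRUE, nrow(transits)))
  transits <- transits[keep, , drop = FALSE]
  if (nrow(transits) == 0L)
    return(tibble::tibble(fly_id = character(0), border = integer(0),
                          transit = integer(0), rel_t = numeric(0),
                          rel_x = numeric(0)))
  rows <- lapply(seq_len(nrow(transits)), function(k) {
    tr <- transits[k, ]
    b <- arena$border_positions[tr$border + 1L]
    sel <- track$t >= tr$t_entry & track$t <= min(tr$t_entry + t_after, tr$t_exit) &
      track$valid
    # entered from the left iff first in-zone x is below the border
    x0 <- track$x[track$t == tr$t_entry]
    sgn <- if (length(x0) && x0[1] < b) 1 else -1   # entry side mapped to negative
    tibble::tibble(fly_id = tr$fly_id, border = tr$border, transit = k,
                   rel_t = track$t[sel] - tr$t_entry,
                   rel_x = sgn * (track$x[sel] - b))
  })
  do.call(rbind, rows)
}

#' Pointwise mean of aligned trajectories
#'
#' @param aligned Output of [align_boundary_trajectories()].
#' @param min_contributors Minimum trajectories contributing to a time point.
#' @return A tibble `rel_t`, `mean_rel_x`, `n`.
#' @export
mean_aligned_trajectory <- function(aligned, min_contributors = 3L) {
  if (nrow(aligned) == 0L)
    return(tibble::tibble(rel_t = numeric(0), mean_rel_x = numeric(0),
                          n = integer(0)))
  key <- round(aligned$rel_t, 6)
  agg <- stats::aggregate(aligned$rel_x, by = list(rel_t = key),
                          FUN = function(v) c(mean(v), length(v)))
  out <- tibble::tibble(rel_t = agg$rel_t,
                        mean_rel_x = agg$x[, 1],
                        n = as.integer(agg$x[, 2]))
  out[out$n >= min_contributors, , drop = FALSE]
}
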