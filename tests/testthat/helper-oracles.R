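# Constructed-track builders and brute-force oracles. The oracles classify
# frames and transits with independent (loop-based, if-chain) logic so they
# never share code paths with the package implementation.

default_arena <- function() arena_spec()

lit_epoch <- function(start = 0, end = 60, intensity = 22)
  illumination_epoch(start, end, intensity, "red")

# piecewise-linear track from waypoints (t, x), regular 25 fps, constant y
waypoint_track <- function(waypoints_t, waypoints_x, fps = 25, y = 2,
                           fly_id = "wp", arena = NULL) {
  t <- seq(min(waypoints_t), max(waypoints_t), by = 1 / fps)
  x <- approx(waypoints_t, waypoints_x, xout = t)$y
  fly_track(fly_id, t, x, rep(y, length(t)), arena = arena)
}

# random bounded step-walk fixture, regular 25 fps
random_fixture <- function(seed, duration = 60, fps = 25, arena = default_arena()) {
  set.seed(seed)
  n <- duration * fps
  steps <- rnorm(n - 1, 0, 0.4) + 0.25 * sin(seq_len(n - 1) / 17)
  x <- numeric(n)
  x[1] <- runif(1, 1, arena$length - 1)
  for (i in 2:n) {
    v <- x[i - 1] + steps[i - 1]
    if (v < 0) v <- -v
    if (v > arena$length) v <- 2 * arena$length - v
    x[i] <- v
  }
  y <- pmin(pmax(cumsum(c(runif(1, 1, 3), rnorm(n - 1, 0, 0.05))), 0),
            arena$width)
  fly_track(sprintf("rand_%d", seed), (seq_len(n) - 1) / fps, x, y,
            arena = arena)
}

# --- brute-force PI oracle: explicit per-frame classification ----------------
oracle_pi <- function(track, arena, epoch, window = 30) {
  in_epoch <- which(track$t >= epoch$start & track$t < epoch$end)
  win <- in_epoch[track$t[in_epoch] >= max(epoch$start, epoch$end - window)]
  t_light <- 0; t_dark <- 0
  for (k in seq_along(win)) {
    i <- win[k]
    if (!track$valid[i]) next
    dt <- if (k < length(win)) track$t[win[k + 1]] - track$t[i]
          else epoch$end - track$t[i]
    lit <- FALSE
    if (length(epoch$lit_quadrants) > 0) {
      q <- 0
      for (b in arena$border_positions) if (track$x[i] >= b) q <- q + 1
      lit <- q %in% epoch$lit_quadrants
    }
    if (lit) t_light <- t_light + dt else t_dark <- t_dark + dt
  }
  if (t_light + t_dark <= 0) return(NA_real_)
  (t_light - t_dark) / (t_light + t_dark)
}

# --- brute-force LSR oracle --------------------------------------------------
oracle_lsr <- function(track, arena, epoch, window = 30) {
  in_epoch <- which(track$t >= epoch$start & track$t < epoch$end)
  win <- in_epoch[track$t[in_epoch] >= max(epoch$start, epoch$end - window)]
  d_l <- d_d <- t_l <- t_d <- 0
  for (k in seq_len(length(win) - 1)) {
    i <- win[k]; j <- win[k + 1]
    if (!track$valid[i] || !track$valid[j]) next
    disp <- sqrt((track$x[j] - track$x[i])^2 + (track$y[j] - track$y[i])^2)
    dt <- track$t[j] - track$t[i]
    lit <- FALSE
    if (length(epoch$lit_quadrants) > 0) {
      q <- 0
      for (b in arena$border_positions) if (track$x[i] >= b) q <- q + 1
      lit <- q %in% epoch$lit_quadrants
    }
    if (lit) { d_l <- d_l + disp; t_l <- t_l + dt }
    else { d_d <- d_d + disp; t_d <- t_d + dt }
  }
  if (d_l <= 0 || d_d <= 0) return(NA_real_)
  log2((d_l / t_l) / (d_d / t_d))
}

# --- brute-force transit oracle: frame-scan state machine --------------------
# returns data.frame(entry_side, exit_side) per transit, mirroring the
# documented segmentation semantics (epoch-start partial and epoch-end open
# transits dropped, re-entry within merge_frames merged)
oracle_transits <- function(track, arena, epoch, merge_frames = 2) {
  sel <- which(track$t >= epoch$start & track$t < epoch$end & track$valid)
  x <- track$x[sel]
  n <- length(x)
  zone_at <- function(xx) {
    for (j in seq_along(arena$border_positions))
      if (abs(xx - arena$border_positions[j]) <= arena$choice_halfwidth)
        return(j)
    NA_integer_
  }
  state_of <- function(border_j, left_side) {
    q <- if (left_side) border_j - 1 else border_j   # 0-based quadrant
    if (length(epoch$lit_quadrants) > 0 && q %in% epoch$lit_quadrants)
      "light" else "dark"
  }
  out <- list()
  cur <- NULL
  i <- 1
  started_outside <- FALSE
  while (i <= n) {
    z <- zone_at(x[i])
    if (!started_outside) {
      if (is.na(z)) started_outside <- TRUE
      i <- i + 1
      next
    }
    if (is.null(cur)) {
      if (!is.na(z)) {
        merged <- FALSE
        if (length(out) > 0) {
          prev <- out[[length(out)]]
          if (prev$border == z && (i - prev$i_exit) <= merge_frames) {
            cur <- list(border = z, entry_left = prev$entry_left,
                        i_entry = prev$i_entry)
            out[[length(out)]] <- NULL
            merged <- TRUE
          }
        }
        if (!merged)
          cur <- list(border = z, i_entry = i,
                      entry_left = x[i] < arena$border_positions[z])
      }
      i <- i + 1
    } else if (is.na(z) || z != cur$border) {
      out[[length(out) + 1]] <- list(
        border = cur$border, entry_left = cur$entry_left,
        i_entry = cur$i_entry, i_exit = i,
        exit_left = x[i] < arena$border_positions[cur$border])
      cur <- NULL
      # do not advance: frame i may open an adjacent-zone transit
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0)
    return(data.frame(entry_side = character(0), exit_side = character(0)))
  do.call(rbind, lapply(out, function(tr)
    data.frame(entry_side = state_of(tr$border, tr$entry_left),
               exit_side = state_of(tr$border, tr$exit_left))))
}

oracle_choice <- function(transits) {
  n <- nrow(transits)
  if (n == 0) return(list(chi = NA_real_, pedl = NA_real_, peld = NA_real_))
  to_l <- sum(transits$exit_side == "light")
  fd <- transits$entry_side == "dark"
  list(chi = (to_l - (n - to_l)) / n,
       pedl = if (any(fd)) mean(transits$exit_side[fd] == "light") else NA_real_,
       peld = if (any(!fd)) mean(transits$exit_side[!fd] == "dark") else NA_real_)
}

# standard two-epoch schedule used across simulator tests
dark_then_lit <- function(intensity = 22, baseline_s = 30, epoch_s = 60) {
  illumination_schedule(
    illumination_epoch(0, baseline_s, color = "dark"),
    illumination_epoch(baseline_s, baseline_s + epoch_s, intensity, "red"))
}
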