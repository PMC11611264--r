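#' Walker parameters for the fly-walk simulator
#'
#' Parameters of the agent-based stadium walker. Two valence mechanisms are
#' independently tunable, mirroring the two hypothesized locomotor modes:
#' a light-dependent walking-speed multiplier `light_speed_multiplier`
#' (speed-modulation, "DAN-like": `log2` of the multiplier is the target
#' per-fly light/dark speed ratio) and boundary-turning biases
#' `p_cross_dark_to_light` / `p_cross_light_to_dark` (choice-at-the-boundary,
#' "MBON-like": the targets for the PEDL / PELD exit proportions).
#'
#' @param base_speed Walking speed in the dark, mm/s.
#' @param speed_noise_cv Coefficient of variation of multiplicative
#'   (lognormal) frame-to-frame speed noise.
#' @param light_speed_multiplier Speed multiplier while lit (`> 0`);
#'   `log2` of it is the expected LSR.
#' @param pause_rate Pause initiation rate while walking, events/s.
#' @param pause_duration_mean Mean pause dwell time, s (exponential).
#' @param heading_persistence Spontaneous x-heading reversal rate, events/s.
#' @param p_cross_dark_to_light Probability that a choice-zone entry from the
#'   dark side exits to the light side.
#' @param p_cross_light_to_dark Probability that an entry from the light side
#'   exits to the dark side.
#' @param lateral_jitter_sd Standard deviation of per-frame lateral (y)
#'   jitter, mm.
#' @return An object of class `walker_params`.
#' @export
walker_params <- function(base_speed = 8, speed_noise_cv = 0.3,
                          light_speed_multiplier = 1,
                          pause_rate = 0.2, pause_duration_mean = 1.0,
                          heading_persistence = 0.1,
                          p_cross_dark_to_light = 0.5,
                          p_cross_light_to_dark = 0.5,
                          lateral_jitter_sd = 0.05) {
  stopifnot(base_speed > 0, speed_noise_cv >= 0, light_speed_multiplier > 0,
            pause_rate >= 0, pause_duration_mean > 0, heading_persistence >= 0,
            p_cross_dark_to_light >= 0, p_cross_dark_to_light <= 1,
            p_cross_light_to_dark >= 0, p_cross_light_to_dark <= 1,
            lateral_jitter_sd >= 0)
  structure(list(base_speed = base_speed, speed_noise_cv = speed_noise_cv,
                 light_speed_multiplier = light_speed_multiplier,
                 pause_rate = pause_rate,
                 pause_duration_mean = pause_duration_mean,
                 heading_persistence = heading_persistence,
                 p_cross_dark_to_light = p_cross_dark_to_light,
                 p_cross_light_to_dark = p_cross_light_to_dark,
                 lateral_jitter_sd = lateral_jitter_sd),
            class = "walker_params")
}

#' Simulate one fly's walk
#'
#' Quasi-1-D agent-based walk at 25 frames/s under an illumination schedule:
#' dominant motion along the long axis with bounded lateral jitter, a
#' two-state pause/walk Markov chain, lognormal multiplicative speed noise,
#' spontaneous heading reversals, reflection at the arena ends, and the two
#' valence mechanisms described in [walker_params()]. The transit outcome at
#' a choice zone is drawn once per entry (from the side-appropriate crossing
#' probability) and steering is committed until zone exit. Within the light
#' gradient band the speed rule interpolates the lit fraction continuously;
#' the behavioral crossing draw and all occupancy scoring use the nominal
#' border.
#'
#' @param params A [walker_params()].
#' @param arena An [arena_spec()].
#' @param schedule An [illumination_schedule()].
#' @param seed Integer seed; identical `(params, seed)` give identical tracks.
#' @param fly_id Identifier for the emitted track.
#' @param fps Frame rate, frames/s.
#' @return A [fly_track()].
#' @export
simulate_fly <- function(params, arena, schedule, seed,
                         fly_id = sprintf("fly_%06d", seed %% 1000000L),
                         fps = 25) {
  stopifnot(inherits(params, "walker_params"), inherits(arena, "arena_spec"))
  if (!inherits(schedule, "illumination_schedule"))
    schedule <- illumination_schedule(schedule)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))

  dt <- 1 / fps
  t0 <- schedule[[1]]$start
  t1 <- schedule[[length(schedule)]]$end
  n <- floor((t1 - t0) * fps)
  t <- t0 + (seq_len(n) - 1L) * dt

  ep_start <- vapply(schedule, `[[`, numeric(1), "start")
  ep_idx <- findInterval(t, ep_start)

  # lognormal multiplicative noise with unit mean and cv = speed_noise_cv
  sdlog <- sqrt(log(1 + params$speed_noise_cv^2))
  mulog <- -sdlog^2 / 2

  x <- numeric(n); y <- numeric(n)
  pos_x <- stats::runif(1, 0, arena$length)
  pos_y <- stats::runif(1, 0.1 * arena$width, 0.9 * arena$width)
  heading <- sample(c(-1, 1), 1)
  paused <- FALSE
  committed <- FALSE          # steering committed inside a choice zone
  zone_now <- NA_integer_

  borders <- arena$border_positions
  chw <- arena$choice_halfwidth
  p_enter_pause <- params$pause_rate * dt
  p_exit_pause <- dt / params$pause_duration_mean
  p_reverse <- params$heading_persistence * dt
  m <- params$light_speed_multiplier

  for (i in seq_len(n)) {
    ep <- schedule[[ep_idx[i]]]

    # pause/walk two-state chain
    if (paused) {
      if (stats::runif(1) < p_exit_pause) paused <- FALSE
    } else if (stats::runif(1) < p_enter_pause) paused <- TRUE

    if (!paused) {
      # choice-zone bookkeeping on the nominal borders
      dists <- abs(pos_x - borders)
      zi <- which.min(dists)
      in_zone <- dists[zi] <= chw
      new_zone <- if (in_zone) zi else NA_integer_
      if (!is.na(new_zone) && (is.na(zone_now) || new_zone != zone_now)) {
        # fresh entry: draw the transit outcome once and commit steering
        b <- borders[new_zone]
        entry_left <- pos_x < b
        side_q <- if (entry_left) new_zone - 1L else new_zone  # 0-based quadrant outside
        entry_lit <- side_q %in% ep$lit_quadrants && length(ep$lit_quadrants) > 0L
        p_cross <- if (length(ep$lit_quadrants) == 0L) 0.5
                   else if (entry_lit) params$p_cross_light_to_dark
                   else params$p_cross_dark_to_light
        cross <- stats::runif(1) < p_cross
        # cross: head away from entry side; reverse: head back toward it
        heading <- if (xor(entry_left, !cross)) 1 else -1
        committed <- TRUE
      } else if (is.na(new_zone)) {
        committed <- FALSE
      }
      zone_now <- new_zone

      if (!committed && stats::runif(1) < p_reverse) heading <- -heading

      f <- lit_fraction(pos_x, arena, ep)
      mult <- 1 + f * (m - 1)
      speed <- params$base_speed * mult *
        stats::rlnorm(1, meanlog = mulog, sdlog = sdlog)
      pos_x <- pos_x + heading * speed * dt
      if (pos_x < 0) { pos_x <- -pos_x; heading <- 1; committed <- FALSE }
      if (pos_x > arena$length) {
        pos_x <- 2 * arena$length - pos_x; heading <- -1; committed <- FALSE
      }
      pos_y <- pos_y + stats::rnorm(1, 0, params$lateral_jitter_sd)
      if (pos_y < 0) pos_y <- -pos_y
      if (pos_y > arena$width) pos_y <- 2 * arena$width - pos_y
    }
    x[i] <- pos_x; y[i] <- pos_y
  }
  fly_track(fly_id, t, x, y, arena = arena)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# deterministic per-fly sub-seed: adding a fly never perturbs existing flies
fly_seed <- function(root_seed, group_index, fly_index) {
  as.integer((as.double(root_seed) + 1000003 * fly_index +
                7919 * 1000003 * group_index) %% 2147483647)
}

#' Simulate a three-group experiment
#'
#' Simulates the standard shared-control design: one test group and two
#' control groups (driver and responder controls), both controls drawn from
#' the same control parameters with distinct per-fly sub-seeds. Deterministic
#' given `seed`; per-fly seeds are derived by a (group, fly) counter so
#' adding a fly never perturbs the others.
#'
#' @param test_params,control_params [walker_params()] for test and controls.
#' @param n_per_group Flies per group.
#' @param arena An [arena_spec()].
#' @param schedule An [illumination_schedule()].
#' @param seed Integer root seed.
#' @param metadata Metadata list copied into each record.
#' @return Named list of three [experiment_record()]s: `test`,
#'   `driver_control`, `responder_control`.
#' @export
simulate_experiment <- function(test_params, control_params, n_per_group,
                                arena, schedule, seed, metadata = list()) {
  stopifnot(n_per_group >= 1)
  if (!inherits(schedule, "illumination_schedule"))
    schedule <- illumination_schedule(schedule)
  groups <- list(test = test_params,
                 driver_control = control_params,
                 responder_control = control_params)
  labels <- c("test", "driver-control", "responder-control")
  out <- vector("list", 3L)
  for (g in 1:3) {
    tracks <- lapply(seq_len(n_per_group), function(i) {
      simulate_fly(groups[[g]], arena, schedule,
                   seed = fly_seed(seed, g, i),
                   fly_id = sprintf("%s_%03d", names(groups)[g], i))
    })
    out[[g]] <- experiment_record(tracks, arena, schedule, labels[g], metadata)
  }
  names(out) <- names(groups)
  out
}

#' Ground truth implied by walker parameters
#'
#' Analytic expectations for the downstream metrics: the expected LSR is
#' `log2` of the light speed multiplier exactly; the expected PEDL and PELD
#' pass through the crossing probabilities; the expected PI sign follows the
#' parameter asymmetries (slower in light or a crossing bias toward light
#' both push PI positive). When the two mechanisms pull in opposite
#' directions, the sign is resolved by a small Monte-Carlo run.
#'
#' @param params A [walker_params()].
#' @param arena,schedule Used only for the Monte-Carlo fallback.
#' @param mc_flies,mc_seed Monte-Carlo fallback size and seed.
#' @return A list of class `ground_truth` with `expected_lsr`,
#'   `expected_pedl`, `expected_peld`, `expected_pi_sign` (-1, 0 or +1) and
#'   `provenance` (`"analytic"` or `"monte_carlo"`).
#' @export
ground_truth <- function(params, arena = arena_spec(),
                         schedule = NULL, mc_flies = 60, mc_seed = 1L) {
  stopifnot(inherits(params, "walker_params"))
  speed_pull <- sign(log2(1 / params$light_speed_multiplier))  # slower in light -> +
  choice_pull <- sign(params$p_cross_dark_to_light - params$p_cross_light_to_dark)
  if (speed_pull == 0 && choice_pull == 0) {
    sign_pi <- 0; prov <- "analytic"
  } else if (speed_pull == 0 || choice_pull == 0 || speed_pull == choice_pull) {
    sign_pi <- sign(speed_pull + choice_pull); prov <- "analytic"
  } else {
    # mechanisms oppose each other: resolve empirically
    if (is.null(schedule))
      schedule <- illumination_schedule(
        illumination_epoch(0, 60, 22, "red"))
    pis <- vapply(seq_len(mc_flies), function(i) {
      tr <- simulate_fly(params, arena, schedule, seed = fly_seed(mc_seed, 9L, i))
      m <- compute_pi(tr, arena, schedule[[1]])
      m$pi
    }, numeric(1))
    sign_pi <- sign(mean(pis, na.rm = TRUE)); prov <- "monte_carlo"
  }
  structure(list(expected_lsr = log2(params$light_speed_multiplier),
                 expected_pedl = params$p_cross_dark_to_light,
                 expected_peld = params$p_cross_light_to_dark,
                 expected_pi_sign = sign_pi,
                 provenance = prov),
            class = "ground_truth")
}
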