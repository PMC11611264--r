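test_that("PI integrates occupancy time over the analysis window", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)

  # whole window in a lit quadrant (but fly shuttles within it): PI = +1
  tr <- waypoint_track(c(0, 30, 60), c(2, 12, 2))
  expect_equal(compute_pi(tr, arena, ep)$pi, 1)

  # constructed 18 s lit / 12 s unlit window: PI = +0.2
  # last 30 s = [30, 60): lit quadrant 2 for 18 s then dark quadrant 1 for 12 s
  tr2 <- waypoint_track(c(0, 29.999, 30, 47.999, 48, 60),
                        c(30, 30, 30, 30, 20, 20))
  got <- compute_pi(tr2, arena, ep)
  expect_equal(got$pi, (18 - 12) / 30, tolerance = 1e-6)
  expect_equal(got$pi, oracle_pi(tr2, arena, ep), tolerance = 1e-12)
})

test_that("single-zone movers get the extreme PI assignment", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)
  # confined to dark quadrant 1, shuttling 6 mm: PI = -1, extreme_assigned
  tr <- waypoint_track(c(0, 30, 60), c(17, 23, 17))
  got <- compute_pi(tr, arena, ep)
  expect_equal(got$pi, -1)
  expect_equal(got$pi_source, "extreme_assigned")

  # confined to lit quadrant 0: +1
  got2 <- compute_pi(waypoint_track(c(0, 30, 60), c(2, 8, 2)), arena, ep)
  expect_equal(got2$pi, 1)
  expect_equal(got2$pi_source, "extreme_assigned")

  # confined but essentially stationary (below movement threshold): measured
  n <- 1500
  still <- fly_track("s", (seq_len(n) - 1) / 25, rep(17, n) + 1e-4 * sin(seq_len(n)),
                     rep(2, n))
  got3 <- compute_pi(still, arena, ep)
  expect_equal(got3$pi, -1)
  expect_equal(got3$pi_source, "measured")
})

test_that("a fly with no valid frames in the window is censored, not an error", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)
  n <- 1500
  tr <- fly_track("v", (seq_len(n) - 1) / 25, rep(10, n), rep(2, n),
                  valid = c(rep(TRUE, 500), rep(FALSE, 1000)))
  got <- compute_pi(tr, arena, ep)
  expect_true(got$censor_pi)
  expect_true(is.na(got$pi))
})

test_that("LSR is exact on constant-speed-per-zone constructed tracks", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)
  # quadrant 2 lit ([27.5, 41.25)), quadrant 1 dark; per-step speed set by the
  # zone of the step's start frame (the attribution convention), 2 mm/s lit
  # and 1 mm/s unlit, bouncing across border 27.5
  n <- 1500; dt <- 0.04
  x <- numeric(n); x[1] <- 22; dir <- 1
  for (i in 2:n) {
    v <- if (x[i - 1] >= 27.5) 2 else 1
    x[i] <- x[i - 1] + dir * v * dt
    if (x[i] > 33) dir <- -1
    if (x[i] < 22) dir <- 1
  }
  tr <- fly_track("gen", (seq_len(n) - 1) * dt, x, rep(2, n))
  got <- compute_lsr(tr, arena, ep)
  expect_false(got$censor_lsr)
  expect_equal(got$lsr, 1.0, tolerance = 1e-9)
  expect_equal(got$mean_speed_light, 2, tolerance = 1e-9)
  expect_equal(got$mean_speed_dark, 1, tolerance = 1e-9)
  expect_equal(got$lsr, oracle_lsr(tr, arena, ep), tolerance = 1e-12)
})

test_that("LSR censoring distinguishes single-zone from stationary flies", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)
  # moves but never leaves dark quadrant 1: single_zone, PI still defined
  tr <- waypoint_track(c(0, 30, 60), c(17, 23, 17))
  got <- compute_lsr(tr, arena, ep)
  expect_true(got$censor_lsr)
  expect_equal(got$censor_reason, "single_zone")
  expect_false(compute_pi(tr, arena, ep)$censor_pi)

  # stationary all epoch: no_movement
  n <- 1500
  still <- fly_track("s", (seq_len(n) - 1) / 25, rep(17, n), rep(2, n))
  got2 <- compute_lsr(still, arena, ep)
  expect_true(got2$censor_lsr)
  expect_equal(got2$censor_reason, "no_movement")
})

test_that("PI and LSR are invariant to a uniform speed rescaling", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)
  tr <- random_fixture(301)
  # rescale time by 2: same path, all speeds halved, same occupancy fractions
  # (equivalently rescale the x excursion; here scale dt via epoch duration)
  fast <- tr
  slow <- fly_track(tr$fly_id, tr$t * 2, tr$x, tr$y)
  ep2 <- lit_epoch(0, 120)
  expect_equal(compute_pi(slow, arena, ep2, window = 60)$pi,
               compute_pi(fast, arena, ep, window = 30)$pi, tolerance = 1e-9)
  expect_equal(compute_lsr(slow, arena, ep2, window = 60)$lsr,
               compute_lsr(fast, arena, ep, window = 30)$lsr,
               tolerance = 1e-9)
})

test_that("conditioning full PI averages the two half scores", {
  # direct arithmetic through occupancy: 70/30 split toward CS+ in both phases
  mk_phase <- function(frac_plus, side, n = 750) {
    t <- (seq_len(n) - 1) / 25
    k <- round(n * frac_plus)
    plus_x <- if (side == "left") 10 else 40
    minus_x <- if (side == "left") 40 else 10
    data.frame(t = t, x = c(rep(plus_x, k), rep(minus_x, n - k)))
  }
  res <- conditioning_pi(mk_phase(0.7, "left"), mk_phase(0.7, "right"),
                         midline = 25, cs_plus_side_a = "left",
                         cs_plus_side_b = "right")
  expect_equal(res$full_pi, 0.4, tolerance = 0.01)

  # opposite halves cancel: side bias removed by the swap
  res2 <- conditioning_pi(mk_phase(0.8, "left"), mk_phase(0.2, "right"),
                          midline = 25, cs_plus_side_a = "left",
                          cs_plus_side_b = "right")
  expect_equal(res2$full_pi, 0, tolerance = 0.01)
  expect_error(conditioning_pi(mk_phase(0.5, "left"), NULL, 25), "phases")
  expect_error(conditioning_pi(mk_phase(0.5, "left"), mk_phase(0.5, "left"),
                               25, "left", "left"), "swap")
})

test_that("group summaries censor per metric, never per fly", {
  arena <- default_arena()
  sch <- dark_then_lit()
  # group of 3: one normal walker, one dark-confined mover, one stationary
  tr1 <- random_fixture(401, duration = 90)
  tr2 <- waypoint_track(c(0, 45, 90), c(17, 23, 17), fly_id = "confined")
  n <- 2250
  tr3 <- fly_track("still", (seq_len(n) - 1) / 25, rep(17, n), rep(2, n))
  rec <- experiment_record(list(tr1, tr2, tr3), arena, sch, "test")
  tab <- summarize_group(rec, 2, smooth = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_false(any(tab$censor_pi))
  expect_equal(tab$censor_reason[tab$fly_id == "confined"], "single_zone")
  expect_equal(tab$censor_reason[tab$fly_id == "still"], "no_movement")
  # censoring asymmetry: #PI >= #LSR and #PI >= #choice flies
  expect_gte(sum(!tab$censor_pi), sum(!tab$censor_lsr))
  expect_gte(sum(!tab$censor_pi), sum(!tab$censor_choice))
  gs <- group_summary(tab)
  expect_equal(gs$n[gs$metric == "pi"], 3L)
  expect_equal(gs$n[gs$metric == "lsr"], 1L)
})
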