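test_that("a monotone crossing yields one crossing transit with correct sides", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)
  # walk from dark quadrant 1 through border 1 (x = 27.5) into lit quadrant 2
  tr <- waypoint_track(c(0, 60), c(20, 40))
  trn <- segment_transits(tr, arena, ep)
  expect_equal(nrow(trn), 1L)
  expect_equal(trn$border, 1L)
  expect_equal(trn$entry_side, "dark")
  expect_equal(trn$exit_side, "light")
  expect_equal(trn$outcome, "crossing")
  expect_true(trn$t_exit > trn$t_entry)
})

test_that("a retreat after partial zone entry is a reversal", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)
  # from dark: enter the border-1 zone to 2.5 mm depth (x = 27), retreat
  tr <- waypoint_track(c(0, 30, 60), c(20, 27, 20))
  trn <- segment_transits(tr, arena, ep)
  expect_equal(nrow(trn), 1L)
  expect_equal(trn$outcome, "reversal")
  expect_equal(trn$entry_side, "dark")
  expect_equal(trn$exit_side, "dark")
  expect_equal(trn$x_max, 27, tolerance = 1e-9)
})

test_that("a hand-enumerated zigzag produces exactly the enumerated transits", {
  arena <- default_arena()
  ep <- lit_epoch(0, 120)
  # 5 zone visits, sides enumerated by hand (zones: [24.5, 30.5] at border 1,
  # [38.25, 44.25] at border 2; quadrants 0, 2 lit):
  # 1) 20 -> 30.5+ : border-1 zone entered from dark q1, exits into lit q2
  # 2) 37 -> 40 -> 37.5 : border-2 zone entered from lit q2 at 38.25,
  #    retreats without reaching 44.25 -> reversal, exit light
  # 3) 37.5 -> 45 : enters at 38.25 from light, exits at 44.25 to dark q3
  # 4) 45 -> 35 : enters at 44.25 from dark, exits at 38.25 to light
  # 5) 35 -> 24 : border-1 zone entered from lit q2 at 30.5, exits at 24.5
  #    to dark q1
  wp_t <- c(0, 10, 20, 25, 30, 40, 50, 60)
  wp_x <- c(20, 30, 37, 40, 37.5, 45, 35, 24)
  tr <- waypoint_track(wp_t, wp_x)
  trn <- segment_transits(tr, arena, ep)
  expect_equal(nrow(trn), 5L)
  expect_equal(trn$border, c(1L, 2L, 2L, 2L, 1L))
  expect_equal(trn$entry_side, c("dark", "light", "light", "dark", "light"))
  expect_equal(trn$exit_side, c("light", "light", "dark", "light", "dark"))
  expect_equal(trn$outcome,
               c("crossing", "reversal", "crossing", "crossing", "crossing"))
  # oracle agreement on the same fixture
  orc <- oracle_transits(tr, arena, ep)
  expect_equal(trn$entry_side, orc$entry_side)
  expect_equal(trn$exit_side, orc$exit_side)
})

test_that("partial transits at epoch boundaries are discarded", {
  arena <- default_arena()
  ep <- lit_epoch(10, 50)
  # in a zone at epoch start (x = 27 at t = 10), exits, then re-enters and is
  # still inside at epoch end
  tr <- waypoint_track(c(0, 20, 40, 60), c(27, 20, 28, 27.2))
  trn <- segment_transits(tr, arena, ep)
  expect_equal(nrow(trn), 0L)
})

test_that("choice metrics follow the exit-count arithmetic and censoring", {
  t3 <- tibble::tibble(entry_side = c("dark", "dark", "light", "light"),
                       exit_side = c("light", "light", "light", "dark"))
  t3$outcome <- ifelse(t3$entry_side == t3$exit_side, "reversal", "crossing")
  cm <- choice_metrics(t3)
  expect_equal(cm$chi, (3 - 1) / 4)
  expect_equal(cm$pedl, 1)
  expect_equal(cm$peld, 0.5)
  expect_equal(cm$n_transits, 4L)
  expect_equal(cm$n_entries_from_dark + cm$n_entries_from_light, cm$n_transits)

  # 2 entries from dark, 1 exiting to light
  t4 <- tibble::tibble(entry_side = c("dark", "dark"),
                       exit_side = c("light", "dark"))
  expect_equal(choice_metrics(t4)$pedl, 0.5)

  # no transits: censored entirely
  cm0 <- choice_metrics(t4[0, ])
  expect_true(cm0$censor_choice)
  expect_true(is.na(cm0$chi) && is.na(cm0$pedl) && is.na(cm0$peld))

  # one-sided entries: the other proportion is censored
  t5 <- tibble::tibble(entry_side = "dark", exit_side = "dark")
  expect_true(is.na(choice_metrics(t5)$peld))
  expect_false(is.na(choice_metrics(t5)$pedl))
})

test_that("ChI identity against per-transit counting holds on random fixtures", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)
  for (seed in 101:110) {
    tr <- random_fixture(seed)
    trn <- segment_transits(tr, arena, ep)
    cm <- choice_metrics(trn)
    orc <- oracle_choice(oracle_transits(tr, arena, ep))
    expect_equal(cm$chi, orc$chi, tolerance = 1e-12)
    expect_equal(cm$pedl, orc$pedl, tolerance = 1e-12)
    expect_equal(cm$peld, orc$peld, tolerance = 1e-12)
    # count conservation
    expect_equal(sum(trn$outcome == "crossing") + sum(trn$outcome == "reversal"),
                 cm$n_transits)
    # ChI reconstruction from PEDL/PELD and entry counts
    nd <- cm$n_entries_from_dark; nl <- cm$n_entries_from_light
    pedl <- ifelse(is.na(cm$pedl), 0, cm$pedl)
    peld <- ifelse(is.na(cm$peld), 0, cm$peld)
    chi_id <- (pedl * nd + (1 - peld) * nl -
                 ((1 - pedl) * nd + peld * nl)) / cm$n_transits
    expect_equal(cm$chi, chi_id, tolerance = 1e-12)
  }
})

test_that("aligned trajectories re-zero time and sign the entry side negative", {
  arena <- default_arena()
  ep <- lit_epoch(0, 60)
  # straight crossing at 2 mm/s through border 1 from the dark (left) side
  tr <- waypoint_track(c(0, 6), c(23, 35))   # 2 mm/s
  trn <- segment_transits(tr, arena, ep)
  al <- align_boundary_trajectories(trn, tr, arena, direction = "dark_to_any")
  expect_gt(nrow(al), 0)
  expect_equal(al$rel_x[al$rel_t == 0], -3, tolerance = 0.05)
  fit <- coef(lm(rel_x ~ rel_t, data = al))
  expect_equal(unname(fit[2]), 2, tolerance = 1e-6)

  # exact mirror about the midline between borders 0 and 1: at border 0 the
  # dark quadrant lies to the right, so the leftward crossing re-signs onto
  # the identical trace
  tr2 <- fly_track("m", tr$t, 41.25 - tr$x, tr$y)
  trn2 <- segment_transits(tr2, arena, ep)
  expect_equal(trn2$border, 0L)
  expect_equal(trn2$entry_side, "dark")
  al2 <- align_boundary_trajectories(trn2, tr2, arena,
                                     direction = "dark_to_any")
  expect_equal(al2$rel_x, al$rel_x, tolerance = 1e-9)
  expect_equal(al2$rel_t, al$rel_t, tolerance = 1e-9)

  # empty selection gives empty output
  expect_equal(nrow(align_boundary_trajectories(trn[0, ], tr, arena)), 0L)
})

test_that("slow-in-light cohorts slow down after the border in aligned traces", {
  arena <- default_arena()
  sch <- dark_then_lit()
  ep <- sch[[2]]
  p <- walker_params(light_speed_multiplier = 0.4)
  rows <- list()
  for (i in 1:25) {
    tr <- simulate_fly(p, arena, sch, seed = 600 + i)
    trn <- segment_transits(tr, arena, ep)
    al <- align_boundary_trajectories(trn, tr, arena, direction = "dark_to_any",
                                      t_after = 4)
    if (nrow(al)) {
      al$fly <- i
      rows[[length(rows) + 1L]] <- al
    }
  }
  al <- do.call(rbind, rows)
  # mean displacement rate while still dark side (rel_x < 0) vs after (>= 0)
  spd <- function(d) {
    s <- split(d, interaction(d$fly, d$transit, drop = TRUE))
    mean(unlist(lapply(s, function(g) abs(diff(g$rel_x)) / diff(g$rel_t))),
         na.rm = TRUE)
  }
  before <- spd(al[al$rel_x < 0, ])
  after <- spd(al[al$rel_x >= 0, ])
  expect_lt(after, before)
})
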