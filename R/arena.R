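#' Stadium arena geometry
#'
#' Describes the banded light/dark stadium ("discorectangle") arena in which
#' flies walk. The long axis is `x`, with the origin at the arena's left end;
#' all positions are in millimetres. Interior borders split the arena into
#' quadrants (0-based indices); quadrant membership uses half-open intervals
#' `[left border, right border)` so a fly sitting exactly on a border is
#' deterministically assigned to the right-hand quadrant. Choice zones extend
#' `choice_halfwidth` mm on either side of every border.
#'
#' @param length Arena length along the long axis, mm.
#' @param width Arena width, mm.
#' @param border_positions Positions of the interior light/dark borders along
#'   the long axis, mm, strictly increasing and strictly inside the arena.
#'   Defaults to quarter points (three borders, four quadrants).
#' @param choice_halfwidth Half-width of the choice zone around each border, mm.
#' @param gradient_width Width of the physical light gradient straddling each
#'   border, mm. Occupancy scoring stays binary at the nominal border; the
#'   gradient only softens the simulator's light-dependent speed rule.
#'
#' @return An object of class `arena_spec`.
#' @export
#' @examples
#' arena_spec()
#' arena_spec(length = 50, width = 5, border_positions = 25, choice_halfwidth = 2)
arena_spec <- function(length = 55, width = 4,
                       border_positions = length * c(1, 2, 3) / 4,
                       choice_halfwidth = 3, gradient_width = 0.67) {
  stopifnot(is.numeric(length), length > 0, is.numeric(width), width > 0,
            is.numeric(border_positions), length(border_positions) >= 1,
            is.numeric(choice_halfwidth), choice_halfwidth > 0,
            is.numeric(gradient_width), gradient_width >= 0)
  border_positions <- as.numeric(border_positions)
  if (is.unsorted(border_positions, strictly = TRUE))
    stop("border_positions must be strictly increasing", call. = FALSE)
  if (border_positions[1] <= 0 || border_positions[length(border_positions)] >= length)
    stop("border_positions must lie strictly inside (0, length)", call. = FALSE)
  if (border_positions[1] - choice_halfwidth < 0 ||
      border_positions[length(border_positions)] + choice_halfwidth > length)
    stop("choice zones must lie inside the arena", call. = FALSE)
  structure(
    list(length = as.numeric(length), width = as.numeric(width),
         border_positions = border_positions,
         n_quadrants = length(border_positions) + 1L,
         choice_halfwidth = as.numeric(choice_halfwidth),
         gradient_width = as.numeric(gradient_width)),
    class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g mm, %d quadrants; borders at %s mm; choice zones +/- %g mm\n",
              x$length, x$width, x$n_quadrants,
              paste(signif(x$border_positions, 4), collapse = ", "),
              x$choice_halfwidth))
  invisible(x)
}

#' Illumination epoch
#'
#' One entry of an experiment's illumination schedule: a time interval during
#' which a fixed subset of quadrants is lit at a fixed intensity, producing
#' the banded light-dark-light-dark pattern (default lit quadrants 0 and 2).
#' A dark epoch has an empty lit set and zero intensity.
#'
#' @param start,end Epoch boundaries, seconds. `end > start`.
#' @param intensity Illumination intensity, uW/mm^2 (0 for dark epochs).
#' @param color One of `"red"`, `"green"`, `"dark"`.
#' @param lit_quadrants Integer vector of 0-based lit quadrant indices; must
#'   be empty exactly when `color == "dark"`.
#'
#' @return An object of class `illumination_epoch`.
#' @export
#' @examples
#' illumination_epoch(0, 60, intensity = 0, color = "dark")
#' illumination_epoch(60, 120, intensity = 22, color = "red")
illumination_epoch <- function(start, end, intensity = 0,
                               color = c("dark", "red", "green"),
                               lit_quadrants = if (match.arg(color) == "dark")
                                 integer(0) else c(0L, 2L)) {
  color <- match.arg(color)
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(intensity))
  if (end <= start) stop("epoch end must exceed start", call. = FALSE)
  if (intensity < 0) stop("intensity must be >= 0", call. = FALSE)
  lit_quadrants <- sort(unique(as.integer(lit_quadrants)))
  if ((color == "dark") != (length(lit_quadrants) == 0L))
    stop("dark epochs (and only dark epochs) have an empty lit set", call. = FALSE)
  structure(
    list(start = as.numeric(start), end = as.numeric(end),
         intensity = as.numeric(intensity), color = color,
         lit_quadrants = lit_quadrants),
    class = "illumination_epoch")
}

#' @export
print.illumination_epoch <- function(x, ...) {
  cat(sprintf("<illumination_epoch> [%g, %g) s, %s %g uW/mm^2, lit quadrants {%s}\n",
              x$start, x$end, x$color, x$intensity,
              paste(x$lit_quadrants, collapse = ",")))
  invisible(x)
}

#' Build and validate an illumination schedule
#'
#' Checks that epochs are time-ordered and non-overlapping and returns them as
#' a list usable as the `schedule` of an [experiment_record()].
#'
#' @param ... `illumination_epoch` objects (or a single list of them).
#' @return A list of epochs with class `illumination_schedule`.
#' @export
#' @examples
#' illumination_schedule(
#'   illumination_epoch(0, 30, color = "dark"),
#'   illumination_epoch(30, 90, intensity = 22, color = "red"))
illumination_schedule <- function(...) {
  epochs <- list(...)
  if (length(epochs) == 1L && !inherits(epochs[[1]], "illumination_epoch"))
    epochs <- epochs[[1]]
  if (length(epochs) == 0L) stop("schedule must contain at least one epoch", call. = FALSE)
  ok <- vapply(epochs, inherits, logical(1), "illumination_epoch")
  if (!all(ok)) stop("all schedule entries must be illumination_epoch objects", call. = FALSE)
  starts <- vapply(epochs, `[[`, numeric(1), "start")
  ends <- vapply(epochs, `[[`, numeric(1), "end")
  o <- order(starts)
  epochs <- epochs[o]; starts <- starts[o]; ends <- ends[o]
  if (length(epochs) > 1L && any(starts[-1] < ends[-length(ends)] - 1e-9))
    stop("epochs in a schedule must not overlap", call. = FALSE)
  structure(epochs, class = c("illumination_schedule", "list"))
}

#' Four-intensity assay schedule
#'
#' Convenience constructor for the standard assay design: a dark baseline
#' before each test epoch, with test epochs of 60 s at increasing intensity.
#' The default red intensities are 1.3, 5, 22 and 70 uW/mm^2 (green assays use
#' 1.6, 7, 28 and 92).
#'
#' @param intensities Numeric vector of test-epoch intensities, uW/mm^2.
#' @param color `"red"` or `"green"`.
#' @param epoch_s Test epoch duration, seconds.
#' @param baseline_s Dark baseline duration before each test epoch, seconds.
#' @param lit_quadrants Lit quadrant indices for every test epoch.
#' @return An `illumination_schedule`.
#' @export
standard_schedule <- function(intensities = c(1.3, 5, 22, 70),
                              color = c("red", "green"),
                              epoch_s = 60, baseline_s = 30,
                              lit_quadrants = c(0L, 2L)) {
  color <- match.arg(color)
  t0 <- 0
  epochs <- list()
  for (i in seq_along(intensities)) {
    epochs[[length(epochs) + 1L]] <-
      illumination_epoch(t0, t0 + baseline_s, 0, "dark")
    t0 <- t0 + baseline_s
    epochs[[length(epochs) + 1L]] <-
      illumination_epoch(t0, t0 + epoch_s, intensities[i], color,
                         lit_quadrants = lit_quadrants)
    t0 <- t0 + epoch_s
  }
  illumination_schedule(epochs)
}

# quadrant index (0-based) for x positions; half-open [border, next border)
quadrant_of <- function(x, arena) {
  findInterval(x, arena$border_positions)
}

# TRUE where the quadrant under x is lit during the epoch
is_lit <- function(x, arena, epoch) {
  if (length(epoch$lit_quadrants) == 0L) return(rep(FALSE, length(x)))
  quadrant_of(x, arena) %in% epoch$lit_quadrants
}

# continuous lit fraction in [0,1]: binary away from borders, linear ramp
# across the gradient band straddling each border (simulator speed rule only)
lit_fraction <- function(x, arena, epoch) {
  if (length(epoch$lit_quadrants) == 0L) return(rep(0, length(x)))
  q <- quadrant_of(x, arena)
  f <- as.numeric(q %in% epoch$lit_quadrants)
  gw <- arena$gradient_width
  if (gw <= 0) return(f)
  for (b in arena$border_positions) {
    in_band <- abs(x - b) < gw / 2
    if (!any(in_band)) next
    lq <- quadrant_of(b - gw, arena)   # quadrant left of the border
    rq <- lq + 1L
    fl <- as.numeric(lq %in% epoch$lit_quadrants)
    fr <- as.numeric(rq %in% epoch$lit_quadrants)
    w <- (x[in_band] - (b - gw / 2)) / gw   # 0 at left edge, 1 at right edge
    f[in_band] <- fl + (fr - fl) * w
  }
  f
}
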