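#' Read an experiment configuration file
#'
#' Reads a YAML experiment configuration describing the arena geometry, the
#' illumination schedule and group metadata, and returns the corresponding
#' [arena_spec()] and [illumination_schedule()] ready for [load_tracks()].
#'
#' The file layout:
#' ```yaml
#' arena:
#'   length_mm: 55
#'   width_mm: 4
#'   borders_mm: [13.75, 27.5, 41.25]
#'   choice_halfwidth_mm: 3
#' schedule:
#'   - {start_s: 0, end_s: 30, intensity_uW_mm2: 0, color: dark}
#'   - {start_s: 30, end_s: 90, intensity_uW_mm2: 22, color: red,
#'      lit_quadrants: [0, 2]}
#' group_label: test
#' metadata:
#'   driver: R58E02
#'   effector: CsChrimson
#' ```
#'
#' @param path Path to the configuration file.
#' @return A list with `arena`, `schedule`, `group_label`, `metadata`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$arena) || is.null(cfg$schedule))
    stop(sprintf("config '%s' needs 'arena' and 'schedule' blocks", path),
         call. = FALSE)
  a <- cfg$arena
  arena <- arena_spec(
    length = a$length_mm %||% 55,
    width = a$width_mm %||% 4,
    border_positions = unlist(a$borders_mm) %||% ((a$length_mm %||% 55) * c(1, 2, 3) / 4),
    choice_halfwidth = a$choice_halfwidth_mm %||% 3,
    gradient_width = a$gradient_width_mm %||% 0.67)
  epochs <- lapply(cfg$schedule, function(e) {
    color <- e$color %||% if ((e$intensity_uW_mm2 %||% 0) > 0) "red" else "dark"
    illumination_epoch(
      start = e$start_s, end = e$end_s,
      intensity = e$intensity_uW_mm2 %||% 0, color = color,
      lit_quadrants = if (color == "dark") integer(0)
                      else unlist(e$lit_quadrants) %||% c(0L, 2L))
  })
  list(arena = arena, schedule = illumination_schedule(epochs),
       group_label = cfg$group_label %||% "test",
       metadata = cfg$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
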