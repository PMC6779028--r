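#' Game layout: twelve clock-direction targets around a central circle
#'
#' Describes the geometry of the reaching game in screen-plane centimetres.
#' Twelve targets sit on a circle of radius `target_distance_cm` around the
#' centre, one per clock numeral: direction `0` is 12 o'clock (straight up)
#' and successive indices advance clockwise in 30 degree steps, so direction
#' `3` is 3 o'clock (straight right). Between reaches the thumb returns to a
#' central circle of radius `center_radius_cm`; a reach is scored from the
#' moment the thumb leaves that circle.
#'
#' The default dimensions are sized for a hand-held tablet. All downstream
#' kinematics are reported in cm/s and s, so they scale with whatever
#' geometry is configured here.
#'
#' @param target_distance_cm Distance from the centre to each target centre.
#' @param target_radius_cm Radius of a target: a touch within this distance
#'   of the target centre collects it.
#' @param center_radius_cm Radius of the central return circle.
#' @param appearance_duration_s How long a target stays on screen before it
#'   counts as missed.
#' @return An object of class `game_layout`.
#' @examples
#' layout <- game_layout()
#' direction_angle(0:11)        # degrees counterclockwise from +x
#' target_position(layout, 3)   # 3 o'clock target sits on the +x axis
#' @export
game_layout <- function(target_distance_cm = 3.5,
                        target_radius_cm = 0.6,
                        center_radius_cm = 0.8,
                        appearance_duration_s = 3) {
  stopifnot(
    is.numeric(target_distance_cm), target_distance_cm > 0,
    is.numeric(target_radius_cm), target_radius_cm > 0,
    is.numeric(center_radius_cm), center_radius_cm > 0,
    is.numeric(appearance_duration_s), appearance_duration_s > 0
  )
  if (target_distance_cm <= center_radius_cm) {
    abort("`target_distance_cm` must exceed `center_radius_cm`.")
  }
  if (target_distance_cm - target_radius_cm - center_radius_cm <= 0) {
    abort("targets must lie fully outside the central circle.")
  }
  structure(
    list(
      center = c(0, 0),
      target_distance_cm = target_distance_cm,
      target_radius_cm = target_radius_cm,
      center_radius_cm = center_radius_cm,
      appearance_duration_s = appearance_duration_s,
      n_directions = 12L
    ),
    class = "game_layout"
  )
}

#' @export
print.game_layout <- function(x, ...) {
  cat("<game_layout> 12 clock directions\n")
  cat(sprintf(
    "  target distance %.2f cm, target radius %.2f cm, center radius %.2f cm\n",
    x$target_distance_cm, x$target_radius_cm, x$center_radius_cm
  ))
  invisible(x)
}

#' @rdname game_layout
#' @param direction Integer direction index (0 = 12 o'clock, clockwise).
#' @export
direction_angle <- function(direction) {
  stopifnot(all(direction %in% 0:11))
  90 - 30 * direction
}

#' @rdname game_layout
#' @param layout A `game_layout`.
#' @export
target_position <- function(layout, direction) {
  stopifnot(inherits(layout, "game_layout"))
  theta <- direction_angle(direction) * pi / 180
  cbind(
    x = layout$target_distance_cm * cos(theta),
    y = layout$target_distance_cm * sin(theta)
  )
}

# straight-line distance a scored reach must cover: from the central circle's
# edge to the nearest edge of the target disc
reach_chord_cm <- function(layout) {
  layout$target_distance_cm - layout$target_radius_cm - layout$center_radius_cm
}

#' Randomised target schedule
#'
#' Draws the order in which the twelve directional targets appear: a uniform
#' random permutation of directions 0-11, reproducible for a given seed.
#' Return-to-centre targets are interleaved between consecutive directions by
#' the session simulator; they are implied and not part of the schedule.
#'
#' @param layout A [game_layout()].
#' @param seed Integer seed controlling the permutation.
#' @return Integer vector: a permutation of `0:11`.
#' @examples
#' make_target_schedule(game_layout(), seed = 7)
#' @export
make_target_schedule <- function(layout, seed) {
  stopifnot(inherits(layout, "game_layout"), is.numeric(seed))
  withr_seed(seed, sample.int(layout$n_directions) - 1L)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
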