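# Hand-built sessions with scripted trajectories, used wherever expected
# kinematics must be computable by hand.

# straight constant-speed reach samples along direction `d`, from the centre
# circle's edge to the target disc's edge, speed v cm/s, sampled every `dt`
straight_reach_samples <- function(layout, d, v, t0, dt = 0.05) {
  th <- (90 - 30 * d) * pi / 180
  ray <- c(cos(th), sin(th))
  r0 <- layout$center_radius_cm
  r1 <- layout$target_distance_cm - layout$target_radius_cm
  dur <- (r1 - r0) / v
  tt <- unique(c(seq(0, dur, by = dt), dur))
  r <- r0 + v * tt
  data.frame(t = t0 + tt, x = r * ray[1], y = r * ray[2], touching = TRUE)
}

# a full 12-direction session of constant-speed straight reaches at speed v;
# one appearance per direction, all collected, dwell at the start point
# before each reach so the boundary crossing is well defined
constant_speed_session <- function(v = 6, layout = game_layout(), dt = 0.05) {
  samples <- list()
  targets <- list()
  for (d in 0:11) {
    t_appear <- 10 * d
    th <- (90 - 30 * d) * pi / 180
    p0 <- c(cos(th), sin(th)) * layout$center_radius_cm
    dwell <- data.frame(
      t = t_appear + c(0, 0.25, 0.5), x = p0[1], y = p0[2], touching = TRUE
    )
    reach <- straight_reach_samples(layout, d, v, t0 = t_appear + 0.5, dt = dt)
    t_res <- reach$t[nrow(reach)]
    samples[[d + 1]] <- rbind(dwell[-3, ], reach)
    targets[[d + 1]] <- data.frame(
      direction = d, appearance_index = 1L,
      t_appear = t_appear, t_resolve = t_res, outcome = "collected"
    )
  }
  cts_session(
    hand_id = "fixture", label = "unknown", layout = layout,
    targets = do.call(rbind, targets), samples = do.call(rbind, samples)
  )
}

# rotate a session's coordinates by `steps` clock positions (clockwise) and
# relabel target directions to match; per-reach kinematics must be unchanged
rotate_session <- function(session, steps) {
  phi <- -steps * 30 * pi / 180   # clockwise rotation of the plane
  sm <- session$samples
  x <- sm$x * cos(phi) - sm$y * sin(phi)
  y <- sm$x * sin(phi) + sm$y * cos(phi)
  sm$x <- x; sm$y <- y
  tg <- session$targets
  tg$direction <- ifelse(is.na(tg$direction), NA_integer_,
                         (tg$direction + steps) %% 12L)
  cts_session(session$hand_id, session$label, session$layout, tg, sm,
              session$pixels_per_cm)
}

# multiply every timestamp in a session by `factor`
rescale_session_time <- function(session, factor) {
  sm <- session$samples
  sm$t <- sm$t * factor
  tg <- session$targets
  tg$t_appear <- tg$t_appear * factor
  tg$t_resolve <- tg$t_resolve * factor
  cts_session(session$hand_id, session$label, session$layout, tg, sm,
              session$pixels_per_cm)
}

# direct-formula Welch oracle, independent of the implementation path
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# cohort medians of every extracted feature column
cohort_feature_medians <- function(table) {
  vapply(feature_cols(), function(cl) median(table[[cl]]), numeric(1))
}
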