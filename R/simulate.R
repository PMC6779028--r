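# ---- reach shape primitives ------------------------------------------------
#
# The speed profile of a simulated reach is the Beta(p+1, p+1) density in
# normalised time: v(tau) = (L/T) * dbeta(tau, p+1, p+1). It is bell-shaped
# and symmetric; p = 2 gives the classic minimum-jerk profile
# 30 tau^2 (1-tau)^2 with peak/mean ratio 1.875. Larger p sharpens the bell,
# so any peak/mean ratio > 1 can be realised:
#   ratio(p) = dbeta(1/2, p+1, p+1) = 4^{-p} / B(p+1, p+1).

bell_peak_ratio <- function(p) exp(-p * log(4) - lbeta(p + 1, p + 1))

# invert ratio(p); ratio must exceed 1
solve_bell_exponent <- function(ratio) {
  if (ratio <= bell_peak_ratio(1e-3)) return(1e-3)
  if (ratio >= bell_peak_ratio(80)) return(80)
  uniroot(function(p) bell_peak_ratio(p) - ratio,
          lower = 1e-3, upper = 80, tol = 1e-9)$root
}

# Arc length of the bowed path P(s) = P0 + s*(P1-P0) + A*sin(pi*s)*n_hat,
# s in [0,1], where n_hat is the unit normal to the chord. The tangent norm
# is sqrt(c^2 + (A*pi*cos(pi*s))^2) with chord length c.
.bow_grid <- seq(0, 1, length.out = 129)
bow_arc_length <- function(amp, chord) {
  g <- sqrt(chord^2 + (amp * pi * cos(pi * .bow_grid))^2)
  h <- diff(.bow_grid)
  sum((g[-length(g)] + g[-1]) / 2 * h)
}

# amplitude whose bowed path has arc length `len` (>= chord)
solve_bow_amplitude <- function(len, chord) {
  if (len <= chord * (1 + 1e-12)) return(0)
  upper <- (len - chord) / 2 + len / 2 + 1e-6   # arc(A) >= 2A for large A
  uniroot(function(a) bow_arc_length(a, chord) - len,
          lower = 0, upper = upper, tol = 1e-9)$root
}

# positions along the bowed path at arc-length fractions `frac` (0..1)
bow_positions <- function(frac, p0, p1, amp) {
  chord_vec <- p1 - p0
  chord <- sqrt(sum(chord_vec^2))
  n_hat <- c(-chord_vec[2], chord_vec[1]) / chord
  g <- sqrt(chord^2 + (amp * pi * cos(pi * .bow_grid))^2)
  h <- diff(.bow_grid)
  cum <- c(0, cumsum((g[-length(g)] + g[-1]) / 2 * h))
  s <- approx(cum / cum[length(cum)], .bow_grid, xout = pmin(pmax(frac, 0), 1),
              rule = 2)$y
  cbind(
    x = p0[1] + s * chord_vec[1] + amp * sin(pi * s) * n_hat[1],
    y = p0[2] + s * chord_vec[2] + amp * sin(pi * s) * n_hat[2]
  )
}

# ---- single-reach simulation ----------------------------------------------

#' Simulate the touch trace of one outbound reach
#'
#' Draws the reach's total time, average speed and peak/average speed ratio
#' from the profile's log-normal distributions for the given direction, then
#' constructs a touch trace that realises them: a bell-shaped (generalised
#' minimum-jerk) speed profile whose exponent is solved to match the drawn
#' peak/average ratio, travelling along a gently bowed path from the central
#' circle's edge to the target disc's edge whose bow amplitude is solved so
#' the path length equals average speed times total time. Sampled at
#' `sampling_rate` Hz with an exact final sample at target contact. Draws
#' that would require a path shorter than the straight reach (or a ratio at
#' or below 1) are redrawn, at most 100 times.
#'
#' Uses the current R random number stream; seed control belongs to
#' [simulate_session()] and [simulate_cohort()].
#'
#' @param direction Clock direction 0-11.
#' @param profile An [impairment_profile()].
#' @param layout A [game_layout()].
#' @param sampling_rate Touchscreen sampling rate in Hz.
#' @param t0 Movement-onset time (seconds since session start).
#' @return A data frame of touch samples (`t`, `x`, `y`, `touching`) from
#'   onset at the centre-circle edge to target contact, with the realised
#'   draws in attribute `"draws"`.
#' @export
simulate_reach <- function(direction, profile, layout = profile$layout,
                           sampling_rate = 60, t0 = 0) {
  stopifnot(inherits(profile, "impairment_profile"),
            direction %in% 0:11, sampling_rate > 0)
  row <- profile$directions[profile$directions$direction == direction, ]
  chord <- reach_chord_cm(layout)
  dt <- 1 / sampling_rate
  ratio_med <- row$max_speed_median / row$avg_speed_median
  sigma_ratio <- max(
    sqrt(max(row$max_speed_sigma^2 - row$avg_speed_sigma^2, 0)), 0.03
  )

  ok <- FALSE
  for (try in seq_len(100)) {
    total_time <- rlnorm(1, log(row$total_time_median), row$total_time_sigma)
    avg_speed <- rlnorm(1, log(row$avg_speed_median), row$avg_speed_sigma)
    ratio <- rlnorm(1, log(ratio_med), sigma_ratio)
    if (avg_speed * total_time >= chord * (1 + 1e-6) &&
        ratio > 1.02 && total_time >= 3 * dt) {
      ok <- TRUE
      break
    }
  }
  if (!ok) {
    abort(sprintf(
      "could not draw a feasible reach for direction %d after 100 attempts",
      direction
    ))
  }

  len <- avg_speed * total_time
  p_exp <- solve_bell_exponent(ratio)
  theta <- direction_angle(direction) * pi / 180
  ray <- c(cos(theta), sin(theta))
  p0 <- ray * layout$center_radius_cm
  p1 <- ray * (layout$target_distance_cm - layout$target_radius_cm)
  amp <- solve_bow_amplitude(len, sqrt(sum((p1 - p0)^2))) *
    sample(c(-1, 1), 1)

  tt <- seq(0, total_time, by = dt)
  if (tt[length(tt)] < total_time - 1e-12) tt <- c(tt, total_time)
  frac <- pbeta(tt / total_time, p_exp + 1, p_exp + 1)
  xy <- bow_positions(frac, p0, p1, abs(amp))
  if (amp < 0) {  # mirror the bow to the other side of the chord
    chord_vec <- p1 - p0
    n_hat <- c(-chord_vec[2], chord_vec[1]) / sqrt(sum(chord_vec^2))
    off <- 2 * ((xy[, 1] - p0[1]) * n_hat[1] + (xy[, 2] - p0[2]) * n_hat[2])
    xy[, 1] <- xy[, 1] - off * n_hat[1]
    xy[, 2] <- xy[, 2] - off * n_hat[2]
  }
  out <- data.frame(t = t0 + tt, x = xy[, 1], y = xy[, 2], touching = TRUE)
  attr(out, "draws") <- list(
    total_time = total_time, avg_speed = avg_speed,
    max_speed = avg_speed * ratio, bell_exponent = p_exp, bow_amp = amp
  )
  out
}

# straight point-to-point movement with a minimum-jerk bell, samples in
# (t0, t0 + duration]; used for centre returns and aborted reaches
.mj_transit <- function(p_from, p_to, t0, duration, dt) {
  tt <- seq(dt, duration, by = dt)
  if (!length(tt)) tt <- duration
  frac <- pbeta(tt / duration, 3, 3)
  list(
    t = t0 + tt,
    x = p_from[1] + frac * (p_to[1] - p_from[1]),
    y = p_from[2] + frac * (p_to[2] - p_from[2]),
    touching = rep(TRUE, length(tt))
  )
}

# stationary dwell samples in (t0, t1)
.dwell <- function(pos, t0, t1, dt) {
  tt <- seq(t0 + dt, t1 - 1e-9, by = dt)
  list(t = tt, x = rep(pos[1], length(tt)), y = rep(pos[2], length(tt)),
       touching = rep(TRUE, length(tt)))
}

#' Simulate a complete game session for one hand
#'
#' Plays out the full protocol: the twelve directional targets appear in a
#' seeded random order; after each is resolved a return-to-centre target
#' guides the thumb back; a missed target reappears once, immediately. Each
#' appearance is missed independently with the profile's miss probability
#' (a miss is simulated as an aborted half-way movement, with the target
#' timing out after the layout's appearance duration). Collected reaches are
#' generated by [simulate_reach()], so the session's extracted kinematics
#' follow the profile's distributions. The result always passes
#' [validate_session()].
#'
#' @param profile An [impairment_profile()].
#' @param layout A [game_layout()].
#' @param sampling_rate Touch sampling rate in Hz (default 60, typical for a
#'   capacitive touchscreen).
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param hand_id Identifier stored in the session.
#' @return A [cts_session()].
#' @examples
#' s <- simulate_session(control_profile(), seed = 42)
#' nrow(validate_session(s))  # 0
#' @export
simulate_session <- function(profile, layout = profile$layout,
                             sampling_rate = 60, seed = 1,
                             hand_id = "sim_hand") {
  stopifnot(inherits(profile, "impairment_profile"))
  withr_seed(seed, {
    dt <- 1 / sampling_rate
    miss_prob <- rep_len(profile$miss_prob, 12)
    schedule <- sample.int(12L) - 1L

    start_point <- function(d) {
      th <- direction_angle(d) * pi / 180
      c(cos(th), sin(th)) * layout$center_radius_cm
    }
    end_point <- function(d) {
      th <- direction_angle(d) * pi / 180
      c(cos(th), sin(th)) * (layout$target_distance_cm - layout$target_radius_cm)
    }

    samples <- vector("list", 96L)
    ns <- 0L
    push_s <- function(ph) {
      if (is.data.frame(ph)) ph <- as.list(ph)
      ns <<- ns + 1L; samples[[ns]] <<- ph
    }
    tg_dir <- integer(); tg_app <- integer()
    tg_t0 <- numeric(); tg_t1 <- numeric(); tg_out <- character()
    push_t <- function(direction, appearance_index, t_appear, t_resolve,
                       outcome) {
      tg_dir <<- c(tg_dir, direction); tg_app <<- c(tg_app, appearance_index)
      tg_t0 <<- c(tg_t0, t_appear); tg_t1 <<- c(tg_t1, t_resolve)
      tg_out <<- c(tg_out, outcome)
    }

    now <- 0
    pos <- start_point(schedule[1])
    push_s(list(t = 0, x = pos[1], y = pos[2], touching = TRUE))

    first_appear <- 0.5
    push_s(.dwell(pos, now, first_appear, dt))
    now <- first_appear

    for (i in seq_along(schedule)) {
      d <- schedule[i]
      for (appearance in 1:2) {
        t_appear <- now
        reaction <- rlnorm(1, log(profile$reaction_median_s),
                           profile$reaction_sigma)
        onset <- t_appear + reaction
        push_s(.dwell(pos, now, onset, dt))
        missed <- runif(1) < miss_prob[d + 1]
        if (!missed) {
          reach <- simulate_reach(d, profile, layout, sampling_rate, t0 = onset)
          push_s(reach)
          t_resolve <- reach$t[nrow(reach)]
          pos <- c(reach$x[nrow(reach)], reach$y[nrow(reach)])
          push_t(direction = d, appearance_index = appearance,
                 t_appear = t_appear, t_resolve = t_resolve,
                 outcome = "collected")
          now <- t_resolve
          break
        }
        # aborted attempt: half-way out and back, then the target times out
        t_resolve <- t_appear + layout$appearance_duration_s
        halfway <- (start_point(d) + end_point(d)) / 2
        dur_out <- min(0.4, (t_resolve - onset) / 3)
        push_s(.mj_transit(pos, halfway, onset, dur_out, dt))
        push_s(.mj_transit(halfway, start_point(d), onset + dur_out, dur_out, dt))
        pos <- start_point(d)
        push_s(.dwell(pos, onset + 2 * dur_out, t_resolve, dt))
        push_t(direction = d, appearance_index = appearance,
               t_appear = t_appear, t_resolve = t_resolve, outcome = "missed")
        now <- t_resolve
        if (appearance == 2L) break
      }
      # return-to-centre target guiding the thumb to the next start point
      if (i < length(schedule)) {
        nxt <- start_point(schedule[i + 1])
        dur_ret <- rlnorm(1, log(0.4), 0.15)
        push_s(.mj_transit(pos, nxt, now, dur_ret, dt))
        push_t(direction = NA_integer_, appearance_index = 1L,
               t_appear = now, t_resolve = now + dur_ret,
               outcome = "collected")
        pos <- nxt
        gap <- 0.2
        push_s(.dwell(pos, now + dur_ret, now + dur_ret + gap, dt))
        now <- now + dur_ret + gap
      }
    }

    ph <- samples[seq_len(ns)]
    sm <- tibble::tibble(
      t = unlist(lapply(ph, `[[`, "t"), use.names = FALSE),
      x = unlist(lapply(ph, `[[`, "x"), use.names = FALSE),
      y = unlist(lapply(ph, `[[`, "y"), use.names = FALSE),
      touching = unlist(lapply(ph, `[[`, "touching"), use.names = FALSE)
    )
    sm <- sm[!duplicated(sm$t), , drop = FALSE]
    stopifnot(all(diff(sm$t) > 0))
    cts_session(
      hand_id = hand_id, label = profile$label, layout = layout,
      targets = tibble::tibble(
        direction = tg_dir, appearance_index = tg_app,
        t_appear = tg_t0, t_resolve = tg_t1, outcome = tg_out
      ),
      samples = sm
    )
  })
}

#' Simulate a two-group cohort of sessions
#'
#' Generates `n_control + n_cts` independent sessions, one per hand, each
#' from its group's impairment profile. Per-hand seeds are derived from the
#' master seed, so the whole cohort (and everything extracted from it
#' downstream) is reproducible.
#'
#' @param n_control,n_cts Number of hands per group.
#' @param control,cts The group [impairment_profile()]s; defaults are the
#'   shipped calibrations.
#' @param layout A [game_layout()].
#' @param sampling_rate Touch sampling rate in Hz.
#' @param seed Master integer seed.
#' @return A list of [cts_session()] objects, controls first.
#' @examples
#' cohort <- simulate_cohort(n_control = 2, n_cts = 2, seed = 7)
#' features_to_table(lapply(cohort, extract_features))
#' @export
simulate_cohort <- function(n_control, n_cts,
                            control = control_profile(),
                            cts = cts_profile(),
                            layout = game_layout(),
                            sampling_rate = 60, seed = 1) {
  stopifnot(n_control >= 0, n_cts >= 0)
  n <- n_control + n_cts
  if (n == 0L) return(list())
  child_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- c(
    sprintf("ctrl_%03d", seq_len(n_control)),
    sprintf("cts_%03d", seq_len(n_cts))
  )
  profiles <- c(rep(list(control), n_control), rep(list(cts), n_cts))
  lapply(seq_len(n), function(i) {
    simulate_session(profiles[[i]], layout = layout,
                     sampling_rate = sampling_rate,
                     seed = child_seeds[i], hand_id = ids[i])
  })
}

#' Synthetic Gaussian feature clusters
#'
#' A direct feature-table generator (no touch simulation) for classifier
#' benchmarks: two spherical Gaussian clusters in the 36-dimensional feature
#' space whose means sit `separation` pooled standard deviations apart in
#' every feature dimension. At `separation = 4` the clusters are separable
#' with a wide margin (the within-class spread is negligible against the
#' mean shift), so a sound cross-validated classifier must score perfectly;
#' with `separation = 0` the features carry no class information.
#'
#' @param n_control,n_cts Hands per group.
#' @param separation Per-feature distance between class means in pooled-SD
#'   units.
#' @param seed Integer seed.
#' @return A feature table as from [features_to_table()].
#' @export
simulate_feature_clusters <- function(n_control, n_cts, separation = 4,
                                      seed = 1) {
  stopifnot(n_control >= 1, n_cts >= 1, separation >= 0)
  withr_seed(seed, {
    k <- length(feature_cols())
    delta <- rep(separation, k)
    m <- rbind(
      matrix(rnorm(n_control * k), n_control, k),
      matrix(rnorm(n_cts * k), n_cts, k) + rep(delta, each = n_cts)
    )
    colnames(m) <- feature_cols()
    dplyr::bind_cols(
      tibble::tibble(
        hand_id = c(sprintf("ctrl_%03d", seq_len(n_control)),
                    sprintf("cts_%03d", seq_len(n_cts))),
        label = rep(c("non-CTS", "CTS"), c(n_control, n_cts))
      ),
      tibble::as_tibble(m)
    )
  })
}
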