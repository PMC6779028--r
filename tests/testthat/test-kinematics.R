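test_that("reach kinematics match hand-computed finite differences", {
  # constant-speed straight reach: 3.0 cm in 0.5 s -> max = avg = 6 cm/s
  seg <- list(
    direction = 3L, t_start = 0, t_end = 0.5, provenance = "collected_1",
    samples = data.frame(
      t = seq(0, 0.5, by = 0.1),
      x = 0.8 + 6 * seq(0, 0.5, by = 0.1),
      y = 0,
      touching = TRUE
    )
  )
  k <- compute_kinematics(seg)
  expect_equal(k$max_speed_cmps, 6)
  expect_equal(k$avg_speed_cmps, 6)
  expect_equal(k$total_time_s, 0.5)

  # two-phase reach: 2.0 cm in 0.2 s then 1.0 cm in 0.3 s
  seg2 <- list(
    direction = 3L, t_start = 0, t_end = 0.5, provenance = "collected_1",
    samples = data.frame(
      t = c(0, 0.2, 0.5), x = c(0.8, 2.8, 3.8), y = 0, touching = TRUE
    )
  )
  k2 <- compute_kinematics(seg2)
  expect_equal(k2$max_speed_cmps, 10)
  expect_equal(k2$avg_speed_cmps, 6)
  expect_equal(k2$total_time_s, 0.5)

  # duplicate timestamps are an error
  seg_dup <- seg2
  seg_dup$samples$t <- c(0, 0.2, 0.2)
  expect_error(compute_kinematics(seg_dup), "duplicate")
})

test_that("lift-off gaps contribute no path length but the clock runs", {
  # 1 cm touching (0.2 s), 1 cm lifted (0.2 s), 1 cm touching (0.1 s)
  seg <- list(
    direction = 3L, t_start = 0, t_end = 0.5, provenance = "collected_1",
    samples = data.frame(
      t = c(0, 0.2, 0.4, 0.5),
      x = c(0.8, 1.8, 2.8, 3.8), y = 0,
      touching = c(TRUE, TRUE, FALSE, TRUE)
    )
  )
  k <- compute_kinematics(seg)
  # both steps bordering the lifted sample are discarded, so only the first
  # 1 cm step (5 cm/s) contributes path; the denominator is still 0.5 s
  expect_equal(k$avg_speed_cmps, 1 / 0.5)
  expect_equal(k$max_speed_cmps, 5)
  expect_equal(k$total_time_s, 0.5)
})

test_that("optional smoothing damps peaks and leaves straight reaches alone", {
  s <- simulate_session(cts_profile(), seed = 77)
  raw <- extract_features(s)$kinematics
  smo <- extract_features(s, smoothing = TRUE)$kinematics
  # averaging positions can only reduce the measured peak and path length
  expect_true(all(smo$max_speed_cmps <= raw$max_speed_cmps + 1e-12))
  expect_true(all(smo$avg_speed_cmps <= raw$avg_speed_cmps + 1e-12))
  expect_identical(smo$total_time_s, raw$total_time_s)

  # a constant-velocity straight line is a fixed point of the moving average
  seg <- list(
    direction = 3L, t_start = 0, t_end = 0.5, provenance = "collected_1",
    samples = data.frame(
      t = seq(0, 0.5, by = 0.1),
      x = 0.8 + 6 * seq(0, 0.5, by = 0.1),
      y = 0, touching = TRUE
    )
  )
  expect_equal(compute_kinematics(seg, smoothing = TRUE),
               compute_kinematics(seg, smoothing = FALSE))
})

test_that("segmentation interpolates the centre-boundary crossing", {
  # 3 o'clock reach along +x; r goes 0.6 -> 1.0 between t = 0.9 and 1.1,
  # crossing r = 0.8 at t = 1.00; disc edge (x = 2.9) reached at t = 1.50
  layout <- game_layout()
  samples <- data.frame(
    t = c(0.9, 1.1, 1.5),
    x = c(0.6, 1.0, 2.9), y = 0,
    touching = TRUE
  )
  targets <- data.frame(
    direction = 3L, appearance_index = 1L,
    t_appear = 0.85, t_resolve = 1.6, outcome = "collected"
  )
  s <- cts_session("h", "unknown", layout, targets, samples)
  segs <- segment_reaches(s)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$t_start, 1.00)
  expect_equal(segs[[1]]$t_end, 1.50)
  # interpolated start point sits on the boundary
  expect_equal(segs[[1]]$samples$x[1], 0.8)
})

test_that("a direction collected on its second appearance is scored from it", {
  layout <- game_layout()
  # appearance 1 (missed): aborted wiggle out and back, times out at t = 3
  wiggle <- data.frame(
    t = c(0.2, 0.5, 0.8, 1.1),
    x = c(0.79, 1.5, 1.5, 0.79), y = 0,
    touching = TRUE
  )
  # appearance 2: clean constant-speed reach starting at t = 3.5
  reach <- straight_reach_samples(layout, 3, v = 7, t0 = 3.5)
  dwell <- data.frame(t = c(3.1, 3.3), x = 0.79, y = 0, touching = TRUE)
  targets <- data.frame(
    direction = 3L, appearance_index = c(1L, 2L),
    t_appear = c(0, 3), t_resolve = c(3, reach$t[nrow(reach)]),
    outcome = c("missed", "collected")
  )
  s <- cts_session("h", "unknown", layout, targets,
                   rbind(wiggle, dwell, reach))
  segs <- segment_reaches(s)
  expect_length(segs, 1L)
  expect_identical(segs[[1]]$provenance, "collected_2")
  expect_gte(segs[[1]]$t_start, 3.5)
  k <- compute_kinematics(segs[[1]])
  expect_equal(k$avg_speed_cmps, 7, tolerance = 1e-6)

  # both appearances missed: scored from the first window
  targets2 <- targets
  targets2$outcome <- c("missed", "missed")
  targets2$t_resolve[2] <- 6
  s2 <- cts_session("h", "unknown", layout, targets2, rbind(wiggle, dwell, reach))
  segs2 <- segment_reaches(s2)
  expect_identical(segs2[[1]]$provenance, "missed")
  expect_lt(segs2[[1]]$t_start, 3)
})

test_that("feature extraction yields 36 canonically ordered values", {
  v <- 6
  s <- constant_speed_session(v = v)
  f <- extract_features(s)
  vals <- feature_values(f)
  expect_length(vals, 36L)
  expect_identical(names(vals), feature_cols())
  expect_true(all(is.finite(vals)))
  # 12 identical constant-speed reaches: every max = every avg = v
  expect_equal(unname(vals[grepl("maxspeed", names(vals))]), rep(v, 12))
  expect_equal(unname(vals[grepl("avgspeed", names(vals))]), rep(v, 12))
  expect_equal(unname(vals[grepl("totaltime", names(vals))]), rep(2.1 / v, 12))
})

test_that("extraction is deterministic and errors on unsegmentable input", {
  s <- simulate_session(control_profile(), seed = 9)
  f1 <- feature_values(extract_features(s))
  f2 <- feature_values(extract_features(s))
  expect_identical(f1, f2)

  # a direction with a target but no touching samples in its window
  s_bad <- constant_speed_session()
  win <- s_bad$targets[s_bad$targets$direction == 2L, ]
  sel <- s_bad$samples$t >= win$t_appear & s_bad$samples$t <= win$t_resolve
  s_bad$samples$touching[sel] <- FALSE
  expect_error(segment_reaches(s_bad), "direction 2")
})

test_that("time rescaling halves speeds and doubles durations", {
  s <- constant_speed_session(v = 6)
  f <- feature_values(extract_features(s))
  f2 <- feature_values(extract_features(rescale_session_time(s, 2)))
  is_speed <- grepl("speed", names(f))
  expect_equal(f2[is_speed], f[is_speed] / 2)
  expect_equal(f2[!is_speed], f[!is_speed] * 2)

  s_sim <- simulate_session(cts_profile(), seed = 21)
  g <- feature_values(extract_features(s_sim))
  g2 <- feature_values(extract_features(rescale_session_time(s_sim, 2)))
  expect_equal(g2[is_speed], g[is_speed] / 2, tolerance = 1e-9)
  expect_equal(g2[!is_speed], g[!is_speed] * 2, tolerance = 1e-9)
})

test_that("rigid rotation permutes directions but preserves kinematics", {
  s <- simulate_session(control_profile(), seed = 13)
  f <- extract_features(s)$kinematics
  for (steps in c(2L, 5L)) {
    fr <- extract_features(rotate_session(s, steps))$kinematics
    reordered <- fr[match((f$direction + steps) %% 12L, fr$direction), ]
    expect_equal(reordered$max_speed_cmps, f$max_speed_cmps, tolerance = 1e-9)
    expect_equal(reordered$avg_speed_cmps, f$avg_speed_cmps, tolerance = 1e-9)
    expect_equal(reordered$total_time_s, f$total_time_s, tolerance = 1e-9)
  }
})

test_that("feature tables bind, round-trip through CSV, and handle empties", {
  feats <- lapply(1:5, function(i) {
    extract_features(simulate_session(control_profile(), seed = i,
                                      hand_id = paste0("h", i)))
  })
  tab <- features_to_table(feats)
  expect_identical(dim(tab), c(5L, 38L))
  expect_identical(names(tab), c("hand_id", "label", feature_cols()))

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, path)
  tab2 <- read_feature_csv(path)
  expect_identical(as.data.frame(tab2), as.data.frame(tab))

  empty <- features_to_table(list())
  expect_identical(dim(empty), c(0L, 38L))
})
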