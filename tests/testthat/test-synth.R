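# a profile with negligible dispersion, handy for exact checks
degenerate_profile <- function(avg = 5, total = 0.5, ratio = 1.875,
                               miss_prob = 0) {
  impairment_profile(
    tibble::tibble(
      direction = 0:11,
      max_speed_median = avg * ratio, max_speed_sigma = 0,
      avg_speed_median = avg, avg_speed_sigma = 0,
      total_time_median = total, total_time_sigma = 0
    ),
    label = "unknown", miss_prob = miss_prob
  )
}

test_that("impairment profiles validate their feasibility invariants", {
  expect_s3_class(control_profile(), "impairment_profile")
  expect_s3_class(cts_profile(), "impairment_profile")

  # implied path shorter than the straight reach is rejected
  expect_error(degenerate_profile(avg = 2, total = 0.5), "infeasible")
  # max median below avg median is rejected
  expect_error(degenerate_profile(ratio = 0.9), "max_speed")
  # dispersion from interval bounds: sigma = log-range / (2 * 1.96)
  p <- control_profile()
  expect_equal(
    p$directions$total_time_sigma[1],
    (log(0.90) - log(0.33)) / (2 * qnorm(0.975)),
    tolerance = 1e-12
  )
})

test_that("simulated reaches realise their drawn kinematics", {
  prof <- degenerate_profile(avg = 5, total = 0.5)
  set.seed(1)
  reach <- simulate_reach(0, prof, sampling_rate = 60)
  draws <- attr(reach, "draws")
  # zero dispersion: the drawn duration is the configured median exactly
  expect_equal(draws$total_time, 0.5)
  span <- reach$t[nrow(reach)] - reach$t[1]
  expect_lt(abs(span - 0.5), 1 / 60)

  # realised path length and peak speed track the draws closely
  step <- sqrt(diff(reach$x)^2 + diff(reach$y)^2)
  expect_equal(sum(step) / span, draws$avg_speed, tolerance = 0.01)
  expect_equal(max(step / diff(reach$t)), draws$max_speed, tolerance = 0.02)

  # same RNG state, same samples
  set.seed(7); r1 <- simulate_reach(3, control_profile())
  set.seed(7); r2 <- simulate_reach(3, control_profile())
  expect_identical(r1, r2)
})

test_that("the minimum-jerk bell has peak/mean speed ratio 1.875", {
  # sample the exponent-2 bell very finely on a straight unit path and
  # compare the finite-difference peak/mean ratio to the closed form 15/8
  tt <- seq(0, 1, by = 1e-4)
  frac <- pbeta(tt, 3, 3)
  speeds <- diff(frac) / diff(tt)
  expect_equal(max(speeds) / (sum(diff(frac)) / 1), 1.875, tolerance = 1e-3)

  # and the simulator's exponent solver inverts the ratio
  prof <- degenerate_profile(avg = 5, total = 0.5, ratio = 1.875)
  set.seed(3)
  reach <- simulate_reach(6, prof)
  expect_equal(attr(reach, "draws")$bell_exponent,
               thumbscreen:::solve_bell_exponent(
                 attr(reach, "draws")$max_speed / attr(reach, "draws")$avg_speed
               ))
})

test_that("simulated sessions always satisfy the protocol", {
  for (seed in c(2, 19, 404)) {
    s <- simulate_session(cts_profile(), seed = seed)
    expect_identical(nrow(validate_session(s)), 0L)
  }

  # no misses: exactly 12 directional target events
  s0 <- simulate_session(degenerate_profile(miss_prob = 0), seed = 5)
  expect_identical(sum(!is.na(s0$targets$direction)), 12L)

  # direction 5 always missed: two appearances there, both missed
  mp <- rep(0, 12); mp[6] <- 1
  s5 <- simulate_session(degenerate_profile(miss_prob = mp), seed = 5)
  tg5 <- s5$targets[!is.na(s5$targets$direction) & s5$targets$direction == 5, ]
  expect_identical(nrow(tg5), 2L)
  expect_identical(tg5$outcome, c("missed", "missed"))
  expect_identical(sort(tg5$appearance_index), c(1L, 2L))
  expect_identical(nrow(validate_session(s5)), 0L)
  # the missed direction still yields a (degraded) segment
  expect_length(segment_reaches(s5), 12L)
})

test_that("sessions and cohorts are reproducible from their seeds", {
  f1 <- feature_values(extract_features(simulate_session(cts_profile(), seed = 33)))
  f2 <- feature_values(extract_features(simulate_session(cts_profile(), seed = 33)))
  expect_identical(f1, f2)

  c1 <- simulate_cohort(2, 3, seed = 12)
  c2 <- simulate_cohort(2, 3, seed = 12)
  expect_identical(length(c1), 5L)
  expect_identical(vapply(c1, `[[`, character(1), "label"),
                   rep(c("non-CTS", "CTS"), c(2, 3)))
  t1 <- features_to_table(lapply(c1, extract_features))
  t2 <- features_to_table(lapply(c2, extract_features))
  expect_identical(t1, t2)
})

test_that("extracted medians recover the configured profile medians", {
  prof <- control_profile()
  seeds <- withr::with_seed(88, sample.int(2^31 - 2, 100))
  tab <- features_to_table(lapply(seq_along(seeds), function(i) {
    extract_features(simulate_session(prof, seed = seeds[i], hand_id = i))
  }))
  # spot-check 12 o'clock: all three parameters within 10% at n = 100
  expect_equal(median(tab$d00_totaltime_s),
               prof$directions$total_time_median[1], tolerance = 0.10)
  expect_equal(median(tab$d00_avgspeed_cmps),
               prof$directions$avg_speed_median[1], tolerance = 0.10)
  expect_equal(median(tab$d00_maxspeed_cmps),
               prof$directions$max_speed_median[1], tolerance = 0.10)
})

test_that("scaling the configured durations scales the recovered medians", {
  base <- degenerate_profile(avg = 6, total = 0.5)
  slow <- degenerate_profile(avg = 6, total = 1.0)
  med_tt <- function(prof) {
    tab <- features_to_table(lapply(1:20, function(i) {
      extract_features(simulate_session(prof, seed = 500 + i, hand_id = i))
    }))
    median(tab$d03_totaltime_s)
  }
  expect_equal(med_tt(slow) / med_tt(base), 2, tolerance = 0.05)
})

test_that("feature clusters separate as configured", {
  tab <- simulate_feature_clusters(20, 20, separation = 4, seed = 9)
  expect_identical(dim(tab), c(40L, 38L))
  mu_a <- colMeans(tab[tab$label == "non-CTS", feature_cols()])
  mu_b <- colMeans(tab[tab$label == "CTS", feature_cols()])
  # per-dimension shift of 4 SD: overall distance 4 * sqrt(36) = 24
  expect_equal(sqrt(sum((mu_a - mu_b)^2)), 24, tolerance = 0.1)
  null_tab <- simulate_feature_clusters(20, 20, separation = 0, seed = 9)
  mu_a0 <- colMeans(null_tab[null_tab$label == "non-CTS", feature_cols()])
  mu_b0 <- colMeans(null_tab[null_tab$label == "CTS", feature_cols()])
  # with no configured separation only sampling noise remains
  expect_lt(sqrt(sum((mu_a0 - mu_b0)^2)), sqrt(sum((mu_a - mu_b)^2)) / 2)
})
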