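# synthetic-data generator: determinism, ground-truth consistency,
# degenerate limits, calibration of injected effects

test_that("behavior generation is deterministic in the seed", {
  a <- generate_behavior(behavior_params(n_flies = 3, seed = 101))
  b <- generate_behavior(behavior_params(n_flies = 3, seed = 101))
  expect_identical(a$monitor$counts, b$monitor$counts)
  expect_identical(a$truth, b$truth)
  c <- generate_behavior(behavior_params(n_flies = 3, seed = 102))
  expect_false(identical(a$monitor$counts, c$monitor$counts))
})

test_that("generator truth equals the 5-min scoring of its own counts", {
  sim <- generate_behavior(behavior_params(n_flies = 8, seed = 103))
  for (f in 1:8) {
    fs <- to_fly_series(sim$monitor, sim$schedule, f)
    expect_identical(score_sleep(fs$counts, 5, fs$flagged),
                     sim$sleep[[f]])
  }
  # and therefore the truth table's sleep minutes match scored minutes
  scored <- sum(score_sleep(to_fly_series(sim$monitor, sim$schedule,
                                          1)$counts))
  expect_equal(scored, sum(sim$truth$sleep_min_total[sim$truth$fly == "ch01"]))
})

test_that("degenerate limits behave as expected", {
  # immediate consolidated night sleep: onset exactly at dusk for every fly
  p <- behavior_params(n_flies = 4, seed = 104,
                       onset = list(mean_min = 0, sd_min = 0),
                       night = list(bout_mean_min = 5000, gap_mean_min = 1))
  sim <- generate_behavior(p)
  for (f in 1:4) {
    fs <- to_fly_series(sim$monitor, sim$schedule, f)
    for (d in 1:2) {
      day <- fs$counts[((d - 1) * 1440 + 1):(d * 1440)]
      expect_true(all(day[721:1440] == 0))
      expect_equal(sleep_onset_after_dusk(day), 12)
    }
  }

  # zero activity everywhere: the whole day scores as sleep
  p0 <- behavior_params(n_flies = 2, seed = 105, lambda0 = 0,
                        morning_amp = 0, evening_ramp_slope = 0,
                        lambda_night = 0, startle_amp = 0,
                        enforce_scoring = FALSE)
  sim0 <- generate_behavior(p0)
  fs0 <- to_fly_series(sim0$monitor, sim0$schedule, 1)
  expect_true(all(score_sleep(fs0$counts)))
})

test_that("cohort estimates match generator ground truth at n = 32", {
  sim <- generate_behavior(behavior_params(seed = 106))
  onsets <- slopes <- numeric(32)
  for (f in 1:32) {
    fs <- to_fly_series(sim$monitor, sim$schedule, f)
    d1 <- fs$counts[1:1440]
    onsets[f] <- sleep_onset_after_dusk(d1)
    slopes[f] <- anticipation_slope(fs)$slope
  }
  truth1 <- sim$truth[sim$truth$day == 1, ]
  # onsets agree fly by fly with the injected latencies
  expect_equal(onsets, truth1$onset_zt_hr)
  # cohort median onset within 10 min of the injected median
  expect_lt(abs(median(onsets) - median(truth1$onset_zt_hr)) * 60, 1e-9)
  # mean slope within 15% of the injected ramp slope
  expect_lt(abs(mean(slopes) - 0.8) / 0.8, 0.15)
})

test_that("doubling the injected onset delay doubles the measured delay", {
  med_delay <- function(delta, seed) {
    sim <- generate_behavior(behavior_params(
      n_flies = 32, seed = seed, delta_onset_min = delta))
    base <- generate_behavior(behavior_params(n_flies = 32, seed = seed + 500))
    m <- function(s) median(vapply(1:32, function(f)
      sleep_onset_after_dusk(
        to_fly_series(s$monitor, s$schedule, f)$counts[1:1440]),
      numeric(1)), na.rm = TRUE)
    (m(sim) - m(base)) * 60
  }
  d30 <- med_delay(30, 107)
  d60 <- med_delay(60, 108)
  expect_lt(abs(d30 - 30), 12)
  expect_lt(abs(d60 - 60), 12)
})

test_that("trace generation is exact in the noiseless limit and deterministic", {
  p <- trace_params(duration_s = 5, spike_rate_hz = 0, noise_sd = 0,
                    seed = 109)
  sim <- generate_trace(p)
  tt <- (0:(5 * 849 - 1)) / 849
  expected <- 1000 + 200 * exp(-tt / 60) + 4.5 * sin(2 * pi * 2 * tt)
  expect_equal(sim$trace$samples, expected, tolerance = 1e-12)
  expect_equal(sim$spike_times_s, numeric(0))

  a <- generate_trace(trace_params(seed = 110))
  b <- generate_trace(trace_params(seed = 110))
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$spike_times_s, b$spike_times_s)
})

test_that("spike counts follow Poisson statistics without refractoriness", {
  set.seed(111)
  counts <- replicate(200, length(random_spike_times(1, 300)))
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300 / 200))
  expect_error(trace_params(spike_depth_sd = -1), "non-negative")
})

test_that("movies embed the planted mask recoverably", {
  mv <- generate_movie(trace_params(duration_s = 6, seed = 112), 10, 30,
                       pixel_noise_sd = 1e-9)
  expect_identical(select_roi_kmeans(mv$movie)$mask, mv$mask)

  mv2 <- generate_movie(trace_params(duration_s = 6, seed = 113), 16, 48,
                        pixel_noise_sd = 2)
  acc <- mean(select_roi_kmeans(mv2$movie)$mask == mv2$mask)
  expect_gte(acc, 0.95)
  expect_error(generate_movie(trace_params(), 0, 10), "signal pixel")
})

test_that("experiment scenarios inject effects only where declared", {
  exp <- build_experiment("E1_activation_DD", n_per_group = 8, seed = 114)
  expect_true(all(vapply(exp$groups, function(g)
    all(g$params$regime == "DD"), TRUE)))
  # no injected effect in DD activation: all groups share effect-free params
  expect_equal(exp$groups[["GAL4>UAS"]]$params$delta_afternoon_wake, 0)

  exp2 <- build_experiment("E1_activation_LD", n_per_group = 8, seed = 115)
  expect_equal(exp2$groups[["GAL4>UAS"]]$params$delta_afternoon_wake, 0.5)
  expect_equal(exp2$groups[["GAL4>UAS"]]$params$afternoon_effect_days, 2L)
  expect_equal(exp2$groups[["GAL4/+"]]$params$delta_afternoon_wake, 0)
  expect_error(build_experiment("nope"), "arg")
})

test_that("experiments round-trip through DAM files and config", {
  exp <- build_experiment("E1_silencing", n_per_group = 4, seed = 116)
  dir <- withr::local_tempdir()
  write_experiment(exp, dir)
  back <- read_experiment(dir)
  expect_equal(back$scenario, "E1_silencing")
  expect_equal(names(back$groups), names(exp$groups))
  expect_equal(back$groups[[1]]$monitor$counts,
               exp$groups[[1]]$monitor$counts)
  r1 <- run_experiment(exp)
  r2 <- run_experiment(back)
  expect_equal(r1$metrics$onset, r2$metrics$onset)
})
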