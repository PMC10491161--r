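# voltage-trace pipeline: detrend, filters, baseline, spike calling, rates

test_that("polynomial detrending removes its own model class exactly", {
  fs <- 849
  tt <- (0:(10 * fs - 1)) / fs
  poly3 <- 1000 - 5 * tt + 0.8 * tt^2 - 0.05 * tt^3
  out <- detrend_photobleach(voltage_trace(poly3, fs))
  expect_lt(max(abs(out$samples)), 1e-9 * max(abs(poly3)))

  cst <- detrend_photobleach(voltage_trace(rep(7, 1000), fs))
  expect_lt(max(abs(cst$samples)), 1e-9)
  expect_error(detrend_photobleach(voltage_trace(1:10, fs), degree = -1),
               ">= 0")
})

test_that("detrending a polynomial plus sinusoid leaves the sinusoid", {
  fs <- 849
  tt <- (0:(30 * fs - 1)) / fs
  sine <- 10 * sin(2 * pi * 4 * tt)
  y <- 500 + 30 * tt - 2 * tt^2 + 0.02 * tt^3 + sine
  out <- detrend_photobleach(voltage_trace(y, fs))$samples
  rms <- sqrt(mean((out - sine)^2))
  expect_lt(rms, 0.01 * 10)
})

test_that("low-pass filter has unit DC gain, linearity, and half gain at cutoff", {
  fs <- 849
  cst <- filter_trace(voltage_trace(rep(5, 2000), fs))
  expect_equal(cst$samples, rep(5, 2000), tolerance = 1e-8)

  set.seed(51)
  a <- rnorm(3000); b <- rnorm(3000)
  fa <- filter_trace(voltage_trace(a, fs))$samples
  fb <- filter_trace(voltage_trace(b, fs))$samples
  fab <- filter_trace(voltage_trace(a + b, fs))$samples
  expect_equal(fab, fa + fb, tolerance = 1e-10)

  # amplitude ratio at the cutoff: -3 dB per pass, squared by filtfilt
  tt <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * (0.5 * fs / 2) * tt)
  y <- filter_trace(voltage_trace(x, fs))$samples
  mid <- 2000:6000
  expect_equal(sd(y[mid]) / sd(x[mid]), 0.5, tolerance = 0.02)
  expect_error(filter_trace(voltage_trace(x, fs), normalized_cutoff = 1.2),
               "\\(0, 1\\)")
})

test_that("band-pass baseline keeps the slow oscillation and rejects DC", {
  fs <- 849
  tt <- (0:(10 * fs - 1)) / fs
  x4 <- sin(2 * pi * 4 * tt)
  b4 <- estimate_baseline(voltage_trace(x4, fs))
  mid <- 2000:6000
  expect_gt(sd(b4[mid]) / sd(x4[mid]), 0.9)

  bdc <- estimate_baseline(voltage_trace(rep(100, 10 * fs), fs))
  expect_lt(abs(mean(bdc)), 1)

  mix <- 5 * sin(2 * pi * 2 * tt) + 3 * sin(2 * pi * 100 * tt)
  bm <- estimate_baseline(voltage_trace(mix, fs))
  resid <- bm[mid] - 5 * sin(2 * pi * 2 * tt[mid])
  expect_lt(sqrt(mean(resid^2)), 0.10 * 5)
  expect_error(estimate_baseline(voltage_trace(mix, fs), band_hz = c(8, 1)),
               "low < high")
})

planted_trace <- function(times, depth, n = 20 * 849, fs = 849, tau = 0.005) {
  y <- numeric(n)
  tt <- (0:(n - 1)) / fs
  for (s in times) {
    i0 <- floor(s * fs) + 1
    idx <- i0:min(n, i0 + 60)
    y[idx] <- y[idx] - depth * exp(-(tt[idx] - s) / tau)
  }
  voltage_trace(y + 2 * sin(2 * pi * 2 * tt), fs)
}

test_that("spike detection finds planted spikes and applies the refractory rule", {
  fs <- 849
  # flat noiseless trace: no spikes, flagged
  flat <- detect_spikes(voltage_trace(rep(0, fs * 2), fs), rep(0, fs * 2))
  expect_equal(flat$n, 0L)
  expect_match(flat$flagged, "no spikes")

  # 10 planted spikes, separation > 100 ms, noiseless
  times <- seq(1, 19, by = 2)
  tr <- planted_trace(times, depth = 10)
  fil <- filter_trace(tr)
  bas <- estimate_baseline(fil)
  st <- detect_spikes(fil, bas)
  expect_equal(st$n, 10L)
  expect_true(all(abs(st$times_s - times) <= 2 / fs))

  # doublet 2 ms apart: only the deeper survives
  tr2 <- planted_trace(c(5, 5.002), depth = 10)
  tr2$samples <- tr2$samples - {
    tt <- (seq_along(tr2$samples) - 1) / fs
    idx <- tt >= 5.002 & tt < 5.06
    extra <- numeric(length(tt)); extra[idx] <- 4 * exp(-(tt[idx] - 5.002) / 0.005)
    extra
  }
  fil2 <- filter_trace(tr2)
  st2 <- detect_spikes(fil2, estimate_baseline(fil2))
  expect_equal(st2$n, 1L)
  expect_equal(st2$times_s, 5.002, tolerance = 3 / fs)
})

test_that("spike rate is count over duration", {
  expect_equal(spike_rate(spike_train(seq(0.5, 19.5, length.out = 10), 20)),
               0.5)
  expect_equal(spike_rate(spike_train(numeric(0), 30)), 0)
  expect_error(spike_train(1:3, 0), "positive")

  # Poisson sampling error band
  set.seed(52)
  r <- 2; T <- 60
  est <- spike_rate(spike_train(random_spike_times(r, T), T))
  expect_lt(abs(est - r), 3 * sqrt(r / T))
})

test_that("the full pipeline is deterministic and drift-invariant", {
  sim <- generate_trace(trace_params(seed = 53))
  r1 <- process_trace(sim$trace)
  r2 <- process_trace(sim$trace)
  expect_identical(r1$spikes$times_s, r2$spikes$times_s)

  n <- length(sim$trace$samples)
  u <- seq(0, 1, length.out = n)
  drift <- 40 + 25 * u - 60 * u^2 + 35 * u^3
  r3 <- process_trace(voltage_trace(sim$trace$samples + drift, 849))
  expect_identical(r1$spikes$times_s, r3$spikes$times_s)

  # zero-spike trace gives rate 0
  z <- generate_trace(trace_params(spike_rate_hz = 0, seed = 54))
  expect_equal(process_trace(z$trace)$rate_hz, 0)
})

test_that("spike count is non-increasing in the detection threshold", {
  sim <- generate_trace(trace_params(seed = 55))
  det <- detrend_photobleach(sim$trace)
  fil <- filter_trace(det)
  bas <- estimate_baseline(fil)
  ns <- vapply(c(0.5, 1, 1.5, 2, 3, 4, 6),
               function(k) detect_spikes(fil, bas, n_sd = k)$n, 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("detection F1 degrades as spike depth shrinks toward the noise", {
  f1 <- vapply(c(6, 2.5, 1), function(depth) {
    m <- sapply(1:3, function(s) {
      sim <- generate_trace(trace_params(seed = 60 + s,
                                         spike_depth_sd = depth))
      out <- process_trace(sim$trace)
      match_spikes(out$spikes$times_s, sim$spike_times_s, tol_s = 0.012,
                   truth_window = c(0.3, 59.7))$f1
    })
    mean(m)
  }, numeric(1))
  expect_true(all(diff(f1) < 0))
})

test_that("traces round-trip through CSV with the rate preserved", {
  tr <- generate_trace(trace_params(duration_s = 2, seed = 59))$trace
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$samples, tr$samples)
  expect_equal(back$rate_hz, tr$rate_hz, tolerance = 1e-6)
})

test_that("two-condition rate comparison matches closed forms", {
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  r <- compare_conditions(c(1, 2, 3), c(4, 5, 6))
  # hand computation: pooled s2 = 1, t = -3 / sqrt(2/3)
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(-3 / sqrt(2 / 3)), 4), tolerance = 1e-12)
  expect_equal(r$direction, -1)
  expect_error(compare_conditions(1, c(1, 2)), "n >= 2")
})

test_that("the t test is calibrated under the null", {
  set.seed(56)
  rej <- mean(replicate(2000, {
    compare_conditions(rnorm(7, 1, 0.3), rnorm(7, 1, 0.3))$p < 0.05
  }))
  expect_gte(rej, 0.04 - 0.005)
  expect_lte(rej, 0.06 + 0.005)
})

test_that("k-means ROI selection recovers planted signal pixels", {
  mv <- generate_movie(trace_params(duration_s = 8, seed = 57), 12, 36,
                       pixel_noise_sd = 0.5)
  roi <- select_roi_kmeans(mv$movie)
  expect_identical(roi$mask, mv$mask)

  # single signal pixel among 63 background
  mv2 <- generate_movie(trace_params(duration_s = 8, seed = 58), 1, 63,
                        pixel_noise_sd = 0.5)
  roi2 <- select_roi_kmeans(mv2$movie)
  expect_true(roi2$mask[1])

  # k = 1 selects everything; degenerate movie is flagged
  roi3 <- select_roi_kmeans(mv$movie, k = 1)
  expect_true(all(roi3$mask))
  expect_equal(roi3$trace, colMeans(mv$movie))
  deg <- select_roi_kmeans(matrix(3, 8, 100))
  expect_true(deg$flagged)
  expect_error(select_roi_kmeans(matrix(rnorm(40), 4, 10), k = 9), "exceed")

  # identical pixel populations: labeling is arbitrary, ROI trace is the
  # common trace either way
  base <- matrix(rep(sin((1:200) / 5), each = 12), 12, 200, byrow = FALSE)
  r <- select_roi_kmeans(base)
  expect_equal(unname(r$trace), sin((1:200) / 5), tolerance = 1e-6)
})
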