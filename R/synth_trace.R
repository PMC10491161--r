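# Synthetic voltage-indicator traces: negative-going spikes riding on a
# slow subthreshold oscillation over an exponential photobleaching decay,
# with Gaussian sensor noise. Spike times follow a refractory Poisson
# process. Everything is deterministic per seed.

#' Parameters for the voltage-trace generator
#'
#' @param duration_s recording length in seconds. Default 60.
#' @param rate_hz sampling rate. Default 849.
#' @param f_offset baseline fluorescence level (a.u.).
#' @param bleach_amp,bleach_tau_s exponential photobleach component
#'   `bleach_amp * exp(-t / bleach_tau_s)`.
#' @param sub_amp,sub_freq_hz,sub_phase slow subthreshold oscillation
#'   (sinusoid; frequency should sit inside the 1-8 Hz baseline band).
#'   Default amplitude 4.5 a.u. (about twice the sensor-noise SD).
#' @param spike_rate_hz Poisson spike rate. Default 1.
#' @param spike_depth_sd spike depth in multiples of the noise SD.
#'   Default 6.
#' @param spike_depth_abs absolute spike depth (a.u.); overrides
#'   `spike_depth_sd` when set (needed for noiseless traces).
#' @param spike_tau_ms exponential spike decay constant. Default 5.
#' @param refractory_ms minimum inter-spike interval. Default 20.
#' @param noise_sd Gaussian noise SD (a.u.). Default 2.
#' @param seed RNG seed (`NULL` = current stream).
#' @return A `trace_params` list.
#' @export
trace_params <- function(duration_s = 60, rate_hz = 849, f_offset = 1000,
                         bleach_amp = 200, bleach_tau_s = 60,
                         sub_amp = 4.5, sub_freq_hz = 2, sub_phase = 0,
                         spike_rate_hz = 1, spike_depth_sd = 6,
                         spike_depth_abs = NULL, spike_tau_ms = 5,
                         refractory_ms = 20, noise_sd = 2, seed = NULL) {
  stopifnot(duration_s > 0, rate_hz > 0, spike_rate_hz >= 0, noise_sd >= 0)
  if (spike_depth_sd < 0 || (!is.null(spike_depth_abs) && spike_depth_abs < 0))
    stop("spike depth must be non-negative")
  if (rate_hz <= 2 * sub_freq_hz)
    stop("sampling rate must exceed twice the subthreshold frequency")
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 f_offset = f_offset, bleach_amp = bleach_amp,
                 bleach_tau_s = bleach_tau_s, sub_amp = sub_amp,
                 sub_freq_hz = sub_freq_hz, sub_phase = sub_phase,
                 spike_rate_hz = spike_rate_hz,
                 spike_depth_sd = spike_depth_sd,
                 spike_depth_abs = spike_depth_abs,
                 spike_tau_ms = spike_tau_ms,
                 refractory_ms = refractory_ms, noise_sd = noise_sd,
                 seed = seed), class = "trace_params")
}

#' Draw spike times from a refractory Poisson process
#'
#' Exponential inter-spike gaps plus a dead time, accumulated until the
#' record ends. With zero refractory period this is a homogeneous Poisson
#' process. Uses the caller's RNG stream.
#'
#' @param rate_hz event rate of the underlying Poisson process, Hz.
#' @param duration_s record length, seconds.
#' @param refractory_ms dead time after each spike. Default 0.
#' @return Ascending spike times in seconds.
#' @export
random_spike_times <- function(rate_hz, duration_s, refractory_ms = 0) {
  draw_spike_times(rate_hz, duration_s, refractory_ms / 1000)
}

# exponential gaps plus dead time, accumulated until the record ends
draw_spike_times <- function(rate_hz, duration_s, refractory_s) {
  if (rate_hz <= 0) return(numeric(0))
  times <- numeric(0)
  t <- 0
  repeat {
    t <- t + rexp(1, rate_hz) + if (length(times)) refractory_s else 0
    if (t >= duration_s) break
    times <- c(times, t)
  }
  times
}

#' Generate a synthetic voltage-indicator trace with known spikes
#'
#' `F(t) = offset + bleach(t) + A sin(2 pi f t + phi)` minus, for each
#' spike time `t_i`, a causal exponential `depth * exp(-(t - t_i)/tau)`,
#' plus Gaussian noise.
#'
#' @param params a [trace_params()] object.
#' @return List of class `trace_sim`: `trace` ([voltage_trace()]),
#'   `spike_times_s` (ground truth), `params`.
#' @export
generate_trace <- function(params) {
  stopifnot(inherits(params, "trace_params"))
  p <- params
  with_seed(p$seed, {
    n <- as.integer(round(p$duration_s * p$rate_hz))
    tt <- (0:(n - 1)) / p$rate_hz
    depth <- p$spike_depth_abs %||% (p$spike_depth_sd * p$noise_sd)
    spikes <- draw_spike_times(p$spike_rate_hz, p$duration_s,
                               p$refractory_ms / 1000)
    y <- p$f_offset + p$bleach_amp * exp(-tt / p$bleach_tau_s) +
      p$sub_amp * sin(2 * pi * p$sub_freq_hz * tt + p$sub_phase)
    if (length(spikes)) {
      tau <- p$spike_tau_ms / 1000
      span <- as.integer(ceiling(10 * tau * p$rate_hz))
      for (s in spikes) {
        i0 <- as.integer(floor(s * p$rate_hz)) + 1L
        idx <- i0:min(n, i0 + span)
        y[idx] <- y[idx] - depth * exp(-(tt[idx] - s) / tau)
      }
    }
    if (p$noise_sd > 0) y <- y + rnorm(n, sd = p$noise_sd)
    structure(list(trace = voltage_trace(y, p$rate_hz),
                   spike_times_s = spikes, params = p),
              class = "trace_sim")
  })
}

#' Generate a pixel-by-time movie with a planted signal ROI
#'
#' Signal pixels share one [generate_trace()] realisation plus independent
#' pixel noise; background pixels carry only the bleach decay plus noise.
#' The true mask is returned for validation of ROI selection.
#'
#' @param params a [trace_params()].
#' @param n_signal_pixels,n_background_pixels pixel counts (signal >= 1).
#' @param pixel_noise_sd independent per-pixel noise SD.
#' @return List of class `movie_sim`: `movie` (pixels x time matrix),
#'   `mask` (logical, `TRUE` = signal), `trace_truth`, `spike_times_s`.
#' @export
generate_movie <- function(params, n_signal_pixels = 16L,
                           n_background_pixels = 48L, pixel_noise_sd = 2) {
  stopifnot(inherits(params, "trace_params"))
  if (n_signal_pixels < 1) stop("need at least one signal pixel")
  if (n_signal_pixels + n_background_pixels < 1) stop("zero pixels")
  p <- params
  with_seed(p$seed, {
    p2 <- p; p2$seed <- NULL
    sim <- generate_trace(p2)
    n <- length(sim$trace$samples)
    tt <- (0:(n - 1)) / p$rate_hz
    bg <- p$f_offset + p$bleach_amp * exp(-tt / p$bleach_tau_s)
    np <- n_signal_pixels + n_background_pixels
    movie <- matrix(0, np, n)
    for (i in seq_len(n_signal_pixels))
      movie[i, ] <- sim$trace$samples +
        if (pixel_noise_sd > 0) rnorm(n, sd = pixel_noise_sd) else 0
    for (i in seq_len(n_background_pixels))
      movie[n_signal_pixels + i, ] <- bg +
        if (pixel_noise_sd > 0) rnorm(n, sd = pixel_noise_sd) else 0
    structure(list(movie = movie,
                   mask = c(rep(TRUE, n_signal_pixels),
                            rep(FALSE, n_background_pixels)),
                   trace_truth = sim$trace$samples,
                   spike_times_s = sim$spike_times_s, params = p),
              class = "movie_sim")
  })
}

#' Match detected to true spike times and score the detection
#'
#' Greedy one-to-one matching within a tolerance window; used to validate
#' the spike pipeline on synthetic traces.
#'
#' @param detected,truth spike time vectors (seconds).
#' @param tol_s matching tolerance. Default 0.01 s.
#' @param truth_window optional `c(lo, hi)`: truth spikes outside it (e.g.
#'   inside the detector's edge-exclusion zone) are not counted as misses,
#'   and detections outside it are ignored.
#' @return List: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
match_spikes <- function(detected, truth, tol_s = 0.01,
                         truth_window = NULL) {
  if (!is.null(truth_window)) {
    truth <- truth[truth >= truth_window[1] & truth <= truth_window[2]]
    detected <- detected[detected >= truth_window[1] &
                           detected <= truth_window[2]]
  }
  used <- logical(length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol_s)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  prec <- if (length(detected)) tp / length(detected) else NA_real_
  rec <- if (length(truth)) tp / length(truth) else NA_real_
  f1 <- if (tp == 0) 0
        else 2 * prec * rec / (prec + rec)
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
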