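# Synthetic crepuscular behavior generator. Emits DAM-format monitor data
# with exact ground truth: a two-state (wake/sleep) semi-Markov process
# drives per-minute sleep; wake minutes emit Poisson beam-break counts from
# a crepuscular rate template (morning peak, midday siesta, evening
# anticipatory ramp, lights-transition startle, consolidated night sleep).
# This is an emulation of the published phenomenology, not a mechanistic
# clock model.

#' Parameters for the behavior generator
#'
#' Defaults describe a wild-type-like crepuscular day under 12:12 LD:
#' a morning activity peak at lights-on, a midday siesta (ZT4-8), an
#' evening anticipatory ramp over ZT9-12 rising into the dusk peak, rapid
#' sleep onset after dusk (mean latency 20 min), and consolidated night
#' sleep. Phenotype injections reproduce the signatures of the
#' manipulations studied: `delta_onset_min` delays post-dusk sleep onset
#' (silencing-like), `delta_afternoon_wake` suppresses ZT6-12 sleep
#' (activation-like), `delta_phase_hr` advances the whole evening program
#' (short-period-clock-like).
#'
#' @param n_flies flies per monitor (<= 32). Default 32.
#' @param day_tags tag per protocol day. Default two `"baseline"` days.
#' @param regime `"LD"`/`"DD"` per day (recycled). DD days drop startle
#'   pulses and run on the entrained template phase.
#' @param temperature_c per-day temperature label.
#' @param lambda0 baseline wake activity, counts/min.
#' @param morning_amp,morning_width_hr Gaussian morning peak at ZT0.
#' @param ramp_start_hr,evening_ramp_slope evening anticipatory ramp:
#'   rate rises by `evening_ramp_slope` counts/min per hour from
#'   `ramp_start_hr` to the evening peak at ZT12 (shifted earlier by
#'   `delta_phase_hr`).
#' @param lambda_night wake activity after the evening peak, counts/min.
#' @param startle_amp extra counts at the two light transitions (LD only).
#' @param siesta list: `start_hr`, `end_hr`, `bout_mean_min`,
#'   `gap_mean_min` for midday sleep.
#' @param night list: `bout_mean_min`, `gap_mean_min` for night sleep.
#' @param onset list: `mean_min`, `sd_min` of the post-dusk sleep-onset
#'   latency (gamma-distributed).
#' @param delta_onset_min added mean onset latency on affected days.
#' @param delta_afternoon_wake probability in \[0,1\] of suppressing each
#'   siesta bout overlapping ZT6-12 on affected days.
#' @param delta_phase_hr advance (hours) of the evening program (ramp,
#'   peak, and evening sleep onset) on affected days.
#' @param onset_effect_days,afternoon_effect_days,phase_effect_days day
#'   indices on which each injection applies. Default: all days.
#' @param sleep_threshold_min scoring threshold the generator guarantees:
#'   every generated sleep bout is at least this long.
#' @param enforce_scoring if `TRUE` (default), wake-minute zero counts
#'   that would be indistinguishable from sleep under the scoring rule are
#'   bumped to 1 count, so generator truth and the 5-min scoring of the
#'   emitted counts coincide exactly. Set `FALSE` to test scorer
#'   robustness to sub-threshold quiescence.
#' @param start_date,lights_on calendar anchoring of the monitor file;
#'   recording starts at lights-on.
#' @param seed RNG seed (`NULL` = use current stream).
#' @return A `behavior_params` list.
#' @export
behavior_params <- function(n_flies = 32L,
                            day_tags = c("baseline", "baseline"),
                            regime = "LD",
                            temperature_c = 22,
                            lambda0 = 1.0,
                            morning_amp = 2.5, morning_width_hr = 0.75,
                            ramp_start_hr = 9, evening_ramp_slope = 0.8,
                            lambda_night = 1.0,
                            startle_amp = 8,
                            siesta = list(start_hr = 4, end_hr = 8,
                                          bout_mean_min = 25,
                                          gap_mean_min = 15),
                            night = list(bout_mean_min = 45,
                                         gap_mean_min = 8),
                            onset = list(mean_min = 20, sd_min = 10),
                            delta_onset_min = 0,
                            delta_afternoon_wake = 0,
                            delta_phase_hr = 0,
                            onset_effect_days = NULL,
                            afternoon_effect_days = NULL,
                            phase_effect_days = NULL,
                            sleep_threshold_min = 5L,
                            enforce_scoring = TRUE,
                            start_date = "2024-01-01",
                            lights_on = "08:00:00",
                            seed = NULL) {
  stopifnot(n_flies >= 1, n_flies <= 32,
            lambda0 >= 0, lambda_night >= 0, startle_amp >= 0,
            onset$mean_min + delta_onset_min >= 0, onset$sd_min >= 0,
            delta_afternoon_wake >= 0, delta_afternoon_wake <= 1)
  n_days <- length(day_tags)
  all_days <- seq_len(n_days)
  p <- list(n_flies = as.integer(n_flies), n_days = n_days,
            day_tags = day_tags,
            regime = rep_len(match.arg(regime, c("LD", "DD"),
                                       several.ok = TRUE), n_days),
            temperature_c = rep_len(temperature_c, n_days),
            lambda0 = lambda0, morning_amp = morning_amp,
            morning_width_hr = morning_width_hr,
            ramp_start_hr = ramp_start_hr,
            evening_ramp_slope = evening_ramp_slope,
            lambda_night = lambda_night, startle_amp = startle_amp,
            siesta = siesta, night = night, onset = onset,
            delta_onset_min = delta_onset_min,
            delta_afternoon_wake = delta_afternoon_wake,
            delta_phase_hr = delta_phase_hr,
            onset_effect_days = onset_effect_days %||% all_days,
            afternoon_effect_days = afternoon_effect_days %||% all_days,
            phase_effect_days = phase_effect_days %||% all_days,
            sleep_threshold_min = as.integer(sleep_threshold_min),
            enforce_scoring = isTRUE(enforce_scoring),
            start_date = start_date, lights_on = lights_on, seed = seed)
  class(p) <- "behavior_params"
  p
}

# crepuscular Poisson rate template for one day, per minute (ZT 0..23:59)
# dphi > 0 advances the evening ramp/peak; regime "DD" drops startle
wake_rate_template <- function(p, dphi = 0, regime = "LD") {
  zt <- (0:1439) / 60
  peak_hr <- 12 - dphi
  rs <- p$ramp_start_hr - dphi
  circ <- pmin(zt, 24 - zt)              # circular distance to ZT0
  lam <- p$lambda0 +
    p$morning_amp * exp(-0.5 * (circ / p$morning_width_hr)^2)
  ramp <- zt >= rs & zt < peak_hr
  lam[ramp] <- lam[ramp] + p$evening_ramp_slope * (zt[ramp] - rs)
  lam[zt >= peak_hr] <- p$lambda_night
  if (regime == "LD") {
    lam[1] <- lam[1] + p$startle_amp                       # lights-on
    lam[721] <- lam[721] + p$startle_amp                   # lights-off
  }
  lam
}

# bout length >= threshold: threshold + rounded exponential tail
rbout <- function(mean_min, threshold) {
  threshold + round(rexp(1, 1 / max(mean_min - threshold, 1)))
}

rgap <- function(mean_min) 1L + rpois(1, max(mean_min - 1, 0))

# one fly-day: returns list(sleep logical(1440), onset_latency_min,
# onset_start_min or NA)
sim_fly_day <- function(p, day) {
  thr <- p$sleep_threshold_min
  dphi <- if (day %in% p$phase_effect_days) p$delta_phase_hr else 0
  sleep <- logical(1440)

  # siesta bouts
  s0 <- as.integer(p$siesta$start_hr * 60) +
    sample.int(15L, 1L)                  # per-day jitter of siesta start
  s1 <- as.integer(p$siesta$end_hr * 60)
  aft_effect <- day %in% p$afternoon_effect_days && p$delta_afternoon_wake > 0
  t <- s0
  while (t + thr <= s1) {
    len <- min(rbout(p$siesta$bout_mean_min, thr), s1 - t)
    if (len >= thr) {
      overlaps_aft <- (t + len) > 360L     # bout touches ZT6-12
      drop <- aft_effect && overlaps_aft &&
        runif(1) < p$delta_afternoon_wake
      if (!drop) sleep[(t + 1L):(t + len)] <- TRUE
    }
    t <- t + len + rgap(p$siesta$gap_mean_min)
  }

  # night: first bout after the (possibly advanced) evening peak
  dusk_eff <- as.integer(round((12 - dphi) * 60))
  m <- p$onset$mean_min +
    if (day %in% p$onset_effect_days) p$delta_onset_min else 0
  lat <- if (p$onset$sd_min == 0) m else {
    shape <- (m / p$onset$sd_min)^2
    rgamma(1, shape = shape, rate = shape / max(m, 1e-9))
  }
  lat <- max(0, round(lat))
  t <- dusk_eff + as.integer(lat)
  onset_start <- if (t < 1440L) t else NA_integer_
  while (t + thr <= 1440L) {
    len <- min(rbout(p$night$bout_mean_min, thr), 1440L - t)
    if (len >= thr) sleep[(t + 1L):(t + len)] <- TRUE
    t <- t + len + rgap(p$night$gap_mean_min)
  }
  list(sleep = sleep, onset_latency_min = lat, onset_start_min = onset_start,
       dphi = dphi)
}

# enforce exact agreement between generated truth and the scoring rule:
# wake zeros adjacent to a sleep bout are bumped to 1; remaining wake
# zero-runs of >= threshold are broken every threshold-th minute
enforce_scoring_consistency <- function(counts, sleep, thr) {
  n <- length(counts)
  wake_zero <- counts == 0L & !sleep
  adj <- wake_zero &
    (c(FALSE, sleep[-n]) | c(sleep[-1], FALSE))
  counts[adj] <- 1L
  wake_zero <- counts == 0L & !sleep
  r <- rle(wake_zero)
  pos <- cumsum(r$lengths) - r$lengths
  for (i in which(r$values & r$lengths >= thr)) {
    bump <- pos[i] + seq(thr, r$lengths[i], by = thr)
    counts[bump] <- 1L
  }
  counts
}

#' Generate synthetic DAM monitor data with ground truth
#'
#' @param params a [behavior_params()] object.
#' @return List of class `behavior_sim`:
#'   `monitor` ([monitor_data()], 32 channels; unused channels all zero),
#'   `schedule` (matching [light_schedule()]),
#'   `truth` (data frame per fly-day: onset latency/ZT, true sleep minutes
#'   total and in ZT0-6 / ZT6-12 / ZT12-24, injected ramp slope and peak
#'   phase), and `sleep` (list per fly of the true per-minute indicator).
#' @export
generate_behavior <- function(params) {
  stopifnot(inherits(params, "behavior_params"))
  p <- params
  with_seed(p$seed, {
    nmin <- p$n_days * 1440L
    counts <- matrix(0L, nmin, 32L)
    sleep_list <- vector("list", p$n_flies)
    rows <- list()
    for (f in seq_len(p$n_flies)) {
      fly_sleep <- logical(nmin)
      fly_counts <- integer(nmin)
      for (d in seq_len(p$n_days)) {
        sim <- sim_fly_day(p, d)
        lam <- wake_rate_template(p, sim$dphi, p$regime[d])
        idx <- ((d - 1L) * 1440L + 1L):(d * 1440L)
        cc <- integer(1440L)
        wake <- !sim$sleep
        cc[wake] <- rpois(sum(wake), lam[wake])
        fly_sleep[idx] <- sim$sleep
        fly_counts[idx] <- cc
        zt_min <- 0:1439
        rows[[length(rows) + 1L]] <- data.frame(
          fly = sprintf("ch%02d", f), day = d, day_tag = p$day_tags[d],
          regime = p$regime[d],
          onset_latency_min = sim$onset_latency_min,
          onset_zt_hr = if (is.na(sim$onset_start_min)) NA_real_
                        else sim$onset_start_min / 60,
          sleep_min_total = sum(sim$sleep),
          sleep_min_ZT0_6 = sum(sim$sleep[zt_min < 360]),
          sleep_min_ZT6_12 = sum(sim$sleep[zt_min >= 360 & zt_min < 720]),
          sleep_min_ZT12_24 = sum(sim$sleep[zt_min >= 720]),
          true_slope = p$evening_ramp_slope,
          true_peak_zt_hr = 12 - sim$dphi,
          stringsAsFactors = FALSE)
      }
      if (p$enforce_scoring)
        fly_counts <- enforce_scoring_consistency(fly_counts, fly_sleep,
                                                  p$sleep_threshold_min)
      counts[, f] <- fly_counts
      sleep_list[[f]] <- fly_sleep
    }
    t0 <- as.POSIXct(paste(p$start_date, p$lights_on), tz = "UTC")
    mon <- monitor_data(t0 + 60 * (0:(nmin - 1L)), counts)
    sched <- light_schedule(p$lights_on, 12, p$day_tags, p$regime,
                            p$temperature_c)
    truth <- do.call(rbind, rows)
    names(sleep_list) <- sprintf("ch%02d", seq_len(p$n_flies))
    structure(list(monitor = mon, schedule = sched, truth = truth,
                   sleep = sleep_list, params = p),
              class = "behavior_sim")
  })
}

#' @export
print.behavior_sim <- function(x, ...) {
  cat("<behavior_sim> ", x$params$n_flies, " flies x ", x$params$n_days,
      " day(s) [", paste(x$params$day_tags, collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}
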