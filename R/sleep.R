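# Sleep scoring under the 5-min inactivity rule and derived metrics.

#' Score sleep from per-minute activity counts
#'
#' A minute is sleep iff it lies in a maximal run of zero-count minutes of
#' length at least `threshold_min` (default 5, the standard inactivity
#' rule). Flagged minutes (e.g. monitor status errors) break runs and are
#' never scored as sleep.
#'
#' @param counts non-negative per-minute counts.
#' @param threshold_min minimum run length in minutes, >= 1.
#' @param flagged optional logical vector marking invalid minutes.
#' @return Logical vector of the same length: `TRUE` = asleep.
#' @export
score_sleep <- function(counts, threshold_min = 5L, flagged = NULL) {
  threshold_min <- as.integer(threshold_min)
  if (threshold_min < 1L) stop("threshold_min must be >= 1")
  if (length(counts) == 0) return(logical(0))
  if (any(counts < 0)) stop("counts must be non-negative")
  flagged <- flagged %||% rep(FALSE, length(counts))
  zero <- counts == 0 & !flagged
  r <- rle(zero)
  r$values <- r$values & r$lengths >= threshold_min
  inverse.rle(r)
}

#' Extract sleep bouts from a sleep indicator
#'
#' Maximal sleep runs become bouts; runs crossing a protocol-day boundary
#' are split at the boundary with both fragments retained and the linkage
#' recorded.
#'
#' @param sleep logical per-minute sleep indicator (from [score_sleep()]);
#'   length a multiple of `day_minutes` (trailing partial day allowed).
#' @param day_minutes minutes per protocol day. Default 1440.
#' @param fly_id optional label attached to the result.
#' @return Data frame with columns `day`, `start_min` and `end_min`
#'   (ZT minutes within the day, half-open), `duration_min`,
#'   `continues_from_prev`, `continues_to_next`.
#' @export
extract_bouts <- function(sleep, day_minutes = 1440L, fly_id = NULL) {
  n <- length(sleep)
  if (n == 0)
    return(structure(data.frame(day = integer(0), start_min = integer(0),
                                end_min = integer(0), duration_min = integer(0),
                                continues_from_prev = logical(0),
                                continues_to_next = logical(0)),
                     fly_id = fly_id))
  r <- rle(as.logical(sleep))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ss <- starts[r$values]
  ee <- ends[r$values]
  out <- list()
  for (i in seq_along(ss)) {
    s <- ss[i] - 1L              # 0-based global minute
    e <- ee[i]                   # exclusive
    d0 <- s %/% day_minutes
    d1 <- (e - 1L) %/% day_minutes
    for (d in d0:d1) {
      fs <- max(s, d * day_minutes)
      fe <- min(e, (d + 1L) * day_minutes)
      out[[length(out) + 1L]] <- data.frame(
        day = d + 1L,
        start_min = fs - d * day_minutes,
        end_min = fe - d * day_minutes,
        duration_min = fe - fs,
        continues_from_prev = fs == d * day_minutes && s < d * day_minutes,
        continues_to_next = fe == (d + 1L) * day_minutes &&
          e > (d + 1L) * day_minutes)
    }
  }
  if (length(out) == 0)
    return(structure(data.frame(day = integer(0), start_min = integer(0),
                                end_min = integer(0),
                                duration_min = integer(0),
                                continues_from_prev = logical(0),
                                continues_to_next = logical(0)),
                     fly_id = fly_id))
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  structure(res, fly_id = fly_id)
}

#' Sleep onset latency after dusk
#'
#' Re-scores sleep on the segment from dusk to the end of the day and
#' returns the ZT (hours) of the first minute of the first qualifying run.
#' A bout straddling dusk therefore yields onset exactly at dusk
#' (`straddle = "dusk"`, the default); with `straddle = "exclude"` such a
#' day returns `NA` instead. No qualifying post-dusk run returns `NA`.
#'
#' @param counts per-minute counts for one full protocol day (1440 min).
#' @param dusk_zt_hr dusk in ZT hours, in \[0, 24). Default 12.
#' @param threshold_min sleep-run threshold, as in [score_sleep()].
#' @param flagged optional logical flags for the same day.
#' @param straddle `"dusk"` or `"exclude"`; see Details.
#' @return Onset as ZT hours (>= `dusk_zt_hr`), or `NA_real_`.
#' @export
sleep_onset_after_dusk <- function(counts, dusk_zt_hr = 12,
                                   threshold_min = 5L, flagged = NULL,
                                   straddle = c("dusk", "exclude")) {
  straddle <- match.arg(straddle)
  if (!(dusk_zt_hr >= 0 && dusk_zt_hr < 24))
    stop("dusk_zt_hr must be in [0, 24)")
  if (length(counts) != 1440L)
    stop("counts must be one full day (1440 minutes)")
  flagged <- flagged %||% rep(FALSE, 1440L)
  dusk_min <- as.integer(round(dusk_zt_hr * 60))
  seg <- (dusk_min + 1L):1440L
  sl <- score_sleep(counts[seg], threshold_min, flagged[seg])
  first <- match(TRUE, sl)
  if (is.na(first)) return(NA_real_)
  if (straddle == "exclude" && first == 1L && dusk_min >= 1L &&
      counts[dusk_min] == 0 && !flagged[dusk_min])
    return(NA_real_)
  (dusk_min + first - 1L) / 60
}

#' Minutes of sleep inside a ZT window
#'
#' Counts sleep minutes whose ZT lies in the half-open window
#' \[start, end). Additive over a partition of the day.
#'
#' @param sleep logical per-minute sleep indicator for one day (1440 min)
#'   or several whole days.
#' @param window a [window_spec()] or `c(start_hr, end_hr)`.
#' @return Total sleep minutes in the window (summed over days).
#' @export
sleep_amount <- function(sleep, window) {
  w <- as_window(window)
  n <- length(sleep)
  if (n == 0) return(0L)
  zt_min <- (seq_len(n) - 1L) %% 1440L
  lo <- round(w$start * 60); hi <- round(w$end * 60)
  sum(sleep & zt_min >= lo & zt_min < hi)
}

#' Change in windowed sleep between two days
#'
#' `sleep_amount(manipulation) - sleep_amount(baseline)`; negative values
#' mean sleep loss under the manipulation.
#'
#' @param manipulation_sleep,baseline_sleep per-minute sleep indicators for
#'   one day each (1440 min).
#' @param window a ZT window as in [sleep_amount()].
#' @param fly_id label used in error messages.
#' @return Difference in minutes.
#' @export
sleep_change <- function(manipulation_sleep, baseline_sleep, window,
                         fly_id = "fly") {
  if (is.null(manipulation_sleep) || is.null(baseline_sleep) ||
      length(manipulation_sleep) != 1440L || length(baseline_sleep) != 1440L)
    stop("pairing error: ", fly_id,
         " is missing a full baseline or manipulation day")
  sleep_amount(manipulation_sleep, window) -
    sleep_amount(baseline_sleep, window)
}

#' Cohort sleep profile in fixed bins
#'
#' @param cohort list of per-minute logical sleep indicators (equal
#'   lengths, whole days; may span multiple days for a 48-h profile).
#' @param bin_minutes bin width; must divide 1440. Default 30.
#' @return Data frame with one row per bin: `zt_hr` (bin start, running
#'   across days), `mean` sleep min/bin across flies, `sem`, `n`, plus a
#'   `per_fly` matrix attribute (bins x flies).
#' @export
sleep_profile <- function(cohort, bin_minutes = 30L) {
  stopifnot(length(cohort) >= 1)
  bin_minutes <- as.integer(bin_minutes)
  if (1440L %% bin_minutes != 0L) stop("bin_minutes must divide 1440")
  n <- length(cohort[[1]])
  if (any(lengths(cohort) != n)) stop("all flies must have equal length")
  nb <- n %/% bin_minutes
  per_fly <- vapply(cohort, function(s)
    as.numeric(tapply(as.numeric(s), rep(seq_len(nb), each = bin_minutes),
                      sum)), numeric(nb))
  per_fly <- matrix(per_fly, nrow = nb)
  m <- rowMeans(per_fly)
  sem <- if (ncol(per_fly) > 1) apply(per_fly, 1, sd) / sqrt(ncol(per_fly))
         else rep(NA_real_, nb)
  structure(data.frame(zt_hr = (seq_len(nb) - 1L) * bin_minutes / 60,
                       mean = m, sem = sem, n = ncol(per_fly)),
            per_fly = per_fly)
}

# per-day sleep indicators for a fly_series, honoring flagged minutes
fly_sleep_days <- function(series, threshold_min = 5L) {
  stopifnot(inherits(series, "fly_series"))
  sl <- score_sleep(series$counts, threshold_min, series$flagged)
  lapply(seq_len(series$n_days), function(d)
    sl[((d - 1L) * 1440L + 1L):(d * 1440L)])
}

#' Dead-fly filter
#'
#' Flies with zero counts over the final `window_hr` hours of the protocol
#' are presumed dead and excluded from all metrics.
#'
#' @param series a `fly_series`.
#' @param window_hr trailing window, hours. Default 12.
#' @return `TRUE` if the fly is alive (any count in the window).
#' @export
is_alive <- function(series, window_hr = 12) {
  n <- length(series$counts)
  k <- min(n, as.integer(round(window_hr * 60)))
  sum(series$counts[(n - k + 1L):n]) > 0
}
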