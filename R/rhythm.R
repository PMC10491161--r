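# Evening anticipation slope and evening peak phase from binned activity.

#' Evening anticipation slope
#'
#' Ordinary least-squares slope of mean activity (counts/min per bin)
#' against bin-start ZT over the window `[transition - window_hr,
#' transition)`, computed per analysis day and averaged across days. The
#' half-open window excludes the bin containing the light transition, so
#' lights-off startle artifacts never enter the fit.
#'
#' @param series a `fly_series` from [to_fly_series()].
#' @param transition_zt_hr the light transition anticipated (dusk = 12).
#' @param window_hr window length before the transition. Default 3
#'   (ZT9-12 for dusk).
#' @param bin_minutes bin width; >= 2 bins must fit in the window.
#' @param days day tags to include; default all tags except `"discard"`.
#' @return List of class `anticipation_result`: `slope` (counts/min per
#'   hour, averaged over days), `per_day` slopes, `window`, `n_days`. The
#'   slope is `NA` with a reason if every window minute is flagged.
#' @export
anticipation_slope <- function(series, transition_zt_hr = 12, window_hr = 3,
                               bin_minutes = 30L, days = NULL) {
  stopifnot(inherits(series, "fly_series"))
  nb_win <- window_hr * 60 / bin_minutes
  if (nb_win < 2) stop("window must contain at least 2 bins")
  b <- bin_series(series, bin_minutes)
  keep_tags <- days %||% setdiff(unique(series$day_tags), "discard")
  lo <- transition_zt_hr - window_hr
  sel_day <- function(d) {
    w <- b[b$day == d & b$day_tag %in% keep_tags &
             b$zt_hr >= lo & b$zt_hr < transition_zt_hr, ]
    if (nrow(w) == 0 || all(is.na(w$mean_counts))) return(NA_real_)
    w <- w[!is.na(w$mean_counts), ]
    if (nrow(w) < 2) return(NA_real_)
    unname(coef(lm(mean_counts ~ zt_hr, data = w))[2])
  }
  days_used <- which(series$day_tags %in% keep_tags)
  per_day <- vapply(days_used, sel_day, numeric(1))
  names(per_day) <- days_used
  slope <- if (all(is.na(per_day))) NA_real_ else mean(per_day, na.rm = TRUE)
  structure(list(fly_id = series$fly_id, slope = slope, per_day = per_day,
                 window = c(lo, transition_zt_hr), n_days = sum(!is.na(per_day)),
                 reason = if (is.na(slope)) "all window minutes flagged/missing"
                          else NULL),
            class = "anticipation_result")
}

#' @export
print.anticipation_result <- function(x, ...) {
  cat("<anticipation_result> ", x$fly_id, ": slope ",
      formatC(x$slope, digits = 3, format = "g"),
      " counts/min/hr over ZT", x$window[1], "-", x$window[2],
      " (", x$n_days, " day(s))\n", sep = "")
  invisible(x)
}

#' Evening peak activity phase
#'
#' Bins the daily activity profile, smooths it with a centered circular
#' moving average, and reports the bin-start ZT of the maximum inside the
#' search window (ties resolved to the earliest bin). Per-day phases are
#' averaged arithmetically after confirming all lie within the search
#' window; a profile constant over the window yields an undefined phase,
#' flagged in the result.
#'
#' The moving-average width is the nearest odd number of bins covering
#' `smooth_hr` (2 h at 30-min bins uses 5 bins).
#'
#' @param series a `fly_series`.
#' @param search search window in ZT hours, default `c(6, 14)` (spans the
#'   pre- and post-dusk peaks so phase advances are detectable).
#' @param smooth_hr smoothing width in hours. Default 2.
#' @param bin_minutes bin width. Default 30.
#' @param days day tags to include; default all except `"discard"`.
#' @return List of class `phase_result`: `phase_zt_hr` (mean over days),
#'   `per_day`, `undefined` flag, smoothing settings.
#' @export
evening_peak_phase <- function(series, search = c(6, 14), smooth_hr = 2,
                               bin_minutes = 30L, days = NULL) {
  stopifnot(inherits(series, "fly_series"))
  w <- as_window(search)
  nb <- 1440L %/% as.integer(bin_minutes)
  half <- floor(smooth_hr * 60 / bin_minutes / 2)
  width <- 2L * half + 1L
  b <- bin_series(series, bin_minutes)
  keep_tags <- days %||% setdiff(unique(series$day_tags), "discard")
  starts <- (seq_len(nb) - 1L) * bin_minutes / 60
  in_win <- starts >= w$start & starts < w$end
  if (!any(in_win)) stop("search window contains no bins")
  per_day <- rep(NA_real_, series$n_days)
  undef <- rep(FALSE, series$n_days)
  for (d in which(series$day_tags %in% keep_tags)) {
    prof <- b$mean_counts[b$day == d]
    prof[is.na(prof)] <- 0
    # centered circular moving average
    ext <- c(utils::tail(prof, half), prof, utils::head(prof, half))
    sm <- stats::filter(ext, rep(1 / width, width), sides = 2)
    sm <- as.numeric(sm[(half + 1L):(half + nb)])
    seg <- sm[in_win]
    if (diff(range(seg)) == 0) { undef[d] <- TRUE; next }
    per_day[d] <- starts[in_win][which.max(seg)]
  }
  used <- !is.na(per_day)
  structure(list(fly_id = series$fly_id,
                 phase_zt_hr = if (any(used)) mean(per_day[used]) else NA_real_,
                 per_day = per_day,
                 undefined = all(!used),
                 search = c(w$start, w$end), smooth_hr = smooth_hr,
                 bin_minutes = bin_minutes),
            class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  if (x$undefined)
    cat("<phase_result> ", x$fly_id, ": undefined (constant profile)\n",
        sep = "")
  else
    cat("<phase_result> ", x$fly_id, ": evening peak at ZT",
        formatC(x$phase_zt_hr, digits = 4, format = "g"), "\n", sep = "")
  invisible(x)
}
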