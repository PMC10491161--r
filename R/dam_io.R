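# DAM2 monitor file I/O.
#
# Column map of the DAM2 dialect (42 tab-separated columns, no header):
#   1      reading index
#   2      date, "d Mon yy" (e.g. "1 Jan 24"); month abbreviations are
#          written/parsed locale-independently
#   3      time, "HH:MM:SS" (1-min resolution)
#   4      status code (1 = valid reading)
#   5-10   six extended-status fields, recorded verbatim
#   11-42  beam-break counts for channels 1-32
.DAM2_META_COLS <- 10L
.DAM2_N_CHANNELS <- 32L
.DAM2_MONTHS <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                  "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' Construct a DAM monitor data object
#'
#' Container for one Trikinetics DAM monitor: per-minute timestamped
#' beam-break counts for 32 channels plus the verbatim status fields.
#'
#' @param timestamp `POSIXct` vector, one per reading, 1-min resolution.
#' @param counts integer matrix, one row per reading, 32 columns.
#' @param status integer vector of status codes (1 = valid). Default all 1.
#' @param index integer reading indices. Default `seq_along(timestamp)`.
#' @param extras integer matrix of the six extended-status fields.
#'   Default all zero.
#' @return An object of class `monitor_data` with fields `index`,
#'   `timestamp`, `status`, `extras`, `counts`, and a `report` list
#'   flagging non-1 status rows and timestamp gaps.
#' @export
monitor_data <- function(timestamp, counts, status = NULL, index = NULL,
                         extras = NULL) {
  n <- length(timestamp)
  counts <- as.matrix(counts)
  if (n > 0 && ncol(counts) != .DAM2_N_CHANNELS)
    stop("counts must have ", .DAM2_N_CHANNELS, " columns")
  if (n > 0 && nrow(counts) != n)
    stop("counts rows must match timestamps")
  if (any(counts < 0)) stop("counts must be non-negative")
  status <- status %||% rep(1L, n)
  index <- index %||% seq_len(n)
  extras <- extras %||% matrix(0L, n, 6L)
  if (n > 1 && any(diff(as.numeric(timestamp)) <= 0))
    stop("timestamps must be strictly increasing")
  gaps <- if (n > 1) which(diff(as.numeric(timestamp)) != 60) else integer(0)
  structure(list(
    index = as.integer(index),
    timestamp = timestamp,
    status = as.integer(status),
    extras = extras,
    counts = counts,
    channel_ids = seq_len(.DAM2_N_CHANNELS),
    report = list(n_rows = n,
                  flagged_rows = which(status != 1L),
                  gap_after_rows = gaps)
  ), class = "monitor_data")
}

#' @export
print.monitor_data <- function(x, ...) {
  cat("<monitor_data> ", x$report$n_rows, " readings, 32 channels\n", sep = "")
  if (x$report$n_rows > 0)
    cat("  span: ", format(x$timestamp[1]), " .. ",
        format(x$timestamp[x$report$n_rows]), "\n", sep = "")
  if (length(x$report$flagged_rows))
    cat("  flagged (status != 1): ", length(x$report$flagged_rows),
        " rows\n", sep = "")
  if (length(x$report$gap_after_rows))
    cat("  timestamp gaps after rows: ",
        paste(utils::head(x$report$gap_after_rows, 5), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

.dam2_format_date <- function(tt) {
  lt <- as.POSIXlt(tt, tz = "UTC")
  sprintf("%d %s %02d", lt$mday, .DAM2_MONTHS[lt$mon + 1L],
          lt$year %% 100L)
}

.dam2_parse_datetime <- function(date_str, time_str, lines = NULL) {
  parts <- strsplit(date_str, " ", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed date field at line(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  m <- vapply(parts, function(p) match(p[2], .DAM2_MONTHS), 0L)
  if (anyNA(m))
    stop("unknown month abbreviation at line(s) ",
         paste(utils::head(which(is.na(m)), 5), collapse = ", "))
  d <- as.integer(vapply(parts, `[`, "", 1L))
  y <- as.integer(vapply(parts, `[`, "", 3L))
  y <- ifelse(y < 70L, 2000L + y, 1900L + y)
  as.POSIXct(sprintf("%04d-%02d-%02d %s", y, m, d, time_str),
             tz = "UTC")
}

#' Read a Trikinetics DAM2 monitor file
#'
#' Parses the classic 42-column tab-delimited DAM2 layout (see the column
#' map in the package source). Rows whose status code is not 1 are kept and
#' flagged in the parse report; downstream metrics exclude flagged minutes.
#'
#' @param path path to a DAM2 text file.
#' @param dialect only `"DAM2"` is supported.
#' @return A [monitor_data()] object.
#' @export
read_dam_monitor <- function(path, dialect = "DAM2") {
  dialect <- match.arg(dialect, "DAM2")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(monitor_data(as.POSIXct(character(0), tz = "UTC"),
                        matrix(integer(0), 0, .DAM2_N_CHANNELS)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- .DAM2_META_COLS + .DAM2_N_CHANNELS
  short <- lengths(fields) < ncols
  if (any(short))
    stop("format error: fewer than ", ncols, " columns at line(s) ",
         paste(utils::head(which(short), 5), collapse = ", "))
  mat <- matrix(unlist(lapply(fields, `[`, seq_len(ncols))),
                nrow = length(fields), byrow = TRUE)
  cnt_chr <- mat[, (.DAM2_META_COLS + 1L):ncols, drop = FALSE]
  suppressWarnings(cnt <- matrix(as.integer(cnt_chr), nrow = nrow(mat)))
  if (anyNA(cnt)) {
    bad <- which(is.na(cnt), arr.ind = TRUE)[1, ]
    stop("parse error: non-integer count at line ", bad[1],
         ", count column ", bad[2])
  }
  suppressWarnings({
    idx <- as.integer(mat[, 1])
    status <- as.integer(mat[, 4])
    extras <- matrix(as.integer(mat[, 5:10]), nrow = nrow(mat))
  })
  if (anyNA(idx) || anyNA(status))
    stop("parse error: non-integer metadata field")
  tt <- .dam2_parse_datetime(mat[, 2], mat[, 3])
  monitor_data(tt, cnt, status = status, index = idx, extras = extras)
}

#' Write a Trikinetics DAM2 monitor file
#'
#' Inverse of [read_dam_monitor()]: `read_dam_monitor(write_dam_monitor(x))`
#' reproduces `x`, and for files produced by this writer the round trip is
#' byte-identical.
#'
#' @param data a [monitor_data()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(data, path) {
  stopifnot(inherits(data, "monitor_data"))
  n <- data$report$n_rows
  if (n == 0) {
    ok <- tryCatch({writeLines(character(0), path); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("I/O error: cannot write ", path)
    return(invisible(path))
  }
  lt <- as.POSIXlt(data$timestamp, tz = "UTC")
  lines <- paste(
    data$index,
    .dam2_format_date(data$timestamp),
    sprintf("%02d:%02d:%02d", lt$hour, lt$min, as.integer(lt$sec)),
    data$status,
    apply(data$extras, 1, paste, collapse = "\t"),
    apply(data$counts, 1, paste, collapse = "\t"),
    sep = "\t")
  ok <- tryCatch({writeLines(lines, path); TRUE}, error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

#' Declare a light/temperature schedule
#'
#' Defines zeitgeber time (ZT0 = lights-on) and tags each protocol day.
#' Under DD, circadian time continues from the entrained phase, so the
#' projected lights-on still defines CT0 and the same mapping applies.
#'
#' @param lights_on lights-on clock time, `"HH:MM:SS"` or fractional hours.
#' @param photoperiod_hr hours of light per cycle, in (0, 24). Default 12.
#' @param day_tags character vector tagging each protocol day, e.g.
#'   `c("baseline", "manipulation")`; `"discard"` days are dropped from
#'   analysis.
#' @param regime per-day light regime, `"LD"` or `"DD"`; recycled.
#' @param temperature_c per-day temperature label in degrees C; recycled.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(lights_on = "08:00:00", photoperiod_hr = 12,
                           day_tags = "baseline", regime = "LD",
                           temperature_c = 22) {
  if (is.character(lights_on)) {
    p <- as.integer(strsplit(lights_on, ":", fixed = TRUE)[[1]])
    p <- c(p, 0L, 0L)[1:3]
    lights_on <- p[1] + p[2] / 60 + p[3] / 3600
  }
  stopifnot(lights_on >= 0, lights_on < 24)
  if (!(photoperiod_hr > 0 && photoperiod_hr < 24))
    stop("photoperiod must be in (0, 24)")
  n <- length(day_tags)
  regime <- rep_len(match.arg(regime, c("LD", "DD"), several.ok = TRUE), n)
  structure(list(lights_on_hr = lights_on,
                 photoperiod_hr = photoperiod_hr,
                 day_tags = day_tags,
                 regime = regime,
                 temperature_c = rep_len(temperature_c, n)),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat("<light_schedule> lights-on ", sprintf("%05.2f", x$lights_on_hr),
      " h, ", x$photoperiod_hr, ":", 24 - x$photoperiod_hr, " cycle\n",
      sep = "")
  cat("  days: ", paste(sprintf("%s[%s,%g°C]", x$day_tags, x$regime,
                                x$temperature_c), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Extract one fly's ZT-aligned minute series
#'
#' Maps clock time to zeitgeber time, `ZT = (clock - lights_on) mod 24`,
#' keeps only whole protocol days (first ZT0 to the last complete day) and
#' attaches per-day tags from the schedule. Partial leading/trailing data
#' are dropped and reported. Minutes whose status code is not 1 are carried
#' as flagged.
#'
#' @param data a [monitor_data()] object.
#' @param schedule a [light_schedule()] covering the retained days.
#' @param channel channel number 1-32.
#' @return An object of class `fly_series`: per-minute `counts` (length a
#'   multiple of 1440), logical `flagged`, `day_tags`, `regime`, and a
#'   `dropped` report.
#' @export
to_fly_series <- function(data, schedule, channel) {
  stopifnot(inherits(data, "monitor_data"), inherits(schedule, "light_schedule"))
  if (!(channel %in% data$channel_ids))
    stop("lookup error: channel ", channel, " not present")
  n <- data$report$n_rows
  if (n == 0) stop("empty monitor data")
  lt <- as.POSIXlt(data$timestamp, tz = "UTC")
  clock_hr <- lt$hour + lt$min / 60 + lt$sec / 3600
  zt_min <- round(((clock_hr - schedule$lights_on_hr) %% 24) * 60)
  zt_min <- as.integer(zt_min %% 1440L)
  first0 <- match(0L, zt_min)
  if (is.na(first0)) stop("coverage error: no ZT0 minute in data")
  n_days <- (n - first0 + 1L) %/% 1440L
  if (n_days < 1L) stop("coverage error: less than one whole ZT day")
  if (length(schedule$day_tags) < n_days)
    stop("coverage error: schedule declares ", length(schedule$day_tags),
         " day(s) but data span ", n_days)
  keep <- first0:(first0 + n_days * 1440L - 1L)
  if (any(diff(as.numeric(data$timestamp[keep])) != 60))
    stop("coverage error: timestamp gap within retained days")
  structure(list(
    fly_id = sprintf("ch%02d", channel),
    channel = as.integer(channel),
    counts = as.integer(data$counts[keep, channel]),
    flagged = data$status[keep] != 1L,
    n_days = n_days,
    day_tags = schedule$day_tags[seq_len(n_days)],
    regime = schedule$regime[seq_len(n_days)],
    dropped = list(leading_min = first0 - 1L,
                   trailing_min = n - (first0 + n_days * 1440L - 1L))
  ), class = "fly_series")
}

#' @export
print.fly_series <- function(x, ...) {
  cat("<fly_series> ", x$fly_id, ": ", x$n_days, " day(s) [",
      paste(x$day_tags, collapse = ", "), "], ",
      sum(x$counts), " total counts\n", sep = "")
  invisible(x)
}

#' Bin a fly series into mean counts per minute
#'
#' @param series a [to_fly_series()] result.
#' @param bin_minutes bin width in minutes; must divide 1440.
#' @param use_flagged if `FALSE` (default) flagged minutes are excluded
#'   from bin means.
#' @return Data frame with one row per bin: `day`, `day_tag`, `zt_hr`
#'   (bin start), `mean_counts` (counts/min), `n_min` minutes used.
#' @export
bin_series <- function(series, bin_minutes = 30L, use_flagged = FALSE) {
  stopifnot(inherits(series, "fly_series"))
  bin_minutes <- as.integer(bin_minutes)
  if (bin_minutes < 1L || 1440L %% bin_minutes != 0L)
    stop("bin_minutes must be a positive divisor of 1440")
  nb <- 1440L %/% bin_minutes
  total <- series$n_days * nb
  bin_of <- rep(seq_len(total), each = bin_minutes)
  cnt <- as.numeric(series$counts)
  use <- if (use_flagged) rep(TRUE, length(cnt)) else !series$flagged
  s <- tapply(ifelse(use, cnt, 0), bin_of, sum)
  m <- tapply(use, bin_of, sum)
  data.frame(
    day = rep(seq_len(series$n_days), each = nb),
    day_tag = rep(series$day_tags, each = nb),
    zt_hr = rep((seq_len(nb) - 1L) * bin_minutes / 60, series$n_days),
    mean_counts = as.numeric(ifelse(m > 0, s / m, NA_real_)),
    n_min = as.integer(m),
    row.names = NULL)
}
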