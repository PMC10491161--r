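# Independent brute-force oracles used to validate the package
# implementations. These deliberately use naive algorithms (explicit
# scans, hand arithmetic) distinct from the package's code paths.

# sleep scoring by explicit run scan: walk the minutes, accumulate zero
# runs, mark a run as sleep when it closes with length >= threshold
oracle_score_sleep <- function(counts, threshold = 5L, flagged = NULL) {
  n <- length(counts)
  if (is.null(flagged)) flagged <- rep(FALSE, n)
  out <- logical(n)
  run_start <- NA_integer_
  for (i in seq_len(n)) {
    zero <- counts[i] == 0 && !flagged[i]
    if (zero && is.na(run_start)) run_start <- i
    if (!zero && !is.na(run_start)) {
      if (i - run_start >= threshold) out[run_start:(i - 1L)] <- TRUE
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start) && n - run_start + 1L >= threshold)
    out[run_start:n] <- TRUE
  out
}

# run-length encoding of sleep bouts by explicit scan (no day split)
oracle_bouts <- function(sleep) {
  n <- length(sleep)
  res <- NULL
  s <- NA_integer_
  for (i in seq_len(n)) {
    if (sleep[i] && is.na(s)) s <- i
    if (!sleep[i] && !is.na(s)) {
      res <- rbind(res, c(s, i - 1L)); s <- NA_integer_
    }
  }
  if (!is.na(s)) res <- rbind(res, c(s, n))
  res
}

# mean-per-bin by explicit loop
oracle_bin_means <- function(x, width) {
  nb <- length(x) %/% width
  vapply(seq_len(nb), function(b)
    mean(x[((b - 1) * width + 1):(b * width)]), numeric(1))
}

# OLS slope via the normal equations
oracle_ols_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# circular moving-average smoothing then windowed argmax (earliest tie)
oracle_peak_phase <- function(prof, starts, half, lo, hi) {
  nb <- length(prof)
  sm <- numeric(nb)
  for (i in seq_len(nb)) {
    idx <- ((i - half - 1L):(i + half - 1L)) %% nb + 1L
    sm[i] <- mean(prof[idx])
  }
  inw <- which(starts >= lo & starts < hi)
  best <- inw[1]
  for (i in inw) if (sm[i] > sm[best]) best <- i
  starts[best]
}

# one-way ANOVA by hand: F, residual MS/df, planned pooled-MS t with
# Bonferroni over m comparisons
oracle_anova <- function(groups, pairs) {
  y <- unlist(groups); N <- length(y); k <- length(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1; df2 <- N - k
  mse <- ssw / df2
  Fv <- (ssb / df1) / mse
  pF <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  m <- nrow(pairs)
  post <- lapply(seq_len(m), function(i) {
    a <- groups[[pairs[i, 1]]]; b <- groups[[pairs[i, 2]]]
    t <- (mean(a) - mean(b)) / sqrt(mse * (1 / length(a) + 1 / length(b)))
    p <- 2 * stats::pt(-abs(t), df2)
    c(t = t, p = p, p_adj = min(1, m * p))
  })
  list(F = Fv, p = pF, mse = mse, df2 = df2, post = post)
}

# Kruskal-Wallis H and Dunn z by explicit rank arithmetic
oracle_kruskal_dunn <- function(groups, pairs) {
  y <- unlist(groups)
  N <- length(y)
  rk <- rank(y)
  sizes <- vapply(groups, length, 0L)
  names(sizes) <- names(groups)
  gidx <- factor(rep(names(groups), sizes), levels = names(groups))
  rsum <- tapply(rk, gidx, sum)
  H <- 12 / (N * (N + 1)) * sum(rsum^2 / sizes) - 3 * (N + 1)
  ties <- table(y)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  rbar <- rsum / sizes
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  m <- nrow(pairs)
  post <- lapply(seq_len(m), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    z <- (rbar[[a]] - rbar[[b]]) / sqrt(s2 * (1 / sizes[[a]] + 1 / sizes[[b]]))
    p <- 2 * stats::pnorm(-abs(z))
    c(z = z, p = p, p_adj = min(1, m * p))
  })
  list(H = H, post = post)
}

# build a fly_series through the real I/O path: counts for channel 1 of a
# monitor that starts exactly at lights-on
make_series <- function(counts, day_tags = NULL, status = NULL) {
  n_days <- length(counts) %/% 1440L
  day_tags <- day_tags %||% rep("baseline", n_days)
  cnt <- matrix(0L, length(counts), 32L)
  cnt[, 1] <- as.integer(counts)
  t0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
  mon <- monitor_data(t0 + 60 * (seq_along(counts) - 1L), cnt,
                      status = status)
  to_fly_series(mon, light_schedule("08:00:00", 12, day_tags), 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
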