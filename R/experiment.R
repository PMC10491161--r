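# Multi-genotype experiment scenarios: build synthetic cohorts with the
# phenotype injected only in the experimental group, run the full metric +
# statistics pipeline, and round-trip experiments through DAM files plus a
# plain-text config.

.SCENARIOS <- c("E1_silencing", "E1_activation_LD", "E1_activation_DD",
                "E2_clock_phase_advance", "null")

#' Build a three-genotype synthetic experiment
#'
#' Emits one experimental cohort and two genetic-control cohorts with the
#' scenario's phenotype injected only in the experimental group:
#' \describe{
#'   \item{E1_silencing}{constitutive (auxin-maintained) silencing: the
#'     post-dusk sleep-onset latency is increased by `delta_onset_min` on
#'     every protocol day (two LD days).}
#'   \item{E1_activation_LD}{thermogenetic activation: one 22 C baseline
#'     day then one hot day; afternoon (ZT6-12) sleep is suppressed with
#'     probability `delta_afternoon_wake` on the hot day only.}
#'   \item{E1_activation_DD}{the same protocol run in constant darkness:
#'     no effect is injected (activation in DD has no behavioral
#'     consequence).}
#'   \item{E2_clock_phase_advance}{short-period clock: the evening
#'     program is advanced by `delta_phase_hr` on every day.}
#'   \item{null}{no injected effect anywhere (calibration).}
#' }
#'
#' @param scenario one of the names above.
#' @param n_per_group flies per genotype (<= 32, one monitor each).
#' @param seed integer seed; the whole experiment is deterministic in it.
#' @param delta_onset_min onset delay injected by `E1_silencing`.
#'   Default 45.
#' @param delta_afternoon_wake afternoon sleep suppression probability for
#'   `E1_activation_LD`. Default 0.5.
#' @param delta_phase_hr evening phase advance for
#'   `E2_clock_phase_advance`. Default 1.
#' @param base overrides passed to [behavior_params()] for all groups.
#' @return List of class `dusk_experiment`: `groups` (named list of
#'   [generate_behavior()] results), `roles`, `schedule`, `scenario`,
#'   `metric` (the scenario's primary read-out).
#' @export
build_experiment <- function(scenario = .SCENARIOS, n_per_group = 32L,
                             seed = 1L, delta_onset_min = 45,
                             delta_afternoon_wake = 0.5,
                             delta_phase_hr = 1, base = list()) {
  scenario <- match.arg(scenario)
  labels <- c("GAL4>UAS", "GAL4/+", "UAS/+")
  roles <- c("experimental", "control", "control")
  names(roles) <- labels
  day_cfg <- switch(scenario,
    E1_silencing = list(day_tags = c("manipulation", "manipulation"),
                        regime = "LD", temperature_c = c(25, 25)),
    E1_activation_LD = list(day_tags = c("baseline", "manipulation"),
                            regime = "LD", temperature_c = c(22, 28)),
    E1_activation_DD = list(day_tags = c("baseline", "manipulation"),
                            regime = "DD", temperature_c = c(22, 28)),
    E2_clock_phase_advance = list(day_tags = c("baseline", "baseline"),
                                  regime = "LD", temperature_c = c(25, 25)),
    null = list(day_tags = c("baseline", "baseline"),
                regime = "LD", temperature_c = c(25, 25)))
  metric <- switch(scenario,
    E1_silencing = "onset", E1_activation_LD = "sleep_change",
    E1_activation_DD = "sleep_change",
    E2_clock_phase_advance = "phase", null = "onset")
  inject <- function(role) {
    if (role != "experimental" || scenario %in% c("null", "E1_activation_DD"))
      return(list())
    switch(scenario,
      E1_silencing = list(delta_onset_min = delta_onset_min),
      E1_activation_LD = list(delta_afternoon_wake = delta_afternoon_wake,
                              afternoon_effect_days = 2L),
      E2_clock_phase_advance = list(delta_phase_hr = delta_phase_hr))
  }
  with_seed(seed, {
    groups <- lapply(labels, function(lb) {
      args <- utils::modifyList(
        c(list(n_flies = n_per_group), day_cfg, base), inject(roles[[lb]]))
      generate_behavior(do.call(behavior_params, args))
    })
    names(groups) <- labels
    structure(list(groups = groups, roles = roles,
                   schedule = groups[[1]]$schedule, scenario = scenario,
                   metric = metric, seed = seed),
              class = "dusk_experiment")
  })
}

#' @export
print.dusk_experiment <- function(x, ...) {
  cat("<dusk_experiment> ", x$scenario, ": ",
      paste(sprintf("%s(%s)", names(x$roles), substr(x$roles, 1, 4)),
            collapse = ", "),
      "; primary metric: ", x$metric, "\n", sep = "")
  invisible(x)
}

# per-fly metric table for one cohort; `which_metrics` limits the costly
# columns computed (onset/slope/phase), the sleep columns are always cheap
cohort_metrics <- function(sim, group, role, threshold_min = 5L,
                           which_metrics = c("onset", "slope", "phase")) {
  sched <- sim$schedule
  rows <- lapply(seq_len(sim$params$n_flies), function(f) {
    fs <- to_fly_series(sim$monitor, sched, f)
    if (!is_alive(fs)) return(NULL)
    days <- fly_sleep_days(fs, threshold_min)
    onset <- slope <- phase <- NA_real_
    if ("onset" %in% which_metrics) {
      per_day <- vapply(seq_len(fs$n_days), function(d)
        sleep_onset_after_dusk(
          fs$counts[((d - 1) * 1440 + 1):(d * 1440)],
          flagged = fs$flagged[((d - 1) * 1440 + 1):(d * 1440)],
          threshold_min = threshold_min), numeric(1))
      onset <- if (all(is.na(per_day))) NA_real_
               else mean(per_day, na.rm = TRUE)
    }
    if ("slope" %in% which_metrics) slope <- anticipation_slope(fs)$slope
    if ("phase" %in% which_metrics) phase <- evening_peak_phase(fs)$phase_zt_hr
    base_d <- match("baseline", fs$day_tags)
    manip_d <- match("manipulation", fs$day_tags)
    schg <- if (!is.na(base_d) && !is.na(manip_d))
      sleep_change(days[[manip_d]], days[[base_d]], c(6, 12),
                   fly_id = fs$fly_id) else NA_real_
    aft <- sum(vapply(days, sleep_amount, 0L, window = c(6, 12)))
    data.frame(group = group, role = role, fly = fs$fly_id,
               onset = onset, slope = slope, phase = phase,
               sleep_change = schg, afternoon_sleep_min = aft,
               total_sleep_min = sum(unlist(days)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full metric + statistics pipeline on an experiment
#'
#' Computes per-fly metrics (post-dusk sleep onset, anticipation slope,
#' evening peak phase, windowed sleep change), applies the dead-fly
#' filter, runs the scenario's primary metric through the normality-gated
#' omnibus + post-hoc scheme (sleep onset is always routed nonparametric),
#' and issues the against-both-controls verdict. Entirely deterministic:
#' no randomness is used in the analysis.
#'
#' @param experiment a [build_experiment()] result (truth not consulted).
#' @param metric override the scenario's primary metric; one of
#'   `"onset"`, `"slope"`, `"phase"`, `"sleep_change"`.
#' @param alpha significance level. Default 0.05.
#' @param out_dir if non-`NULL`, write `metrics.csv`, `stats.csv` and
#'   `verdicts.csv` there (deterministic formatting).
#' @return List of class `dusk_analysis`: `metrics` (per-fly table),
#'   `report` (`stat_report`), `verdict`, `attrition`.
#' @export
run_experiment <- function(experiment, metric = NULL, alpha = 0.05,
                           out_dir = NULL) {
  stopifnot(inherits(experiment, "dusk_experiment"))
  metric <- metric %||% experiment$metric
  metric <- match.arg(metric, c("onset", "slope", "phase", "sleep_change"))
  tabs <- lapply(names(experiment$groups), function(g)
    cohort_metrics(experiment$groups[[g]], g, experiment$roles[[g]],
                   which_metrics = intersect(metric,
                                             c("onset", "slope", "phase"))))
  metrics <- do.call(rbind, tabs)
  vals <- split(metrics[[metric]], metrics$group)[names(experiment$groups)]
  attrition <- data.frame(
    group = names(experiment$groups),
    n_total = vapply(experiment$groups,
                     function(s) s$params$n_flies, 0L),
    n_alive = vapply(split(metrics$fly, metrics$group), length,
                     0L)[names(experiment$groups)],
    n_metric = vapply(vals, function(v) sum(!is.na(v)), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  design <- group_design(lapply(vals, function(v) v[!is.na(v)]),
                         unname(experiment$roles))
  report <- choose_test(design, force_nonparametric = metric == "onset",
                        alpha = alpha)
  verdict <- vs_both_controls(report)
  res <- structure(list(metrics = metrics, metric = metric, report = report,
                        verdict = verdict, attrition = attrition,
                        scenario = experiment$scenario),
                   class = "dusk_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fm <- function(d) { d[] <- lapply(d, function(col)
      if (is.numeric(col)) formatC(col, digits = 10, format = "g") else col)
      d }
    write.csv(fm(metrics), file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
    writeLines(format_stat_report(report), file.path(out_dir, "stats.csv"))
    write.csv(fm(verdict), file.path(out_dir, "verdicts.csv"),
              row.names = FALSE)
  }
  res
}

#' @export
print.dusk_analysis <- function(x, ...) {
  cat("<dusk_analysis> ", x$scenario, ", metric: ", x$metric, "\n", sep = "")
  print(x$report)
  for (i in seq_len(nrow(x$verdict)))
    cat("  verdict ", x$verdict$experimental[i], ": ",
        if (x$verdict$significant[i]) "significant vs both controls"
        else "not significant", "\n", sep = "")
  invisible(x)
}

#' Write an experiment to DAM files plus a plain-text config
#'
#' One DAM2 monitor file per genotype and a `config.txt` of tab-separated
#' `key value` lines (schedule, day tags, and per-group monitor file,
#' role and channel list).
#'
#' @param experiment a `dusk_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "dusk_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sched <- experiment$schedule
  lines <- c(
    paste("scenario", experiment$scenario, sep = "\t"),
    paste("lights_on_hr", sched$lights_on_hr, sep = "\t"),
    paste("photoperiod_hr", sched$photoperiod_hr, sep = "\t"),
    paste("day_tags", paste(sched$day_tags, collapse = ","), sep = "\t"),
    paste("regime", paste(sched$regime, collapse = ","), sep = "\t"),
    paste("temperature_c", paste(sched$temperature_c, collapse = ","),
          sep = "\t"))
  for (i in seq_along(experiment$groups)) {
    g <- names(experiment$groups)[i]
    fn <- sprintf("monitor%d.txt", i)
    write_dam_monitor(experiment$groups[[g]]$monitor, file.path(dir, fn))
    lines <- c(lines, paste("group", g, experiment$roles[[g]], fn,
                            paste0("1-", experiment$groups[[g]]$params$n_flies),
                            sep = "\t"))
  }
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read an experiment back from DAM files and config
#'
#' Inverse of [write_experiment()] up to ground truth (which is not
#' serialized): the returned experiment can be analysed with
#' [run_experiment()].
#'
#' @param dir directory containing `config.txt` and the monitor files.
#' @return A `dusk_experiment` (with empty `truth`/`sleep` slots).
#' @export
read_experiment <- function(dir) {
  cfg <- readLines(file.path(dir, "config.txt"))
  fields <- strsplit(cfg, "\t", fixed = TRUE)
  kv <- function(key) {
    hit <- fields[vapply(fields, function(f) f[1] == key, TRUE)]
    if (!length(hit)) stop("config missing key: ", key)
    hit
  }
  one <- function(key) kv(key)[[1]][2]
  sched <- light_schedule(
    as.numeric(one("lights_on_hr")), as.numeric(one("photoperiod_hr")),
    strsplit(one("day_tags"), ",")[[1]],
    strsplit(one("regime"), ",")[[1]],
    as.numeric(strsplit(one("temperature_c"), ",")[[1]]))
  scenario <- one("scenario")
  groups <- list(); roles <- character(0)
  for (f in kv("group")) {
    lab <- f[2]
    ch <- as.integer(strsplit(f[5], "-", fixed = TRUE)[[1]])
    mon <- read_dam_monitor(file.path(dir, f[4]))
    groups[[lab]] <- structure(
      list(monitor = mon, schedule = sched, truth = NULL, sleep = NULL,
           params = list(n_flies = ch[2])),
      class = "behavior_sim")
    roles[lab] <- f[3]
  }
  structure(list(groups = groups, roles = roles, schedule = sched,
                 scenario = scenario,
                 metric = switch(scenario,
                                 E1_silencing = "onset",
                                 E1_activation_LD = "sleep_change",
                                 E1_activation_DD = "sleep_change",
                                 E2_clock_phase_advance = "phase",
                                 "onset"),
                 seed = NA_integer_),
            class = "dusk_experiment")
}
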