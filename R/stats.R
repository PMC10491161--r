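# Statistical scheme: omnibus tests, planned post-hoc comparisons between
# each experimental group and each of its genetic controls, normality
# gating, and the "significant against both controls" verdict.

#' Define a multi-group comparison design
#'
#' Planned comparisons are each experimental group against each control,
#' mirroring the standard genetic-control structure (GAL4>UAS vs GAL4/+
#' and UAS/+).
#'
#' @param values named list of numeric vectors, one per group.
#' @param roles character vector (same names/order), each
#'   `"experimental"` or `"control"`.
#' @return Object of class `group_design` with the planned pair list.
#' @export
group_design <- function(values, roles) {
  stopifnot(is.list(values), length(values) >= 2)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("groups must be named")
  roles <- match.arg(roles, c("experimental", "control"), several.ok = TRUE)
  roles <- rep_len(roles, length(values))
  names(roles) <- names(values)
  values <- lapply(values, function(v) v[!is.na(v)])
  if (any(lengths(values) == 0)) stop("empty group")
  if (any(!vapply(values, function(v) all(is.finite(v)), TRUE)))
    stop("group values must be finite")
  if (!any(roles == "experimental") || !any(roles == "control"))
    stop("need at least one experimental and one control group")
  pairs <- expand.grid(experimental = names(values)[roles == "experimental"],
                       control = names(values)[roles == "control"],
                       stringsAsFactors = FALSE)
  structure(list(values = values, roles = roles, pairs = pairs),
            class = "group_design")
}

new_stat_report <- function(omnibus, posthoc, alpha, correction, trail) {
  stopifnot(all(posthoc$p_adj + 1e-12 >= posthoc$p_raw),
            all(posthoc$p_adj <= 1))
  structure(list(omnibus = omnibus, posthoc = posthoc, alpha = alpha,
                 correction = correction, decision_trail = trail),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  o <- x$omnibus
  cat(o$test, ": statistic = ", formatC(o$statistic, digits = 4,
                                        format = "g"),
      ", df = ", paste(formatC(o$df, digits = 4, format = "g"),
                       collapse = ", "),
      ", P = ", formatC(o$p, digits = 3, format = "g"), "\n", sep = "")
  for (i in seq_len(nrow(x$posthoc))) {
    r <- x$posthoc[i, ]
    cat("  ", r$experimental, " vs ", r$control, ": P = ",
        formatC(r$p_adj, digits = 3, format = "g"), " [",
        p_stars(r$p_adj), "]\n", sep = "")
  }
  if (length(x$decision_trail))
    cat("  trail: ", paste(unlist(x$decision_trail), collapse = "; "),
        "\n", sep = "")
  invisible(x)
}

#' One-way ANOVA with Bonferroni planned comparisons
#'
#' Omnibus one-way ANOVA over all groups; planned pairwise t statistics
#' use the ANOVA residual mean square and its degrees of freedom (the
#' classic Bonferroni multiple-comparison test), with raw p-values
#' multiplied by the number of planned comparisons and capped at 1.
#'
#' @param design a [group_design()]; every group needs n >= 2.
#' @param alpha significance level. Default 0.05.
#' @param welch use per-pair Welch t tests instead of the pooled residual
#'   variance. Default `FALSE`.
#' @return A `stat_report`.
#' @export
anova_bonferroni <- function(design, alpha = 0.05, welch = FALSE) {
  stopifnot(inherits(design, "group_design"))
  if (any(lengths(design$values) < 2)) stop("every group needs n >= 2")
  y <- unlist(design$values, use.names = FALSE)
  g <- factor(rep(names(design$values), lengths(design$values)),
              levels = names(design$values))
  a <- anova(lm(y ~ g))
  mse <- a[["Mean Sq"]][2]
  dfres <- a[["Df"]][2]
  Fstat <- a[["F value"]][1]
  pF <- a[["Pr(>F)"]][1]
  if (!is.finite(Fstat)) { Fstat <- 0; pF <- 1 }   # all groups identical
  m <- nrow(design$pairs)
  rows <- lapply(seq_len(m), function(i) {
    e <- design$pairs$experimental[i]; c0 <- design$pairs$control[i]
    ve <- design$values[[e]]; vc <- design$values[[c0]]
    if (welch) {
      tt <- t.test(ve, vc)
      stat <- unname(tt$statistic); df <- unname(tt$parameter)
      p <- tt$p.value
    } else {
      se <- sqrt(mse * (1 / length(ve) + 1 / length(vc)))
      stat <- if (se == 0) 0 else (mean(ve) - mean(vc)) / se
      df <- dfres
      p <- if (se == 0) 1 else 2 * pt(-abs(stat), df)
    }
    data.frame(experimental = e, control = c0, statistic = stat, df = df,
               p_raw = p, p_adj = min(1, m * p),
               direction = sign(mean(ve) - mean(vc)),
               stringsAsFactors = FALSE)
  })
  posthoc <- do.call(rbind, rows)
  posthoc$significant <- posthoc$p_adj < alpha
  new_stat_report(
    list(test = "One-way ANOVA", statistic = Fstat,
         df = a[["Df"]], p = pF),
    posthoc, alpha, "bonferroni",
    list(sprintf("%d planned comparison(s), %s t",
                 m, if (welch) "Welch" else "pooled-MS")))
}

# tie-corrected pooled rank variance term used by Dunn's z
dunn_tie_term <- function(ranks) {
  tab <- table(ranks)
  sum(tab^3 - tab) / (12 * (length(ranks) - 1))
}

#' Kruskal-Wallis with Dunn's planned post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis omnibus H; Dunn z statistics for each
#' planned pair from the pooled rank variance with tie correction,
#' Bonferroni-adjusted over the planned comparisons only.
#'
#' @inheritParams anova_bonferroni
#' @return A `stat_report`.
#' @export
kruskal_dunn <- function(design, alpha = 0.05) {
  stopifnot(inherits(design, "group_design"))
  if (any(lengths(design$values) < 2)) stop("every group needs n >= 2")
  y <- unlist(design$values, use.names = FALSE)
  g <- factor(rep(names(design$values), lengths(design$values)),
              levels = names(design$values))
  N <- length(y)
  if (diff(range(y)) == 0) {
    H <- 0; pH <- 1; dfH <- length(design$values) - 1
  } else {
    kw <- kruskal.test(y, g)
    H <- unname(kw$statistic); pH <- kw$p.value; dfH <- unname(kw$parameter)
  }
  rk <- rank(y)
  rbar <- tapply(rk, g, mean)
  nn <- tapply(rk, g, length)
  s2 <- N * (N + 1) / 12 - dunn_tie_term(rk)
  m <- nrow(design$pairs)
  rows <- lapply(seq_len(m), function(i) {
    e <- design$pairs$experimental[i]; c0 <- design$pairs$control[i]
    se <- sqrt(s2 * (1 / nn[[e]] + 1 / nn[[c0]]))
    z <- if (se == 0) 0 else (rbar[[e]] - rbar[[c0]]) / se
    p <- if (se == 0) 1 else 2 * pnorm(-abs(z))
    data.frame(experimental = e, control = c0, statistic = z, df = NA_real_,
               p_raw = p, p_adj = min(1, m * p),
               direction = sign(median(design$values[[e]]) -
                                  median(design$values[[c0]])),
               stringsAsFactors = FALSE)
  })
  posthoc <- do.call(rbind, rows)
  posthoc$significant <- posthoc$p_adj < alpha
  new_stat_report(
    list(test = "Kruskal-Wallis", statistic = H, df = dfH, p = pH),
    posthoc, alpha, "bonferroni",
    list(sprintf("%d planned Dunn comparison(s), tie-corrected", m)))
}

#' Choose the parametric or nonparametric branch
#'
#' Per-group Shapiro-Wilk normality check at `shapiro_alpha`; any
#' rejection (or any group too small to test, or with zero variance)
#' routes to the nonparametric branch. A force flag overrides to
#' nonparametric unconditionally — used for sleep onset time, which is
#' bounded below by dusk and treated as non-normal throughout. The
#' decision trail records every gate outcome.
#'
#' @param design a [group_design()].
#' @param force_nonparametric skip the gate and use [kruskal_dunn()].
#' @param alpha post-hoc significance level.
#' @param shapiro_alpha normality-test level. Default 0.05.
#' @return A `stat_report` from the chosen branch, with the normality
#'   decision trail attached.
#' @export
choose_test <- function(design, force_nonparametric = FALSE, alpha = 0.05,
                        shapiro_alpha = 0.05) {
  stopifnot(inherits(design, "group_design"))
  trail <- list()
  nonpar <- FALSE
  if (force_nonparametric) {
    nonpar <- TRUE
    trail <- c(trail, "forced nonparametric")
  } else {
    for (nm in names(design$values)) {
      v <- design$values[[nm]]
      if (length(v) < 3) {
        nonpar <- TRUE
        trail <- c(trail, sprintf("%s: n=%d < 3, cannot test normality -> nonparametric",
                                  nm, length(v)))
      } else if (sd(v) == 0) {
        nonpar <- TRUE
        trail <- c(trail, sprintf("%s: zero variance -> nonparametric", nm))
      } else {
        p <- shapiro.test(v)$p.value
        trail <- c(trail, sprintf("%s: Shapiro-Wilk p=%.3g", nm, p))
        if (p < shapiro_alpha) nonpar <- TRUE
      }
    }
  }
  rep <- if (nonpar) kruskal_dunn(design, alpha)
         else anova_bonferroni(design, alpha)
  rep$decision_trail <- c(trail,
                          sprintf("branch: %s",
                                  if (nonpar) "Kruskal-Wallis + Dunn"
                                  else "ANOVA + Bonferroni"),
                          rep$decision_trail)
  rep
}

#' Verdict against both genetic controls
#'
#' An experimental group's phenotype is called significant only if its
#' adjusted p-value is below alpha against BOTH controls and the effect
#' direction agrees across the two comparisons.
#'
#' @param report a `stat_report` containing both control comparisons for
#'   each experimental group.
#' @param alpha significance level; defaults to the report's.
#' @return Data frame: `experimental`, `significant`, `direction`
#'   (agreed sign or 0), `n_controls`.
#' @export
vs_both_controls <- function(report, alpha = NULL) {
  stopifnot(inherits(report, "stat_report"))
  alpha <- alpha %||% report$alpha
  ph <- report$posthoc
  exps <- unique(ph$experimental)
  rows <- lapply(exps, function(e) {
    sub <- ph[ph$experimental == e, ]
    if (nrow(sub) < 2)
      stop("incomplete-design error: ", e, " lacks both control comparisons")
    agree <- length(unique(sub$direction)) == 1 && sub$direction[1] != 0
    data.frame(experimental = e,
               significant = all(sub$p_adj < alpha) && agree,
               direction = if (agree) sub$direction[1] else 0,
               n_controls = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format a stat report as a figure-legend style text block
#'
#' @param report a `stat_report`.
#' @return Character vector of lines ("*, P < 0.05; **, P < 0.01;
#'   ***, P < 0.001; ns").
#' @export
format_stat_report <- function(report) {
  o <- report$omnibus
  out <- sprintf("%s: statistic = %.4g, P = %.3g", o$test, o$statistic, o$p)
  for (i in seq_len(nrow(report$posthoc))) {
    r <- report$posthoc[i, ]
    out <- c(out, sprintf("%s vs %s: adjusted P = %.3g (%s)",
                          r$experimental, r$control, r$p_adj,
                          p_stars(r$p_adj)))
  }
  c(out, "*, P < 0.05; **, P < 0.01; ***, P < 0.001; ns, not significant")
}
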