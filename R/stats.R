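# Statistical battery: two-way mixed-design repeated-measures ANOVA with
# Bonferroni post hocs for the DTI metrics, one-way ANOVA with Tukey HSD for
# the cell counts, and Pearson correlation with simple linear regression for
# the metric-histology relationship.

check_rm_design <- function(d) {
  for (col in c("subject_id", "group", "timepoint", "value"))
    if (!col %in% names(d))
      qdti_stop(sprintf("column '%s' missing", col), "qdti_invalid_input")
  tps <- unique(d$timepoint)
  if (length(tps) < 2L)
    qdti_stop("repeated-measures design needs >= 2 timepoints", "qdti_incomplete_design")
  if (length(unique(d$group)) < 2L)
    qdti_stop("need >= 2 groups", "qdti_incomplete_design")
  tab <- table(d$subject_id, d$timepoint)
  if (any(tab != 1L))
    qdti_stop(sprintf("incomplete design: subject(s) without every timepoint: %s",
                      paste(rownames(tab)[rowSums(tab != 1L) > 0], collapse = ", ")),
              "qdti_incomplete_design")
  invisible(tps)
}

#' Mixed-design repeated-measures ANOVA
#'
#' Classical split-plot sums-of-squares decomposition for one between-
#' subjects factor (group) and one within-subjects factor (timepoint):
#' the group effect is tested against the subject-within-group stratum, the
#' timepoint and group x timepoint effects against the subject x timepoint
#' stratum. With two timepoints (the default design) sphericity holds
#' trivially, so no correction is applied. Effects whose sum of squares is
#' exactly zero report F = 0, p = 1.
#'
#' @param data Data frame with columns `subject_id`, `group`, `timepoint`,
#'   `value` — e.g. one ROI x metric slice of the cohort metric table.
#' @return Object of class `rm_anova_result`: `effects` (effect, df1, df2,
#'   ss, F, p) and `cell_means` (group x timepoint means).
#' @export
rm_anova <- function(data) {
  tps <- check_rm_design(data)
  d <- data.frame(value = data$value,
                  subject = factor(data$subject_id),
                  group = factor(data$group),
                  timepoint = factor(data$timepoint, levels = tps))
  fit <- stats::aov(value ~ group * timepoint + Error(subject), data = d)
  s <- summary(fit)
  betw <- s[["Error: subject"]][[1]]
  with_ <- s[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    c(df = tab$Df[i], ss = tab$`Sum Sq`[i])
  }
  g  <- pick(betw, "group");             eb <- pick(betw, "Residuals")
  tm <- pick(with_, "timepoint");        ew <- pick(with_, "Residuals")
  gt <- pick(with_, "group:timepoint")
  # sums of squares that are zero by construction come back from the QR as
  # ~1e-30 round-off; anything below a relative floor is treated as exact 0
  ss_floor <- 1e-12 * max(sum((d$value - mean(d$value))^2), .Machine$double.xmin)
  frow <- function(effect, x, err) {
    if (x[["ss"]] <= ss_floor) x[["ss"]] <- 0
    ms <- x[["ss"]] / x[["df"]]; mse <- err[["ss"]] / err[["df"]]
    f <- if (x[["ss"]] == 0) 0 else if (mse == 0 || err[["ss"]] <= ss_floor) Inf else ms / mse
    p <- if (x[["ss"]] == 0) 1 else stats::pf(f, x[["df"]], err[["df"]], lower.tail = FALSE)
    data.frame(effect = effect, df1 = x[["df"]], df2 = err[["df"]],
               ss = x[["ss"]], F = f, p = p, stringsAsFactors = FALSE)
  }
  effects <- rbind(frow("group", g, eb),
                   frow("timepoint", tm, ew),
                   frow("group:timepoint", gt, ew))
  cm <- stats::aggregate(value ~ group + timepoint, d, mean)
  names(cm)[3] <- "mean"
  structure(list(effects = effects, cell_means = cm), class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("<rm_anova_result>\n"); print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Pairwise group contrasts with Bonferroni control
#'
#' All pairwise group comparisons, by default separately at each timepoint
#' (`mode = "per_day"`, using the pooled within-group variance of that
#' timepoint), or on subject means averaged over timepoints
#' (`mode = "averaged"`). A contrast is declared significant when its raw
#' two-sided p is below `alpha` divided by the number of contrasts
#' (0.05 / 3 for three groups); the capped Bonferroni-multiplied p is
#' reported alongside.
#'
#' @inheritParams rm_anova
#' @param alpha Family-wise type-I error level (default 0.05).
#' @param mode `"per_day"` or `"averaged"`.
#' @return Data frame (timepoint, contrast, mean_diff, t, df, p, p_bonf,
#'   significant).
#' @export
posthoc_bonferroni <- function(data, alpha = 0.05,
                               mode = c("per_day", "averaged")) {
  mode <- match.arg(mode)
  tps <- check_rm_design(data)
  if (any(table(data$group[data$timepoint == tps[1]]) < 2L))
    qdti_stop("every group needs >= 2 subjects", "qdti_insufficient_data")
  slices <- if (mode == "per_day") {
    stats::setNames(lapply(tps, function(tp) data[data$timepoint == tp, ]), tps)
  } else {
    m <- stats::aggregate(value ~ subject_id + group, data, mean)
    list(averaged = m)
  }
  rows <- list()
  for (tp in names(slices)) {
    d <- slices[[tp]]
    gs <- sort(unique(d$group))
    n <- tapply(d$value, d$group, length)[gs]
    m <- tapply(d$value, d$group, mean)[gs]
    ss_within <- sum(tapply(d$value, d$group, function(v) sum((v - mean(v))^2)))
    dfe <- sum(n) - length(gs)
    mse <- ss_within / dfe
    pairs <- utils::combn(gs, 2L)
    ncon <- ncol(pairs)
    for (j in seq_len(ncon)) {
      a <- pairs[1, j]; b <- pairs[2, j]
      se <- sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
      tval <- if (se == 0) 0 else (m[[a]] - m[[b]]) / se
      p <- if (se == 0) 1 else 2 * stats::pt(-abs(tval), dfe)
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = tp, contrast = paste(a, "vs", b),
        mean_diff = m[[a]] - m[[b]], t = tval, df = dfe, p = p,
        p_bonf = min(1, ncon * p), significant = p < alpha / ncon,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' One-way ANOVA across groups followed by all-pairs Tukey honestly-
#' significant-difference comparisons; unequal group sizes are handled by
#' the Tukey-Kramer form (as implemented by [stats::TukeyHSD()] on the
#' studentized-range distribution with pooled within-group variance).
#'
#' @param data Data frame with columns `group` and `count` (or `value`) —
#'   e.g. one stain x ROI slice of the synthetic histology counts.
#' @return List with `F`, `df1`, `df2`, `p`, and `tukey`, a data frame
#'   (contrast, diff, lwr, upr, p_adj).
#' @export
oneway_anova_tukey <- function(data) {
  vcol <- if ("count" %in% names(data)) "count" else "value"
  d <- data.frame(value = as.numeric(data[[vcol]]), group = factor(data$group))
  if (nlevels(d$group) < 2L || any(table(d$group) < 2L))
    qdti_stop("need >= 2 groups with >= 2 observations each", "qdti_insufficient_data")
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  ss_floor <- 1e-12 * max(sum((d$value - mean(d$value))^2), .Machine$double.xmin)
  if (tab$`Sum Sq`[2] <= ss_floor)
    qdti_stop("zero within-group variance everywhere: Tukey HSD undefined",
              "qdti_degenerate_variance")
  f <- if (tab$`Sum Sq`[1] <= ss_floor) 0 else tab$`F value`[1]
  p <- if (tab$`Sum Sq`[1] <= ss_floor) 1 else tab$`Pr(>F)`[1]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(contrast = gsub("-", " vs ", rownames(tk), fixed = TRUE),
                      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(F = f, df1 = tab$Df[1], df2 = tab$Df[2], p = p, tukey = tukey)
}

#' Pearson correlation with simple linear regression
#'
#' Product-moment correlation with a two-sided t-based p-value (n - 2
#' degrees of freedom) and the least-squares line of `y` on `x`. The
#' identity `r^2 = R^2` of the regression is verified internally.
#'
#' @param x,y Numeric vectors of equal length >= 3 (e.g. ROI-mean q values
#'   and cell counts).
#' @return Object of class `correlation_result`: `r`, `p`, `n`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
pearson_with_regression <- function(x, y) {
  if (length(x) != length(y)) qdti_stop("x and y lengths differ", "qdti_invalid_input")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) qdti_stop("need at least 3 pairs", "qdti_insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    qdti_stop("correlation undefined for constant input", "qdti_undefined_correlation")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  r <- unname(ct$estimate)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # perfect fits warn in summary.lm
  stopifnot(abs(r^2 - r2) < 1e-10)
  structure(list(r = r, p = ct$p.value, n = length(x),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (n = %d, p = %.3g), y = %.4g + %.4g x\n",
              x$r, x$n, x$p, x$intercept, x$slope))
  invisible(x)
}

#' Run the full group-comparison battery over a metric table
#'
#' For every ROI x metric cell: repeated-measures ANOVA (group, timepoint,
#' interaction) plus pairwise Bonferroni post hocs per timepoint.
#'
#' @param metric_table Long-format cohort table from
#'   [assemble_cohort_table()].
#' @param alpha Significance level (default 0.05).
#' @param posthoc_mode Passed to [posthoc_bonferroni()].
#' @return Data frame with one row per test (test, roi, metric, effect,
#'   statistic, df1, df2, p, significant).
#' @export
run_group_stats <- function(metric_table, alpha = 0.05,
                            posthoc_mode = "per_day") {
  rows <- list()
  for (roi in unique(metric_table$roi)) {
    for (m in unique(metric_table$metric)) {
      d <- metric_table[metric_table$roi == roi & metric_table$metric == m, ]
      an <- rm_anova(d)
      for (i in seq_len(nrow(an$effects)))
        rows[[length(rows) + 1L]] <- data.frame(
          test = "rmANOVA", roi = roi, metric = m,
          effect = an$effects$effect[i], statistic = an$effects$F[i],
          df1 = an$effects$df1[i], df2 = an$effects$df2[i],
          p = an$effects$p[i],
          significant = an$effects$p[i] < alpha, stringsAsFactors = FALSE)
      ph <- posthoc_bonferroni(d, alpha = alpha, mode = posthoc_mode)
      for (i in seq_len(nrow(ph)))
        rows[[length(rows) + 1L]] <- data.frame(
          test = "posthoc_bonferroni", roi = roi, metric = m,
          effect = paste(ph$timepoint[i], ph$contrast[i]),
          statistic = ph$t[i], df1 = 1L, df2 = ph$df[i], p = ph$p[i],
          significant = ph$significant[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA + Tukey battery over synthetic histology counts
#'
#' @param counts Count table from [generate_ihc_counts()].
#' @param alpha Significance level.
#' @return Data frame with ANOVA and Tukey rows per stain x ROI.
#' @export
run_ihc_stats <- function(counts, alpha = 0.05) {
  rows <- list()
  for (st in unique(counts$stain)) for (roi in unique(counts$roi)) {
    d <- counts[counts$stain == st & counts$roi == roi, ]
    res <- tryCatch(oneway_anova_tukey(d), qdti_degenerate_variance = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      test = "oneway_anova", roi = roi, metric = st, effect = "group",
      statistic = res$F, df1 = res$df1, df2 = res$df2, p = res$p,
      significant = res$p < alpha, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(res$tukey)))
      rows[[length(rows) + 1L]] <- data.frame(
        test = "tukey_hsd", roi = roi, metric = st,
        effect = res$tukey$contrast[i], statistic = res$tukey$diff[i],
        df1 = res$df1, df2 = res$df2, p = res$tukey$p_adj[i],
        significant = res$tukey$p_adj[i] < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate final-timepoint ROI metrics with histology counts
#'
#' Pools all groups (the regression design of the study emulated) and
#' correlates each requested ROI's final-timepoint metric with each stain's
#' counts in the same ROI.
#'
#' @param metric_table Cohort metric table.
#' @param counts Histology count table.
#' @param rois,stains Which ROI / stain combinations to test (defaults: the
#'   remote white matter ROIs against astrocyte and microglia stains).
#' @param metric Metric to correlate (default `"q"`).
#' @return Data frame (roi, stain, metric, n, r, p, slope, intercept).
#' @export
run_metric_ihc_correlations <- function(metric_table, counts,
                                        rois = c("EC", "IC"),
                                        stains = c("GFAP", "CD68"),
                                        metric = "q") {
  tp <- utils::tail(unique(metric_table$timepoint), 1)
  rows <- list()
  for (roi in rois) for (st in stains) {
    mt <- metric_table[metric_table$roi == roi & metric_table$metric == metric &
                       metric_table$timepoint == tp, ]
    ct <- counts[counts$roi == roi & counts$stain == st, ]
    merged <- merge(mt[, c("subject_id", "value")],
                    ct[, c("subject_id", "count")], by = "subject_id")
    res <- pearson_with_regression(merged$value, merged$count)
    rows[[length(rows) + 1L]] <- data.frame(
      roi = roi, stain = st, metric = metric, n = res$n, r = res$r, p = res$p,
      slope = res$slope, intercept = res$intercept, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
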