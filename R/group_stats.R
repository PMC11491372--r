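# Between-condition statistics on the per-cell metric table: one-way ANOVA
# with Tukey HSD multiple comparisons, and Student's (equal-variance)
# two-sample t-tests, mirroring the figure-caption conventions (error bars =
# SEM; asterisk thresholds 0.05 / 0.01 / 0.001 / 0.0001).

#' Significance stars at the conventional thresholds
#' @param p p-value(s)
#' @return character vector: "ns", "*", "**", "***" or "****"
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Compare a metric between condition groups
#'
#' One-way ANOVA (F and p) on per-cell values pooled across experiments, with
#' Tukey HSD adjusted p-values for all unordered group pairs when there are
#' three or more groups, and a Student's equal-variance two-sample t-test
#' when there are exactly two. Group means and standard errors of the mean
#' are always reported.
#'
#' @param records data.frame of per-cell metrics (e.g. from [read_records()])
#' @param metric column name of the metric to compare
#' @param grouping column name of the condition label (default "condition")
#' @return a `GroupComparison` list: `metric`, `groups` (n, mean, sem per
#'   group), `anova_F`, `anova_p`, `tukey` (data.frame of pairwise adjusted
#'   p), `ttest_p` (two-group case only)
#' @export
compare_groups <- function(records, metric, grouping = "condition") {
  stopifnot(is.data.frame(records))
  if (!metric %in% names(records)) stop(sprintf("metric '%s' absent", metric))
  if (!grouping %in% names(records)) stop(sprintf("column '%s' absent", grouping))
  df <- records[!is.na(records[[metric]]) & !is.na(records[[grouping]]), ]
  y <- df[[metric]]
  gr <- factor(df[[grouping]])
  n_per <- table(gr)
  if (length(n_per) < 2L) stop("need at least 2 groups")
  if (any(n_per < 2L)) {
    stop(sprintf("groups with < 2 observations: %s",
                 paste(names(n_per)[n_per < 2L], collapse = ", ")))
  }
  groups <- data.frame(
    group = names(n_per),
    n = as.integer(n_per),
    mean = as.numeric(tapply(y, gr, mean)),
    sem = as.numeric(tapply(y, gr, function(v) stats::sd(v) / sqrt(length(v))))
  )

  # fully degenerate data (every observation identical): the F statistic is
  # 0/0; report the null identity F = 0, p = 1 instead of float noise
  if (stats::sd(y) == 0) {
    pairs <- utils::combn(levels(gr), 2)
    tukey <- data.frame(
      comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
      diff = 0, p_adj = 1
    )
    return(structure(
      list(metric = metric, groups = groups, anova_F = 0, anova_p = 1,
           tukey = tukey, ttest_p = if (length(n_per) == 2L) 1 else NULL),
      class = "GroupComparison"
    ))
  }

  fit <- stats::aov(y ~ gr)
  an <- summary(fit)[[1]]
  anova_F <- an[["F value"]][1]
  anova_p <- an[["Pr(>F)"]][1]
  # degenerate all-identical data: define F = 0, p = 1 rather than NaN
  if (!is.finite(anova_F)) {
    anova_F <- 0
    anova_p <- 1
  }

  tukey <- NULL
  if (length(n_per) >= 2L) {
    tk <- stats::TukeyHSD(fit)$gr
    tukey <- data.frame(
      comparison = rownames(tk),
      diff = tk[, "diff"],
      p_adj = ifelse(is.finite(tk[, "p adj"]), tk[, "p adj"], 1),
      row.names = NULL
    )
  }

  ttest_p <- NULL
  if (length(n_per) == 2L) {
    lv <- levels(gr)
    a <- y[gr == lv[1]]; b <- y[gr == lv[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      ttest_p <- 1
    } else {
      ttest_p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    }
  }

  structure(
    list(metric = metric, groups = groups, anova_F = anova_F,
         anova_p = anova_p, tukey = tukey, ttest_p = ttest_p),
    class = "GroupComparison"
  )
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison of %s: F = %.4g, p = %.4g (%s)\n",
              x$metric, x$anova_F, x$anova_p, significance_stars(x$anova_p)))
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %-18s n = %-3d mean = %.4g +/- %.4g (SEM)\n",
                g$group, g$n, g$mean, g$sem))
  }
  if (!is.null(x$tukey)) {
    for (i in seq_len(nrow(x$tukey))) {
      tk <- x$tukey[i, ]
      cat(sprintf("  Tukey %-28s p_adj = %.4g (%s)\n",
                  tk$comparison, tk$p_adj, significance_stars(tk$p_adj)))
    }
  }
  if (!is.null(x$ttest_p)) {
    cat(sprintf("  Student's t-test p = %.4g (%s)\n",
                x$ttest_p, significance_stars(x$ttest_p)))
  }
  invisible(x)
}

#' Flatten GroupComparisons into a stats table
#'
#' @param comparisons list of `GroupComparison` objects
#' @return data.frame with one row per test (ANOVA, each Tukey pair, t-test)
#' @export
comparisons_to_df <- function(comparisons) {
  rows <- list()
  for (cmp in comparisons) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = cmp$metric, test = "anova", comparison = "all groups",
      statistic = cmp$anova_F, p = cmp$anova_p, p_adj = NA_real_,
      stars = significance_stars(cmp$anova_p)
    )
    if (!is.null(cmp$tukey)) {
      for (i in seq_len(nrow(cmp$tukey))) {
        tk <- cmp$tukey[i, ]
        rows[[length(rows) + 1L]] <- data.frame(
          metric = cmp$metric, test = "tukey", comparison = tk$comparison,
          statistic = tk$diff, p = NA_real_, p_adj = tk$p_adj,
          stars = significance_stars(tk$p_adj)
        )
      }
    }
    if (!is.null(cmp$ttest_p)) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = cmp$metric, test = "student_t",
        comparison = paste(cmp$groups$group, collapse = " vs "),
        statistic = NA_real_, p = cmp$ttest_p, p_adj = NA_real_,
        stars = significance_stars(cmp$ttest_p)
      )
    }
  }
  do.call(rbind, rows)
}
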