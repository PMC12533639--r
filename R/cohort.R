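#' Per-sample summary table
#'
#' One row per catalog: sample id, optional group label, number of unique
#' eccDNA calls and their mean length (NA for an empty catalog). This table
#' is the unit of all cohort analyses.
#'
#' @param catalogs list of `circle_catalog` objects.
#' @param groups optional character vector of group labels, recycled
#'   against the catalogs.
#' @return A `sample_table` data.frame: `sample_id`, `group`, `n_eccDNA`,
#'   `mean_length`.
#' @export
per_sample_summary <- function(catalogs, groups = NA_character_) {
  if (length(catalogs) < 1) stop_invalid("need at least one catalog")
  ids <- vapply(catalogs, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop_invalid("duplicate sample_id: %s", ids[duplicated(ids)][1])
  tab <- data.frame(
    sample_id = ids,
    group = rep_len(groups, length(catalogs)),
    n_eccDNA = vapply(catalogs, `[[`, integer(1), "n_eccDNA"),
    mean_length = vapply(catalogs, `[[`, numeric(1), "mean_length"),
    stringsAsFactors = FALSE)
  class(tab) <- c("sample_table", "data.frame")
  tab
}

#' Compare a value between sample groups
#'
#' Two groups: classical unpaired two-sided Student's t test
#' (pooled variance; Welch behind `welch = TRUE`). More than two groups:
#' one-way ANOVA. Also reports per-group mean and SD and the fold change of
#' group means relative to the declared reference group.
#'
#' @param table a data.frame with at least the value and group columns.
#' @param value_column name of the numeric column compared.
#' @param group_column name of the group-label column.
#' @param reference reference group for the fold change (default: first
#'   group in table order).
#' @param welch use the Welch (unequal-variance) t test for two groups.
#' @return A `group_comparison` list: `groups` (mean, sd, n per group),
#'   `test` (`students_t` / `welch_t` / `one_way_anova`), `statistic`,
#'   `df`, `p_value`, `fold_change` (per non-reference group),
#'   `reference`.
#' @export
compare_groups <- function(table, value_column, group_column = "group",
                           reference = NULL, welch = FALSE) {
  if (!value_column %in% names(table))
    stop_invalid("no column '%s' in table", value_column)
  if (!group_column %in% names(table))
    stop_invalid("no column '%s' in table", group_column)
  x <- table[[value_column]]
  g <- as.character(table[[group_column]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  lev <- unique(g)
  if (length(lev) < 2) stop_invalid("need at least 2 groups")
  sizes <- table(factor(g, levels = lev))
  if (any(sizes < 2))
    stop_invalid("group '%s' has fewer than 2 samples",
                 names(sizes)[sizes < 2][1])
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop_invalid("unknown reference group '%s'",
                                        reference)
  per <- data.frame(group = lev,
                    n = as.integer(sizes[lev]),
                    mean = vapply(lev, function(l) mean(x[g == l]),
                                  numeric(1)),
                    sd = vapply(lev, function(l) stats::sd(x[g == l]),
                                numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (length(lev) == 2L) {
    other <- setdiff(lev, reference)
    a <- x[g == other]; b <- x[g == reference]
    test <- if (welch) "welch_t" else "students_t"
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # degenerate but permitted: both groups constant
      df <- length(a) + length(b) - 2
      statistic <- if (mean(a) == mean(b)) 0
      else sign(mean(a) - mean(b)) * Inf
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tt <- t.test(a, b, var.equal = !welch)
      statistic <- unname(tt$statistic); df <- unname(tt$parameter)
      p <- tt$p.value
    }
  } else {
    fit <- aov(x ~ factor(g, levels = lev))
    av <- anova(fit)
    test <- "one_way_anova"
    statistic <- av[["F value"]][1]
    df <- c(av[["Df"]][1], av[["Df"]][2])
    p <- av[["Pr(>F)"]][1]
  }
  ref_mean <- per$mean[per$group == reference]
  fc <- setNames(per$mean[per$group != reference] / ref_mean,
                 per$group[per$group != reference])
  structure(list(groups = per, test = test, statistic = statistic, df = df,
                 p_value = p, fold_change = fc, reference = reference,
                 value = value_column),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s) on '%s': statistic = %.4g, p = %.4g\n",
              x$test, x$value, x$statistic, x$p_value))
  print(x$groups)
  cat(sprintf("  fold change vs '%s': %s\n", x$reference,
              paste(sprintf("%s = %.3g", names(x$fold_change),
                            x$fold_change), collapse = ", ")))
  invisible(x)
}

#' Median stratification into high and low groups
#'
#' Splits samples at the median of a value: strictly above the median is
#' `high`, strictly below is `low`, and samples exactly at the median are
#' assigned in table order to whichever group is currently smaller, low
#' first on an exact balance (the declared tie rule). With equally many
#' samples on both sides this reduces to low-then-high alternation, and the
#' two groups never differ in size by more than the imbalance the non-tied
#' values force (at most one when ties can absorb it).
#'
#' @param table a data.frame with a `sample_id` column.
#' @param value_column numeric column to stratify on.
#' @return A `stratified_cohort` list: `labels` (data.frame `sample_id`,
#'   `value`, `label`), `split_value` (the median).
#' @export
stratify_high_low <- function(table, value_column) {
  if (!value_column %in% names(table))
    stop_invalid("no column '%s' in table", value_column)
  x <- table[[value_column]]
  if (length(x) < 2) stop_invalid("need at least 2 samples")
  if (length(unique(x)) == 1L)
    stop_invalid("degenerate split: all values of '%s' identical",
                 value_column)
  med <- median(x)
  label <- ifelse(x > med, "eccDNA_high",
                  ifelse(x < med, "eccDNA_low", NA_character_))
  ties <- which(is.na(label))
  if (length(ties) > 0) {  # fill the smaller group first, low on a balance
    n_low <- sum(label == "eccDNA_low", na.rm = TRUE)
    n_high <- sum(label == "eccDNA_high", na.rm = TRUE)
    for (i in ties) {
      if (n_low <= n_high) {
        label[i] <- "eccDNA_low"; n_low <- n_low + 1L
      } else {
        label[i] <- "eccDNA_high"; n_high <- n_high + 1L
      }
    }
  }
  structure(list(labels = data.frame(sample_id = table$sample_id,
                                     value = x, label = label,
                                     stringsAsFactors = FALSE),
                 split_value = med),
            class = "stratified_cohort")
}

#' @export
print.stratified_cohort <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("stratified_cohort: median %.4g; %s\n", x$split_value,
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Pearson correlation between two sample-level variables
#'
#' @param table a data.frame.
#' @param x_column,y_column numeric column names; both need at least 3
#'   complete pairs and nonzero variance.
#' @return List with `r` (Pearson's correlation coefficient), `r_squared`,
#'   `p_value` (two-sided, from the t transform of r) and `n`.
#' @export
correlate <- function(table, x_column, y_column) {
  for (col in c(x_column, y_column))
    if (!col %in% names(table)) stop_invalid("no column '%s' in table", col)
  x <- table[[x_column]]; y <- table[[y_column]]
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_invalid("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("zero-variance column; correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(x))
}

#' Render a cohort report
#'
#' Writes a machine-readable `report.json`, a human-readable `report.md`
#' and per-section TSV tables under `tables/`. Sections with no content are
#' omitted; output is deterministic (re-running on the same inputs is
#' byte-identical).
#'
#' @param summaries optional `sample_table` (see [per_sample_summary()]).
#' @param comparisons optional named list of `group_comparison` objects.
#' @param stratification optional `stratified_cohort`.
#' @param correlations optional named list of [correlate()] results.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(summaries = NULL, comparisons = NULL,
                          stratification = NULL, correlations = NULL,
                          out_dir) {
  if (is.null(summaries) && is.null(comparisons) &&
      is.null(stratification) && is.null(correlations))
    stop_invalid("at least one report section must be present")
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- character()
  json <- list()
  md <- c("# eccDNA cohort report", "")
  if (!is.null(summaries)) {
    json$samples <- as.data.frame(summaries)
    p <- file.path(out_dir, "tables", "samples.tsv")
    write.table(summaries, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    md <- c(md, "## Per-sample summary", "",
            sprintf("- %s (%s): %d eccDNA, mean length %s bp",
                    summaries$sample_id, summaries$group,
                    summaries$n_eccDNA,
                    ifelse(is.na(summaries$mean_length), "NA",
                           sprintf("%.1f", summaries$mean_length))), "")
  }
  if (!is.null(comparisons) && length(comparisons) > 0) {
    json$comparisons <- lapply(comparisons, function(cp)
      list(test = cp$test, statistic = cp$statistic, df = cp$df,
           p_value = cp$p_value, reference = cp$reference,
           fold_change = as.list(cp$fold_change), groups = cp$groups))
    md <- c(md, "## Group comparisons", "")
    for (nm in names(comparisons)) {
      cp <- comparisons[[nm]]
      md <- c(md, sprintf("- %s: %s, statistic %.6g, p %.6g", nm, cp$test,
                          cp$statistic, cp$p_value))
    }
    md <- c(md, "")
  }
  if (!is.null(stratification)) {
    json$stratification <- list(split_value = stratification$split_value,
                                labels = stratification$labels)
    p <- file.path(out_dir, "tables", "stratification.tsv")
    write.table(stratification$labels, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
    md <- c(md, "## eccDNA-high / eccDNA-low stratification", "",
            sprintf("- split at median = %.6g", stratification$split_value),
            "")
  }
  if (!is.null(correlations) && length(correlations) > 0) {
    json$correlations <- correlations
    md <- c(md, "## Correlations", "")
    for (nm in names(correlations)) {
      cr <- correlations[[nm]]
      md <- c(md, sprintf("- %s: r = %.4f, R^2 = %.4f, p = %.6g (n = %d)",
                          nm, cr$r, cr$r_squared, cr$p_value, cr$n))
    }
    md <- c(md, "")
  }
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  mp <- file.path(out_dir, "report.md")
  writeLines(md, mp)
  invisible(c(jp, mp, paths))
}
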