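mk_catalog <- function(id, lengths) {
  n <- length(lengths)
  if (n == 0) return(eccpipe:::new_circle_catalog(id, eccpipe:::empty_calls()))
  calls <- data.frame(call_id = sprintf("%s_c%03d", id, seq_len(n)),
                      chrom = "chr1", start = 0L,
                      end = as.integer(lengths),
                      length = as.integer(lengths), split_support = 2L,
                      discordant_support = 0L, mean_depth = 1,
                      enrichment = 10, stringsAsFactors = FALSE)
  eccpipe:::new_circle_catalog(id, calls)
}

test_that("per-sample summaries report counts and mean lengths", {
  cats <- list(mk_catalog("s1", c(1000, 2000)), mk_catalog("s2", numeric(0)),
               mk_catalog("s3", c(500, 500, 800)))
  tab <- per_sample_summary(cats, groups = c("a", "a", "b"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$mean_length[1], 1500)
  expect_equal(tab$n_eccDNA[2], 0)
  expect_true(is.na(tab$mean_length[2]))
  expect_error(per_sample_summary(list(mk_catalog("s", 1), mk_catalog("s", 1))),
               "duplicate")
})

test_that("two-group comparison is the classical pooled-variance t test", {
  tab <- data.frame(sample_id = sprintf("s%d", 1:6),
                    group = rep(c("g1", "g2"), each = 3),
                    v = c(5, 5, 5, 5, 5, 5))
  cmp0 <- compare_groups(tab, "v")
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)

  # textbook case: {1..5} vs {2..6}; |t| = 1, df = 8, pooled variance
  tab2 <- data.frame(sample_id = sprintf("s%d", 1:10),
                     group = rep(c("g1", "g2"), each = 5),
                     v = c(1:5, 2:6))
  cmp <- compare_groups(tab2, "v")
  expect_equal(cmp$test, "students_t")
  expect_equal(abs(cmp$statistic), 1, tolerance = 1e-12)
  expect_equal(cmp$df, 8)
  expect_equal(cmp$p_value, 2 * pt(-1, 8), tolerance = 1e-12)

  # fold change of group means: 14,835 vs 1,353 exceeds 10
  tab3 <- data.frame(sample_id = sprintf("s%d", 1:10),
                     group = rep(c("wt", "mut"), c(4, 6)),
                     n_ecc = c(1300, 1400, 1353, 1359,
                               14000, 15000, 14835, 15200, 14500, 15475))
  cmp3 <- compare_groups(tab3, "n_ecc", reference = "wt")
  expect_gt(unname(cmp3$fold_change["mut"]), 10)

  expect_error(compare_groups(data.frame(sample_id = 1:3,
                                         group = c("a", "a", "b"),
                                         v = 1:3), "v"),
               "fewer than 2")
})

test_that("t and ANOVA match independent closed-form computation", {
  # independent oracle: textbook formulas written out directly
  bf_t <- function(x, y) {
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    list(t = t, df = length(x) + length(y) - 2,
         p = 2 * pt(-abs(t), length(x) + length(y) - 2))
  }
  bf_anova <- function(groups) {
    all <- unlist(groups)
    gm <- mean(all)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                      numeric(1)))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
    df1 <- length(groups) - 1
    df2 <- length(all) - length(groups)
    f <- (ssb / df1) / (ssw / df2)
    list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
  }
  set.seed(99)
  for (k in seq_len(100)) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1); n3 <- sample(3:10, 1)
    x <- rnorm(n1, 10, 2); y <- rnorm(n2, 12, 3); z <- rnorm(n3, 9, 1)
    tab <- data.frame(sample_id = seq_len(n1 + n2),
                      group = rep(c("x", "y"), c(n1, n2)), v = c(x, y))
    cmp <- compare_groups(tab, "v", reference = "y")
    want <- bf_t(x, y)
    expect_equal(cmp$statistic, want$t, tolerance = 1e-10)
    expect_equal(cmp$p_value, want$p, tolerance = 1e-10)

    tab3 <- data.frame(sample_id = seq_len(n1 + n2 + n3),
                       group = rep(c("x", "y", "z"), c(n1, n2, n3)),
                       v = c(x, y, z))
    cmp3 <- compare_groups(tab3, "v")
    want3 <- bf_anova(list(x, y, z))
    expect_equal(cmp3$test, "one_way_anova")
    expect_equal(cmp3$statistic, want3$f, tolerance = 1e-10)
    expect_equal(cmp3$p_value, want3$p, tolerance = 1e-10)

    # classical identity on two groups: F = t^2
    tabf <- tab
    cmpf <- compare_groups(tabf, "v")
    fit <- aov(v ~ group, data = tabf)
    f <- anova(fit)[["F value"]][1]
    expect_equal(f, cmpf$statistic^2, tolerance = 1e-10)
  }
})

test_that("median stratification follows the declared tie rule", {
  tab <- data.frame(sample_id = sprintf("s%d", 1:4), v = c(1, 2, 3, 4))
  st <- stratify_high_low(tab, "v")
  expect_equal(st$labels$label, c("eccDNA_low", "eccDNA_low",
                                  "eccDNA_high", "eccDNA_high"))
  # ties at the median alternate low-then-high in order
  tab2 <- data.frame(sample_id = sprintf("s%d", 1:4), v = c(1, 2, 2, 4))
  st2 <- stratify_high_low(tab2, "v")
  expect_equal(st2$labels$label[2:3], c("eccDNA_low", "eccDNA_high"))

  # group sizes never differ by more than one, over random tables
  set.seed(17)
  for (k in seq_len(100)) {
    n <- sample(4:50, 1)
    tabk <- data.frame(sample_id = seq_len(n),
                       v = sample.int(10, n, replace = TRUE))
    if (length(unique(tabk$v)) == 1) next
    stk <- stratify_high_low(tabk, "v")
    d <- sum(stk$labels$label == "eccDNA_high") -
      sum(stk$labels$label == "eccDNA_low")
    expect_lte(abs(d), 1)
    # invariant to row order up to the tie rule: same high/low sizes
    perm <- tabk[sample.int(n), ]
    stp <- stratify_high_low(perm, "v")
    expect_equal(table(stp$labels$label), table(stk$labels$label))
  }
  expect_error(stratify_high_low(data.frame(sample_id = 1:3, v = c(2, 2, 2)),
                                 "v"), "degenerate")
})

test_that("correlation requires variance and recovers linear structure", {
  tab <- data.frame(sample_id = 1:5, x = 1:5, y = 2 * (1:5) + 3)
  r <- correlate(tab, "x", "y")
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_error(correlate(data.frame(sample_id = 1:4, x = rep(1, 4),
                                    y = 1:4), "x", "y"), "zero-variance")
  expect_error(correlate(data.frame(sample_id = 1:2, x = 1:2, y = 1:2),
                         "x", "y"), "at least 3")
})

test_that("reports render deterministically and omit empty sections", {
  cats <- list(mk_catalog("s1", c(1000, 2000)),
               mk_catalog("s2", c(900, 1100, 1500)),
               mk_catalog("s3", c(3000, 4000)),
               mk_catalog("s4", c(600, 700, 900, 1200)))
  tab <- per_sample_summary(cats, groups = c("a", "a", "b", "b"))
  cmp <- list(n_eccDNA = compare_groups(tab, "n_eccDNA"))
  st <- stratify_high_low(tab, "n_eccDNA")
  d1 <- file.path(tempfile("rep"), "r1"); d2 <- file.path(tempfile("rep"), "r2")
  render_report(tab, cmp, st, correlations = NULL, out_dir = d1)
  render_report(tab, cmp, st, correlations = NULL, out_dir = d2)
  j1 <- readLines(file.path(d1, "report.json"))
  expect_identical(j1, readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "report.md")),
                   readLines(file.path(d2, "report.md")))
  parsed <- jsonlite::fromJSON(file.path(d1, "report.json"))
  expect_true(all(c("samples", "comparisons", "stratification") %in%
                    names(parsed)))
  expect_false("correlations" %in% names(parsed))
  expect_error(render_report(out_dir = tempdir()), "at least one")
})
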