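test_that("gene-content trichotomy follows containment and overlap", {
  ann <- fx_annotation()
  g <- ann$genes[1, ]

  # call containing the entire gene
  cls <- classify_circle(list(chrom = g$chrom, start = g$start - 100,
                              end = g$end + 100), ann)
  expect_equal(cls$kind, "full_gene")

  # call strictly inside one intron
  intr <- ann$features[ann$features$kind == "intron" &
                         ann$features$end - ann$features$start > 20, ][1, ]
  gchrom <- ann$genes$chrom[ann$genes$gene_id == intr$gene_id]
  cls2 <- classify_circle(list(chrom = gchrom, start = intr$start + 2,
                               end = intr$end - 2), ann)
  expect_equal(cls2$kind, "partial_gene")
  expect_equal(cls2$subtype, "intronic")

  # gene desert
  lens <- chrom_lengths(fx_assembly())
  desert <- NULL
  for (ch in names(lens)) {
    gg <- ann$genes[ann$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    gaps <- data.frame(s = c(0L, gg$end), e = c(gg$start, lens[[ch]]))
    gaps <- gaps[gaps$e - gaps$s > 200, ]
    if (nrow(gaps) > 0) { desert <- list(ch = ch, g = gaps[1, ]); break }
  }
  cls3 <- classify_circle(list(chrom = desert$ch,
                               start = desert$g$s + 10,
                               end = desert$g$s + 110), ann)
  expect_equal(cls3$kind, "intergenic")

  expect_error(classify_circle(list(chrom = "chrNope", start = 0, end = 10),
                               ann), "chrNope")
})

test_that("classifier agrees with the per-base brute force", {
  set.seed(88)
  for (seed in 1:3) {
    asm <- make_reference(1, 80000, seed = 200 + seed)
    ann <- make_annotation(asm, 8, c(1500, 6000), c(2, 4),
                           seed = 300 + seed)
    for (k in seq_len(100)) {
      a <- sample.int(80000L - 3000L, 1) - 1L
      b <- a + sample(200:3000, 1)
      got <- classifier_label(classify_circle(
        list(chrom = "chr1", start = a, end = b), ann))
      expect_equal(got, bf_classify("chr1", a, b, ann))
    }
  }
})

test_that("catalog summaries bin, count and conserve correctly", {
  calls <- data.frame(call_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(0L, 100L, 200L),
                      end = c(500L, 800L, 7200L),
                      length = c(500L, 700L, 7000L),
                      split_support = 2L, discordant_support = 0L,
                      mean_depth = 10, enrichment = 100,
                      stringsAsFactors = FALSE)
  cat1 <- eccpipe:::new_circle_catalog("s1", calls)
  s <- summarize_catalog(cat1)
  expect_equal(s$n_eccDNA, 3)
  expect_equal(s$histogram$count[s$histogram$bin_start == 400], 1)
  expect_equal(s$histogram$count[s$histogram$bin_start == 600], 1)
  expect_equal(s$histogram$count[s$histogram$bin_start == 7000], 1)
  expect_equal(sum(s$histogram$count), 3)
  expect_equal(s$range_fraction, 2 / 3)

  # empty catalog: defined zeros, undefined percentage marker
  s0 <- summarize_catalog(eccpipe:::new_circle_catalog("e",
                                                       eccpipe:::empty_calls()))
  expect_equal(s0$n_eccDNA, 0)
  expect_true(is.na(s0$range_fraction))
  expect_equal(nrow(s0$histogram), 0)

  # conservation invariants on a simulated catalog, any bin size
  pipe <- run_small_pipeline(n_circles = 10, n_read_pairs = 4000, seed = 41)
  for (bs in c(100, 200, 500)) {
    ss <- summarize_catalog(pipe$catalog, pipe$ann, bin_size = bs)
    expect_equal(sum(ss$histogram$count), ss$n_eccDNA)
    expect_equal(sum(ss$content_counts), ss$n_eccDNA)
    expect_equal(sum(ss$per_chrom$count), ss$n_eccDNA)
  }

  # classifier matches simulated origin classes for the unambiguous kinds
  truth <- pipe$circles
  ev <- evaluate_calls(truth, pipe$catalog)
  cls <- eccpipe:::classify_calls(pipe$catalog$calls, pipe$ann)
  m <- ev$matches
  for (i in seq_len(nrow(m))) {
    oc <- truth$origin_class[truth$circle_id == m$circle_id[i]]
    ci <- which(pipe$catalog$calls$call_id == m$call_id[i])
    if (oc %in% c("full_gene", "intergenic"))
      expect_equal(cls$kind[ci], oc)
  }
})

test_that("full-gene percentages render at two significant figures", {
  expect_equal(full_gene_report(17, 5413)$pct, "0.31%")
  expect_equal(full_gene_report(44, 58860)$pct, "0.075%")
  expect_equal(full_gene_report(0, 100)$pct, "0.0%")
  expect_true(is.na(full_gene_report(0, 0)$pct))
  r <- full_gene_report(c(full_gene = 2, partial_gene = 3, intergenic = 5))
  expect_equal(r$n_total, 10L)
  expect_equal(r$pct, "20%")
})

test_that("chromosome distribution tests proportionality to length", {
  lens <- c(chr1 = 1e6, chr2 = 2e6)
  # uniform multinomial placement: p should not reject (binomial bound
  # chosen before the run: P(reject at 0.01) ~ 0.01)
  set.seed(61)
  n <- 3000
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
  calls <- data.frame(call_id = sprintf("c%04d", 1:n), chrom = chrom,
                      start = 0L, end = 1000L, length = 1000L,
                      split_support = 2L, discordant_support = 0L,
                      mean_depth = 1, enrichment = 10,
                      stringsAsFactors = FALSE)
  cd <- chromosome_distribution(eccpipe:::new_circle_catalog("u", calls),
                                lens)
  expect_gt(cd$p_value, 0.01)
  expect_equal(sum(cd$table$observed), n)

  # all calls on one of two equal chromosomes: statistic = n by hand
  lens2 <- c(chrA = 1e6, chrB = 1e6)
  calls2 <- calls[1:100, ]; calls2$chrom <- "chrA"
  cd2 <- chromosome_distribution(eccpipe:::new_circle_catalog("x", calls2),
                                 lens2)
  expect_equal(cd2$statistic, 100)

  # exactly proportional counts: statistic 0, p = 1
  calls3 <- calls[1:300, ]
  calls3$chrom <- rep(c("chr1", "chr2"), c(100, 200))
  cd3 <- chromosome_distribution(eccpipe:::new_circle_catalog("p", calls3),
                                 lens)
  expect_equal(cd3$statistic, 0)
  expect_equal(cd3$p_value, 1)

  # small expected counts are flagged
  cd4 <- chromosome_distribution(eccpipe:::new_circle_catalog("s",
                                                              calls[1, ]),
                                 lens)
  expect_true(cd4$small_expected_warning)
  expect_error(chromosome_distribution(eccpipe:::new_circle_catalog(
    "y", calls), c(chr1 = 1e6)), "at least 2")
})
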