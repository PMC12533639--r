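# Fabricate a coverage profile with real read depth over one region.
mk_profile <- function(chrom = "chrC", len = 20000L,
                       region = c(1000L, 10000L), n = 200L, seed = 51) {
  set.seed(seed)
  pos <- sort(sample(region[1]:(region[2] - 150L), n, replace = TRUE))
  rec <- make_records(sprintf("cv%04d", seq_len(n)), chrom, pos)
  coverage_profile(rec, setNames(len, chrom))
}

mk_junctions <- function(starts, ends, chrom = "chrC") {
  chrom <- rep_len(chrom, length(starts))
  ev <- data.frame(chrom = chrom, start = as.integer(starts),
                   end = as.integer(ends),
                   source = rep_len("split_read", length(starts)),
                   qname = sprintf("j%03d", seq_along(starts)),
                   stringsAsFactors = FALSE)
  class(ev) <- c("junction_evidence", "data.frame")
  ev
}

mk_discordants <- function(starts, ends, chrom = "chrC") {
  ev <- mk_junctions(starts, ends, chrom)
  ev$source <- rep_len("discordant_pair", nrow(ev))
  ev
}

no_discordants <- mk_discordants(integer(0), integer(0))

test_that("support and enrichment rules decide calls as specified", {
  prof <- mk_profile()
  cfg <- caller_config()

  # 3 identical split junctions, enriched region -> one call, support 3
  cat1 <- cluster_and_call(mk_junctions(rep(1000, 3), rep(10000, 3)),
                           no_discordants, prof, cfg, "t")
  expect_equal(cat1$n_eccDNA, 1)
  expect_equal(cat1$calls$split_support, 3L)
  expect_equal(cat1$calls$length, 9000L)
  expect_gt(cat1$calls$enrichment, 2)

  # a single split read is not enough under defaults
  cat2 <- cluster_and_call(mk_junctions(1000, 10000), no_discordants,
                           prof, cfg, "t")
  expect_equal(cat2$n_eccDNA, 0)
  expect_equal(unname(cat2$log$rejected["low_support"]), 1L)

  # ... unless two discordant pairs corroborate it
  cat3 <- cluster_and_call(mk_junctions(1000, 10000),
                           mk_discordants(c(1200, 1300), c(9800, 9700)),
                           prof, cfg, "t")
  expect_equal(cat3$n_eccDNA, 1)
  expect_equal(cat3$calls$discordant_support, 2L)

  # discordant evidence alone never calls
  cat4 <- cluster_and_call(mk_junctions(integer(0), integer(0)),
                           mk_discordants(c(1200, 1300), c(9800, 9700)),
                           prof, cfg, "t")
  expect_equal(cat4$n_eccDNA, 0)

  # support in an unenriched region is rejected on enrichment
  cat5 <- cluster_and_call(mk_junctions(rep(12000, 3), rep(19000, 3)),
                           no_discordants, prof, cfg, "t")
  expect_equal(cat5$n_eccDNA, 0)
  expect_equal(unname(cat5$log$rejected["low_enrichment"]), 1L)

  # too-short candidates are rejected on length
  cat6 <- cluster_and_call(mk_junctions(rep(1000, 3), rep(1100, 3)),
                           no_discordants, prof, cfg, "t")
  expect_equal(cat6$n_eccDNA, 0)
  expect_equal(unname(cat6$log$rejected["bad_length"]), 1L)

  # empty evidence, empty catalog
  cat7 <- cluster_and_call(mk_junctions(integer(0), integer(0)),
                           no_discordants, prof, cfg, "t")
  expect_equal(cat7$n_eccDNA, 0)
})

test_that("nearby junctions merge; distinct overlapping calls both stand", {
  prof <- mk_profile()
  cfg <- caller_config()
  # within epsilon on both breakpoints: one merged call, supports summed
  j <- mk_junctions(c(1000, 1003, 1000, 1004), c(10000, 10003, 9998, 10002))
  cat1 <- cluster_and_call(j, no_discordants, prof, cfg, "t")
  expect_equal(cat1$n_eccDNA, 1)
  expect_equal(cat1$calls$split_support, 4L)

  # overlapping but outside epsilon: both calls appear
  j2 <- mk_junctions(c(1000, 1000, 1500, 1500), c(10000, 10000, 9500, 9500))
  cat2 <- cluster_and_call(j2, no_discordants, prof, cfg, "t")
  expect_equal(cat2$n_eccDNA, 2)
  expect_true(all(diff(cat2$calls$start) > 0))  # sorted by start
})

test_that("union-find clustering matches brute-force transitive closure", {
  set.seed(77)
  for (k in seq_len(20)) {
    n <- sample(10:200, 1)
    starts <- sample.int(5000, n, replace = TRUE)
    ends <- starts + 500L + sample.int(200, n, replace = TRUE)
    eps <- sample(c(2L, 5L, 10L), 1)
    got <- eccpipe:::cluster_breakpoints(starts, ends, eps)
    want <- bf_cluster(starts, ends, eps)
    expect_true(same_clustering(got, want))
  }
})

test_that("identical input produces byte-identical catalogs", {
  pipe <- run_small_pipeline(n_circles = 5, n_read_pairs = 2500, seed = 23)
  c1 <- call_circles(pipe$truth$sam_path, chrom_lengths(pipe$asm),
                     caller_config(), "rep")
  c2 <- call_circles(pipe$truth$sam_path, chrom_lengths(pipe$asm),
                     caller_config(), "rep")
  t1 <- tempfile(); t2 <- tempfile()
  write_catalog(c1, tsv_path = t1)
  write_catalog(c2, tsv_path = t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("catalog round-trips through TSV and BED keeps the length rule", {
  pipe <- run_small_pipeline(n_circles = 5, n_read_pairs = 2500, seed = 29)
  cat1 <- pipe$catalog
  expect_gt(cat1$n_eccDNA, 0)
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  write_catalog(cat1, bed, tsv)
  back <- read_catalog(tsv)
  expect_equal(back$calls, cat1$calls)
  expect_equal(back$sample_id, cat1$sample_id)
  expect_equal(back$n_eccDNA, cat1$n_eccDNA)
  # BED start/end are the 0-based half-open interval: end - start = length
  fields <- strsplit(readLines(bed), "\t")
  for (i in seq_along(fields)) {
    expect_equal(as.integer(fields[[i]][3]) - as.integer(fields[[i]][2]),
                 cat1$calls$length[i])
  }
  # malformed TSV reports a line
  bad <- tempfile()
  writeLines(c("sample_id\tcall_id\tchrom\tstart\tend\tlength",
               "s\tc1\tchr1\t100\t50\t50"), bad)
  expect_error(read_catalog(bad), "missing column")
})
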