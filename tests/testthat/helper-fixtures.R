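# Shared fixtures and independent brute-force oracles.

# Small assembly/annotation reused across tests (built once per run).
fx_env <- new.env()

fx_assembly <- function() {
  if (is.null(fx_env$asm))
    fx_env$asm <- make_reference(2, c(100000, 150000), gc = 0.45, seed = 101)
  fx_env$asm
}

# Larger two-chromosome genome (3 Mb total) for end-to-end recovery runs.
fx_big <- function() {
  if (is.null(fx_env$big)) {
    asm <- make_reference(2, c(1e6, 2e6), gc = 0.41, seed = 7001)
    ann <- make_annotation(asm, 60, c(2000, 8000), c(2, 5), seed = 7002)
    fx_env$big <- list(asm = asm, ann = ann)
  }
  fx_env$big
}

fx_annotation <- function() {
  if (is.null(fx_env$ann))
    fx_env$ann <- make_annotation(fx_assembly(), 12, c(2000, 6000),
                                  c(2, 4), seed = 102)
  fx_env$ann
}

# Construct an alignment_records data.frame directly (internal frame:
# 0-based positions).
make_records <- function(qname, chrom, pos, strand = "+", cigar = "150M",
                         mate = 1L, is_supplementary = FALSE,
                         mapped = TRUE, mate_chrom = chrom,
                         mate_pos = pos, mate_strand = "+",
                         is_proper = FALSE) {
  n <- length(qname)
  for (v in c("chrom", "pos", "strand", "cigar", "mate", "is_supplementary",
              "mapped", "mate_chrom", "mate_pos", "mate_strand",
              "is_proper"))
    assign(v, rep_len(get(v), n))
  geom <- eccpipe:::parse_cigar_geometry(cigar)
  rec <- data.frame(qname = qname, mate = mate, chrom = chrom, pos = pos,
                    strand = strand, cigar = cigar,
                    left_clip = geom$left_clip, ref_len = geom$ref_len,
                    right_clip = geom$right_clip, read_len = geom$read_len,
                    is_supplementary = is_supplementary, mapped = mapped,
                    mate_chrom = mate_chrom, mate_pos = mate_pos,
                    mate_strand = mate_strand, mate_mapped = rep_len(TRUE, n),
                    is_proper = is_proper, stringsAsFactors = FALSE)
  class(rec) <- c("alignment_records", "data.frame")
  rec
}

# Write a SAM file from 1-based fields.
write_test_sam <- function(path, body, sq = c(chrT = 200000L)) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)))
  writeLines(c(header, body), path)
  path
}

sam_line <- function(qname, flag, chrom, pos1, cigar, pnext1 = pos1,
                     seq = NULL, mapq = 60L) {
  if (is.null(seq)) {
    geom <- eccpipe:::parse_cigar_geometry(cigar)
    n <- max(geom$read_len, 1L)
    seq <- strrep("A", n)
  }
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t0\t%s\t%s",
          qname, flag, chrom, pos1, mapq, cigar, pnext1, seq,
          strrep("?", nchar(seq)))
}

# Brute-force single-linkage clustering by transitive closure (BFS over the
# eps-adjacency graph); independent of the union-find implementation.
bf_cluster <- function(starts, ends, eps) {
  n <- length(starts)
  adj <- outer(starts, starts, function(a, b) abs(a - b) <= eps) &
    outer(ends, ends, function(a, b) abs(a - b) <= eps)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# Canonical form of a clustering: sets of member indices.
cluster_sets <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}

same_clustering <- function(a, b) {
  setequal(lapply(cluster_sets(a), paste, collapse = ","),
           lapply(cluster_sets(b), paste, collapse = ","))
}

# Brute-force per-base gene-content classifier.
bf_classify <- function(chrom, start, end, ann) {
  g <- ann$genes[ann$genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return("intergenic")
  ov <- pmin(end, g$end) - pmax(start, g$start)
  if (all(ov <= 0)) return("intergenic")
  if (any(g$start >= start & g$end <= end)) return("full_gene")
  f <- ann$features[ann$features$gene_id %in% g$gene_id[ov > 0], ,
                    drop = FALSE]
  # materialize the kind of every base of the query interval
  base_kind <- rep(NA_character_, end - start)
  for (i in seq_len(nrow(f))) {
    lo <- max(start, f$start[i]); hi <- min(end, f$end[i])
    if (hi > lo) base_kind[(lo - start + 1L):(hi - start)] <- f$kind[i]
  }
  order_k <- c("intron", "exon", "five_prime_utr", "three_prime_utr")
  tot <- vapply(order_k, function(k) sum(base_kind == k, na.rm = TRUE),
                numeric(1))
  win <- order_k[which.max(tot)]
  paste0("partial_",
         c(intron = "intronic", exon = "exonic",
           five_prime_utr = "five_prime_utr",
           three_prime_utr = "three_prime_utr")[[win]])
}

# Map classify_circle output onto the bf_classify label space.
classifier_label <- function(cls) {
  if (cls$kind != "partial_gene") cls$kind
  else paste0("partial_", cls$subtype)
}

# Small end-to-end simulation + calling, shared by several tests.
run_small_pipeline <- function(n_circles = 8, n_read_pairs = 4000,
                               error_rate = 0, background_frac = 0,
                               seed = 5, sample_id = "s1") {
  asm <- fx_assembly(); ann <- fx_annotation()
  cfg <- sim_config(n_circles = n_circles, n_read_pairs = n_read_pairs,
                    error_rate = error_rate,
                    background_frac = background_frac, seed = seed)
  circles <- sample_circles(asm, ann, cfg)
  truth <- simulate_reads(asm, circles, cfg, out_prefix = tempfile("pipe"),
                          write_fastq = FALSE)
  catalog <- call_circles(truth$sam_path, chrom_lengths(asm),
                          caller_config(), sample_id)
  list(asm = asm, ann = ann, cfg = cfg, circles = circles, truth = truth,
       catalog = catalog)
}
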