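#' Simulate a rolling-circle-amplified paired-end library
#'
#' Models the circle-enriched library end to end: each circle is amplified
#' into a tandem concatemer (geometric copy number, minimum 2, mean
#' `rca_fold`), fragmented uniformly, and sequenced as FR (innie) 150-bp
#' paired-end reads. A fragment spanning the circle junction yields an
#' outward-facing (RF) pair in linear coordinates; a read spanning the
#' junction yields a split alignment (right-clipped primary near the circle
#' end plus a left-clipped supplementary at the circle start, emitted when
#' both segments are at least 20 bp). A `background_frac` fraction of pairs
#' is drawn from random linear genomic fragments, standing in for incomplete
#' exonuclease digestion. Alignments are emitted directly as a truth SAM
#' (positions are known exactly), so no external aligner is needed.
#'
#' @param assembly a `genome_assembly`.
#' @param circles a `true_circles` data.frame from [sample_circles()].
#' @param config a [sim_config()].
#' @param out_prefix path prefix for output files (`<prefix>.sam`,
#'   `<prefix>_R1.fastq`, `<prefix>_R2.fastq`, `<prefix>_truth.tsv`).
#' @param write_fastq emit FASTQ files as well as the truth SAM.
#' @return A `sim_truth` list: `circles`, `reads` (per-read provenance:
#'   qname, mate, origin circle or `background`, primary position, strand,
#'   junction flag), `read_counts` (pairs and expected coverage per circle),
#'   and the paths written.
#' @export
simulate_reads <- function(assembly, circles, config,
                           out_prefix = tempfile("eccsim"),
                           write_fastq = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  lens <- chrom_lengths(assembly)
  if (nrow(circles) > 0) {
    if (any(!circles$chrom %in% names(lens)))
      stop_invalid("circle chromosome not in assembly")
    if (any(circles$end > lens[circles$chrom]) || any(circles$start < 0))
      stop_invalid("circle interval outside chromosome bounds")
    if (any(circles$length < config$read_len))
      stop_invalid("circle shorter than read_len (%d); rejected",
                   config$read_len)
  }
  rl <- config$read_len
  reads_seed <- (config$seed + 77003L) %% 2147483647L
  sim <- with_seed(reads_seed, {
    n_bg <- rbinom(1L, config$n_read_pairs, config$background_frac)
    n_circ <- config$n_read_pairs - n_bg
    alloc <- integer(nrow(circles))
    if (nrow(circles) > 0 && n_circ > 0)
      alloc <- as.integer(rmultinom(1L, n_circ, prob = circles$length))
    parts <- vector("list", nrow(circles) + 1L)
    for (i in seq_len(nrow(circles))) {
      if (alloc[i] == 0L) next
      circ <- circles[i, ]
      cseq <- subseq0(assembly, circ$chrom, circ$start, circ$end)
      parts[[i]] <- sim_circle_pairs(circ, alloc[i], cseq, config)
    }
    if (n_bg > 0L)
      parts[[length(parts)]] <- sim_background_pairs(assembly, n_bg, config)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    recs <- do.call(rbind, lapply(parts, `[[`, "records"))
    prov <- do.call(rbind, lapply(parts, `[[`, "provenance"))
    if (is.null(recs)) {
      recs <- empty_sam_records(); prov <- empty_provenance()
    }
    # read sequence lives on the read (primary and supplementary records of
    # one read share it); substitution errors are applied per read
    prim <- !bitwAnd(recs$flag, 2048L)
    prov$seq <- recs$seq[match(paste(prov$qname, prov$mate),
                               paste(recs$qname[prim], recs$mate[prim]))]
    if (config$error_rate > 0 && nrow(prov) > 0) {
      prov$seq <- apply_substitutions(prov$seq, config$error_rate)
      recs$seq <- prov$seq[match(paste(recs$qname, recs$mate),
                                 paste(prov$qname, prov$mate))]
    }
    list(records = recs, provenance = prov, n_bg = n_bg, alloc = alloc)
  })
  sam_path <- paste0(out_prefix, ".sam")
  write_truth_sam(sim$records, lens, sam_path)
  fq1 <- paste0(out_prefix, "_R1.fastq"); fq2 <- paste0(out_prefix, "_R2.fastq")
  if (write_fastq) write_sim_fastq(sim$provenance, rl, fq1, fq2)
  truth_path <- paste0(out_prefix, "_truth.tsv")
  counts <- data.frame(circle_id = circles$circle_id, chrom = circles$chrom,
                       start = circles$start, end = circles$end,
                       length = circles$length,
                       origin_class = circles$origin_class,
                       n_reads = 2L * sim$alloc,
                       coverage = 2 * sim$alloc * rl / circles$length,
                       stringsAsFactors = FALSE)
  write.table(counts, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  prov <- sim$provenance
  prov$seq <- NULL
  structure(list(circles = circles, reads = prov, read_counts = counts,
                 n_background_pairs = sim$n_bg, sam_path = sam_path,
                 fastq_paths = if (write_fastq) c(fq1, fq2) else NULL,
                 truth_path = truth_path, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("sim_truth: %d circle(s), %d read pair(s) ",
                     "(%d background)\n  SAM: %s\n"),
              nrow(x$circles), sum(x$read_counts$n_reads) / 2 +
                x$n_background_pairs,
              x$n_background_pairs, x$sam_path))
  invisible(x)
}

# Truncated normal by inverse CDF (always n RNG draws; deterministic).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

sim_circle_pairs <- function(circ, n_pairs, cseq, cfg) {
  L <- circ$length; rl <- cfg$read_len; cs <- circ$start
  copies <- 2L + rgeom(1L, 1 / (cfg$rca_fold - 1))
  concat_len <- copies * L
  ins <- as.integer(round(rnorm_trunc(n_pairs, cfg$insert_mean,
                                      cfg$insert_sd, cfg$insert_min,
                                      min(cfg$insert_max, concat_len))))
  ins <- pmin(pmax(ins, rl), concat_len)
  s <- floor(runif(n_pairs) * (concat_len - ins + 1))
  a1 <- s %% L
  a2 <- (s + ins - rl) %% L
  frag_wraps <- (s %% L) + ins > L
  qn <- sprintf("%s_p%06d", circ$circle_id, seq_len(n_pairs))
  circ2 <- paste0(cseq, cseq)
  r1 <- read_geometry(a1, L, rl); r2 <- read_geometry(a2, L, rl)
  proper <- !frag_wraps
  build_pair_output(qn, circ$chrom, cs, circ2, r1, r2, proper, rl,
                    origin = circ$circle_id)
}

sim_background_pairs <- function(assembly, n_pairs, cfg) {
  lens <- chrom_lengths(assembly); rl <- cfg$read_len
  chrom <- sample(names(lens), n_pairs, replace = TRUE, prob = lens)
  ins <- as.integer(round(rnorm_trunc(n_pairs, cfg$insert_mean,
                                      cfg$insert_sd, cfg$insert_min,
                                      cfg$insert_max)))
  ins <- pmin(ins, lens[chrom] - 1L)
  start <- floor(runif(n_pairs) * (lens[chrom] - ins))
  qn <- sprintf("bg_p%06d", seq_len(n_pairs))
  p1 <- as.integer(start); p2 <- as.integer(start + ins - rl)
  seq1 <- vapply(seq_len(n_pairs), function(i)
    subseq0(assembly, chrom[i], p1[i], p1[i] + rl), character(1))
  seq2 <- vapply(seq_len(n_pairs), function(i)
    subseq0(assembly, chrom[i], p2[i], p2[i] + rl), character(1))
  qual <- strrep("?", rl)
  recs <- rbind(
    data.frame(qname = qn, mate = 1L, flag = 99L, chrom = chrom, pos1 = p1 + 1L,
               cigar = paste0(rl, "M"), pnext1 = p2 + 1L, seq = seq1,
               stringsAsFactors = FALSE),
    data.frame(qname = qn, mate = 2L, flag = 147L, chrom = chrom,
               pos1 = p2 + 1L, cigar = paste0(rl, "M"), pnext1 = p1 + 1L,
               seq = seq2, stringsAsFactors = FALSE))
  recs <- recs[order(match(recs$qname, qn), recs$mate), , drop = FALSE]
  prov <- data.frame(qname = rep(qn, each = 2L), mate = rep(1:2, n_pairs),
                     origin = "background",
                     chrom = rep(chrom, each = 2L),
                     pos = as.vector(rbind(p1, p2)),
                     strand = rep(c("+", "-"), n_pairs),
                     spans_junction = FALSE, stringsAsFactors = FALSE)
  list(records = recs, provenance = prov)
}

# Split geometry of a read covering circle offsets [a, a + rl) on a circle
# of length L: leading segment length, wrap flag, supplementary eligibility.
read_geometry <- function(a, L, rl, min_seg = 20L) {
  wrap <- a + rl > L
  seg1 <- ifelse(wrap, L - a, rl)
  seg2 <- rl - seg1
  has_supp <- wrap & seg1 >= min_seg & seg2 >= min_seg
  list(a = a, wrap = wrap, seg1 = as.integer(seg1), seg2 = as.integer(seg2),
       has_supp = has_supp)
}

# Assemble SAM records and provenance for n pairs on one circle.
build_pair_output <- function(qn, chrom, cs, circ2, r1, r2, proper, rl,
                              origin) {
  n <- length(qn)
  mk_mate <- function(g, strand_rev) {
    # primary record geometry for one mate; reference-orientation CIGAR is
    # identical for + and - strand reads
    pos0 <- integer(n); cig <- character(n)
    plain <- !g$wrap
    pos0[plain] <- cs + g$a[plain]
    cig[plain] <- paste0(rl, "M")
    w <- g$wrap & (g$has_supp | g$seg2 < g$seg1)   # primary = leading segment
    pos0[w] <- cs + g$a[w]
    cig[w] <- paste0(g$seg1[w], "M", g$seg2[w], "S")
    w2 <- g$wrap & !g$has_supp & g$seg2 >= g$seg1  # short leading tail only
    pos0[w2] <- cs
    cig[w2] <- paste0(g$seg1[w2], "S", g$seg2[w2], "M")
    seqs <- substring(circ2, g$a + 1L, g$a + rl)
    list(pos0 = pos0, cigar = cig, seq = seqs)
  }
  m1 <- mk_mate(r1, FALSE); m2 <- mk_mate(r2, TRUE)
  f1 <- 1L + 64L + 32L + ifelse(proper, 2L, 0L)
  f2 <- 1L + 128L + 16L + ifelse(proper, 2L, 0L)
  prim <- rbind(
    data.frame(qname = qn, mate = 1L, flag = f1, chrom = chrom,
               pos1 = m1$pos0 + 1L, cigar = m1$cigar, pnext1 = m2$pos0 + 1L,
               seq = m1$seq, stringsAsFactors = FALSE),
    data.frame(qname = qn, mate = 2L, flag = f2, chrom = chrom,
               pos1 = m2$pos0 + 1L, cigar = m2$cigar, pnext1 = m1$pos0 + 1L,
               seq = m2$seq, stringsAsFactors = FALSE))
  supp <- NULL
  mk_supp <- function(g, m, mate, flag_base, mate_pos0) {
    k <- which(g$has_supp)
    if (length(k) == 0L) return(NULL)
    data.frame(qname = qn[k], mate = mate, flag = flag_base[k] + 2048L,
               chrom = chrom, pos1 = cs + 1L,
               cigar = paste0(g$seg1[k], "S", g$seg2[k], "M"),
               pnext1 = mate_pos0[k] + 1L, seq = m$seq[k],
               stringsAsFactors = FALSE)
  }
  supp <- rbind(mk_supp(r1, m1, 1L, f1, m2$pos0),
                mk_supp(r2, m2, 2L, f2, m1$pos0))
  recs <- rbind(prim, supp)
  recs <- recs[order(match(recs$qname, qn), recs$mate,
                     bitwAnd(recs$flag, 2048L)), , drop = FALSE]
  prov <- data.frame(
    qname = rep(qn, each = 2L), mate = rep(1:2, n), origin = origin,
    chrom = chrom,
    pos = as.vector(rbind(m1$pos0, m2$pos0)),
    strand = rep(c("+", "-"), n),
    spans_junction = as.vector(rbind(r1$wrap, r2$wrap)),
    stringsAsFactors = FALSE)
  list(records = recs, provenance = prov)
}

empty_sam_records <- function() {
  data.frame(qname = character(), mate = integer(), flag = integer(),
             chrom = character(), pos1 = integer(), cigar = character(),
             pnext1 = integer(), seq = character(), stringsAsFactors = FALSE)
}

empty_provenance <- function() {
  data.frame(qname = character(), mate = integer(), origin = character(),
             chrom = character(), pos = integer(), strand = character(),
             spans_junction = logical(), stringsAsFactors = FALSE)
}

# Random substitutions at a fixed per-base rate; never emits the original
# base at a mutated position.
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  nc <- nchar(seqs)
  n_err <- rbinom(length(seqs), nc, rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nc[i], n_err[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

write_truth_sam <- function(recs, lens, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), unname(lens)),
              "@PG\tID:eccpipe\tPN:eccpipe")
  qual <- vapply(nchar(recs$seq), function(n) strrep("?", n), character(1))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t%s\t%s",
                  recs$qname, recs$flag, recs$chrom, recs$pos1, recs$cigar,
                  recs$pnext1, recs$seq, qual)
  writeLines(c(header, body), path)
  invisible(path)
}

write_sim_fastq <- function(prov, rl, fq1, fq2) {
  qual <- strrep("?", rl)
  emit <- function(rows, path) {
    seqs <- rows$seq
    rev <- rows$strand == "-"
    if (any(rev))
      seqs[rev] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rev])))
    writeLines(as.vector(rbind(paste0("@", rows$qname, "/", rows$mate[1]),
                               seqs, "+", qual)), path)
  }
  emit(prov[prov$mate == 1L, , drop = FALSE], fq1)
  emit(prov[prov$mate == 2L, , drop = FALSE], fq2)
  invisible(c(fq1, fq2))
}
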