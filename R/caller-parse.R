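#' Parse SAM/BAM alignments into a record table
#'
#' Reads a SAM (or BAM) file through Rsamtools and normalizes it to the
#' caller's internal record frame: 0-based positions, decoded flags and clip
#' geometry. Unmapped records are retained with `mapped = FALSE`. A QC
#' summary (total reads, mapped fraction) is attached as the `"qc"`
#' attribute; the mapped fraction is the standard first health check of a
#' circle-enriched library.
#'
#' @param sam_path path to a SAM or BAM file with an `@SQ` header.
#' @return An `alignment_records` data.frame with columns `qname`, `mate`
#'   (1, 2 or 0 for unpaired), `chrom`, `pos` (0-based), `strand`, `cigar`,
#'   `left_clip`, `ref_len` (reference bases consumed), `right_clip`,
#'   `read_len` (query bases), `is_supplementary`, `mapped`, `mate_chrom`,
#'   `mate_pos` (0-based), `mate_strand`, `is_proper`.
#' @export
parse_alignments <- function(sam_path) {
  if (!file.exists(sam_path)) stop_invalid("alignment file not found: %s",
                                           sam_path)
  bam <- sam_path
  if (!grepl("\\.bam$", sam_path, ignore.case = TRUE)) {
    hdr <- readLines(sam_path, n = 50L)
    if (!any(startsWith(hdr, "@SQ")))
      stop_invalid("SAM parse error: missing @SQ header lines in %s",
                   sam_path)
    bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    Rsamtools::BamFile(bam),
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "mrnm", "mpos")))[[1]]
  flag <- res$flag
  n <- length(flag)
  mapped <- bitwAnd(flag, 4L) == 0L
  cg <- parse_cigar_geometry(res$cigar, mapped)
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                 ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L))
  rec <- data.frame(
    qname = res$qname,
    mate = mate,
    chrom = as.character(res$rname),
    pos = res$pos - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = res$cigar,
    left_clip = cg$left_clip, ref_len = cg$ref_len,
    right_clip = cg$right_clip, read_len = cg$read_len,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    mapped = mapped,
    mate_chrom = as.character(res$mrnm),
    mate_pos = res$mpos - 1L,
    mate_strand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    mate_mapped = bitwAnd(flag, 8L) == 0L,
    is_proper = bitwAnd(flag, 2L) > 0L,
    stringsAsFactors = FALSE)
  n_primary <- sum(!rec$is_supplementary)
  qc <- list(total_reads = n_primary,
             total_records = n,
             mapped_fraction = if (n_primary > 0)
               sum(mapped & !rec$is_supplementary) / n_primary else NA_real_)
  attr(rec, "qc") <- qc
  class(rec) <- c("alignment_records", "data.frame")
  rec
}

#' @export
print.alignment_records <- function(x, ...) {
  qc <- attr(x, "qc")
  if (is.null(qc)) {  # subset without QC: plain table view
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat(sprintf(paste0("alignment_records: %d record(s), %d read(s), ",
                     "mapped fraction %.4f\n"),
              qc$total_records, qc$total_reads, qc$mapped_fraction))
  invisible(x)
}

# Clip geometry from CIGAR strings. Query-consumed ops: M, I, S (H treated
# as S for geometry); reference-consumed: M, D. Ops outside {M,I,D,S,H}
# raise a parse error.
parse_cigar_geometry <- function(cigars, mapped = NULL) {
  n <- length(cigars)
  out <- list(left_clip = integer(n), ref_len = integer(n),
              right_clip = integer(n), read_len = integer(n))
  todo <- if (is.null(mapped)) !is.na(cigars) & cigars != "*" else
    mapped & !is.na(cigars) & cigars != "*"
  if (!any(todo)) return(out)
  toks <- regmatches(cigars[todo], gregexpr("[0-9]+[A-Z=]", cigars[todo]))
  geom <- lapply(toks, function(tk) {
    len <- as.integer(sub("[A-Z=]$", "", tk))
    op <- sub("^[0-9]+", "", tk)
    bad <- setdiff(op, c("M", "I", "D", "S", "H"))
    if (length(bad) > 0)
      stop_invalid("CIGAR parse error: unsupported op '%s'", bad[1])
    clip <- op %in% c("S", "H")
    k <- length(op)
    left <- 0L
    i <- 1L
    while (i <= k && clip[i]) { left <- left + len[i]; i <- i + 1L }
    right <- 0L
    j <- k
    while (j >= i && clip[j]) { right <- right + len[j]; j <- j - 1L }
    c(left,
      sum(len[op %in% c("M", "D")]),
      right,
      sum(len[op %in% c("M", "I", "S", "H")]))
  })
  geom <- do.call(rbind, geom)
  out$left_clip[todo] <- geom[, 1]
  out$ref_len[todo] <- geom[, 2]
  out$right_clip[todo] <- geom[, 3]
  out$read_len[todo] <- geom[, 4]
  out
}
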