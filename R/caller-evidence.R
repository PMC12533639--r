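#' Extract split-read junction evidence
#'
#' Pairs each primary alignment with its supplementary record(s) by read
#' identity. Circular geometry — the leading read segment (no left clip)
#' mapping *downstream* of the trailing, left-clipped segment on the same
#' chromosome and strand — yields one junction: circle start = trailing
#' segment's start, circle end = leading segment's end (its position plus
#' reference-consumed length). Linear split geometry (leading segment
#' upstream) and cross-chromosome or cross-strand splits yield nothing and
#' are tallied.
#'
#' @param records an `alignment_records` data.frame.
#' @return A `junction_evidence` data.frame (`chrom`, `start`, `end`,
#'   `source = "split_read"`, `qname`) with a `"tallies"` attribute counting
#'   skipped split categories.
#' @export
extract_split_junctions <- function(records) {
  rec <- records[records$mapped, , drop = FALSE]
  key <- paste(rec$qname, rec$mate)
  supp <- rec[rec$is_supplementary, , drop = FALSE]
  prim <- rec[!rec$is_supplementary, , drop = FALSE]
  tallies <- c(non_circular_split = 0L, cross_chrom_or_strand = 0L,
               ambiguous_clip = 0L)
  if (nrow(supp) == 0L)
    return(empty_junctions(tallies))
  pk <- paste(prim$qname, prim$mate)
  m <- match(paste(supp$qname, supp$mate), pk)
  ok <- !is.na(m)
  supp <- supp[ok, , drop = FALSE]; pm <- prim[m[ok], , drop = FALSE]
  same <- supp$chrom == pm$chrom & supp$strand == pm$strand
  tallies["cross_chrom_or_strand"] <- sum(!same)
  supp <- supp[same, , drop = FALSE]; pm <- pm[same, , drop = FALSE]
  if (nrow(supp) == 0L) return(empty_junctions(tallies))
  # orient each (primary, supplementary) pair into leading/trailing segments
  p_leading <- pm$left_clip == 0L & supp$left_clip > 0L
  s_leading <- supp$left_clip == 0L & pm$left_clip > 0L
  amb <- !(p_leading | s_leading)
  tallies["ambiguous_clip"] <- sum(amb)
  lead_pos <- ifelse(p_leading, pm$pos, supp$pos)
  lead_end <- lead_pos + ifelse(p_leading, pm$ref_len, supp$ref_len)
  trail_pos <- ifelse(p_leading, supp$pos, pm$pos)
  circular <- !amb & lead_pos > trail_pos
  tallies["non_circular_split"] <- sum(!amb & lead_pos <= trail_pos)
  idx <- which(circular)
  if (length(idx) == 0L) return(empty_junctions(tallies))
  ev <- data.frame(chrom = supp$chrom[idx],
                   start = as.integer(trail_pos[idx]),
                   end = as.integer(lead_end[idx]),
                   source = "split_read",
                   qname = supp$qname[idx], stringsAsFactors = FALSE)
  ev <- ev[ev$end > ev$start, , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "tallies") <- tallies
  class(ev) <- c("junction_evidence", "data.frame")
  ev
}

empty_junctions <- function(tallies = integer()) {
  structure(data.frame(chrom = character(), start = integer(),
                       end = integer(), source = character(),
                       qname = character(), stringsAsFactors = FALSE),
            tallies = tallies,
            class = c("junction_evidence", "data.frame"))
}

#' Extract outward-facing discordant-pair evidence
#'
#' A sequenced fragment spanning a circular junction leaves its mates
#' outward-facing (RF) in linear coordinates: the leftmost mate on the minus
#' strand, the rightmost on the plus strand. Each such pair (both mates
#' mapped, same chromosome, span at most `max_circle_len`) contributes a
#' containing-interval hint from the leftmost mate's start to the rightmost
#' mate's end — not a precise breakpoint. Proper FR pairs and
#' inter-chromosomal pairs are ignored with counters.
#'
#' @param records an `alignment_records` data.frame.
#' @param max_circle_len largest admissible mate span, bp.
#' @return A `junction_evidence` data.frame with `source =
#'   "discordant_pair"` and a `"tallies"` attribute.
#' @export
extract_discordant_pairs <- function(records, max_circle_len = 10e6) {
  prim <- records[records$mapped & !records$is_supplementary &
                    records$mate %in% c(1L, 2L), , drop = FALSE]
  tallies <- c(fr_or_other = 0L, inter_chromosomal = 0L, span_too_long = 0L)
  r1 <- prim[prim$mate == 1L, , drop = FALSE]
  r2 <- prim[prim$mate == 2L, , drop = FALSE]
  m <- match(r1$qname, r2$qname)
  ok <- !is.na(m)
  r1 <- r1[ok, , drop = FALSE]; r2 <- r2[m[ok], , drop = FALSE]
  if (nrow(r1) == 0L) return(empty_discordant(tallies))
  same <- r1$chrom == r2$chrom
  tallies["inter_chromosomal"] <- sum(!same)
  r1 <- r1[same, , drop = FALSE]; r2 <- r2[same, , drop = FALSE]
  left_is_1 <- r1$pos <= r2$pos
  left_strand <- ifelse(left_is_1, r1$strand, r2$strand)
  right_strand <- ifelse(left_is_1, r2$strand, r1$strand)
  rf <- left_strand == "-" & right_strand == "+"
  tallies["fr_or_other"] <- sum(!rf)
  r1 <- r1[rf, , drop = FALSE]; r2 <- r2[rf, , drop = FALSE]
  if (nrow(r1) == 0L) return(empty_discordant(tallies))
  start <- pmin(r1$pos, r2$pos)
  end <- pmax(r1$pos + r1$ref_len, r2$pos + r2$ref_len)
  keep <- (end - start) <= max_circle_len
  tallies["span_too_long"] <- sum(!keep)
  if (!any(keep)) return(empty_discordant(tallies))
  ev <- data.frame(chrom = r1$chrom[keep],
                   start = as.integer(start[keep]),
                   end = as.integer(end[keep]),
                   source = "discordant_pair",
                   qname = r1$qname[keep], stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  attr(ev, "tallies") <- tallies
  class(ev) <- c("junction_evidence", "data.frame")
  ev
}

empty_discordant <- function(tallies) {
  structure(data.frame(chrom = character(), start = integer(),
                       end = integer(), source = character(),
                       qname = character(), stringsAsFactors = FALSE),
            tallies = tallies,
            class = c("junction_evidence", "data.frame"))
}
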