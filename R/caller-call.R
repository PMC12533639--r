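#' Cluster junction evidence and call circles
#'
#' Split-read junctions are single-linkage clustered with tolerance
#' `epsilon` on *both* breakpoints (per chromosome); candidate breakpoints
#' are the per-cluster medians. Discordant evidence corroborates the
#' candidate whose breakpoints it brackets within `epsilon + max_insert`.
#' A candidate becomes a call iff its split support reaches `min_split`, or
#' a single split read is corroborated by `min_discordant_rescue` discordant
#' pairs; the call interval must further be enriched at least
#' `min_enrichment` over background and have an admissible length. Calls
#' within `epsilon` on both breakpoints are merged with supports summed.
#' All rejections are tallied by reason in the catalog log. Lengths follow
#' the 0-based half-open convention throughout: `length = end - start`.
#'
#' @param junctions split-read `junction_evidence`
#'   (see [extract_split_junctions()]).
#' @param discordants discordant-pair `junction_evidence`
#'   (see [extract_discordant_pairs()]).
#' @param coverage a [coverage_profile()].
#' @param config a [caller_config()].
#' @param sample_id sample label carried into the catalog.
#' @return A `circle_catalog`: list with `sample_id`, `calls` (data.frame
#'   `call_id`, `chrom`, `start`, `end`, `length`, `split_support`,
#'   `discordant_support`, `mean_depth`, `enrichment`, sorted by
#'   chromosome and start), `n_eccDNA`, `mean_length` and a `log` of
#'   evidence tallies and rejection reasons.
#' @export
cluster_and_call <- function(junctions, discordants, coverage, config,
                             sample_id = "sample") {
  stopifnot(inherits(config, "caller_config"))
  log <- list(n_split_evidence = nrow(junctions),
              n_discordant_evidence = nrow(discordants),
              split_tallies = attr(junctions, "tallies"),
              discordant_tallies = attr(discordants, "tallies"),
              rejected = c(low_support = 0L, low_enrichment = 0L,
                           bad_length = 0L))
  if (nrow(junctions) == 0L)
    return(new_circle_catalog(sample_id, empty_calls(), log))
  cand <- do.call(rbind, lapply(split(junctions, junctions$chrom),
                                function(j) {
    cl <- cluster_breakpoints(j$start, j$end, config$epsilon)
    agg <- lapply(split(seq_len(nrow(j)), cl), function(k)
      data.frame(chrom = j$chrom[k[1]],
                 start = as.integer(round(median(j$start[k]))),
                 end = as.integer(round(median(j$end[k]))),
                 split_support = length(k), stringsAsFactors = FALSE))
    do.call(rbind, agg)
  }))
  rownames(cand) <- NULL
  cand$discordant_support <- assign_discordants(cand, discordants,
                                                config$epsilon,
                                                config$max_insert)
  cand$length <- cand$end - cand$start
  enr <- lapply(seq_len(nrow(cand)), function(i)
    region_enrichment(coverage, cand$chrom[i], cand$start[i], cand$end[i]))
  cand$mean_depth <- vapply(enr, `[[`, numeric(1), "mean_depth")
  cand$enrichment <- vapply(enr, `[[`, numeric(1), "enrichment")
  supported <- cand$split_support >= config$min_split |
    (cand$split_support >= 1L &
       cand$discordant_support >= config$min_discordant_rescue)
  enriched <- cand$enrichment >= config$min_enrichment
  len_ok <- cand$length >= config$min_circle_len &
    cand$length <= config$max_circle_len
  log$rejected["low_support"] <- sum(!supported)
  log$rejected["low_enrichment"] <- sum(supported & !enriched)
  log$rejected["bad_length"] <- sum(supported & enriched & !len_ok)
  calls <- cand[supported & enriched & len_ok, , drop = FALSE]
  calls <- merge_calls(calls, config$epsilon)
  calls <- calls[order(calls$chrom, calls$start, calls$end), , drop = FALSE]
  rownames(calls) <- NULL
  if (nrow(calls) > 0)
    calls$call_id <- sprintf("%s_ecc%05d", sample_id, seq_len(nrow(calls)))
  else calls$call_id <- character(0)
  calls <- calls[, c("call_id", "chrom", "start", "end", "length",
                     "split_support", "discordant_support", "mean_depth",
                     "enrichment")]
  new_circle_catalog(sample_id, calls, log)
}

# Single-linkage clustering of (start, end) pairs with tolerance eps on
# both coordinates; union-find over a start-sorted sliding window.
cluster_breakpoints <- function(starts, ends, eps) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(starts, ends)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    b <- a + 1L
    while (b <= n && starts[ord[b]] - starts[i] <= eps) {
      j <- ord[b]
      if (abs(ends[j] - ends[i]) <= eps) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
      b <- b + 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Count discordant evidence bracketing each candidate: the evidence interval
# must lie inside the candidate (within eps slack) and each of its ends
# within eps + max_insert of the matching breakpoint. Each evidence row
# corroborates at most one candidate (the nearest by total breakpoint
# distance).
assign_discordants <- function(cand, disc, eps, max_insert) {
  counts <- integer(nrow(cand))
  if (is.null(disc) || nrow(disc) == 0L || nrow(cand) == 0L) return(counts)
  slack <- eps + max_insert
  for (d in seq_len(nrow(disc))) {
    ok <- which(cand$chrom == disc$chrom[d] &
                  disc$start[d] >= cand$start - eps &
                  disc$end[d] <= cand$end + eps &
                  disc$start[d] - cand$start <= slack &
                  cand$end - disc$end[d] <= slack)
    if (length(ok) == 0L) next
    dist <- abs(disc$start[d] - cand$start[ok]) +
      abs(cand$end[ok] - disc$end[d])
    best <- ok[which.min(dist)]
    counts[best] <- counts[best] + 1L
  }
  counts
}

merge_calls <- function(calls, eps) {
  if (nrow(calls) <= 1L) return(calls)
  out <- lapply(split(calls, calls$chrom), function(cc) {
    cl <- cluster_breakpoints(cc$start, cc$end, eps)
    do.call(rbind, lapply(split(seq_len(nrow(cc)), cl), function(k)
      data.frame(chrom = cc$chrom[k[1]],
                 start = as.integer(round(median(cc$start[k]))),
                 end = as.integer(round(median(cc$end[k]))),
                 split_support = sum(cc$split_support[k]),
                 discordant_support = sum(cc$discordant_support[k]),
                 length = NA_integer_,
                 mean_depth = stats::weighted.mean(cc$mean_depth[k],
                                                   cc$split_support[k]),
                 enrichment = stats::weighted.mean(cc$enrichment[k],
                                                   cc$split_support[k]),
                 stringsAsFactors = FALSE)))
  })
  res <- do.call(rbind, out)
  res$length <- res$end - res$start
  rownames(res) <- NULL
  res
}

empty_calls <- function() {
  data.frame(call_id = character(), chrom = character(), start = integer(),
             end = integer(), length = integer(), split_support = integer(),
             discordant_support = integer(), mean_depth = numeric(),
             enrichment = numeric(), stringsAsFactors = FALSE)
}

#' Construct a circle catalog from a call table
#'
#' Builds a `circle_catalog` from an externally assembled call data.frame
#' (for example calls imported from another caller). `length` is derived as
#' `end - start` when absent; missing support/depth columns default to
#' zero.
#'
#' @param sample_id sample label.
#' @param calls data.frame with at least `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A `circle_catalog`.
#' @export
circle_catalog <- function(sample_id, calls) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0)
    stop_invalid("calls lack column(s): %s", paste(miss, collapse = ", "))
  if (any(calls$end <= calls$start))
    stop_invalid("every call needs end > start")
  if (is.null(calls$length)) calls$length <- calls$end - calls$start
  if (is.null(calls$call_id))
    calls$call_id <- sprintf("%s_ecc%05d", sample_id,
                             seq_len(nrow(calls)))
  for (col in c("split_support", "discordant_support"))
    if (is.null(calls[[col]])) calls[[col]] <- 0L
  for (col in c("mean_depth", "enrichment"))
    if (is.null(calls[[col]])) calls[[col]] <- NA_real_
  calls <- calls[order(calls$chrom, calls$start, calls$end),
                 c("call_id", "chrom", "start", "end", "length",
                   "split_support", "discordant_support", "mean_depth",
                   "enrichment"), drop = FALSE]
  rownames(calls) <- NULL
  new_circle_catalog(sample_id, calls)
}

new_circle_catalog <- function(sample_id, calls, log = list()) {
  structure(list(sample_id = sample_id, calls = calls,
                 n_eccDNA = nrow(calls),
                 mean_length = if (nrow(calls) > 0) mean(calls$length)
                 else NA_real_,
                 log = log),
            class = "circle_catalog")
}

#' @export
print.circle_catalog <- function(x, ...) {
  cat(sprintf("circle_catalog '%s': %d unique eccDNA call(s)",
              x$sample_id, x$n_eccDNA))
  if (x$n_eccDNA > 0)
    cat(sprintf(", mean length %.1f bp", x$mean_length))
  cat("\n")
  if (x$n_eccDNA > 0) {
    print(head(x$calls, 6))
    if (x$n_eccDNA > 6) cat(sprintf("  ... %d more\n", x$n_eccDNA - 6))
  }
  invisible(x)
}

#' @export
as.data.frame.circle_catalog <- function(x, ...) x$calls

#' Call circles from a SAM/BAM file
#'
#' End-to-end caller: parse alignments, extract split-read and
#' outward-facing discordant evidence, profile coverage, then cluster and
#' call. Identical input and configuration produce an identical catalog.
#'
#' @param sam_path SAM/BAM path.
#' @param assembly_lengths named chromosome lengths, bp (e.g.
#'   [chrom_lengths()]).
#' @param config a [caller_config()].
#' @param sample_id sample label.
#' @return A `circle_catalog`; the parser QC is stored in `$log$qc`.
#' @examples
#' \donttest{
#' asm <- make_reference(1, 100000, seed = 1)
#' ann <- make_annotation(asm, 0, seed = 1)
#' cfg <- sim_config(n_circles = 3, n_read_pairs = 3000, error_rate = 0,
#'                   background_frac = 0, seed = 2)
#' truth <- simulate_reads(asm, sample_circles(asm, ann, cfg), cfg,
#'                         write_fastq = FALSE)
#' call_circles(truth$sam_path, chrom_lengths(asm))
#' }
#' @export
call_circles <- function(sam_path, assembly_lengths,
                         config = caller_config(), sample_id = "sample") {
  rec <- parse_alignments(sam_path)
  junc <- extract_split_junctions(rec)
  disc <- extract_discordant_pairs(rec, config$max_circle_len)
  cov <- coverage_profile(rec, assembly_lengths, bin = config$coverage_bin,
                          background_pseudocount =
                            config$background_pseudocount)
  cat_ <- cluster_and_call(junc, disc, cov, config, sample_id)
  cat_$log$qc <- attr(rec, "qc")
  cat_
}

#' Write / read a circle catalog
#'
#' The BED file is BED6 with 0-based half-open start/end (so `end - start`
#' reproduces the reported length), name = call id and score = split
#' support. The TSV carries the full call table plus the sample id and
#' round-trips exactly.
#'
#' @param catalog a `circle_catalog`.
#' @param bed_path,tsv_path output paths (`NULL` skips that format).
#' @return `write_catalog` returns the paths invisibly; `read_catalog` a
#'   `circle_catalog`.
#' @export
write_catalog <- function(catalog, bed_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(catalog, "circle_catalog"))
  if (!is.null(bed_path)) {
    b <- catalog$calls
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", b$chrom, b$start, b$end,
                     b$call_id, b$split_support)
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path)) {
    tab <- cbind(sample_id = catalog$sample_id, catalog$calls)
    write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' @rdname write_catalog
#' @export
read_catalog <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop_invalid("catalog not found: %s", tsv_path)
  tab <- tryCatch(read.delim(tsv_path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop_invalid("catalog parse error in %s: %s", tsv_path,
                                 conditionMessage(e)))
  need <- c("sample_id", "call_id", "chrom", "start", "end", "length",
            "split_support", "discordant_support", "mean_depth",
            "enrichment")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop_invalid("catalog parse error in %s (line 1): missing column(s) %s",
                 tsv_path, paste(miss, collapse = ", "))
  bad <- which(tab$end < tab$start)
  if (length(bad) > 0)
    stop_invalid("catalog parse error in %s at line %d: end < start",
                 tsv_path, bad[1] + 1L)
  sample_id <- if (nrow(tab) > 0) tab$sample_id[1] else "sample"
  calls <- tab[, setdiff(need, "sample_id")]
  calls$chrom <- as.character(calls$chrom)
  for (col in c("start", "end", "length", "split_support",
                "discordant_support"))
    calls[[col]] <- as.integer(calls[[col]])
  new_circle_catalog(sample_id, calls)
}
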