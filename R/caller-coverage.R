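#' Binned read-depth profile
#'
#' Per-base depth from the reference-consuming part of every mapped record
#' (primary and supplementary; soft-clipped tails do not count), summarized
#' as mean depth per fixed-width bin. The genome-wide background is the
#' median over all bins plus a pseudocount, so enrichment stays defined on
#' sparse, circle-enriched genomes where the median is zero.
#'
#' @param records an `alignment_records` data.frame.
#' @param assembly_lengths named vector of chromosome lengths, bp.
#' @param bin bin width, bp.
#' @param background_pseudocount reads/bp added to the background median.
#' @return A `coverage_profile`: per-chromosome depth [S4Vectors::Rle] and
#'   bin means, plus `background` depth.
#' @export
coverage_profile <- function(records, assembly_lengths, bin = 50L,
                             background_pseudocount = 0.01) {
  stopifnot(length(assembly_lengths) > 0, bin >= 1)
  rec <- records[records$mapped & records$ref_len > 0, , drop = FALSE]
  cov <- list(); bins <- list()
  for (chrom in names(assembly_lengths)) {
    L <- assembly_lengths[[chrom]]
    sub <- rec[rec$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$pos + 1L,
                           width = sub$ref_len)
    ir <- IRanges::restrict(ir, start = 1L, end = as.integer(L))
    cv <- IRanges::coverage(ir, width = as.integer(L))
    starts <- seq.int(1L, L, by = bin)
    widths <- pmin(bin, L - starts + 1L)
    v <- IRanges::Views(cv, start = starts, width = widths)
    cov[[chrom]] <- cv
    bins[[chrom]] <- IRanges::viewMeans(v)
  }
  allbins <- unlist(bins, use.names = FALSE)
  background <- median(allbins) + background_pseudocount
  structure(list(coverage = cov, bins = bins, bin = as.integer(bin),
                 background = background,
                 lengths = assembly_lengths),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(paste0("coverage_profile: %d chromosome(s), %d-bp bins, ",
                     "background %.4g reads/bp\n"),
              length(x$coverage), x$bin, x$background))
  invisible(x)
}

#' Mean depth and enrichment of an interval
#'
#' @param profile a [coverage_profile()].
#' @param chrom chromosome name.
#' @param start,end interval, 0-based half-open.
#' @return List with `mean_depth` and `enrichment` (mean depth over the
#'   profile background).
#' @export
region_enrichment <- function(profile, chrom, start, end) {
  if (!chrom %in% names(profile$coverage))
    stop_invalid("unknown chromosome '%s' in coverage profile", chrom)
  cv <- profile$coverage[[chrom]]
  end <- min(end, length(cv))
  md <- mean(S4Vectors::window(cv, start + 1L, end))
  list(mean_depth = md, enrichment = md / profile$background)
}
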