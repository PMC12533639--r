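#' Caller configuration
#'
#' Thresholds and tolerances of the circle caller. The evidence classes
#' (split reads, outward-facing discordant pairs, coverage enrichment) are
#' fixed; every threshold is configurable. Defaults favour precision on
#' circle-enriched libraries, where split reads carry the decision and
#' coverage is only a weak discriminator: a candidate becomes a call iff it
#' has `>= min_split` split reads, or `>= 1` split read corroborated by
#' `>= min_discordant_rescue` outward-facing pairs, and its coverage
#' enrichment over the genome-wide background is `>= min_enrichment`.
#' Discordant pairs alone never produce a call (their breakpoints are only
#' insert-size accurate).
#'
#' @param epsilon breakpoint clustering / merge tolerance, bp.
#' @param min_split minimum split-read support for a call.
#' @param min_discordant_rescue discordant support that rescues a candidate
#'   with a single split read.
#' @param min_enrichment minimum mean-depth enrichment over background.
#' @param background_pseudocount reads/bp added to the background median so
#'   enrichment is defined on sparse genomes.
#' @param min_circle_len,max_circle_len admissible call lengths, bp.
#' @param max_insert largest plausible sequencing insert, bp; bounds how far
#'   a discordant pair's interval may sit inside a candidate's breakpoints.
#' @param coverage_bin bin width of the depth profile, bp.
#' @return A validated `caller_config` list.
#' @export
caller_config <- function(epsilon = 5L, min_split = 2L,
                          min_discordant_rescue = 2L, min_enrichment = 2.0,
                          background_pseudocount = 0.01,
                          min_circle_len = 200L, max_circle_len = 10e6,
                          max_insert = 1000L, coverage_bin = 50L) {
  cfg <- list(epsilon = as.integer(epsilon),
              min_split = as.integer(min_split),
              min_discordant_rescue = as.integer(min_discordant_rescue),
              min_enrichment = min_enrichment,
              background_pseudocount = background_pseudocount,
              min_circle_len = as.integer(min_circle_len),
              max_circle_len = as.numeric(max_circle_len),
              max_insert = as.integer(max_insert),
              coverage_bin = as.integer(coverage_bin))
  for (f in names(cfg))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop_invalid("caller_config field `%s` must be positive", f)
  if (cfg$min_circle_len >= cfg$max_circle_len)
    stop_invalid("need min_circle_len < max_circle_len")
  structure(cfg, class = "caller_config")
}

#' @export
print.caller_config <- function(x, ...) {
  cat(sprintf(paste0("caller_config: eps %d bp, min_split %d ",
                     "(or 1 split + %d discordant), enrichment >= %.2g, ",
                     "length [%d, %.3g] bp\n"),
              x$epsilon, x$min_split, x$min_discordant_rescue,
              x$min_enrichment, x$min_circle_len, x$max_circle_len))
  invisible(x)
}
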