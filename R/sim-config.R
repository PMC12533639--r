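#' Simulation configuration for a circle-enriched library
#'
#' Bundles every tunable of the synthetic rolling-circle library. Defaults
#' model the sequenced libraries the pipeline targets: 150-bp paired-end
#' reads from rolling-circle-amplified circles whose lengths follow a
#' truncated log-normal placing most mass between 400 and 6000 bp, with a
#' small linear-DNA background standing in for incomplete exonuclease
#' digestion.
#'
#' @param n_circles number of true circles to simulate.
#' @param n_read_pairs total read pairs emitted (circle + background).
#' @param length_meanlog,length_sdlog log-normal parameters of the circle
#'   length distribution (defaults `log(1200)`, `0.8`).
#' @param min_len,max_len truncation bounds of the length distribution, bp.
#' @param origin_mix named probabilities over origin classes `intergenic`,
#'   `partial_gene`, `full_gene`; must sum to 1. The default weights
#'   intergenic and partial-gene classes heavily, with full-gene circles rare.
#' @param rca_fold mean concatemer copy number of rolling-circle
#'   amplification (geometric, minimum 2 copies).
#' @param insert_mean,insert_sd,insert_min,insert_max sequencing insert size
#'   distribution: normal truncated to `[insert_min, insert_max]` bp.
#' @param read_len read length, bp.
#' @param error_rate per-base substitution probability.
#' @param background_frac fraction of read pairs drawn from random linear
#'   genomic fragments.
#' @param seed integer seed; all simulation randomness flows from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_circles = 50L,
                       n_read_pairs = 20000L,
                       length_meanlog = log(1200),
                       length_sdlog = 0.8,
                       min_len = 200L,
                       max_len = 10000L,
                       origin_mix = c(intergenic = 0.597,
                                      partial_gene = 0.4,
                                      full_gene = 0.003),
                       rca_fold = 10,
                       insert_mean = 350,
                       insert_sd = 50,
                       insert_min = 200L,
                       insert_max = 1000L,
                       read_len = 150L,
                       error_rate = 0.001,
                       background_frac = 0.01,
                       seed = 1L) {
  cfg <- list(n_circles = as.integer(n_circles),
              n_read_pairs = as.integer(n_read_pairs),
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              origin_mix = origin_mix, rca_fold = rca_fold,
              insert_mean = insert_mean, insert_sd = insert_sd,
              insert_min = as.integer(insert_min),
              insert_max = as.integer(insert_max),
              read_len = as.integer(read_len),
              error_rate = error_rate,
              background_frac = background_frac,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_circles)) stop_invalid("`n_circles` must be >= 0")
  if (!is_count(cfg$n_read_pairs)) stop_invalid("`n_read_pairs` must be >= 0")
  mix <- cfg$origin_mix
  need <- c("intergenic", "partial_gene", "full_gene")
  if (!all(need %in% names(mix)) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-8)
    stop_invalid("`origin_mix` must be probabilities over {%s} summing to 1",
                 paste(need, collapse = ", "))
  if (cfg$length_sdlog <= 0) stop_invalid("`length_sdlog` must be > 0")
  if (cfg$min_len < 1 || cfg$max_len <= cfg$min_len)
    stop_invalid("need 0 < min_len < max_len")
  if (cfg$read_len > cfg$insert_min)
    stop_invalid("`read_len` (%d) must be <= minimum insert (%d)",
                 cfg$read_len, cfg$insert_min)
  if (cfg$read_len > cfg$min_len)
    stop_invalid("`read_len` (%d) must be <= minimum circle length (%d)",
                 cfg$read_len, cfg$min_len)
  for (r in c("error_rate", "background_frac"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1)
      stop_invalid("`%s` must be in [0, 1]", r)
  if (cfg$rca_fold < 2) stop_invalid("`rca_fold` must be >= 2")
  if (cfg$insert_min > cfg$insert_max || cfg$insert_sd < 0)
    stop_invalid("invalid insert size distribution")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d circles, %d read pairs, read_len %d, ",
                     "error %.4g, background %.3g, seed %d\n"),
              x$n_circles, x$n_read_pairs, x$read_len, x$error_rate,
              x$background_frac, x$seed))
  invisible(x)
}

#' Mass of the circle length distribution on an interval
#'
#' Analytic mass of the truncated log-normal length model on
#' `[lo, hi)`; used to check simulated catalogs against their target
#' distribution.
#'
#' @param config a `sim_config`.
#' @param lo,hi interval bounds in bp.
#' @return A probability.
#' @export
length_dist_mass <- function(config, lo = 400, hi = 6000) {
  plnorm_trunc_mass(lo, hi, config$length_meanlog, config$length_sdlog,
                    config$min_len, config$max_len)
}
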