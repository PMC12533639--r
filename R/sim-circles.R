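#' Sample ground-truth circles from an assembly
#'
#' Draws `n_circles` true eccDNA intervals with lengths from the config's
#' truncated log-normal and origin classes from `origin_mix`. Placement is
#' class-targeted rejection sampling: intergenic circles overlap no gene
#' span, partial-gene circles overlap but do not fully contain a gene, and
#' full-gene circles are positioned to contain at least one entire gene
#' span. Each placement is verified with the gene-content classifier.
#'
#' @param assembly a `genome_assembly`.
#' @param annotation an `annotation_set` on the same assembly; may have zero
#'   genes only if `origin_mix` puts all weight on `intergenic`.
#' @param config a [sim_config()].
#' @return A `true_circles` data.frame: `circle_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `length`, `origin_class`.
#' @export
sample_circles <- function(assembly, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- chrom_lengths(assembly)
  mix <- config$origin_mix
  if (nrow(annotation$genes) == 0 &&
      (mix[["partial_gene"]] > 0 || mix[["full_gene"]] > 0))
    stop_invalid("origin_mix gives weight to gene classes but annotation is empty")
  if (config$n_circles == 0L)
    return(empty_true_circles())
  with_seed(config$seed, {
    classes <- sample(names(mix), config$n_circles, replace = TRUE,
                      prob = mix)
    lengths <- as.integer(round(rlnorm_trunc(
      config$n_circles, config$length_meanlog, config$length_sdlog,
      config$min_len, config$max_len)))
    lengths <- pmax(pmin(lengths, config$max_len),
                    max(config$min_len, config$read_len))
    # a full-gene circle must be at least as long as some gene span, so
    # its length is redrawn from the same distribution conditioned on that
    if (any(classes == "full_gene")) {
      min_span <- min(annotation$genes$end - annotation$genes$start)
      if (min_span + 2 >= config$max_len)
        stop_invalid("cannot place full_gene circles: shortest gene span (%d) reaches max_len", min_span)
      k <- which(classes == "full_gene" & lengths <= min_span)
      if (length(k) > 0)
        lengths[k] <- as.integer(round(rlnorm_trunc(
          length(k), config$length_meanlog, config$length_sdlog,
          min_span + 2, config$max_len)))
    }
    out <- vector("list", config$n_circles)
    for (i in seq_len(config$n_circles)) {
      out[[i]] <- place_circle(classes[i], lengths[i], lens, annotation)
      out[[i]]$circle_id <- sprintf("circ%04d", i)
    }
    res <- do.call(rbind, out)
    res <- res[, c("circle_id", "chrom", "start", "end", "length",
                   "origin_class")]
    class(res) <- c("true_circles", "data.frame")
    res
  })
}

empty_true_circles <- function() {
  structure(data.frame(circle_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       length = integer(), origin_class = character(),
                       stringsAsFactors = FALSE),
            class = c("true_circles", "data.frame"))
}

place_circle <- function(class, len, lens, annotation, max_tries = 1000L) {
  ok_chroms <- names(lens)[lens > len]
  if (length(ok_chroms) == 0)
    stop_invalid("no chromosome longer than requested circle length %d", len)
  genes <- annotation$genes
  for (try in seq_len(max_tries)) {
    if (class == "full_gene") {
      cand <- genes[(genes$end - genes$start) <= len &
                      genes$chrom %in% ok_chroms, , drop = FALSE]
      if (nrow(cand) == 0)
        stop_invalid("cannot place a full_gene circle: no gene span <= %d bp",
                     len)
      g <- cand[sample.int(nrow(cand), 1L), ]
      lo <- max(0L, g$end - len)
      hi <- min(g$start, lens[[g$chrom]] - len)
      if (hi < lo) next
      start <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
      chrom <- g$chrom
    } else {
      chrom <- if (length(ok_chroms) == 1L) ok_chroms else
        sample(ok_chroms, 1L, prob = lens[ok_chroms])
      start <- sample.int(lens[[chrom]] - len, 1L) - 1L
    }
    end <- start + len
    cls <- classify_interval(chrom, start, end, annotation)$kind
    if (cls == class)
      return(data.frame(chrom = chrom, start = as.integer(start),
                        end = as.integer(end), length = as.integer(len),
                        origin_class = class, stringsAsFactors = FALSE))
  }
  stop_invalid("could not place a circle of class '%s' after %d tries",
               class, max_tries)
}
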