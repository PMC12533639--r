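#' Classify a circle's gene content
#'
#' The trichotomy used for catalog characterization: `full_gene` iff at
#' least one entire gene span lies inside the call interval (containment
#' wins over any other overlap); `intergenic` iff the interval overlaps no
#' gene span; otherwise `partial_gene`, subtyped by the feature kind with
#' the largest overlapped base count among `five_prime_utr`, `exon`,
#' `intron` and `three_prime_utr` (ties broken in the fixed order intron >
#' exon > 5'UTR > 3'UTR).
#'
#' @param call a list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param annotation an `annotation_set`.
#' @return List with `kind` and, for partial-gene calls, `subtype`
#'   (`five_prime_utr`, `three_prime_utr`, `exonic` or `intronic`).
#' @export
classify_circle <- function(call, annotation) {
  classify_interval(as.character(call$chrom[1]), call$start[1], call$end[1],
                    annotation)
}

SUBTYPE_TIE_ORDER <- c("intron", "exon", "five_prime_utr", "three_prime_utr")
SUBTYPE_LABEL <- c(intron = "intronic", exon = "exonic",
                   five_prime_utr = "five_prime_utr",
                   three_prime_utr = "three_prime_utr")

classify_interval <- function(chrom, start, end, annotation) {
  if (!chrom %in% annotation$chroms &&
      !chrom %in% annotation$genes$chrom)
    stop_invalid("unknown chromosome '%s'", chrom)
  g <- query_genes(annotation, chrom, start, end)
  if (nrow(g) == 0L) return(list(kind = "intergenic", subtype = NULL))
  if (any(g$start >= start & g$end <= end))
    return(list(kind = "full_gene", subtype = NULL))
  f <- annotation$features[annotation$features$gene_id %in% g$gene_id, ,
                           drop = FALSE]
  ov <- pmax(0L, pmin(end, f$end) - pmax(start, f$start))
  by_kind <- tapply(ov, factor(f$kind, levels = SUBTYPE_TIE_ORDER), sum,
                    default = 0L)
  by_kind[is.na(by_kind)] <- 0L
  win <- SUBTYPE_TIE_ORDER[which.max(by_kind)]  # which.max keeps tie order
  list(kind = "partial_gene", subtype = unname(SUBTYPE_LABEL[win]))
}

# Vectorized classification of a whole catalog.
classify_calls <- function(calls, annotation) {
  if (nrow(calls) == 0L)
    return(data.frame(kind = character(), subtype = character(),
                      stringsAsFactors = FALSE))
  res <- lapply(seq_len(nrow(calls)), function(i)
    classify_interval(calls$chrom[i], calls$start[i], calls$end[i],
                      annotation))
  data.frame(kind = vapply(res, `[[`, character(1), "kind"),
             subtype = vapply(res, function(r)
               if (is.null(r$subtype)) NA_character_ else r$subtype,
               character(1)),
             stringsAsFactors = FALSE)
}

#' Summarize a catalog by length, origin and gene content
#'
#' The standard characterization of a per-sample catalog: a length
#' histogram in fixed 200-bp half-open bins, the fraction of calls with
#' length in `[400, 6000)`, per-chromosome counts and mean lengths, and —
#' given an annotation — gene-content class counts with the full-gene
#' percentage rendered at two significant figures.
#'
#' @param catalog a `circle_catalog`.
#' @param annotation optional `annotation_set`; content classification is
#'   skipped when absent.
#' @param bin_size histogram bin width, bp.
#' @param len_range length-2 vector, the reported half-open length range.
#' @return A `catalog_summary` list: `n_eccDNA`, `mean_length`,
#'   `histogram` (data.frame `bin_start`, `bin_end`, `count`),
#'   `range_fraction`, `len_range`, `per_chrom` (count and mean length per
#'   chromosome), `content_counts`, `subtype_counts`, `full_gene_report`.
#' @export
summarize_catalog <- function(catalog, annotation = NULL, bin_size = 200L,
                              len_range = c(400L, 6000L)) {
  stopifnot(inherits(catalog, "circle_catalog"), bin_size >= 1)
  calls <- catalog$calls
  n <- nrow(calls)
  if (n == 0L) {
    hist <- data.frame(bin_start = integer(), bin_end = integer(),
                       count = integer())
    out <- list(sample_id = catalog$sample_id, n_eccDNA = 0L,
                mean_length = NA_real_, histogram = hist,
                range_fraction = NA_real_, len_range = len_range,
                per_chrom = data.frame(chrom = character(),
                                       count = integer(),
                                       mean_length = numeric()),
                content_counts = NULL, subtype_counts = NULL,
                full_gene_report = NULL)
    class(out) <- "catalog_summary"
    return(out)
  }
  len <- calls$length
  k <- floor(len / bin_size)
  counts <- tabulate(k + 1L, nbins = max(k) + 1L)
  hist <- data.frame(bin_start = bin_size * (seq_along(counts) - 1L),
                     bin_end = bin_size * seq_along(counts),
                     count = counts)
  rf <- mean(len >= len_range[1] & len < len_range[2])
  pc <- do.call(rbind, lapply(split(len, calls$chrom), function(x)
    data.frame(count = length(x), mean_length = mean(x))))
  pc <- data.frame(chrom = rownames(pc), pc, row.names = NULL,
                   stringsAsFactors = FALSE)
  content_counts <- NULL; subtype_counts <- NULL; fgr <- NULL
  if (!is.null(annotation)) {
    cls <- classify_calls(calls, annotation)
    content_counts <- table(factor(cls$kind, levels = c("full_gene",
                                                        "partial_gene",
                                                        "intergenic")))
    content_counts <- setNames(as.integer(content_counts),
                               names(content_counts))
    subtype_counts <- table(factor(cls$subtype[cls$kind == "partial_gene"],
                                   levels = unname(SUBTYPE_LABEL)))
    subtype_counts <- setNames(as.integer(subtype_counts),
                               names(subtype_counts))
    fgr <- full_gene_report(content_counts)
  }
  structure(list(sample_id = catalog$sample_id, n_eccDNA = n,
                 mean_length = mean(len), histogram = hist,
                 range_fraction = rf, len_range = len_range,
                 per_chrom = pc, content_counts = content_counts,
                 subtype_counts = subtype_counts, full_gene_report = fgr),
            class = "catalog_summary")
}

#' @export
summary.circle_catalog <- function(object, annotation = NULL,
                                   bin_size = 200L,
                                   len_range = c(400L, 6000L), ...) {
  summarize_catalog(object, annotation, bin_size, len_range)
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("catalog_summary '%s': %d eccDNA\n", x$sample_id, x$n_eccDNA))
  if (x$n_eccDNA == 0L) return(invisible(x))
  cat(sprintf("  mean length: %.1f bp\n", x$mean_length))
  cat(sprintf("  fraction in [%d, %d) bp: %.4f\n", x$len_range[1],
              x$len_range[2], x$range_fraction))
  if (!is.null(x$content_counts)) {
    cat("  content:", paste(sprintf("%s=%d", names(x$content_counts),
                                    x$content_counts), collapse = ", "),
        "\n")
    cat(sprintf("  full-gene: %d of %d (%s)\n", x$full_gene_report$n_full,
                x$full_gene_report$n_total, x$full_gene_report$pct))
  }
  invisible(x)
}

#' @export
plot.circle_catalog <- function(x, bin_size = 200L, ...) {
  if (x$n_eccDNA == 0L) stop_invalid("empty catalog: nothing to plot")
  len <- x$calls$length
  breaks <- seq(0, (max(len) %/% bin_size + 1L) * bin_size, by = bin_size)
  graphics::hist(len, breaks = breaks, right = FALSE,
                 main = sprintf("eccDNA length distribution (%s)",
                                x$sample_id),
                 xlab = sprintf("length (bp), bin size %d bp", bin_size),
                 ...)
  invisible(x)
}

#' Full-gene percentage report
#'
#' Renders "n of N calls carried full genes" with the percentage at two
#' significant figures (e.g. 17 of 5413 renders as `0.31%`).
#'
#' @param content_counts named count vector containing `full_gene` (for
#'   example the `content_counts` of a [summarize_catalog()]), or a single
#'   full-gene count when `n_total` is supplied.
#' @param n_total total call count (only when `content_counts` is a bare
#'   count).
#' @return List with `n_full`, `n_total` and `pct` (text; `NA` marks an
#'   undefined percentage on an empty catalog).
#' @export
full_gene_report <- function(content_counts, n_total = NULL) {
  if (is.null(n_total)) {
    if (is.null(names(content_counts)) ||
        !"full_gene" %in% names(content_counts))
      stop_invalid("`content_counts` must be named and include 'full_gene'")
    n_full <- content_counts[["full_gene"]]
    n_total <- sum(content_counts)
  } else {
    n_full <- content_counts
  }
  if (n_total == 0)
    return(list(n_full = 0L, n_total = 0L, pct = NA_character_))
  list(n_full = as.integer(n_full), n_total = as.integer(n_total),
       pct = format_pct_2sig(100 * n_full / n_total))
}

#' Chromosome-of-origin distribution and proportionality test
#'
#' Counts calls per chromosome and tests, by chi-square goodness of fit,
#' whether counts are proportional to chromosome length — the expected
#' pattern when circles arise uniformly across the genome.
#'
#' @param catalog a `circle_catalog`.
#' @param assembly_lengths named chromosome lengths, bp (at least 2
#'   chromosomes).
#' @return A `chrom_distribution` list: `table` (chrom, length, observed,
#'   expected, mean call length), `statistic`, `p_value`,
#'   `small_expected_warning` (any expected count below 1).
#' @export
chromosome_distribution <- function(catalog, assembly_lengths) {
  stopifnot(inherits(catalog, "circle_catalog"))
  if (length(assembly_lengths) < 2)
    stop_invalid("need at least 2 chromosomes")
  chroms <- names(assembly_lengths)
  obs <- table(factor(catalog$calls$chrom, levels = chroms))
  obs <- setNames(as.integer(obs), chroms)
  p <- assembly_lengths / sum(assembly_lengths)
  expected <- sum(obs) * p
  small <- any(expected < 1)
  if (sum(obs) == 0) {
    stat <- NA_real_; pval <- NA_real_
  } else if (all(abs(obs - expected) < 1e-9)) {
    stat <- 0; pval <- 1
  } else {
    ct <- suppressWarnings(chisq.test(obs, p = p))
    stat <- unname(ct$statistic); pval <- unname(ct$p.value)
  }
  ml <- vapply(chroms, function(ch) {
    x <- catalog$calls$length[catalog$calls$chrom == ch]
    if (length(x) == 0) NA_real_ else mean(x)
  }, numeric(1))
  structure(list(table = data.frame(chrom = chroms,
                                    length = unname(assembly_lengths),
                                    observed = unname(obs),
                                    expected = unname(expected),
                                    mean_length = unname(ml),
                                    stringsAsFactors = FALSE),
                 statistic = stat, p_value = pval,
                 small_expected_warning = small),
            class = "chrom_distribution")
}

#' @export
print.chrom_distribution <- function(x, ...) {
  cat(sprintf("chrom_distribution: chi-square = %.4g, p = %.4g%s\n",
              x$statistic, x$p_value,
              if (x$small_expected_warning) " (small expected counts)"
              else ""))
  print(x$table)
  invisible(x)
}
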