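#' Generate a seeded synthetic gene annotation
#'
#' Places non-overlapping single-transcript genes on an assembly. Every gene
#' span is tiled exactly by its ordered features: a 5'UTR, `>= 1` exons with
#' introns between consecutive exons, and a 3'UTR (for minus-strand genes the
#' 5'UTR sits at the high-coordinate end). Placement is rejection sampling
#' with a retry cap of `100 * n_genes`.
#'
#' @param assembly a `genome_assembly`.
#' @param n_genes number of genes to place.
#' @param gene_len_range length-2 vector, min/max gene length in bp; the max
#'   must be shorter than the shortest chromosome.
#' @param n_exons_range length-2 integer vector, min/max exon count per gene.
#' @param seed integer seed.
#' @return An `annotation_set`: list with `genes` (data.frame `gene_id`,
#'   `chrom`, `start`, `end`, `strand`; 0-based half-open), `features`
#'   (data.frame `gene_id`, `kind`, `start`, `end`) and a
#'   [GenomicRanges::GRanges] interval index used for overlap queries.
#' @examples
#' asm <- make_reference(1, 50000, seed = 1)
#' ann <- make_annotation(asm, 3, c(2000, 6000), c(2, 4), seed = 3)
#' ann$genes
#' @export
make_annotation <- function(assembly, n_genes, gene_len_range = c(2000, 10000),
                            n_exons_range = c(2, 5), seed = 1L) {
  if (length(assembly_seqs(assembly)) == 0) stop_invalid("`assembly` is empty")
  if (!is_count(n_genes)) stop_invalid("`n_genes` must be a non-negative integer")
  lens <- chrom_lengths(assembly)
  if (max(gene_len_range) >= min(lens))
    stop_invalid("max gene length (%d) must be < shortest chromosome (%d)",
                 max(gene_len_range), min(lens))
  if (min(gene_len_range) < 30)
    stop_invalid("genes shorter than 30 bp cannot hold the minimal feature set")
  genes <- list(); feats <- list()
  if (n_genes > 0) {
    placed <- with_seed(seed, {
      occupied <- lapply(names(lens), function(x) NULL)
      names(occupied) <- names(lens)
      out_g <- vector("list", n_genes); out_f <- vector("list", n_genes)
      n_placed <- 0L; tries <- 0L; cap <- 100L * n_genes
      while (n_placed < n_genes && tries < cap) {
        tries <- tries + 1L
        chrom <- sample(names(lens), 1L, prob = lens)
        L <- sample(gene_len_range[1]:gene_len_range[2], 1L)
        start <- sample.int(lens[[chrom]] - L + 1L, 1L) - 1L
        end <- start + L
        occ <- occupied[[chrom]]
        if (!is.null(occ) && any(start < occ[, 2] & end > occ[, 1])) next
        n_placed <- n_placed + 1L
        occupied[[chrom]] <- rbind(occ, c(start, end))
        gid <- sprintf("gene%04d", n_placed)
        strand <- sample(c("+", "-"), 1L)
        n_ex <- sample(n_exons_range[1]:n_exons_range[2], 1L)
        out_g[[n_placed]] <- data.frame(
          gene_id = gid, chrom = chrom, start = start, end = end,
          strand = strand, stringsAsFactors = FALSE)
        out_f[[n_placed]] <- tile_gene(gid, start, end, strand, n_ex)
      }
      if (n_placed < n_genes)
        stop_invalid(paste0("could not place %d genes without overlap ",
                            "(placed %d after %d tries)"),
                     n_genes, n_placed, tries)
      list(g = do.call(rbind, out_g[seq_len(n_placed)]),
           f = do.call(rbind, out_f[seq_len(n_placed)]))
    })
    genes <- placed$g; feats <- placed$f
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    feats <- data.frame(gene_id = character(), kind = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  }
  new_annotation_set(genes, feats, names(lens))
}

# Tile a gene span with 5'UTR / exons / introns / 3'UTR (genomic order;
# strand decides which end carries the 5'UTR).
tile_gene <- function(gene_id, start, end, strand, n_exons) {
  L <- end - start
  n_parts <- 2L + n_exons + (n_exons - 1L)
  cuts <- sort(sample.int(L - 1L, n_parts - 1L))
  bounds <- c(0L, cuts, L)
  kinds_tx <- c("five_prime_utr",
                rep(c("exon", "intron"), length.out = 2L * n_exons - 1L),
                "three_prime_utr")
  kinds <- if (strand == "+") kinds_tx else rev(kinds_tx)
  data.frame(gene_id = gene_id, kind = kinds,
             start = start + bounds[-length(bounds)],
             end = start + bounds[-1L], stringsAsFactors = FALSE)
}

new_annotation_set <- function(genes, features, chroms) {
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  features <- features[order(match(features$gene_id, genes$gene_id),
                             features$start), , drop = FALSE]
  rownames(features) <- NULL
  idx <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    gene_id = genes$gene_id)
  structure(list(genes = genes, features = features, index = idx,
                 chroms = chroms),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d gene(s) on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Genes overlapping an interval
#'
#' @param annotation an `annotation_set`.
#' @param chrom chromosome name.
#' @param start,end query interval, 0-based half-open.
#' @return The rows of `annotation$genes` whose span overlaps the query.
#' @export
query_genes <- function(annotation, chrom, start, end) {
  stopifnot(inherits(annotation, "annotation_set"), end > start)
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, annotation$index)
  annotation$genes[S4Vectors::subjectHits(hits), , drop = FALSE]
}

#' Write / read annotations as GFF3
#'
#' On disk coordinates are 1-based inclusive (GFF3); in memory they are
#' 0-based half-open. Feature types written are `gene`, `five_prime_UTR`,
#' `exon` and `three_prime_UTR`; introns are implicit on disk and
#' materialized as inter-exon gaps on read.
#'
#' @param annotation an `annotation_set`.
#' @param path file path.
#' @return `write_gff3` returns `path` invisibly; `read_gff3` an
#'   `annotation_set`.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  g <- annotation$genes
  f <- annotation$features[annotation$features$kind != "intron", , drop = FALSE]
  disk_type <- c(five_prime_utr = "five_prime_UTR", exon = "exon",
                 three_prime_utr = "three_prime_UTR")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf("%s\teccpipe\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom[i], g$start[i] + 1L, g$end[i],
                              g$strand[i], g$gene_id[i]))
    fi <- f[f$gene_id == g$gene_id[i], , drop = FALSE]
    lines <- c(lines, sprintf("%s\teccpipe\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                              g$chrom[i], disk_type[fi$kind], fi$start + 1L,
                              fi$end, g$strand[i], fi$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_invalid("GFF3 file not found: %s", path)
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  gdf <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = as.character(gdf$ID),
                      chrom = gdf$seqnames,
                      start = gdf$start - 1L, end = gdf$end,
                      strand = gdf$strand, stringsAsFactors = FALSE)
  fdf <- df[df$type != "gene", , drop = FALSE]
  mem_kind <- c(five_prime_UTR = "five_prime_utr", exon = "exon",
                three_prime_UTR = "three_prime_utr")
  parent <- vapply(fdf$Parent, function(p) as.character(p)[1], character(1))
  features <- data.frame(gene_id = parent,
                         kind = unname(mem_kind[as.character(fdf$type)]),
                         start = fdf$start - 1L, end = fdf$end,
                         stringsAsFactors = FALSE)
  # materialize introns: gaps between consecutive exons of a gene
  intr <- lapply(split(features[features$kind == "exon", ],
                       features$gene_id[features$kind == "exon"]),
                 function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(gene_id = ex$gene_id[-1L], kind = "intron",
               start = ex$end[-nrow(ex)], end = ex$start[-1L],
               stringsAsFactors = FALSE)
  })
  intr <- do.call(rbind, intr)
  if (!is.null(intr)) {
    intr <- intr[intr$end > intr$start, , drop = FALSE]
    features <- rbind(features, intr)
  }
  new_annotation_set(genes, features, unique(genes$chrom))
}

# Light structural validation so malformed records fail with a line number
# before the full parse.
validate_gff3_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L)
      stop_invalid("GFF3 parse error at line %d: expected 9 columns, got %d",
                   i, length(fields))
    s <- suppressWarnings(as.integer(fields[4]))
    e <- suppressWarnings(as.integer(fields[5]))
    if (is.na(s) || is.na(e))
      stop_invalid("GFF3 parse error at line %d: non-numeric coordinates", i)
    if (e < s)
      stop_invalid("GFF3 parse error at line %d: end (%d) < start (%d)",
                   i, e, s)
  }
  invisible(TRUE)
}
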