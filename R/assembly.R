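#' Generate a seeded synthetic reference genome
#'
#' Draws i.i.d. bases over {A, C, G, T} with a target GC content, one
#' chromosome per requested length. The result is the coordinate frame for
#' everything downstream; internally all coordinates are 0-based half-open.
#'
#' @param n_chroms number of chromosomes.
#' @param lengths integer vector of chromosome lengths in bp (one per
#'   chromosome, each at least 10 kb).
#' @param gc target GC fraction in `[0, 1]`.
#' @param seed integer seed; the same call with the same seed is
#'   byte-identical.
#' @return A `genome_assembly`: a [Biostrings::DNAStringSet] of chromosome
#'   sequences named `chr1`, `chr2`, ... with class attribute
#'   `"genome_assembly"`.
#' @examples
#' asm <- make_reference(2, c(20000, 30000), gc = 0.42, seed = 7)
#' chrom_lengths(asm)
#' @export
make_reference <- function(n_chroms, lengths, gc = 0.41, seed = 1L) {
  if (!is_count(n_chroms, min = 1L))
    stop_invalid("`n_chroms` must be a positive integer")
  if (length(lengths) != n_chroms)
    stop_invalid("`lengths` must have %d entries, got %d", n_chroms,
                 length(lengths))
  if (any(!vapply(lengths, is_count, logical(1), min = 1L)) ||
      any(lengths < 10000))
    stop_invalid("every chromosome length must be a positive integer >= 10000 bp")
  if (!is.numeric(gc) || gc < 0 || gc > 1)
    stop_invalid("`gc` must be a fraction in [0, 1]")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, lapply(as.integer(lengths), function(L) {
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = "")
  }))
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- paste0("chr", seq_len(n_chroms))
  new_genome_assembly(dss)
}

new_genome_assembly <- function(dss) {
  structure(list(seqs = dss), class = "genome_assembly")
}

assembly_seqs <- function(assembly) {
  if (inherits(assembly, "genome_assembly")) assembly$seqs else assembly
}

#' Chromosome lengths of an assembly
#'
#' @param assembly a `genome_assembly` (or any `DNAStringSet`).
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(assembly) {
  s <- assembly_seqs(assembly)
  setNames(Biostrings::width(s), names(s))
}

#' @export
print.genome_assembly <- function(x, ...) {
  lens <- chrom_lengths(x)
  cat(sprintf("genome_assembly: %d chromosome(s), %s bp total\n",
              length(lens), format(sum(lens), big.mark = ",")))
  for (i in seq_along(lens))
    cat(sprintf("  %s  %s bp\n", names(lens)[i],
                format(lens[[i]], big.mark = ",")))
  invisible(x)
}

#' Write / read an assembly as FASTA
#'
#' FASTA is wrapped at 80 columns; `read_fasta(write_fasta(x))` is identity.
#'
#' @param assembly a `genome_assembly`.
#' @param path file path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` returns a
#'   `genome_assembly`.
#' @export
write_fasta <- function(assembly, path) {
  Biostrings::writeXStringSet(assembly_seqs(assembly), path, width = 80L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_invalid("FASTA file not found: %s", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0) stop_invalid("no sequences in FASTA: %s", path)
  if (anyDuplicated(names(dss)))
    stop_invalid("duplicate sequence names in FASTA: %s", path)
  new_genome_assembly(dss)
}

# Extract a subsequence in the internal 0-based half-open frame.
subseq0 <- function(assembly, chrom, start, end) {
  as.character(Biostrings::subseq(assembly_seqs(assembly)[[chrom]],
                                  start + 1L, end))
}
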