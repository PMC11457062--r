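#' Simulate a reference genome
#'
#' Generates random chromosome sequences with a target GC content. Bases are
#' drawn i.i.d. (no repeat structure), which is sufficient for exercising
#' variant-based statistics and exact k-mer anchoring; it does not emulate
#' repetitive or low-complexity regions of real fish genomes.
#'
#' @param chrom_lengths named numeric vector (or list of `(name, length)`
#'   pairs) of chromosome lengths in bp; each must be >= 10000.
#' @param gc_fraction target GC content in `[0, 1]` (default 0.44, a typical
#'   teleost value).
#' @param seed integer seed; output is byte-reproducible for a fixed seed.
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome. The
#'   index (names and lengths, `.fai` style) is available via
#'   [reference_index()].
#' @export
simulate_reference <- function(chrom_lengths, gc_fraction = 0.44, seed = 1) {
  chrom_lengths <- normalize_chrom_lengths(chrom_lengths)
  if (any(chrom_lengths < 10000))
    stopf("all chromosome lengths must be >= 10 kb (got %s)",
          paste(chrom_lengths[chrom_lengths < 10000], collapse = ", "))
  if (gc_fraction < 0 || gc_fraction > 1)
    stopf("gc_fraction must be in [0, 1]")
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  Biostrings::DNAStringSet(setNames(seqs, names(chrom_lengths)))
}

# accept named vector or list of (name, length) pairs; validate
normalize_chrom_lengths <- function(chrom_lengths) {
  if (is.list(chrom_lengths) && is.null(names(chrom_lengths))) {
    nm <- vapply(chrom_lengths, function(x) as.character(x[[1]]), "")
    len <- vapply(chrom_lengths, function(x) as.numeric(x[[2]]), 0)
    chrom_lengths <- setNames(len, nm)
  }
  chrom_lengths <- unlist(chrom_lengths)
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stopf("chromosome names must be present and unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stopf("chromosome lengths must be positive")
  chrom_lengths
}

#' Reference index (names and lengths)
#'
#' @param reference a `DNAStringSet`.
#' @return `data.frame(chrom, length)`, the `.fai`-style index.
#' @export
reference_index <- function(reference) {
  data.frame(chrom = names(reference),
             length = Biostrings::width(reference),
             stringsAsFactors = FALSE)
}

#' Write a reference FASTA plus a .fai-style index
#'
#' @param reference a `DNAStringSet`.
#' @param path output FASTA path; the index is written to `<path>.fai`
#'   (name and length columns; offsets follow the fixed 70 bp line width).
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path, width = 70L)
  idx <- reference_index(reference)
  # fai columns: name, length, offset, linebases, linewidth
  offs <- numeric(nrow(idx))
  off <- 0
  for (i in seq_len(nrow(idx))) {
    off <- off + nchar(idx$chrom[i]) + 2 # ">name\n"
    offs[i] <- off
    nlines <- ceiling(idx$length[i] / 70)
    off <- off + idx$length[i] + nlines
  }
  fai <- data.frame(idx$chrom, idx$length, offs, 70L, 71L)
  utils::write.table(fai, paste0(path, ".fai"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a reference FASTA
#' @param path FASTA path.
#' @return A `DNAStringSet`.
#' @export
read_reference <- function(path) {
  Biostrings::readDNAStringSet(path)
}
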