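## Read simulation
##
## Reads are sampled uniformly from each individual's two haplotypes: the
## reference edited by that individual's SNP genotypes (het alternate
## alleles assigned to a random haplotype per site), with the male-only
## insert appended to haplotype 2 of carrier males. Per-base substitution
## errors are applied at a stated rate. Single-end reads of fixed length
## are emitted; the mean depth over a contig of width w is exactly
## n_reads_on_contig * read_len / w.

# deterministic per-sample seed fan-out
sample_seed <- function(master, idx) {
  m <- 2147483647
  as.integer(((abs(as.numeric(master)) %% m) * 16807 +
                as.numeric(idx) * 104729 + 3) %% (m - 1) + 1)
}

#' Build one individual's two haplotype sequence sets
#'
#' @param cohort a `pike_cohort`.
#' @param reference the reference `DNAStringSet`.
#' @param sample sample id.
#' @param seed seed controlling het-allele haplotype assignment.
#' @return A list of two `DNAStringSet`s (haplotype 1 and 2); carrier males
#'   additionally carry the insert contig on haplotype 2. Indel sites are
#'   left at the reference base (substitution-only editing).
#' @export
sample_haplotypes <- function(cohort, reference, sample, seed = 1) {
  gtv <- cohort$vcf$gt[, sample]
  sites <- cohort$vcf$sites
  zyg <- gt_zygosity(matrix(gtv, ncol = 1))[, 1]
  snp <- nchar(sites$ref) == 1 & nchar(sites$alt) == 1
  h1 <- h2 <- as.list(reference)
  with_seed(seed, {
    for (cn in unique(sites$chrom)) {
      i <- which(sites$chrom == cn & snp & !is.na(zyg) & zyg > 0)
      if (!length(i)) next
      hom <- i[zyg[i] == 2]
      het <- i[zyg[i] == 1]
      het_on_1 <- het[as.logical(rbinom(length(het), 1, 0.5))]
      het_on_2 <- setdiff(het, het_on_1)
      edit <- function(seq, at) {
        if (!length(at)) return(seq)
        Biostrings::replaceLetterAt(seq, sites$pos[at],
                                    paste(sites$alt[at], collapse = ""))
      }
      h1[[cn]] <- edit(h1[[cn]], sort(c(hom, het_on_1)))
      h2[[cn]] <- edit(h2[[cn]], sort(c(hom, het_on_2)))
    }
  })
  h1 <- Biostrings::DNAStringSet(h1)
  h2 <- Biostrings::DNAStringSet(h2)
  if (sample %in% cohort$truth$carriers && !is.null(cohort$insert))
    h2 <- c(h2, cohort$insert)
  list(h1 = h1, h2 = h2)
}

# sample reads (character vector) from a haplotype pair
reads_from_haplotypes <- function(haps, coverage_x, read_len, error_rate,
                                  genome_len, seed) {
  seqs <- c(haps$h1, haps$h2)
  w <- Biostrings::width(seqs)
  if (read_len > min(w))
    stopf("read_len %d exceeds the shortest contig (%d bp)", read_len, min(w))
  n_reads <- round(coverage_x * genome_len / read_len)
  with_seed(seed, {
    si <- sample.int(length(seqs), n_reads, replace = TRUE, prob = w)
    starts <- floor(runif(n_reads) * (w[si] - read_len + 1)) + 1
    seq_chr <- as.character(seqs)
    reads <- substring(seq_chr[si], starts, starts + read_len - 1)
    if (error_rate > 0) {
      nerr <- rbinom(n_reads, read_len, error_rate)
      for (r in which(nerr > 0)) {
        at <- sample.int(read_len, nerr[r])
        for (p in at)
          substr(reads[r], p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
    }
  })
  attr(reads, "contig") <- names(seqs)[si]
  reads
}

#' Simulate per-sample sequencing reads
#'
#' @param cohort a `pike_cohort` (optionally with a planted sex region).
#' @param reference the reference `DNAStringSet`.
#' @param coverage_x target mean depth per individual (> 0; default 15).
#' @param read_len read length in bp (default 150, as sequenced for the
#'   emulated cohort); must not exceed the shortest contig.
#' @param error_rate per-base substitution error probability (default 0.001).
#' @param out_dir if non-NULL, single-end FASTQ files
#'   (`<sample>.fastq.gz`) are written there.
#' @param gzip write gzip-compressed FASTQ (default TRUE).
#' @param seed master seed; per-sample seeds are derived deterministically.
#' @return A list: `fastq` (named paths, or NULL), `depth` (data.table
#'   `sample`, `region`, `mean_depth` with chromosome and insert rows), and
#'   `n_reads` (named integer).
#' @export
simulate_reads <- function(cohort, reference, coverage_x = 15,
                           read_len = 150, error_rate = 0.001,
                           out_dir = NULL, gzip = TRUE, seed = 1) {
  if (coverage_x <= 0) stopf("coverage_x must be positive")
  idx <- reference_index(reference)
  if (read_len > min(idx$length))
    stopf("read_len exceeds the shortest chromosome")
  paths <- c()
  depth <- list()
  n_reads <- c()
  for (j in seq_along(cohort$sheet$sample)) {
    sm <- cohort$sheet$sample[j]
    reads <- sample_reads_for_individual(cohort, reference, sm, coverage_x,
                                         read_len, error_rate, seed)
    depth[[sm]] <- read_depth_by_contig(reads, cohort, reference, read_len, sm)
    n_reads[sm] <- length(reads)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(out_dir, paste0(sm, if (gzip) ".fastq.gz" else ".fastq"))
      write_fastq(reads, f, sm)
      paths[sm] <- f
    }
  }
  list(fastq = if (length(paths)) paths, depth = rbindlist(depth),
       n_reads = n_reads)
}

# one individual's reads (used by simulate_reads and the streaming k-mer scan)
sample_reads_for_individual <- function(cohort, reference, sample,
                                        coverage_x = 15, read_len = 150,
                                        error_rate = 0.001, seed = 1) {
  j <- match(sample, cohort$sheet$sample)
  if (is.na(j)) stopf("unknown sample '%s'", sample)
  sseed <- sample_seed(seed, j)
  haps <- sample_haplotypes(cohort, reference, sample, seed = sseed)
  reads_from_haplotypes(haps, coverage_x, read_len, error_rate,
                        sum(Biostrings::width(reference)), sseed + 1)
}

# per-contig mean depth from read provenance (haplotypes of one chromosome
# are pooled under the chromosome name)
read_depth_by_contig <- function(reads, cohort, reference, read_len, sample) {
  contig <- attr(reads, "contig")
  regions <- c(names(reference),
               if (!is.null(cohort$insert)) names(cohort$insert))
  lens <- c(Biostrings::width(reference),
            if (!is.null(cohort$insert)) Biostrings::width(cohort$insert))
  counts <- table(factor(contig, levels = regions))
  data.table(sample = sample, region = regions,
             mean_depth = as.numeric(counts) * read_len / lens)
}

#' Write / read a single-end FASTQ file
#'
#' @param reads character vector of read sequences.
#' @param path output path (`.gz` suffix gives gzip output).
#' @param prefix read-name prefix.
#' @return `path` (write) or a character vector of reads (read).
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  qual <- strrep("I", nchar(reads))
  lines <- as.vector(rbind(sprintf("@%s_%d", prefix, seq_along(reads)),
                           reads, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x)
}
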