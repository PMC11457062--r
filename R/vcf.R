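## In-memory VCF container
##
## The pipeline's substrate is a light S3 container (`pike_vcf`) holding the
## site table (CHROM/POS/REF/ALT/QUAL plus GATK-style INFO annotations), a
## genotype-string matrix (GT) and a per-genotype depth matrix (DP).
## Reading standard VCF uses VariantAnnotation; writing emits VCF v4.2 text
## directly (the writer controls the exact INFO/FORMAT layout the simulator
## promises).

INFO_FIELDS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Construct a pike_vcf object
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated for multiallelic sites), `qual`, and optionally
#'   the INFO annotations `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`
#'   (NA = annotation absent at that site).
#' @param gt character matrix (sites x samples) of genotype strings such as
#'   `"0/0"`, `"0/1"`, `"./."`; column names are sample ids.
#' @param dp integer matrix of per-genotype depths, same shape as `gt`,
#'   or `NULL` if depths are unavailable.
#' @return An object of class `pike_vcf`.
#' @export
pike_vcf <- function(sites, gt, dp = NULL) {
  sites <- as.data.table(sites)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stopf("sites must have columns %s", paste(need, collapse = ", "))
  if (!"qual" %in% names(sites)) sites[, qual := NA_real_]
  for (f in INFO_FIELDS) if (!f %in% names(sites)) sites[[f]] <- NA_real_
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(sites)) stopf("gt rows must match sites")
  if (is.null(colnames(gt))) stopf("gt must have sample column names")
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    if (!identical(dim(dp), dim(gt))) stopf("dp shape must match gt")
    colnames(dp) <- colnames(gt)
  }
  ord <- order(sites$chrom, sites$pos)
  structure(list(sites = sites[ord], gt = gt[ord, , drop = FALSE],
                 dp = if (!is.null(dp)) dp[ord, , drop = FALSE],
                 samples = colnames(gt)),
            class = "pike_vcf")
}

#' @export
print.pike_vcf <- function(x, ...) {
  cat(sprintf("pike_vcf: %d sites x %d samples (%d chromosome(s))\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' Number of sites in a pike_vcf
#' @param vcf a `pike_vcf`.
#' @return Integer site count.
#' @export
n_sites <- function(vcf) nrow(vcf$sites)

# row/column subset preserving structure
vcf_subset <- function(vcf, sites = NULL, samples = NULL) {
  i <- sites %||% seq_len(nrow(vcf$sites))
  j <- samples %||% vcf$samples
  pike_vcf(vcf$sites[i], vcf$gt[i, j, drop = FALSE],
           if (!is.null(vcf$dp)) vcf$dp[i, j, drop = FALSE])
}

#' Write a pike_vcf as VCF v4.2 text
#'
#' INFO carries the GATK-style annotations (absent ones are omitted per
#' site); FORMAT is `GT:DP` (or `GT` when depths are unavailable).
#'
#' @param vcf a `pike_vcf`.
#' @param path output path (`.vcf`; use a `.gz` suffix for gzip output).
#' @param reference optional `DNAStringSet` used to emit `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path, reference = NULL) {
  s <- vcf$sites
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pikescan",
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   INFO_FIELDS,
                   c("Quality by depth", "Fisher strand bias",
                     "RMS mapping quality", "Mapping quality rank sum",
                     "Read position rank sum")),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  if (!is.null(reference))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(reference),
                          Biostrings::width(reference)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", vcf$samples),
                      collapse = "\t"))
  info <- rep("", nrow(s))
  for (f in INFO_FIELDS) {
    v <- s[[f]]
    piece <- ifelse(is.na(v), "",
                    sprintf("%s=%s", f, formatC(v, digits = 8, format = "g")))
    info <- ifelse(piece == "", info,
                   ifelse(info == "", piece, paste(info, piece, sep = ";")))
  }
  info[info == ""] <- "."
  if (!is.null(vcf$dp)) {
    dpc <- vcf$dp
    dpc[] <- ifelse(is.na(vcf$dp), ".", as.character(vcf$dp))
    sample_cols <- matrix(paste(vcf$gt, dpc, sep = ":"), nrow = nrow(s))
    fmt <- "GT:DP"
  } else {
    sample_cols <- vcf$gt
    fmt <- "GT"
  }
  body <- do.call(paste, c(list(
    s$chrom, s$pos, s$id %||% ".", s$ref, s$alt,
    ifelse(is.na(s$qual), ".", formatC(s$qual, digits = 8, format = "g")),
    "PASS", info, fmt),
    lapply(seq_len(ncol(sample_cols)), function(j) sample_cols[, j]),
    sep = "\t"))
  if (grepl("\\.gz$", path)) {
    # block-gzip so htslib-based readers can seek the result
    tmp <- sub("\\.gz$", "", tempfile(fileext = ".vcf"))
    writeLines(c(hdr, body), tmp)
    Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
    unlink(tmp)
  } else {
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a VCF file into a pike_vcf
#'
#' Parsing is delegated to [VariantAnnotation::readVcf()]; the GATK-style
#' INFO annotations are picked up when declared in the header.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @return A `pike_vcf`.
#' @export
read_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- VariantAnnotation::alt(v)
  alt_chr <- unname(vapply(as(alt, "CharacterList"), paste, "", collapse = ","))
  sites <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt_chr,
    qual = as.numeric(VariantAnnotation::qual(v)))
  inf <- VariantAnnotation::info(v)
  for (f in INFO_FIELDS)
    sites[[f]] <- if (f %in% colnames(inf)) as.numeric(inf[[f]]) else NA_real_
  g <- VariantAnnotation::geno(v)
  gt <- g$GT
  rownames(gt) <- NULL
  dp <- if ("DP" %in% names(g)) {
    d <- g$DP
    rownames(d) <- NULL
    storage.mode(d) <- "integer"
    d
  }
  pike_vcf(sites, gt, dp)
}

## genotype-string coding ----------------------------------------------------

# zygosity code per genotype string: 0 hom_ref, 1 het, 2 hom_alt, NA missing
gt_zygosity <- function(gt) {
  u <- unique(as.vector(gt))
  code <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NA_integer_)
    if (al[1] != al[2]) return(1L)
    if (al[1] == "0") 0L else 2L
  }, integer(1))
  z <- code[match(as.vector(gt), u)]
  matrix(z, nrow = nrow(gt), dimnames = dimnames(gt))
}

# non-reference allele copies per genotype (0..2), NA if missing
gt_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  code <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }, integer(1))
  d <- code[match(as.vector(gt), u)]
  matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
}

## sample sheet ---------------------------------------------------------------

#' Construct / validate a sample sheet
#'
#' @param sample character sample ids (unique).
#' @param population character population labels.
#' @param sex phenotypic sex: `"male"`, `"female"` or `"unknown"`
#'   (`"M"`/`"F"` accepted and normalized).
#' @return `data.frame(sample, population, sex)`.
#' @export
sample_sheet <- function(sample, population, sex) {
  if (anyDuplicated(sample)) stopf("sample ids must be unique")
  sex <- tolower(as.character(sex))
  sex[sex %in% c("m", "male")] <- "male"
  sex[sex %in% c("f", "female")] <- "female"
  sex[!sex %in% c("male", "female")] <- "unknown"
  data.frame(sample = as.character(sample),
             population = as.character(population),
             sex = sex, stringsAsFactors = FALSE)
}

#' Write / read a sample sheet TSV
#' @param sheet a sample sheet data.frame.
#' @param path TSV path.
#' @return `path` (write) or the sheet (read).
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  sample_sheet(x$sample, x$population, x$sex)
}
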