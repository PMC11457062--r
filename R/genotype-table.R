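#' Genotype table: the central substrate for diversity and sex screens
#'
#' Combines a [pike_vcf] with a sample sheet and precomputes per-genotype
#' zygosity codes (0 hom-ref, 1 het, 2 hom-alt, NA missing) and
#' non-reference allele dosages.
#'
#' @param vcf a [pike_vcf].
#' @param sheet a [sample_sheet()] covering every VCF sample.
#' @return An object of class `genotype_table` with elements `sites`,
#'   `gt`, `zyg`, `dos`, `samples`, `sheet`.
#' @export
genotype_table <- function(vcf, sheet) {
  missing_samples <- setdiff(vcf$samples, sheet$sample)
  if (length(missing_samples))
    stopf("samples absent from the sheet: %s",
          paste(missing_samples, collapse = ", "))
  sheet <- sheet[match(vcf$samples, sheet$sample), ]
  structure(list(sites = vcf$sites, gt = vcf$gt,
                 zyg = gt_zygosity(vcf$gt), dos = gt_dosage(vcf$gt),
                 samples = vcf$samples, sheet = sheet),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites x %d samples, populations: %s\n",
              nrow(x$sites), length(x$samples),
              paste(unique(x$sheet$population), collapse = ", ")))
  invisible(x)
}

# subset helper (sites by index, samples by id)
gtab_subset <- function(tab, sites = NULL, samples = NULL) {
  i <- sites %||% seq_len(nrow(tab$sites))
  j <- samples %||% tab$samples
  structure(list(sites = tab$sites[i], gt = tab$gt[i, j, drop = FALSE],
                 zyg = tab$zyg[i, j, drop = FALSE],
                 dos = tab$dos[i, j, drop = FALSE], samples = j,
                 sheet = tab$sheet[match(j, tab$sheet$sample), ]),
            class = "genotype_table")
}

# biallelic-site mask (single ALT allele)
is_biallelic <- function(tab) !grepl(",", tab$sites$alt, fixed = TRUE)
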