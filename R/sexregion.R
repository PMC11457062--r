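#' Specify an XY sex-linked region to plant
#'
#' The region emulates an XY system realized two ways: SNPs inside a
#' chromosomal interval at which every carrier-population male is
#' heterozygous and every female homozygous-reference, and a male-only
#' insert contig (an *amhby*-like scaffold, pure presence/absence) absent
#' from the reference and carried on one haplotype of carrier males.
#'
#' @param chrom chromosome name holding the region.
#' @param start,end 1-based inclusive interval bounds (bp), `start <= end`.
#' @param male_het_snp_count number of male-linked SNPs to plant (>= 0).
#' @param insert_name contig name for the male-only insert.
#' @param insert_length insert length in bp (default 5000).
#' @param carrier_populations population names whose males carry the system.
#' @return A `sex_region_spec` list.
#' @export
sex_region_spec <- function(chrom, start, end, male_het_snp_count,
                            insert_name = "amhby_scaffold",
                            insert_length = 5000,
                            carrier_populations) {
  if (start > end) stopf("start must be <= end")
  if (male_het_snp_count < 0) stopf("male_het_snp_count must be >= 0")
  if (insert_length <= 0) stopf("insert_length must be positive")
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end),
                 male_het_snp_count = as.integer(male_het_snp_count),
                 insert_name = insert_name,
                 insert_length = as.integer(insert_length),
                 carrier_populations = as.character(carrier_populations)),
            class = "sex_region_spec")
}

#' Plant an XY sex-linked region into a simulated cohort
#'
#' Adds exactly `region$male_het_snp_count` SNP sites inside the region at
#' which every male of a carrier population is heterozygous (`0/1`) and
#' every other sample is homozygous reference, with filter-passing INFO
#' annotations; records a male-only insert sequence absent from the
#' reference, carried on one haplotype of carrier males (realized when
#' reads are simulated); and updates the truth set.
#'
#' @param cohort a `pike_cohort` from [simulate_cohort()].
#' @param region a [sex_region_spec()].
#' @param reference the `DNAStringSet` the cohort was simulated on.
#' @param seed integer seed (default derived from the cohort's seed).
#' @return The modified `pike_cohort` (new `vcf`, `truth$sex_region`,
#'   `truth$carriers`, and `insert` as a `DNAStringSet`).
#' @export
plant_sex_region <- function(cohort, region, reference, seed = NULL) {
  stopifnot(inherits(cohort, "pike_cohort"),
            inherits(region, "sex_region_spec"))
  idx <- reference_index(reference)
  if (!region$chrom %in% idx$chrom)
    stopf("region chromosome '%s' is not in the reference", region$chrom)
  chrom_len <- idx$length[idx$chrom == region$chrom]
  if (region$end > chrom_len)
    stopf("region [%d, %d] exceeds chromosome length %d",
          region$start, region$end, chrom_len)
  if (!all(region$carrier_populations %in% cohort$sheet$population))
    stopf("carrier populations must be cohort populations")
  seed <- seed %||% derive_seed(cohort$spec$seed, "sexregion")
  sheet <- cohort$sheet
  carriers <- sheet$sample[sheet$sex == "male" &
                             sheet$population %in% region$carrier_populations]
  k <- region$male_het_snp_count
  with_seed(seed, {
    taken <- cohort$vcf$sites[chrom == region$chrom, pos]
    avail <- setdiff(seq(region$start, region$end), taken)
    if (length(avail) < k)
      stopf("region too small for %d new sites", k)
    new_pos <- sort(sample(avail, k))
    ref_base <- ref_bases_at(reference, rep(region$chrom, k), new_pos)
    alt_base <- random_alt_base(ref_base)
    new_sites <- data.table(
      chrom = region$chrom, pos = new_pos,
      id = sprintf("sexsnp%04d", seq_len(k)),
      ref = ref_base, alt = alt_base,
      qual = runif(k, 100, 2000),
      QD = runif(k, 5, 35), FS = runif(k, 0, 30), MQ = runif(k, 40, 60),
      MQRankSum = rnorm(k, 0, 2), ReadPosRankSum = rnorm(k, 0, 2))
    new_gt <- matrix("0/0", k, nrow(sheet),
                     dimnames = list(NULL, sheet$sample))
    new_gt[, carriers] <- "0/1"
    new_dp <- matrix(rpois(k * nrow(sheet), cohort$spec$mean_depth), k,
                     dimnames = list(NULL, sheet$sample))
    insert <- simulate_reference(
      setNames(max(region$insert_length, 10000), region$insert_name),
      seed = seed + 1)
    insert <- Biostrings::subseq(insert, 1, region$insert_length)
  })
  vcf <- pike_vcf(rbind(cohort$vcf$sites, new_sites, fill = TRUE),
                  rbind(cohort$vcf$gt, new_gt),
                  if (!is.null(cohort$vcf$dp)) rbind(cohort$vcf$dp, new_dp))
  truth <- cohort$truth
  new_keys <- paste0(region$chrom, ":", new_pos)
  truth$site_class <- c(truth$site_class,
                        setNames(rep("male_linked", k), new_keys))
  truth$sex_region <- list(chrom = region$chrom, start = region$start,
                           end = region$end, insert_name = region$insert_name)
  truth$carriers <- carriers
  cohort$vcf <- vcf
  cohort$truth <- truth
  cohort$insert <- insert
  cohort$region <- region
  cohort
}

## truth-set JSON -------------------------------------------------------------

#' Write / read the machine-readable truth file
#'
#' Serializes the planted parameters of a synthetic cohort (true sexes,
#' per-site classifications, sex region, carriers, expected heterozygosity,
#' planted filter failures) as JSON for parameter-recovery tests.
#'
#' @param truth a `truth_set` (from a `pike_cohort`).
#' @param path JSON path.
#' @return `path` (write) or a `truth_set` (read).
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$planted_fail <- as.data.frame(truth$planted_fail)
  x$freq <- as.data.frame(truth$freq)
  # named vectors as JSON objects (jsonlite drops names of atomic vectors)
  for (f in c("true_sex", "site_class", "expected_het", "theta"))
    x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$true_sex <- unlist(x$true_sex)
  x$site_class <- unlist(x$site_class)
  x$expected_het <- unlist(x$expected_het)
  x$theta <- unlist(x$theta)
  x$planted_fail <- as.data.table(x$planted_fail)
  x$freq <- as.data.table(x$freq)
  structure(x, class = "truth_set")
}
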