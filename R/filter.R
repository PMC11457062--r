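## Variant-filter cascade
##
## Reproduces the published post-genotyping filter cascade: SNP selection,
## the GATK hard filter (QD/FS/MQ/MQRankSum/ReadPosRankSum), then the
## VCFtools-style site filters (QUAL, mean depth window, missing count,
## minor allele count, homozygote presence, not-all-heterozygous), applied
## in the printed order with a retention report after every step. A missing
## INFO annotation never causes removal (GATK's behavior for rank-sum
## fields); mean depth is taken over non-missing genotypes (the VCFtools
## site-mean-depth convention).

#' Filter thresholds
#'
#' Defaults are the published cascade's parameters: QD >= 2, FS <= 60,
#' MQ >= 30, MQRankSum >= -12.5, ReadPosRankSum >= -8.0, QUAL >= 20,
#' site mean depth in `[10, 60]`, at most 10 individuals missing, minor
#' allele count >= 1, at least one homozygous call, and not all
#' heterozygous.
#'
#' @param qd_min,fs_max,mq_min,mqranksum_min,readposranksum_min GATK
#'   hard-filter cutoffs.
#' @param qual_min minimum site QUAL.
#' @param mean_depth_min,mean_depth_max window for the site mean depth
#'   (over non-missing genotypes).
#' @param max_missing_count maximum number of missing genotypes per site.
#' @param mac_min minimum copies of the minor allele.
#' @param require_homozygote require >= 1 homozygous (ref or alt) call.
#' @param drop_all_het drop sites whose non-missing genotypes are all
#'   heterozygous.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(qd_min = 2, fs_max = 60, mq_min = 30,
                              mqranksum_min = -12.5,
                              readposranksum_min = -8.0, qual_min = 20,
                              mean_depth_min = 10, mean_depth_max = 60,
                              max_missing_count = 10, mac_min = 1,
                              require_homozygote = TRUE,
                              drop_all_het = TRUE) {
  x <- list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
            mqranksum_min = mqranksum_min,
            readposranksum_min = readposranksum_min, qual_min = qual_min,
            mean_depth_min = mean_depth_min, mean_depth_max = mean_depth_max,
            max_missing_count = max_missing_count, mac_min = mac_min,
            require_homozygote = require_homozygote,
            drop_all_het = drop_all_het)
  num <- unlist(x[1:10])
  if (any(!is.finite(num))) stopf("all numeric thresholds must be finite")
  if (mean_depth_min > mean_depth_max)
    stopf("mean_depth_min must be <= mean_depth_max")
  structure(x, class = "filter_thresholds")
}

#' Keep SNP sites only
#'
#' A site is a SNP iff REF and every ALT allele are single bases;
#' multiallelic SNPs are retained.
#'
#' @param vcf a [pike_vcf].
#' @return The SNP-only `pike_vcf` (possibly empty).
#' @export
select_snps <- function(vcf) {
  s <- vcf$sites
  bad <- is.na(s$ref) | is.na(s$alt) | s$ref == "" | s$alt == ""
  if (any(bad))
    stopf("unreadable REF/ALT at site row %d", which(bad)[1])
  alt_ok <- vapply(strsplit(s$alt, ",", fixed = TRUE),
                   function(a) all(nchar(a) == 1), TRUE)
  keep <- nchar(s$ref) == 1 & alt_ok
  vcf_subset(vcf, which(keep))
}

#' Apply the GATK-style hard filter
#'
#' A site is removed iff any present annotation violates its cutoff
#' (`QD < qd_min`, `FS > fs_max`, `MQ < mq_min`,
#' `MQRankSum < mqranksum_min`, `ReadPosRankSum < readposranksum_min`).
#' A missing annotation never causes removal.
#'
#' @param vcf a [pike_vcf].
#' @param thresholds a [filter_thresholds()].
#' @return The filtered `pike_vcf`.
#' @export
hard_filter <- function(vcf, thresholds = filter_thresholds()) {
  s <- vcf$sites
  fails <- function(v, bad) !is.na(v) & bad(v)
  drop <- fails(s$QD, function(v) v < thresholds$qd_min) |
    fails(s$FS, function(v) v > thresholds$fs_max) |
    fails(s$MQ, function(v) v < thresholds$mq_min) |
    fails(s$MQRankSum, function(v) v < thresholds$mqranksum_min) |
    fails(s$ReadPosRankSum, function(v) v < thresholds$readposranksum_min)
  vcf_subset(vcf, which(!drop))
}

# per-site summaries used by the site filters
site_summaries <- function(vcf) {
  zyg <- gt_zygosity(vcf$gt)
  n_missing <- rowSums(is.na(zyg))
  n_called <- ncol(zyg) - n_missing
  mean_dp <- if (!is.null(vcf$dp)) {
    rowSums(vcf$dp, na.rm = TRUE) / pmax(rowSums(!is.na(vcf$dp)), 1)
  }
  list(zyg = zyg, n_missing = n_missing, n_called = n_called,
       mean_dp = mean_dp)
}

# minor-allele copy count per site: copies of the least frequent allele of
# the declared REF/ALT set among non-missing genotypes (diploid, so up to
# 2 per sample); an unobserved declared allele gives mac 0
minor_allele_count <- function(gt, alt) {
  n_alleles <- lengths(strsplit(alt, ",", fixed = TRUE)) + 1L
  vapply(seq_len(nrow(gt)), function(i) {
    al <- unlist(strsplit(gt[i, ], "[/|]"))
    al <- al[al != "."]
    if (!length(al)) return(0L)
    counts <- tabulate(as.integer(al) + 1L, nbins = n_alleles[i])
    as.integer(min(counts))
  }, 0L)
}

#' Apply the site-level filters with a per-step report
#'
#' Steps in the published order: QUAL >= `qual_min`; mean depth over
#' non-missing genotypes within `[mean_depth_min, mean_depth_max]`;
#' missing-genotype count <= `max_missing_count`; minor-allele copy
#' count at least `mac_min`; at least one homozygous genotype; not all non-missing
#' genotypes heterozygous. Returns the filtered VCF and a report recording
#' retention after every step.
#'
#' @param vcf a [pike_vcf] with GT (and DP, required by the depth step).
#' @param thresholds a [filter_thresholds()].
#' @return list(`vcf`, `report`), where `report` is a data.frame
#'   (`step`, `parameter`, `n_retained`).
#' @export
site_filters <- function(vcf, thresholds = filter_thresholds()) {
  if (is.null(vcf$dp))
    stopf("VCF has no DP: the mean-depth step cannot run")
  report <- list()
  keep_step <- function(v, step, param, pred) {
    ss <- site_summaries(v)
    v2 <- vcf_subset(v, which(pred(v, ss)))
    report[[length(report) + 1]] <<- data.frame(
      step = step, parameter = param, n_retained = nrow(v2$sites),
      stringsAsFactors = FALSE)
    v2
  }
  v <- keep_step(vcf, "Min. quality", thresholds$qual_min,
                 function(v, ss) !is.na(v$sites$qual) &
                   v$sites$qual >= thresholds$qual_min)
  v <- keep_step(v, "Min. mean depth", thresholds$mean_depth_min,
                 function(v, ss) ss$mean_dp >= thresholds$mean_depth_min)
  v <- keep_step(v, "Max. mean depth", thresholds$mean_depth_max,
                 function(v, ss) ss$mean_dp <= thresholds$mean_depth_max)
  v <- keep_step(v, "Max. missing count", thresholds$max_missing_count,
                 function(v, ss) ss$n_missing <= thresholds$max_missing_count)
  v <- keep_step(v, "Minor allele count", thresholds$mac_min,
                 function(v, ss) minor_allele_count(v$gt, v$sites$alt) >=
                   thresholds$mac_min)
  if (thresholds$require_homozygote || thresholds$drop_all_het) {
    v <- keep_step(v, "Per locus heterozygous genotypes", "<100%",
                   function(v, ss) {
                     n_het <- rowSums(ss$zyg == 1, na.rm = TRUE)
                     ok <- rep(TRUE, nrow(v$sites))
                     if (thresholds$require_homozygote)
                       ok <- ok & (ss$n_called - n_het) > 0
                     if (thresholds$drop_all_het)
                       ok <- ok & !(ss$n_called > 0 & n_het == ss$n_called)
                     ok
                   })
  }
  list(vcf = v, report = do.call(rbind, report))
}

#' Run the full filter cascade
#'
#' SNP selection, hard filter, then site filters, with a report mirroring
#' the published table (step, parameter, variants retained).
#'
#' @param vcf a [pike_vcf] of raw genotypes (may include indels).
#' @param thresholds a [filter_thresholds()].
#' @return list(`vcf`, `report`).
#' @export
filter_cascade <- function(vcf, thresholds = filter_thresholds()) {
  report <- data.frame(step = "Raw genotypes (includes indels)",
                       parameter = "-", n_retained = nrow(vcf$sites),
                       stringsAsFactors = FALSE)
  v <- select_snps(vcf)
  report <- rbind(report, data.frame(step = "SNP variants only",
                                     parameter = "-",
                                     n_retained = nrow(v$sites)))
  v <- hard_filter(v, thresholds)
  report <- rbind(report, data.frame(step = "GATK-style hard filter",
                                     parameter = "-",
                                     n_retained = nrow(v$sites)))
  sf <- site_filters(v, thresholds)
  list(vcf = sf$vcf, report = rbind(report, sf$report))
}

#' Retention percentage
#'
#' @param n_raw raw variant count (> 0).
#' @param n_retained retained count (<= `n_raw`).
#' @return `100 * n_retained / n_raw`, rounded to one decimal.
#' @export
retention_percent <- function(n_raw, n_retained) {
  if (n_raw <= 0) stopf("n_raw must be positive")
  if (n_retained > n_raw) stopf("n_retained cannot exceed n_raw")
  round_half_up(1000 * n_retained / n_raw) / 10
}
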