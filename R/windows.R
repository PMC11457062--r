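## Chromosome-window variant-density scan with Tukey outlier detection

#' Tile chromosomes into fixed-width windows
#'
#' Windows are 0-based half-open (BED convention); the final window of a
#' chromosome is truncated at the chromosome length.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param width window width in bp (> 0; default 1e6, as published).
#' @return data.frame(chrom, start, end) with `ceil(length/width)` windows
#'   per chromosome.
#' @export
make_windows <- function(chrom_lengths, width = 1e6) {
  if (width <= 0) stopf("width must be positive")
  chrom_lengths <- normalize_chrom_lengths(chrom_lengths)
  rbindlist(lapply(names(chrom_lengths), function(cn) {
    L <- chrom_lengths[[cn]]
    starts <- seq(0, L - 1, by = width)
    data.table(chrom = cn, start = starts, end = pmin(starts + width, L))
  }))[, .(chrom, start, end)] |> as.data.frame()
}

#' Count variants per window
#'
#' A variant at 1-based position p belongs to the half-open window with
#' `p - 1` in `[start, end)`; so position 1,000,000 falls in the first
#' 1-Mbp window and 1,000,001 in the second. Variants on chromosomes
#' absent from the windows are skipped with a warning (count in attribute
#' `n_skipped`).
#'
#' @param vcf a [pike_vcf] (or any data.frame with `chrom` and `pos`).
#' @param windows window table from [make_windows()].
#' @return `windows` with an `n_variants` column.
#' @export
count_per_window <- function(vcf, windows) {
  sites <- if (inherits(vcf, "pike_vcf")) vcf$sites else as.data.table(vcf)
  w <- as.data.table(windows)
  known <- sites$chrom %in% unique(w$chrom)
  if (any(!known))
    warnf("%d variant(s) on chromosomes without windows were skipped",
          sum(!known))
  s <- sites[known]
  w[, n_variants := 0L]
  if (nrow(s)) {
    for (cn in unique(s$chrom)) {
      wi <- which(w$chrom == cn)
      breaks <- c(w$start[wi], w$end[wi][length(wi)])
      hit <- findInterval(s[chrom == cn, pos] - 1, breaks,
                          rightmost.closed = FALSE)
      hit <- hit[hit >= 1 & hit <= length(wi)]
      cnt <- tabulate(hit, nbins = length(wi))
      w$n_variants[wi] <- w$n_variants[wi] + cnt
    }
  }
  out <- as.data.frame(w[, .(chrom, start, end, n_variants)])
  attr(out, "n_skipped") <- sum(!known)
  out
}

#' Tukey boxplot outlier threshold for window counts
#'
#' Hinges are Tukey hinges (median-inclusive halves, the `fivenum` /
#' `boxplot.stats` convention, deliberately not type-7 quantiles);
#' threshold = upper hinge + 1.5 x inter-hinge range; outliers are windows
#' with counts strictly above the threshold.
#'
#' @param counts integer vector of per-window variant counts (>= 5 windows).
#' @return list(`q1_hinge`, `q3_hinge`, `iqr`, `threshold`,
#'   `outliers` = indices of outlier windows).
#' @export
outlier_threshold <- function(counts) {
  if (length(counts) < 5) stopf("need >= 5 windows for the outlier rule")
  fn <- fivenum(counts)
  q1 <- fn[2]
  q3 <- fn[4]
  iqr <- q3 - q1
  thr <- q3 + 1.5 * iqr
  list(q1_hinge = q1, q3_hinge = q3, iqr = iqr, threshold = thr,
       outliers = which(counts > thr))
}

#' Per-chromosome variant density (variants per kbp)
#'
#' @param window_densities output of [count_per_window()].
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return data.frame(chrom, n_variants, length, per_kbp).
#' @export
per_chrom_density <- function(window_densities, chrom_lengths) {
  chrom_lengths <- normalize_chrom_lengths(chrom_lengths)
  wd <- as.data.table(window_densities)
  if (!nrow(wd)) stopf("empty window table")
  tot <- wd[, .(n_variants = sum(n_variants)), by = chrom]
  out <- data.table(chrom = names(chrom_lengths),
                    length = as.numeric(chrom_lengths))
  out <- merge(out, tot, by = "chrom", all.x = TRUE, sort = FALSE)
  out[is.na(n_variants), n_variants := 0L]
  out[, per_kbp := n_variants / (length / 1000)]
  as.data.frame(out[, .(chrom, n_variants, length, per_kbp)])
}
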