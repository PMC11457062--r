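## Per-individual and per-population diversity statistics

#' Per-sample genotype tallies and per-population means
#'
#' Counts heterozygous and homozygous-alternate genotypes per sample over
#' non-missing calls, with arithmetic population means — the per-individual
#' variant summary of the published cohort (its west-to-east gradient is
#' the structure the synthetic generator emulates).
#'
#' @param tab a [genotype_table()].
#' @param samples optional subset of sample ids.
#' @return list(`per_sample` = data.frame(sample, population, n_het,
#'   n_hom_alt), `per_population` = data.frame(population, mean_het,
#'   mean_hom_alt, n)).
#' @export
genotype_tallies <- function(tab, samples = NULL) {
  if (!nrow(tab$sites)) stopf("empty genotype table")
  if (!is.null(samples)) {
    unknown <- setdiff(samples, tab$samples)
    if (length(unknown))
      stopf("samples not in table: %s", paste(unknown, collapse = ", "))
    tab <- gtab_subset(tab, samples = samples)
  }
  z <- tab$zyg
  per_sample <- data.frame(
    sample = tab$samples,
    population = tab$sheet$population,
    n_het = colSums(z == 1, na.rm = TRUE),
    n_hom_alt = colSums(z == 2, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  ps <- as.data.table(per_sample)
  per_population <- as.data.frame(ps[, .(
    mean_het = mean(n_het), mean_hom_alt = mean(n_hom_alt), n = .N),
    by = population])
  list(per_sample = per_sample, per_population = per_population)
}

#' Observed heterozygosity of a population
#'
#' Mean over loci of (heterozygous calls / non-missing calls) within the
#' population; loci with no non-missing call in the population are skipped.
#' Under zero missingness this equals (mean per-sample het count) / n_loci.
#'
#' @param tab a [genotype_table()].
#' @param population population name.
#' @return H_OBS, a single number in `[0, 1]`.
#' @export
observed_heterozygosity <- function(tab, population) {
  ids <- tab$sheet$sample[tab$sheet$population == population]
  if (!length(ids)) stopf("population '%s' has no samples", population)
  z <- tab$zyg[, ids, drop = FALSE]
  n_called <- rowSums(!is.na(z))
  n_het <- rowSums(z == 1, na.rm = TRUE)
  use <- n_called > 0
  if (!any(use)) stopf("no locus with a non-missing call in '%s'", population)
  mean(n_het[use] / n_called[use])
}

# per-population allele copy counts for one site's genotype strings
site_allele_counts <- function(gt_row, pops) {
  al <- strsplit(gt_row, "[/|]")
  tab <- list()
  for (p in unique(pops)) {
    a <- unlist(al[pops == p])
    a <- a[a != "."]
    tab[[p]] <- table(a)
  }
  tab
}

#' Private alleles per population
#'
#' A (locus, allele) pair is private to population p iff its copy count is
#' positive in p and zero in every other population; only pairs with copy
#' count >= `min_count` in p are reported (the published analysis uses both
#' `min_count = 1` and `min_count = 4`).
#'
#' @param tab a [genotype_table()].
#' @param populations populations to scan (default: all in the sheet; >= 2
#'   required).
#' @param min_count minimum copy number of the private allele (default 1).
#' @return named integer vector of private-allele counts per population.
#' @export
private_alleles <- function(tab, populations = NULL, min_count = 1) {
  populations <- populations %||% unique(tab$sheet$population)
  if (length(populations) < 2)
    stopf("privacy is undefined for a single population")
  ids <- tab$sheet$sample[tab$sheet$population %in% populations]
  pops <- tab$sheet$population[match(ids, tab$sheet$sample)]
  out <- setNames(integer(length(populations)), populations)
  bi <- is_biallelic(tab)
  dosv <- tab$dos[, ids, drop = FALSE]
  ## fast path for biallelic sites: count copies of each allele per pop
  if (any(bi)) {
    d <- dosv[bi, , drop = FALSE]
    for (p in populations) {
      inp <- pops == p
      alt_in <- rowSums(d[, inp, drop = FALSE], na.rm = TRUE)
      alt_out <- rowSums(d[, !inp, drop = FALSE], na.rm = TRUE)
      ref_in <- 2 * rowSums(!is.na(d[, inp, drop = FALSE])) - alt_in
      ref_out <- 2 * rowSums(!is.na(d[, !inp, drop = FALSE])) - alt_out
      out[p] <- out[p] + sum(alt_in >= min_count & alt_out == 0) +
        sum(ref_in >= min_count & ref_out == 0)
    }
  }
  ## generic path for multiallelic sites
  for (i in which(!bi)) {
    counts <- site_allele_counts(tab$gt[i, ids], pops)
    alleles <- unique(unlist(lapply(counts, names)))
    for (a in alleles) {
      have <- vapply(counts, function(ct)
        if (a %in% names(ct)) as.integer(ct[[a]]) else 0L, 0L)
      inp <- have > 0
      if (sum(inp) == 1 && have[inp] >= min_count)
        out[names(have)[inp]] <- out[names(have)[inp]] + 1L
    }
  }
  out
}

#' Pairwise fixed-difference counts
#'
#' For each ordered population pair (A, B): the number of biallelic sites
#' at which every non-missing A genotype is homozygous-alternate and every
#' non-missing B genotype is homozygous-reference (both populations must
#' have at least one call). Non-biallelic sites are skipped (count logged
#' as an attribute). Also reports per-population fixed-alternate totals.
#'
#' @param tab a [genotype_table()].
#' @param populations populations to compare (default: all).
#' @return list(`matrix` = ordered-pair counts with rows = fixed-alt
#'   population A, `fixed_alt` = per-population fixed-alt site totals);
#'   attribute `n_skipped` = non-biallelic site count.
#' @export
fixed_difference_matrix <- function(tab, populations = NULL) {
  populations <- populations %||% unique(tab$sheet$population)
  bi <- is_biallelic(tab)
  z <- tab$zyg[bi, , drop = FALSE]
  fixed_alt <- fixed_ref <- list()
  for (p in populations) {
    ids <- tab$sheet$sample[tab$sheet$population == p]
    zp <- z[, ids, drop = FALSE]
    called <- rowSums(!is.na(zp)) > 0
    fixed_alt[[p]] <- called & rowSums(zp != 2, na.rm = TRUE) == 0
    fixed_ref[[p]] <- called & rowSums(zp != 0, na.rm = TRUE) == 0
  }
  m <- matrix(0L, length(populations), length(populations),
              dimnames = list(populations, populations))
  for (a in populations) for (b in setdiff(populations, a))
    m[a, b] <- sum(fixed_alt[[a]] & fixed_ref[[b]])
  res <- list(matrix = m,
              fixed_alt = vapply(fixed_alt, sum, 0L))
  attr(res, "n_skipped") <- sum(!bi)
  res
}

#' Average SNP spacing and per-individual divergence
#'
#' `snp_spacing()` is the genome length divided by the variant count,
#' rounded half-up to integer bp (matching the published "one heterozygous
#' SNP every 5,199 bp" convention); `divergence_percent()` is
#' `100 * count / length`.
#'
#' @param genome_length_bp ungapped genome length in bp.
#' @param variant_count (possibly fractional mean) variant count (> 0 for
#'   spacing).
#' @return spacing in bp (integer) or divergence in percent.
#' @export
snp_spacing <- function(genome_length_bp, variant_count) {
  if (variant_count <= 0) stopf("variant_count must be positive")
  round_half_up(genome_length_bp / variant_count)
}

#' @rdname snp_spacing
#' @export
divergence_percent <- function(genome_length_bp, variant_count) {
  if (genome_length_bp <= 0) stopf("genome_length_bp must be positive")
  100 * variant_count / genome_length_bp
}

#' Identity-by-state distance matrix
#'
#' distance(i, j) = mean over co-called sites of (allele mismatch count)/2,
#' in `[0, 1]`; the mismatch count between two diploid genotypes is
#' 2 minus the size of the optimal allele pairing (so het vs het = 0,
#' hom-ref vs het = 1, hom-ref vs hom-alt = 2). A pair with zero co-called
#' sites gets NA and is flagged in the `undefined_pairs` attribute. This
#' allele-sharing distance stands in for the published genome-wide
#' dendrogram's input.
#'
#' @param tab a [genotype_table()] (>= 2 samples).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
ibs_distance_matrix <- function(tab) {
  n <- length(tab$samples)
  if (n < 2) stopf("need >= 2 samples")
  bi <- is_biallelic(tab)
  d_bi <- tab$dos[bi, , drop = FALSE]
  ## multiallelic sites: mismatch via allele multisets
  multi <- which(!bi)
  mm_multi <- function(g1, g2) {
    a1 <- strsplit(g1, "[/|]")
    a2 <- strsplit(g2, "[/|]")
    vapply(seq_along(a1), function(i) {
      x <- a1[[i]]; y <- a2[[i]]
      if (any(x == ".") || any(y == ".")) return(NA_real_)
      shared <- sum(pmin(table(factor(x, levels = union(x, y))),
                         table(factor(y, levels = union(x, y)))))
      2 - shared
    }, 0)
  }
  m <- matrix(0, n, n, dimnames = list(tab$samples, tab$samples))
  undef <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diff_bi <- abs(d_bi[, i] - d_bi[, j])
    diffs <- diff_bi
    if (length(multi))
      diffs <- c(diffs, mm_multi(tab$gt[multi, i], tab$gt[multi, j]))
    ok <- !is.na(diffs)
    if (!any(ok)) {
      m[i, j] <- m[j, i] <- NA_real_
      undef <- c(undef, paste(tab$samples[i], tab$samples[j], sep = "-"))
    } else {
      m[i, j] <- m[j, i] <- mean(diffs[ok]) / 2
    }
  }
  attr(m, "undefined_pairs") <- undef
  m
}
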