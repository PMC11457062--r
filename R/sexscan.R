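## Genotype-pattern and coverage-ratio sex-linkage detectors

#' Prefilter sites for an XY sex screen
#'
#' Drops every site at which any non-missing genotype in the analyzed
#' group is homozygous-alternate. Rationale: against a female-derived
#' reference with an XY system, sex-linked variation appears only as
#' heterozygous or homozygous-reference genotypes, so hom-alt sites are
#' not expected to be part of the system. The alternative of masking
#' individual hom-alt genotypes (rather than dropping the site) is exposed
#' via `mode = "mask"`.
#'
#' @param tab a [genotype_table()].
#' @param group sample ids to consider (non-empty subset of the table).
#' @param mode `"drop_site"` (default) or `"mask"` (set hom-alt genotypes
#'   missing, keep sites).
#' @return The reduced `genotype_table`.
#' @export
prefilter_sex_sites <- function(tab, group = tab$samples,
                                mode = c("drop_site", "mask")) {
  mode <- match.arg(mode)
  if (!length(group)) stopf("empty group")
  unknown <- setdiff(group, tab$samples)
  if (length(unknown))
    stopf("unknown samples: %s", paste(unknown, collapse = ", "))
  z <- tab$zyg[, group, drop = FALSE]
  if (mode == "drop_site") {
    any_hom_alt <- rowSums(z == 2, na.rm = TRUE) > 0
    gtab_subset(tab, which(!any_hom_alt), group)
  } else {
    tab <- gtab_subset(tab, samples = group)
    mask <- tab$zyg == 2
    tab$zyg[mask] <- NA_integer_
    tab$dos[mask] <- NA_integer_
    tab$gt[mask] <- "./."
    tab
  }
}

#' Scan for sex-specific heterozygosity patterns
#'
#' A site is `male_specific_het` iff at most `tolerance` males are
#' not heterozygous AND at most `tolerance` females are heterozygous
#' (missing genotypes excluded from both tallies); symmetrically for
#' `female_specific_het`. Returns the flagged sites and a per-chromosome
#' histogram of counts in fixed-width bins.
#'
#' @param tab a [genotype_table()].
#' @param sexes optional named vector sample -> sex; defaults to the
#'   table's sheet. At least one sample per sex is required.
#' @param tolerance allowed exceptions per rule (default 0).
#' @param bin_bp histogram bin width (default 100000).
#' @return list(`sites` = data.frame(chrom, pos, pattern, n_males_not_het,
#'   n_females_het, n_females_not_het, n_males_het), `histogram` =
#'   data.frame(chrom, start, end, pattern, n)).
#' @export
exact_pattern_scan <- function(tab, sexes = NULL, tolerance = 0,
                               bin_bp = 1e5) {
  sexes <- sexes %||% setNames(tab$sheet$sex, tab$sheet$sample)
  males <- names(sexes)[sexes == "male"]
  females <- names(sexes)[sexes == "female"]
  males <- intersect(males, tab$samples)
  females <- intersect(females, tab$samples)
  if (!length(males) || !length(females))
    stopf("need >= 1 sample of each sex")
  zm <- tab$zyg[, males, drop = FALSE]
  zf <- tab$zyg[, females, drop = FALSE]
  m_not_het <- rowSums(zm != 1, na.rm = TRUE)
  f_het <- rowSums(zf == 1, na.rm = TRUE)
  f_not_het <- rowSums(zf != 1, na.rm = TRUE)
  m_het <- rowSums(zm == 1, na.rm = TRUE)
  male_sp <- m_not_het <= tolerance & f_het <= tolerance
  female_sp <- f_not_het <= tolerance & m_het <= tolerance
  ## a site matching both patterns (possible only in degenerate tiny
  ## cohorts) is reported once per pattern
  flag <- which(male_sp | female_sp)
  sites <- data.frame(
    chrom = tab$sites$chrom[flag], pos = tab$sites$pos[flag],
    pattern = ifelse(male_sp[flag], "male_specific_het",
                     "female_specific_het"),
    n_males_not_het = m_not_het[flag], n_females_het = f_het[flag],
    n_females_not_het = f_not_het[flag], n_males_het = m_het[flag],
    stringsAsFactors = FALSE)
  hist <- if (nrow(sites)) {
    h <- as.data.table(sites)[, .N, by = .(
      chrom, start = floor((pos - 1) / bin_bp) * bin_bp, pattern)]
    setorder(h, chrom, start)
    data.frame(chrom = h$chrom, start = h$start, end = h$start + bin_bp,
               pattern = h$pattern, n = h$N, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               pattern = character(), n = integer())
  }
  list(sites = sites, histogram = hist)
}

#' DAPC-based screen for sex-linked candidate sites
#'
#' Runs [prefilter_sex_sites()], then DAPC with sex as the group, then
#' [snpzip_select()] on the first discriminant axis; candidate sites are
#' the structural set intersected with the [exact_pattern_scan()] hits.
#'
#' @param tab a [genotype_table()] restricted to one population/group.
#' @param sexes optional named vector sample -> sex (default: sheet).
#' @param n_pc retained PCs (default 10; sex screens run within small
#'   groups).
#' @param tolerance passed to [exact_pattern_scan()].
#' @return list(`candidates` = data.frame(chrom, pos, pattern, loading),
#'   `model` = the `dapc_model`, `pattern_hits`, `structural_n`).
#' @export
sex_dapc_screen <- function(tab, sexes = NULL, n_pc = 10, tolerance = 0) {
  sexes <- sexes %||% setNames(tab$sheet$sex, tab$sheet$sample)
  keep <- names(sexes)[sexes %in% c("male", "female")]
  tab2 <- prefilter_sex_sites(tab, keep)
  model <- suppressWarnings(
    dapc(tab2, sexes[tab2$samples], n_pc = n_pc, n_df = 1))
  ld <- model$loadings[, 1]
  struct_idx <- model$kept_sites[snpzip_select(ld)]
  scan <- exact_pattern_scan(tab2, sexes, tolerance = tolerance)
  key_struct <- paste0(tab2$sites$chrom[struct_idx], ":",
                       tab2$sites$pos[struct_idx])
  key_scan <- paste0(scan$sites$chrom, ":", scan$sites$pos)
  common <- intersect(key_struct, key_scan)
  i_scan <- match(common, key_scan)
  loading_by_key <- setNames(ld[match(struct_idx, model$kept_sites)],
                             key_struct)
  candidates <- data.frame(
    chrom = scan$sites$chrom[i_scan], pos = scan$sites$pos[i_scan],
    pattern = scan$sites$pattern[i_scan],
    loading = as.numeric(loading_by_key[common]),
    stringsAsFactors = FALSE)
  list(candidates = candidates, model = model, pattern_hits = scan$sites,
       structural_n = length(struct_idx))
}

#' Coverage-ratio presence/absence genotyping
#'
#' For each sample, the mean depth on a target region (e.g. the
#' male-limited *amhby*-like scaffold) is divided by the mean depth on a
#' control region (e.g. the longest autosome) and thresholded:
#' `present` if ratio >= `present_min` (hemizygous carriers are expected
#' near 0.5), `absent` if ratio <= `absent_max`, else `ambiguous`. The
#' thresholds are package defaults; the emulated study reports only "a
#' clear difference in coverage".
#'
#' @param depth data.frame(sample, region, mean_depth).
#' @param target,control region names.
#' @param present_min,absent_max call thresholds (defaults 0.25 / 0.05).
#' @return data.frame(sample, target_depth, control_depth, ratio, call).
#' @export
coverage_ratio_genotype <- function(depth, target, control,
                                    present_min = 0.25, absent_max = 0.05) {
  d <- as.data.table(depth)
  need <- c("sample", "region", "mean_depth")
  if (!all(need %in% names(d)))
    stopf("depth table needs columns %s", paste(need, collapse = ", "))
  wide <- merge(d[region == target, .(sample, target_depth = mean_depth)],
                d[region == control, .(sample, control_depth = mean_depth)],
                by = "sample", all = TRUE)
  if (anyNA(wide$control_depth) || any(wide$control_depth <= 0)) {
    bad <- wide$sample[is.na(wide$control_depth) | wide$control_depth <= 0]
    stopf("zero or missing control depth for sample(s): %s",
          paste(bad, collapse = ", "))
  }
  wide[is.na(target_depth), target_depth := 0]
  wide[, ratio := target_depth / control_depth]
  wide[, call := ifelse(ratio >= present_min, "present",
                        ifelse(ratio <= absent_max, "absent", "ambiguous"))]
  as.data.frame(wide)
}
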