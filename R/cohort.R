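## Synthetic multi-population diploid cohort
##
## The generator states a simple world the downstream statistics assume:
## biallelic SNP sites placed uniformly along the reference; per-site
## ancestral frequency q ~ U(0,1) shared across populations; each
## population's frequency drawn from the Balding-Nichols drift model,
## p_pop ~ Beta(m(1-F)/F, (1-m)(1-F)/F) with mean m = s_pop * q, so that
## populations diverge with the stated F_ST (strong drift produces
## population-private and fixed alleles, as observed in post-glacial pike).
## The shrinkage factor s_pop is solved from the requested per-site
## expected heterozygosity theta via E[2p(1-p)] = (1-F)(s - (2/3)s^2)
## under q ~ U(0,1), so realized per-population heterozygosity has an
## exact expectation. Genotypes are drawn Hardy-Weinberg within
## populations and site-independently (no linkage). Private sites have a
## nonzero frequency parameter in exactly one population. GATK-style INFO
## annotations are synthesized with stated per-criterion failure fractions
## so the filter cascade's per-step report is checkable against plants.

# default per-criterion deliberate-failure fractions; the defaults reproduce
# the per-step removal fractions of the published 47-sample filter report
# (hard-filter criteria calibrated so (1-f)^5 ~ 0.872)
default_fail_fractions <- function() {
  c(qd = 0.027, fs = 0.027, mq = 0.027, mqranksum = 0.027,
    readposranksum = 0.027, qual = 0.0019, depth_low = 0.028,
    depth_high = 0.0013, high_missing = 0.019)
}

#' Specify a synthetic cohort
#'
#' @param populations data.frame with columns `name`, `n_males`,
#'   `n_females` (unknown-sex individuals are not simulated).
#' @param theta named numeric, per-population expected per-site
#'   heterozygosity (probability that a genotype at a segregating site is
#'   heterozygous). Must be in (0, 0.375 * (1 - fst)]; the upper bound is
#'   the maximum achievable under the uniform-ancestral-frequency
#'   Balding-Nichols model.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_sites total SNP site count; default `round(0.00145 * genome
#'   length)`, the raw SNP density of the published pike cohort
#'   (1,363,731 SNPs over 940.8 Mbp).
#' @param private_allele_rate fraction of sites whose alternate allele is
#'   restricted to one population (default 0.15).
#' @param missing_rate per-genotype missing probability (default 0.01).
#' @param indel_fraction fraction of sites emitted as 2-bp indels rather
#'   than SNPs (default 0), for exercising SNP selection.
#' @param mean_depth,depth_sd per-sample mean sequencing depth and its
#'   between-sample SD (defaults 20 and 3.3, the published cohort's values).
#' @param fail_fractions named numeric of per-criterion deliberate failure
#'   fractions for `qd`, `fs`, `mq`, `mqranksum`, `readposranksum`, `qual`,
#'   `depth_low`, `depth_high`, `high_missing`; see
#'   `pikescan:::default_fail_fractions()`.
#' @param annot_missing_rate fraction of sites whose rank-sum INFO
#'   annotations are absent (default 0.01; missing annotations pass the
#'   hard filter, as in GATK).
#' @param fst Balding-Nichols drift parameter (default 0.25, matching the
#'   strong founder-effect differentiation of post-glacial pike
#'   populations); 0 gives identical frequencies across populations.
#' @param seed integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(populations, theta, chrom_lengths, n_sites = NULL,
                        private_allele_rate = 0.15, missing_rate = 0.01,
                        indel_fraction = 0, mean_depth = 20, depth_sd = 3.3,
                        fail_fractions = default_fail_fractions(),
                        annot_missing_rate = 0.01, fst = 0.25,
                        seed = 1) {
  populations <- as.data.frame(populations)
  if (!all(c("name", "n_males", "n_females") %in% names(populations)))
    stopf("populations needs columns name, n_males, n_females")
  if (anyDuplicated(populations$name)) stopf("population names must be unique")
  chrom_lengths <- normalize_chrom_lengths(chrom_lengths)
  if (!all(populations$name %in% names(theta)))
    stopf("theta must be named for every population")
  if (fst < 0 || fst >= 1) stopf("fst must be in [0, 1)")
  th <- theta[populations$name]
  th_max <- 0.375 * (1 - fst)
  if (any(th <= 0 | th > th_max))
    stopf(paste("theta implies expected heterozygosity outside (0, %.3f];",
                "the uniform-frequency Balding-Nichols model cannot",
                "exceed 3/8 * (1 - fst) per site"), th_max)
  rates <- c(private_allele_rate, missing_rate, indel_fraction,
             annot_missing_rate, fail_fractions)
  if (any(rates < 0 | rates > 1)) stopf("all rates must lie in [0, 1]")
  ff <- default_fail_fractions()
  ff[names(fail_fractions)] <- fail_fractions
  if (is.null(n_sites)) n_sites <- round(0.00145 * sum(chrom_lengths))
  structure(list(populations = populations, theta = th,
                 chrom_lengths = chrom_lengths, n_sites = as.integer(n_sites),
                 private_allele_rate = private_allele_rate,
                 missing_rate = missing_rate, indel_fraction = indel_fraction,
                 mean_depth = mean_depth, depth_sd = depth_sd,
                 fail_fractions = ff, annot_missing_rate = annot_missing_rate,
                 fst = fst, seed = as.integer(seed)),
            class = "cohort_spec")
}

# shrinkage factor s solving (1-F)(s - (2/3)s^2) = theta for the
# Balding-Nichols mean m = s*q, q ~ U(0,1)
theta_shrinkage <- function(theta, fst = 0) {
  0.75 * (1 - sqrt(1 - 8 * theta / (3 * (1 - fst))))
}

# Balding-Nichols draw: p ~ Beta(m(1-F)/F, (1-m)(1-F)/F), mean m; F = 0
# degenerates to p = m
rbalding_nichols <- function(m, fst) {
  if (fst == 0) return(m)
  lambda <- (1 - fst) / fst
  p <- stats::rbeta(length(m), m * lambda, (1 - m) * lambda)
  # rbeta returns NaN when both shapes are 0 (m exactly 0 or 1)
  p[m == 0] <- 0
  p[m == 1] <- 1
  p
}

#' Simulate a multi-population diploid cohort VCF with planted truth
#'
#' Places biallelic sites uniformly on `reference`, draws per-population
#' allele frequencies under the drift-shrinkage model of [cohort_spec()],
#' draws genotypes under Hardy-Weinberg, synthesizes GATK-style INFO
#' annotations with stated deliberate-failure fractions, and records every
#' generative decision in a truth set.
#'
#' @param spec a [cohort_spec()].
#' @param reference a `DNAStringSet` covering `spec$chrom_lengths`.
#' @return A list of class `pike_cohort` with elements `vcf` ([pike_vcf]),
#'   `sheet` (sample sheet), and `truth` (see [write_truth()]).
#' @export
simulate_cohort <- function(spec, reference) {
  stopifnot(inherits(spec, "cohort_spec"))
  idx <- reference_index(reference)
  if (!all(names(spec$chrom_lengths) %in% idx$chrom))
    stopf("reference lacks chromosomes named in the spec")
  pops <- spec$populations
  sheet <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    p <- pops[i, ]
    n <- p$n_males + p$n_females
    sample_sheet(sprintf("%s_%02d", p$name, seq_len(n)), rep(p$name, n),
                 c(rep("male", p$n_males), rep("female", p$n_females)))
  }))
  n_samp <- nrow(sheet)
  ns <- spec$n_sites
  cl <- spec$chrom_lengths
  with_seed(spec$seed, {
    ## site placement, uniform over the genome, unique within chromosome
    n_per_chrom <- as.vector(stats::rmultinom(1, ns, cl / sum(cl)))
    sites <- rbindlist(lapply(seq_along(cl), function(i) {
      data.table(chrom = names(cl)[i],
                 pos = sort(sample.int(cl[i], n_per_chrom[i])))
    }))
    ref_base <- ref_bases_at(reference, sites$chrom, sites$pos)
    alt_base <- random_alt_base(ref_base)
    ## indels: mutate a fraction into 2-bp ref or alt records
    is_indel <- runif(ns) < spec$indel_fraction
    if (any(is_indel)) {
      nxt <- ref_bases_at(reference, sites$chrom[is_indel],
                          pmin(sites$pos[is_indel] + 1,
                               cl[sites$chrom[is_indel]]))
      del <- runif(sum(is_indel)) < 0.5
      ref_base[is_indel][del] <- paste0(ref_base[is_indel][del], nxt[del])
      alt_base[is_indel][!del] <-
        paste0(ref_base[is_indel][!del], alt_base[is_indel][!del])
    }
    ## site classification
    cls <- rep("neutral", ns)
    priv <- runif(ns) < spec$private_allele_rate
    priv_pop <- sample(pops$name, ns, replace = TRUE)
    cls[priv] <- paste0("private:", priv_pop[priv])
    cls[is_indel] <- "indel"
    ## per-population frequencies (Balding-Nichols drift around s_pop * q)
    q <- runif(ns)
    s_pop <- theta_shrinkage(spec$theta, spec$fst)
    pmat <- vapply(pops$name, function(pn) {
      p <- rbalding_nichols(s_pop[[pn]] * q, spec$fst)
      p[priv & priv_pop != pn & !is_indel] <- 0
      p
    }, numeric(ns))
    ## genotypes, Hardy-Weinberg per population
    gt <- matrix("0/0", ns, n_samp, dimnames = list(NULL, sheet$sample))
    for (j in seq_len(n_samp)) {
      d <- rbinom(ns, 2, pmat[, sheet$population[j]])
      gt[, j] <- c("0/0", "0/1", "1/1")[d + 1]
    }
    ## missingness: background plus planted high-missing sites
    if (spec$missing_rate > 0)
      gt[runif(length(gt)) < spec$missing_rate] <- "./."
    ff <- spec$fail_fractions
    hm <- runif(ns) < ff[["high_missing"]]
    hm_n <- min(11L, n_samp - 1L) # >10 missing when the cohort allows it
    for (i in which(hm)) gt[i, sample.int(n_samp, hm_n)] <- "./."
    ## depths
    samp_mu <- pmax(rnorm(n_samp, spec$mean_depth, spec$depth_sd), 5)
    dp <- vapply(seq_len(n_samp),
                 function(j) rpois(ns, samp_mu[j]), integer(ns))
    fail_dlo <- runif(ns) < ff[["depth_low"]]
    fail_dhi <- !fail_dlo & runif(ns) < ff[["depth_high"]]
    if (any(fail_dlo))
      dp[fail_dlo, ] <- rpois(sum(fail_dlo) * n_samp, runif(sum(fail_dlo), 2, 8))
    if (any(fail_dhi))
      dp[fail_dhi, ] <- rpois(sum(fail_dhi) * n_samp, runif(sum(fail_dhi), 65, 95))
    dimnames(dp) <- list(NULL, sheet$sample)
    dp[gt == "./."] <- NA_integer_
    ## INFO annotations with planted failures
    fail <- data.table(
      qd = runif(ns) < ff[["qd"]], fs = runif(ns) < ff[["fs"]],
      mq = runif(ns) < ff[["mq"]], mqranksum = runif(ns) < ff[["mqranksum"]],
      readposranksum = runif(ns) < ff[["readposranksum"]],
      qual = runif(ns) < ff[["qual"]],
      depth_low = fail_dlo, depth_high = fail_dhi, high_missing = hm)
    draw <- function(failv, pass_fun, fail_fun) {
      x <- pass_fun(ns)
      x[failv] <- fail_fun(sum(failv))
      x
    }
    sites[, `:=`(
      id = sprintf("site%06d", seq_len(ns)),
      ref = ref_base, alt = alt_base,
      qual = draw(fail$qual, function(n) runif(n, 30, 2000),
                  function(n) runif(n, 1, 19.5)),
      QD = draw(fail$qd, function(n) runif(n, 5, 35),
                function(n) runif(n, 0.05, 1.95)),
      FS = draw(fail$fs, function(n) runif(n, 0, 30),
                function(n) runif(n, 60.5, 200)),
      MQ = draw(fail$mq, function(n) runif(n, 40, 60),
                function(n) runif(n, 5, 29.5)),
      MQRankSum = draw(fail$mqranksum, function(n) rnorm(n, 0, 2),
                       function(n) runif(n, -30, -12.6)),
      ReadPosRankSum = draw(fail$readposranksum, function(n) rnorm(n, 0, 2),
                            function(n) runif(n, -20, -8.1)))]
    if (spec$annot_missing_rate > 0) {
      am <- runif(ns) < spec$annot_missing_rate
      sites[am, `:=`(MQRankSum = NA_real_, ReadPosRankSum = NA_real_)]
    }
  })
  ## expected per-individual heterozygous-genotype count (truth); indel
  ## sites are genotyped under the same frequency model, so they count.
  ## Computed over ATTEMPTED sites: sites realized without any alternate
  ## allele are dropped below, but they contribute zero heterozygotes, so
  ## the expectation is unchanged.
  n_shared <- sum(cls %in% c("neutral", "indel"))
  exp_het <- vapply(pops$name, function(pn) {
    n_rel <- n_shared + sum(cls == paste0("private:", pn))
    n_rel * spec$theta[[pn]] * (1 - spec$missing_rate)
  }, 0)
  ## caller semantics: only sites with an observed alternate allele are
  ## emitted (a genotyper never reports a site without variant evidence)
  alt_copies <- rowSums(gt_dosage(gt), na.rm = TRUE)
  keep <- which(alt_copies > 0)
  sites <- sites[keep]
  gt <- gt[keep, , drop = FALSE]
  dp <- dp[keep, , drop = FALSE]
  cls <- cls[keep]
  fail <- fail[keep]
  pmat <- pmat[keep, , drop = FALSE]
  site_key <- paste0(sites$chrom, ":", sites$pos)
  fail[, site := site_key]
  freq <- data.table(site = site_key)
  for (pn in pops$name) freq[[pn]] <- pmat[, pn]
  truth <- structure(list(
    true_sex = setNames(sheet$sex, sheet$sample),
    site_class = setNames(cls, site_key),
    expected_het = exp_het,
    theta = spec$theta,
    freq = freq,
    planted_fail = fail,
    sex_region = NULL, carriers = character(), insert = NULL,
    seed = spec$seed), class = "truth_set")
  structure(list(vcf = pike_vcf(sites, gt, dp), sheet = sheet, truth = truth,
                 spec = spec), class = "pike_cohort")
}

#' @export
print.pike_cohort <- function(x, ...) {
  cat(sprintf("pike_cohort: %d sites, %d samples, %d population(s)%s\n",
              nrow(x$vcf$sites), nrow(x$sheet),
              length(unique(x$sheet$population)),
              if (!is.null(x$truth$sex_region)) ", sex region planted" else ""))
  invisible(x)
}

# reference bases at (chrom, pos), returned as characters
ref_bases_at <- function(reference, chrom, pos) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    v <- Biostrings::extractAt(reference[[cn]],
                               IRanges::IRanges(pos[i], width = 1))
    out[i] <- as.character(v)
  }
  out
}

# a random base different from ref
random_alt_base <- function(ref_base) {
  bases <- c("A", "C", "G", "T")
  vapply(ref_base, function(b) sample(setdiff(bases, b), 1), "",
         USE.NAMES = FALSE)
}
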