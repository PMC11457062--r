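# shared fixtures, built in code; expensive objects are cached for the
# whole test session in `.fixture_cache`

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a genotype table built directly from a zygosity-code matrix
# (0 hom_ref / 1 het / 2 hom_alt / NA missing), one chromosome
make_tab <- function(zyg, pops, sexes = NULL, chrom = "chr1",
                     pos = NULL, ref = "A", alt = "T") {
  n_sites <- nrow(zyg)
  n_samp <- ncol(zyg)
  ids <- sprintf("s%02d", seq_len(n_samp))
  gt <- matrix(c("0/0", "0/1", "1/1")[zyg + 1], n_sites, n_samp)
  gt[is.na(gt)] <- "./."
  colnames(gt) <- ids
  if (is.null(pos)) pos <- seq_len(n_sites) * 10
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = ref, alt = alt, qual = 100)
  sheet <- sample_sheet(ids, pops, sexes %||% rep("unknown", n_samp))
  genotype_table(pike_vcf(sites, gt), sheet)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small reference genome shared across synth tests
small_reference <- function() {
  cached("small_ref", simulate_reference(c(chr1 = 50000, chr2 = 20000),
                                         seed = 11))
}

# small two-population cohort with planted sex region, no missing data
small_cohort <- function() {
  cached("small_cohort", {
    ref <- small_reference()
    pops <- data.frame(name = c("A", "B"), n_males = c(5L, 3L),
                       n_females = c(5L, 3L))
    spec <- cohort_spec(pops, c(A = 0.16, B = 0.05),
                        c(chr1 = 50000, chr2 = 20000), n_sites = 2000,
                        private_allele_rate = 0.15, missing_rate = 0,
                        indel_fraction = 0.1,
                        fail_fractions = c(high_missing = 0), seed = 101)
    co <- simulate_cohort(spec, ref)
    reg <- sex_region_spec("chr1", 10000, 30000, 50,
                           insert_length = 2000,
                           carrier_populations = "A")
    plant_sex_region(co, reg, ref, seed = 202)
  })
}

# hand-written 20-site filter fixture: 12 samples, one designed failure
# per site (or a designed pass); expected per-step tallies in
# filter_fixture_expected()
filter_fixture <- function() {
  n <- 12L
  ids <- sprintf("s%02d", 1:n)
  base_gt <- function(pattern) {
    # pattern: character vector length 12 of "R","H","A","."
    c(R = "0/0", H = "0/1", A = "1/1", "." = "./.")[pattern]
  }
  mixed <- rep(c("R", "H", "A"), 4)          # 4 hom-ref, 4 het, 4 hom-alt
  rows <- list(
    # 1-5: one hard-filter failure each (values at/over the boundary)
    list(QD = 1.9,  gt = mixed),                      # QD < 2
    list(FS = 60.1, gt = mixed),                      # FS > 60
    list(MQ = 29.9, gt = mixed),                      # MQ < 30
    list(MQRankSum = -12.6, gt = mixed),              # MQRankSum < -12.5
    list(ReadPosRankSum = -8.1, gt = mixed),          # ReadPosRankSum < -8
    # 6: boundary passes (QD exactly 2, FS exactly 60, MQ exactly 30)
    list(QD = 2, FS = 60, MQ = 30, MQRankSum = -12.5,
         ReadPosRankSum = -8, gt = mixed),
    # 7: all INFO annotations absent -> passes the hard filter
    list(QD = NA, FS = NA, MQ = NA, MQRankSum = NA, ReadPosRankSum = NA,
         gt = mixed),
    # 8: QUAL below 20
    list(qual = 19.9, gt = mixed),
    # 9: low mean depth; 10: high mean depth
    list(dp = 5L, gt = mixed),
    list(dp = 61L, gt = mixed),
    # 11: 11 missing genotypes (> 10)
    list(gt = c(rep(".", 11), "R")),
    # 12: exactly 10 missing -> passes
    list(gt = c(rep(".", 10), "R", "H")),
    # 13: monomorphic (mac 0)
    list(gt = rep("R", 12)),
    # 14: singleton het (mac 1) -> passes
    list(gt = c("H", rep("R", 11))),
    # 15: all het -> removed by the <100% heterozygous rule
    list(gt = rep("H", 12)),
    # 16: all het but one missing -> still all-het among called, removed
    list(gt = c(rep("H", 11), ".")),
    # 17: 2-bp insertion (removed at the SNP step)
    list(ref = "A", alt = "AT", gt = mixed),
    # 18: 2-bp deletion
    list(ref = "AT", alt = "A", gt = mixed),
    # 19: multiallelic SNP, retained throughout
    list(alt = "T,G", gt = c("R", "R", "H", "A", mixed[1:8])),
    # 20: clean passing site
    list(gt = mixed))
  sites <- data.frame(chrom = "chr1", pos = seq_len(20) * 100,
                      ref = "A", alt = "T", qual = 100,
                      QD = 20, FS = 5, MQ = 50, MQRankSum = 0,
                      ReadPosRankSum = 0)
  gt <- matrix("0/0", 20, n, dimnames = list(NULL, ids))
  dp <- matrix(20L, 20, n, dimnames = list(NULL, ids))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    for (f in intersect(names(r), names(sites))) sites[i, f] <- r[[f]]
    gt[i, ] <- base_gt(r$gt)
    if (!is.null(r$dp)) dp[i, ] <- r$dp
  }
  # site 19 multiallelic: give one sample a 1/2 genotype
  gt[19, 4] <- "1/2"
  dp[gt == "./."] <- NA_integer_
  pike_vcf(sites, gt, dp)
}

# hand tally for the fixture above, following the printed cascade order
filter_fixture_expected <- function() {
  data.frame(
    step = c("Raw genotypes (includes indels)", "SNP variants only",
             "GATK-style hard filter", "Min. quality", "Min. mean depth",
             "Max. mean depth", "Max. missing count", "Minor allele count",
             "Per locus heterozygous genotypes"),
    n_retained = c(20L,  # all
                   18L,  # drop 17, 18 (indels)
                   13L,  # drop 1-5
                   12L,  # drop 8
                   11L,  # drop 9
                   10L,  # drop 10
                   9L,   # drop 11
                   8L,   # drop 13
                   6L))  # drop 15, 16
}

# cohort at the heterozygosity-expectation contract scale (>= 50k sites,
# >= 5 diploids per population)
big_cohort <- function() {
  cached("big_cohort", {
    ref <- simulate_reference(c(chrA = 2e6), seed = 12)
    pops <- data.frame(name = c("A", "B"), n_males = 3L, n_females = 3L)
    spec <- cohort_spec(pops, c(A = 0.16, B = 0.05), c(chrA = 2e6),
                        n_sites = 50000, private_allele_rate = 0.15,
                        missing_rate = 0, indel_fraction = 0.05,
                        fail_fractions = c(high_missing = 0), seed = 303)
    simulate_cohort(spec, ref)
  })
}

# full-scale demo run (the acceptance world: 10-Mbp genome, 5M/5F
# carriers, 100 planted male-linked SNPs, error-free 15x reads); executed
# once per session and reused by the acceptance criteria
acceptance_demo <- function() {
  cached("acceptance_demo", {
    t0 <- Sys.time()
    res <- run_demo(demo_config(out_dir = tempfile("pikescan_acc_"),
                                seed = 20240808))
    res$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  })
}

# three-population cohort with private alleles (genotypes only), used for
# DAPC assignment tests
three_pop_cohort <- function() {
  cached("three_pop", {
    ref <- small_reference()
    pops <- data.frame(name = c("P1", "P2", "P3"), n_males = c(3L, 3L, 3L),
                       n_females = c(3L, 3L, 3L))
    spec <- cohort_spec(pops, c(P1 = 0.16, P2 = 0.10, P3 = 0.05),
                        c(chr1 = 50000, chr2 = 20000), n_sites = 3000,
                        private_allele_rate = 0.3, missing_rate = 0.01,
                        seed = 77)
    simulate_cohort(spec, ref)
  })
}
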