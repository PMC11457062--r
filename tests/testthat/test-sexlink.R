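# sex-linked-region detectors

test_that("count_kmers: manual enumeration, canonical symmetry, N handling", {
  # 12-bp read, k = 5: 8 windows; canonical forms collapse to
  # {ACGTA x4, CGTAC x4} (worked out by hand)
  kc <- count_kmers(list(s = "ACGTACGTACGT"), k = 5)
  expect_identical(kc$counts$kmer, c("ACGTA", "CGTAC"))
  expect_identical(kc$counts$s, c(4L, 4L))
  # a read and its reverse complement give identical count sets
  r <- "AACCGGTTACGATCGA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  k1 <- count_kmers(list(a = r), k = 7)$counts
  k2 <- count_kmers(list(a = rc), k = 7)$counts
  expect_identical(k1, k2)
  # windows containing non-ACGT bases are skipped
  kn <- count_kmers(list(a = "ACGTNACGT"), k = 5)
  expect_equal(nrow(kn$counts), 0)
  kn2 <- count_kmers(list(a = "ACGTTNACGTT"), k = 5)
  expect_equal(sum(kn2$counts$a), 2) # one window each side of the N
  expect_error(count_kmers(list(a = "ACGT"), k = 4), "odd")
  expect_warning(count_kmers(list(a = character(0)), k = 5), "empty")
})

test_that("sex_specific_kmers matches the published thresholds and bounds", {
  sheet <- sample_sheet(sprintf("s%d", 1:6), rep("P", 6),
                        c("male", "male", "male",
                          "female", "female", "female"))
  mk_counts <- function(m, f) {
    structure(list(k = 31, counts = data.table::data.table(
      kmer = "K", s1 = m[1], s2 = m[2], s3 = m[3],
      s4 = f[1], s5 = f[2], s6 = f[3]), samples = sheet$sample),
      class = "kmer_count_set")
  }
  # published worked case: males (3,3,3) sum 9, females (0,1,2) -> retained
  expect_length(sex_specific_kmers(mk_counts(c(3, 3, 3), c(0, 1, 2)),
                                   sheet, "P"), 1)
  # sum exactly 7 -> rejected ("more than 7" is strict)
  expect_length(sex_specific_kmers(mk_counts(c(3, 3, 1), c(0, 0, 0)),
                                   sheet, "P"), 0)
  expect_length(sex_specific_kmers(mk_counts(c(3, 3, 2), c(0, 0, 0)),
                                   sheet, "P"), 1)
  # a female with 3 copies -> rejected; a male with 0 -> rejected
  expect_length(sex_specific_kmers(mk_counts(c(5, 5, 5), c(3, 0, 0)),
                                   sheet, "P"), 0)
  expect_length(sex_specific_kmers(mk_counts(c(9, 9, 0), c(0, 0, 0)),
                                   sheet, "P"), 0)
  # < 3 per sex is rejected by the inclusion criterion
  sheet2 <- sample_sheet(sprintf("s%d", 1:6), rep("P", 6),
                         c("male", "male", "male", "male", "male", "female"))
  expect_error(sex_specific_kmers(mk_counts(c(1, 1, 1), c(1, 1, 1)),
                                  sheet2, "P"), "3 samples per sex")
})

test_that("exhaustive count grid equals brute-force predicate evaluation", {
  grid <- as.matrix(expand.grid(m1 = 0:4, m2 = 0:4, m3 = 0:4,
                                f1 = 0:4, f2 = 0:4, f3 = 0:4))
  fake_kmers <- sprintf("K%05d", seq_len(nrow(grid)))
  counts <- structure(list(
    k = 31,
    counts = data.table::data.table(
      kmer = fake_kmers, s1 = grid[, 1], s2 = grid[, 2], s3 = grid[, 3],
      s4 = grid[, 4], s5 = grid[, 5], s6 = grid[, 6]),
    samples = sprintf("s%d", 1:6)), class = "kmer_count_set")
  sheet <- sample_sheet(sprintf("s%d", 1:6), rep("P", 6),
                        c("male", "male", "male",
                          "female", "female", "female"))
  got <- sex_specific_kmers(counts, sheet, "P")
  rule <- sex_kmer_rule()
  brute <- fake_kmers[vapply(seq_len(nrow(grid)), function(i) {
    m <- grid[i, 1:3]
    f <- grid[i, 4:6]
    all(f <= rule$opposite_max) && all(m >= rule$target_min) &&
      sum(m) > rule$target_sum_min_exclusive
  }, TRUE)]
  expect_identical(as.character(got), brute)
})

test_that("rule monotonicity: relaxing thresholds never shrinks the set", {
  set.seed(44)
  n <- 500
  counts <- structure(list(
    k = 31,
    counts = data.table::data.table(
      kmer = sprintf("K%04d", 1:n),
      s1 = rpois(n, 3), s2 = rpois(n, 3), s3 = rpois(n, 3),
      s4 = rpois(n, 1), s5 = rpois(n, 1), s6 = rpois(n, 1)),
    samples = sprintf("s%d", 1:6)), class = "kmer_count_set")
  sheet <- sample_sheet(sprintf("s%d", 1:6), rep("P", 6),
                        c("male", "male", "male",
                          "female", "female", "female"))
  base <- sex_specific_kmers(counts, sheet, "P")
  looser_opp <- sex_specific_kmers(counts, sheet, "P",
                                   rule = sex_kmer_rule(opposite_max = 4))
  expect_true(all(base %in% looser_opp))
  stricter_min <- sex_specific_kmers(counts, sheet, "P",
                                     rule = sex_kmer_rule(target_min = 3))
  expect_true(all(stricter_min %in% base))
})

test_that("streaming scan equals table-based scan on small read sets", {
  co <- small_cohort()
  ref <- small_reference()
  pop_a <- co$sheet$sample[co$sheet$population == "A"]
  reads <- lapply(setNames(nm = pop_a), function(sm)
    pikescan:::sample_reads_for_individual(co, ref, sm, coverage_x = 6,
                                           read_len = 100,
                                           error_rate = 0, seed = 19))
  counts <- count_kmers(reads, k = 31)
  sheet_a <- co$sheet[co$sheet$population == "A", ]
  tabled <- sex_specific_kmers(counts, sheet_a, "A", "male")
  streamed <- sex_specific_kmers_stream(function(sm) reads[[sm]],
                                        sheet_a, "A", "male", k = 31)
  expect_identical(sort(as.character(tabled)),
                   sort(as.character(streamed)))
  expect_gt(length(streamed), 0)
})

test_that("map_kmers_to_genome: exact hits, strand, unmapped, one mismatch", {
  ref <- small_reference()
  chr1 <- as.character(ref[[1]])
  km_fwd <- substr(chr1, 101, 131)
  km_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr1, 501, 531))))
  absent <- strrep("AT", 16)
  absent <- substr(absent, 1, 31)
  res <- map_kmers_to_genome(c(km_fwd, km_rev, absent), ref)
  h <- res$hits
  expect_true(any(h$kmer == km_fwd & h$chrom == "chr1" & h$pos == 101 &
                    h$strand == "+"))
  expect_true(any(h$kmer == km_rev & h$chrom == "chr1" & h$pos == 501 &
                    h$strand == "-"))
  expect_true(absent %in% res$unmapped)
  # one substitution breaks the exact match but maps with max_mismatch = 1
  km_mut <- km_fwd
  substr(km_mut, 16, 16) <- setdiff(c("A", "C", "G", "T"),
                                    substr(km_fwd, 16, 16))[1]
  res0 <- map_kmers_to_genome(km_mut, ref, max_mismatch = 0)
  expect_true(km_mut %in% res0$unmapped)
  res1 <- map_kmers_to_genome(km_mut, ref, max_mismatch = 1)
  expect_true(any(res1$hits$kmer == km_mut & res1$hits$pos == 101))
})

test_that("kmer_window_density conserves hits and locates the signal", {
  hits <- data.table::data.table(
    kmer = sprintf("K%d", 1:5), chrom = "chr1",
    pos = c(100, 5000, 9999, 10001, 15000), strand = "+")
  w <- make_windows(c(chr1 = 50000, chr2 = 20000), 1e4)
  kd <- kmer_window_density(hits, w)
  expect_equal(sum(kd$n_kmers), 5)
  expect_equal(kd$n_kmers[kd$chrom == "chr1"][1:2], c(3L, 2L))
  expect_true(all(kd$n_kmers[kd$chrom == "chr2"] == 0))
})

test_that("prefilter_sex_sites drops hom-alt sites (or masks genotypes)", {
  z <- rbind(c(0, 1, 2),   # hom-alt present -> dropped
             c(0, 1, 1),   # kept
             c(0, 0, 0),   # kept
             c(NA, 2, 1))  # dropped
  tab <- make_tab(z, pops = rep("P", 3),
                  sexes = c("male", "male", "female"))
  red <- prefilter_sex_sites(tab)
  expect_equal(nrow(red$sites), 2)
  # brute-force oracle over a random fixture
  set.seed(3)
  z2 <- matrix(sample(c(0:2, NA), 90, replace = TRUE), 30, 3)
  tab2 <- make_tab(z2, pops = rep("P", 3),
                   sexes = c("male", "female", "female"))
  red2 <- prefilter_sex_sites(tab2)
  keep <- vapply(seq_len(30), function(i)
    !any(z2[i, ] == 2, na.rm = TRUE), TRUE)
  expect_equal(nrow(red2$sites), sum(keep))
  masked <- prefilter_sex_sites(tab2, mode = "mask")
  expect_equal(nrow(masked$sites), 30)
  expect_false(any(masked$zyg == 2, na.rm = TRUE))
  expect_error(prefilter_sex_sites(tab, character(0)), "empty")
})

test_that("exact_pattern_scan patterns, tolerance, and histogram", {
  sexes <- c(rep("male", 5), rep("female", 5))
  z_male_sp <- matrix(c(rep(1, 5), rep(0, 5)), 1)
  tab <- make_tab(z_male_sp, pops = rep("P", 10), sexes = sexes)
  res <- exact_pattern_scan(tab)
  expect_equal(res$sites$pattern, "male_specific_het")
  # 4/5 males het: tolerance 0 not flagged, tolerance 1 flagged
  z_45 <- matrix(c(1, 1, 1, 1, 0, rep(0, 5)), 1)
  tab45 <- make_tab(z_45, pops = rep("P", 10), sexes = sexes)
  expect_equal(nrow(exact_pattern_scan(tab45, tolerance = 0)$sites), 0)
  expect_equal(exact_pattern_scan(tab45, tolerance = 1)$sites$pattern,
               "male_specific_het")
  # female-specific symmetry; missing calls are excluded from tallies
  z_f <- matrix(c(rep(0, 4), NA, rep(1, 5)), 1)
  tabf <- make_tab(z_f, pops = rep("P", 10), sexes = sexes)
  expect_equal(exact_pattern_scan(tabf)$sites$pattern, "female_specific_het")
  # histogram bins per chromosome
  z2 <- matrix(rep(c(rep(1, 5), rep(0, 5)), 3), nrow = 3, byrow = TRUE)
  tab2 <- make_tab(z2, pops = rep("P", 10), sexes = sexes,
                   pos = c(100, 200, 150100))
  h <- exact_pattern_scan(tab2)$histogram
  expect_equal(h$n, c(2L, 1L))
  expect_equal(h$start, c(0, 100000))
  expect_error(exact_pattern_scan(
    make_tab(z_male_sp, pops = rep("P", 10),
             sexes = rep("male", 10))), "each sex")
})

test_that("planted male-linked sites are recovered exactly at tolerance 0", {
  co <- small_cohort()
  tab <- genotype_table(co$vcf, co$sheet)
  tab_a <- pikescan:::gtab_subset(
    tab, samples = co$sheet$sample[co$sheet$population == "A"])
  res <- exact_pattern_scan(tab_a, tolerance = 0)
  keys <- paste0(res$sites$chrom, ":", res$sites$pos)
  planted <- names(co$truth$site_class)[
    co$truth$site_class == "male_linked"]
  expect_true(all(planted %in%
                    keys[res$sites$pattern == "male_specific_het"]))
})

test_that("false positives on a null cohort stay near the HWE expectation", {
  ref <- small_reference()
  pops <- data.frame(name = "N", n_males = 5L, n_females = 5L)
  spec <- cohort_spec(pops, c(N = 0.2), c(chr1 = 50000, chr2 = 20000),
                      n_sites = 4000, private_allele_rate = 0,
                      missing_rate = 0,
                      fail_fractions = c(high_missing = 0), seed = 55)
  co <- simulate_cohort(spec, ref)
  tab <- genotype_table(co$vcf, co$sheet)
  res <- exact_pattern_scan(tab, tolerance = 0)
  # oracle: sum over sites of P(all 5 M het) * P(all 5 F hom-ref) under
  # HWE at the generative (truth) allele frequency
  keys <- paste0(tab$sites$chrom, ":", tab$sites$pos)
  p <- co$truth$freq$N[match(keys, co$truth$freq$site)]
  exp_m <- sum((2 * p * (1 - p))^5 * ((1 - p)^2)^5)
  obs_m <- sum(res$sites$pattern == "male_specific_het")
  # 3x the binomial expectation, plus a small-count Poisson allowance
  expect_lte(obs_m, 3 * exp_m + 5)
})

test_that("sex_dapc_screen concentrates candidates in the planted region", {
  co <- small_cohort()
  tab <- genotype_table(co$vcf, co$sheet)
  tab_a <- pikescan:::gtab_subset(
    tab, samples = co$sheet$sample[co$sheet$population == "A"])
  scr <- sex_dapc_screen(tab_a, n_pc = 6)
  cand <- scr$candidates
  expect_gt(nrow(cand), 0)
  frac_in <- mean(cand$chrom == "chr1" & cand$pos >= 10000 &
                    cand$pos <= 30000)
  expect_gte(frac_in, 0.9)
  # permuted sexes: candidates collapse to null level
  set.seed(10)
  sx <- setNames(tab_a$sheet$sex, tab_a$sheet$sample)
  perm <- setNames(sample(sx), names(sx))
  scr_p <- sex_dapc_screen(tab_a, sexes = perm, n_pc = 6)
  expect_lt(nrow(scr_p$candidates), nrow(cand) / 5)
})

test_that("coverage_ratio_genotype arithmetic, calls, and rescale invariance", {
  depth <- data.frame(sample = c("a", "b", "c"),
                      region = "amhby", mean_depth = c(12, 0, 2))
  depth <- rbind(depth, data.frame(sample = c("a", "b", "c"),
                                   region = "LG01",
                                   mean_depth = c(24, 20, 20)))
  calls <- coverage_ratio_genotype(depth, "amhby", "LG01")
  expect_equal(calls$ratio, c(0.5, 0, 0.1))
  expect_equal(calls$call, c("present", "absent", "ambiguous"))
  # uniform depth rescaling leaves calls unchanged
  depth2 <- depth
  depth2$mean_depth <- depth2$mean_depth * 3.7
  expect_equal(coverage_ratio_genotype(depth2, "amhby", "LG01")$call,
               calls$call)
  bad <- depth
  bad$mean_depth[bad$sample == "b" & bad$region == "LG01"] <- 0
  expect_error(coverage_ratio_genotype(bad, "amhby", "LG01"), "control")
})
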