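# synthetic-data module: reference, cohort, sex region, reads

test_that("simulate_reference honors lengths, alphabet, GC and determinism", {
  ref <- simulate_reference(c(c1 = 1e5, c2 = 2e4), gc_fraction = 0.5,
                            seed = 3)
  expect_identical(reference_index(ref)$length, c(100000L, 20000L))
  expect_identical(as.character(ref),
                   as.character(simulate_reference(
                     c(c1 = 1e5, c2 = 2e4), gc_fraction = 0.5, seed = 3)))
  # oracle: direct base count; binomial bound at n = 1e5 (~6 sd)
  gc <- sum(Biostrings::letterFrequency(ref, c("G", "C"))) / 120000
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
  freq <- Biostrings::alphabetFrequency(ref[[1]])
  expect_equal(sum(freq[c("A", "C", "G", "T")]), 100000)
  expect_error(simulate_reference(c(c1 = 5000)), "10 kb")
  expect_error(simulate_reference(c(c1 = -1)), "positive")
})

test_that("cohort_spec validates rates, names and theta bound", {
  pops <- data.frame(name = c("A", "B"), n_males = 2L, n_females = 2L)
  cl <- c(chr1 = 50000)
  expect_error(cohort_spec(pops, c(A = 0.5, B = 0.1), cl),
               "cannot exceed 3/8")
  expect_error(cohort_spec(pops, c(A = 0.1, B = 0.1), cl, fst = 1.2),
               "fst")
  expect_error(cohort_spec(pops, c(A = 0.1), cl), "named for every")
  expect_error(
    cohort_spec(rbind(pops, pops), c(A = 0.1, B = 0.1), cl), "unique")
  expect_error(cohort_spec(pops, c(A = 0.1, B = 0.1), cl,
                           missing_rate = 1.5), "rates")
})

test_that("simulated cohort recovers theta ordering and expectations", {
  co <- small_cohort()
  tab <- genotype_table(co$vcf, co$sheet)
  tal <- genotype_tallies(tab)$per_population
  a <- tal$mean_het[tal$population == "A"]
  b <- tal$mean_het[tal$population == "B"]
  expect_gt(a, b)                      # theta 0.16 vs 0.05, >3x separation
  # realized means within 10% of truth expectations at the contract scale
  # (>= 5 diploids per population, >= 50k sites)
  cb <- big_cohort()
  tb <- genotype_table(cb$vcf, cb$sheet)
  talb <- genotype_tallies(tb)$per_population
  for (p in c("A", "B")) {
    got <- talb$mean_het[talb$population == p]
    expect_lt(abs(got - cb$truth$expected_het[[p]]) /
                cb$truth$expected_het[[p]], 0.10)
  }
})

test_that("planted private sites are private by construction; rate 0 has none", {
  ref <- small_reference()
  pops <- data.frame(name = c("A", "B"), n_males = 3L, n_females = 3L)
  mk <- function(rate) {
    spec <- cohort_spec(pops, c(A = 0.15, B = 0.15),
                        c(chr1 = 50000, chr2 = 20000), n_sites = 1500,
                        private_allele_rate = rate, missing_rate = 0,
                        seed = 31)
    simulate_cohort(spec, ref)
  }
  co0 <- mk(0)
  co3 <- mk(0.3)
  # rate 0: no private classification planted
  expect_true(all(co0$truth$site_class %in% c("neutral", "indel")))
  # oracle = per-site population scan: at every planted private:P site the
  # alternate allele has zero copies outside P
  tab3 <- genotype_table(co3$vcf, co3$sheet)
  keys <- paste0(tab3$sites$chrom, ":", tab3$sites$pos)
  for (p in c("A", "B")) {
    idx <- which(co3$truth$site_class[keys] == paste0("private:", p))
    expect_gt(length(idx), 50)
    outside <- tab3$sheet$sample[tab3$sheet$population != p]
    expect_equal(sum(tab3$dos[idx, outside], na.rm = TRUE), 0)
  }
  # planting privacy increases realized private-allele counts
  # (drift-realized privacy exists in both worlds; plants add to it)
  p0 <- sum(private_alleles(genotype_table(co0$vcf, co0$sheet)))
  p3 <- sum(private_alleles(tab3))
  expect_lt(p0, p3)
})

test_that("missing_rate = 0 gives a VCF without missing genotypes", {
  co <- small_cohort() # missing_rate 0 and no planted high-missing sites
  expect_false(any(co$vcf$gt == "./."))
})

test_that("plant_sex_region constructs the exact genotype pattern", {
  co <- small_cohort()
  keys <- paste0(co$vcf$sites$chrom, ":", co$vcf$sites$pos)
  planted <- which(co$truth$site_class[keys] == "male_linked")
  expect_length(planted, 50)
  expect_true(all(co$vcf$sites$pos[planted] >= 10000 &
                    co$vcf$sites$pos[planted] <= 30000))
  sheet <- co$sheet
  carriers <- sheet$sample[sheet$population == "A" & sheet$sex == "male"]
  others <- setdiff(sheet$sample, carriers)
  expect_identical(co$truth$carriers, carriers)
  expect_true(all(co$vcf$gt[planted, carriers] == "0/1"))
  expect_true(all(co$vcf$gt[planted, others] == "0/0"))
  # planted REF alleles match the reference sequence
  ref <- small_reference()
  expect_identical(
    pikescan:::ref_bases_at(ref, co$vcf$sites$chrom[planted],
                            co$vcf$sites$pos[planted]),
    co$vcf$sites$ref[planted])
  expect_error(plant_sex_region(co, sex_region_spec(
    "nope", 1, 100, 5, carrier_populations = "A"), ref), "not in the")
  expect_error(plant_sex_region(co, sex_region_spec(
    "chr2", 1, 99999, 5, carrier_populations = "A"), ref), "exceeds")
})

test_that("carrier males carry the insert on exactly one haplotype", {
  co <- small_cohort()
  ref <- small_reference()
  carrier <- co$truth$carriers[1]
  female <- co$sheet$sample[co$sheet$sex == "female"][1]
  hc <- sample_haplotypes(co, ref, carrier, seed = 5)
  hf <- sample_haplotypes(co, ref, female, seed = 5)
  expect_true("amhby_scaffold" %in% names(hc$h2))
  expect_false("amhby_scaffold" %in% names(hc$h1))
  expect_false("amhby_scaffold" %in% c(names(hf$h1), names(hf$h2)))
})

test_that("read simulation: count arithmetic, determinism, depth, errors", {
  co <- small_cohort()
  ref <- small_reference()
  r1 <- pikescan:::sample_reads_for_individual(co, ref, "A_01",
                                               coverage_x = 10,
                                               read_len = 100,
                                               error_rate = 0, seed = 9)
  # coverage 10x over 70 kb at 100 bp -> 7,000 reads
  expect_equal(length(r1), 7000)
  expect_true(all(nchar(r1) == 100))
  r2 <- pikescan:::sample_reads_for_individual(co, ref, "A_01",
                                               coverage_x = 10,
                                               read_len = 100,
                                               error_rate = 0, seed = 9)
  expect_identical(r1, r2)
  sim <- simulate_reads(co, ref, coverage_x = 6, read_len = 100,
                        error_rate = 0, seed = 9)
  d <- sim$depth
  chrom_d <- d[d$region %in% c("chr1", "chr2"), ]
  expect_true(all(abs(chrom_d$mean_depth - 6) / 6 < 0.15))
  ins <- d[d$region == "amhby_scaffold", ]
  expect_true(all(ins$mean_depth[ins$sample %in% co$truth$carriers] > 1))
  expect_true(all(ins$mean_depth[!ins$sample %in% co$truth$carriers] == 0))
  expect_error(simulate_reads(co, ref, coverage_x = 0), "positive")
  expect_error(simulate_reads(co, ref, read_len = 30000), "shortest")
})

test_that("error-free female reads contain no insert-derived 31-mer", {
  co <- small_cohort()
  ref <- small_reference()
  female <- co$sheet$sample[co$sheet$sex == "female"][1]
  rf <- pikescan:::sample_reads_for_individual(co, ref, female,
                                               coverage_x = 8,
                                               read_len = 100,
                                               error_rate = 0, seed = 13)
  # oracle: exhaustive canonical k-mer scan of the reads vs the insert
  kc <- count_kmers(list(f = rf), k = 31)
  insert_kmers <- count_kmers(list(i = as.character(co$insert)), k = 31)
  expect_length(intersect(kc$counts$kmer, insert_kmers$counts$kmer), 0)
  # and a carrier male's reads do contain insert 31-mers
  male <- co$truth$carriers[1]
  rm_ <- pikescan:::sample_reads_for_individual(co, ref, male,
                                                coverage_x = 8,
                                                read_len = 100,
                                                error_rate = 0, seed = 13)
  kcm <- count_kmers(list(m = rm_), k = 31)
  expect_gt(length(intersect(kcm$counts$kmer, insert_kmers$counts$kmer)), 0)
})

test_that("FASTQ round trip and truth JSON round trip", {
  co <- small_cohort()
  reads <- c("ACGTACGTAAGG", "TTTTACGTACGT")
  f <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads, f)
  expect_identical(read_fastq(f), setNames(reads, paste0("read_", 1:2)))
  tj <- tempfile(fileext = ".json")
  write_truth(co$truth, tj)
  tr <- read_truth(tj)
  expect_identical(tr$true_sex, co$truth$true_sex)
  expect_identical(tr$site_class, co$truth$site_class)
  expect_equal(tr$sex_region$start, 10000)
  expect_identical(tr$carriers, co$truth$carriers)
})
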