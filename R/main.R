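## Command-line entry point
##
## Usage: pikescan <subcommand> [options]; subcommands mirror the pipeline
## stages. An executable launcher ships in inst/bin/pikescan; equivalently
## run `Rscript -e 'pikescan::pikescan_main()' -- <subcommand> ...`.

#' Command-line interface dispatcher
#'
#' Subcommands: `simulate`, `filter`, `diversity`, `windows`, `dapc`,
#' `sexkmer`, `sexscan`, `sexdepth`, `demo`.
#'
#' @param args character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
pikescan_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  subs <- c("simulate", "filter", "diversity", "windows", "dapc",
            "sexkmer", "sexscan", "sexdepth", "demo")
  if (!length(args) || !args[1] %in% subs) {
    message("usage: pikescan {", paste(subs, collapse = ", "), "} [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  switch(cmd,
         demo = cli_demo(rest),
         simulate = cli_simulate(rest),
         filter = cli_filter(rest),
         diversity = cli_diversity(rest),
         windows = cli_windows(rest),
         dapc = cli_dapc(rest),
         sexscan = cli_sexscan(rest),
         sexdepth = cli_sexdepth(rest),
         sexkmer = cli_sexkmer(rest))
  invisible(0L)
}

cli_opts <- function(rest, option_list) {
  optparse::parse_args(optparse::OptionParser(option_list = option_list),
                       args = rest)
}

cli_demo <- function(rest) {
  o <- cli_opts(rest, list(
    optparse::make_option("--out", default = "pikescan_demo"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--skip", default = "")))
  skip <- strsplit(o$skip, ",")[[1]]
  run_demo(demo_config(out_dir = o$out, seed = o$seed, skip = skip))
}

cli_simulate <- function(rest) {
  o <- cli_opts(rest, list(
    optparse::make_option("--out", default = "pikescan_sim"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--fastq", action = "store_true", default = FALSE)))
  cfg <- demo_config(out_dir = o$out, seed = o$seed,
                     skip = if (o$fastq) character() else "sexkmer",
                     write_fastq = o$fastq)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(cfg$chrom_lengths,
                                  seed = derive_seed(o$seed, "reference"))
  write_reference(reference, file.path(o$out, "reference.fa"))
  spec <- cohort_spec(cfg$populations, cfg$theta, cfg$chrom_lengths,
                      n_sites = cfg$n_sites,
                      indel_fraction = cfg$indel_fraction,
                      seed = derive_seed(o$seed, "cohort"))
  cohort <- simulate_cohort(spec, reference)
  region <- sex_region_spec(cfg$region$chrom, cfg$region$start,
                            cfg$region$end, cfg$region$male_het_snp_count,
                            cfg$region$insert_name, cfg$region$insert_length,
                            cfg$region$carriers)
  cohort <- plant_sex_region(cohort, region, reference)
  write_vcf(cohort$vcf, file.path(o$out, "cohort.vcf"), reference)
  write_sample_sheet(cohort$sheet, file.path(o$out, "samples.tsv"))
  write_truth(cohort$truth, file.path(o$out, "truth.json"))
  Biostrings::writeXStringSet(cohort$insert, file.path(o$out, "insert.fa"))
  if (o$fastq)
    simulate_reads(cohort, reference, out_dir = file.path(o$out, "fastq"),
                   error_rate = cfg$error_rate,
                   seed = derive_seed(o$seed, "reads"))
  message("simulated cohort written to ", o$out)
}

cli_filter <- function(rest) {
  o <- cli_opts(rest, list(
    optparse::make_option("--vcf"), optparse::make_option("--out"),
    optparse::make_option("--report", default = "filter_report.tsv"),
    optparse::make_option("--max-missing-count", dest = "mmc",
                          type = "integer", default = 10L),
    optparse::make_option("--mac", type = "integer", default = 1L)))
  v <- read_vcf(o$vcf)
  fc <- filter_cascade(v, filter_thresholds(max_missing_count = o$mmc,
                                            mac_min = o$mac))
  write_vcf(fc$vcf, o$out)
  write_tsv_prov(fc$report, o$report)
  message(sprintf("retained %d of %d (%.1f%%)",
                  tail(fc$report$n_retained, 1), fc$report$n_retained[1],
                  retention_percent(fc$report$n_retained[1],
                                    tail(fc$report$n_retained, 1))))
}

cli_diversity <- function(rest) {
  o <- cli_opts(rest, list(
    optparse::make_option("--vcf"), optparse::make_option("--samples"),
    optparse::make_option("--out-prefix", dest = "prefix", default = "div")))
  tab <- genotype_table(read_vcf(o$vcf), read_sample_sheet(o$samples))
  tal <- genotype_tallies(tab)
  pops <- unique(tab$sheet$population)
  hobs <- vapply(pops, function(p) observed_heterozygosity(tab, p), 0)
  write_tsv_prov(tal$per_sample, paste0(o$prefix, "_tallies.tsv"))
  ps <- tal$per_population
  ps$H_OBS <- hobs[ps$population]
  if (length(pops) >= 2) {
    priv <- private_alleles(tab)
    ps$private_alleles <- priv[ps$population]
    fd <- fixed_difference_matrix(tab)
    write_tsv_prov(as.data.frame(fd$matrix), paste0(o$prefix, "_fixed.tsv"))
  }
  ps$tajimas_D <- vapply(ps$population, function(p)
    tajimas_d_windows(tab, p)$mean_D, 0)
  write_tsv_prov(ps, paste0(o$prefix, "_populations.tsv"))
  write_tsv_prov(as.data.frame(ibs_distance_matrix(tab)),
                 paste0(o$prefix, "_ibs.tsv"))
  message("diversity tables written with prefix ", o$prefix)
}

cli_windows <- function(rest) {
  o <- cli_opts(rest, list(
    optparse::make_option("--vcf"), optparse::make_option("--fai"),
    optparse::make_option("--width", type = "double", default = 1e6),
    optparse::make_option("--out", default = "windows.tsv")))
  fai <- utils::read.table(o$fai, sep = "\t")
  lens <- setNames(as.numeric(fai[[2]]), fai[[1]])
  wd <- count_per_window(read_vcf(o$vcf), make_windows(lens, o$width))
  outl <- outlier_threshold(wd$n_variants)
  write_tsv_prov(wd, o$out)
  jsonlite::write_json(outl[1:4], paste0(tools::file_path_sans_ext(o$out),
                                         "_outliers.json"),
                       auto_unbox = TRUE)
  message(sprintf("outlier threshold %.1f; %d outlier window(s)",
                  outl$threshold, length(outl$outliers)))
}

cli_dapc <- function(rest) {
  o <- cli_opts(rest, list(
    optparse::make_option("--vcf"), optparse::make_option("--samples"),
    optparse::make_option("--groups", default = "population"),
    optparse::make_option("--n-pc", dest = "npc", type = "integer",
                          default = 24L),
    optparse::make_option("--n-df", dest = "ndf", type = "integer",
                          default = 3L),
    optparse::make_option("--out-prefix", dest = "prefix", default = "dapc")))
  tab <- genotype_table(read_vcf(o$vcf), read_sample_sheet(o$samples))
  groups <- tab$sheet[[o$groups]]
  m <- suppressWarnings(dapc(tab, groups, n_pc = o$npc, n_df = o$ndf))
  write_tsv_prov(data.frame(sample = tab$samples, m$df_scores,
                            group = groups, assigned = m$assignments),
                 paste0(o$prefix, "_scores.tsv"))
  write_tsv_prov(data.frame(site = rownames(m$loadings), m$loadings),
                 paste0(o$prefix, "_loadings.tsv"))
  message(sprintf("training accuracy %.3f", m$accuracy))
}

cli_sexscan <- function(rest) {
  o <- cli_opts(rest, list(
    optparse::make_option("--vcf"), optparse::make_option("--samples"),
    optparse::make_option("--tolerance", type = "integer", default = 0L),
    optparse::make_option("--out", default = "sexscan.tsv")))
  tab <- genotype_table(read_vcf(o$vcf), read_sample_sheet(o$samples))
  scan <- exact_pattern_scan(tab, tolerance = o$tolerance)
  write_tsv_prov(scan$sites, o$out)
  message(sprintf("%d sex-specific site(s)", nrow(scan$sites)))
}

cli_sexdepth <- function(rest) {
  o <- cli_opts(rest, list(
    optparse::make_option("--depth"), optparse::make_option("--target"),
    optparse::make_option("--control"),
    optparse::make_option("--out", default = "coverage_calls.tsv")))
  calls <- coverage_ratio_genotype(read_tsv_prov(o$depth), o$target,
                                   o$control)
  write_tsv_prov(calls, o$out)
  message(sprintf("%d present / %d absent / %d ambiguous",
                  sum(calls$call == "present"), sum(calls$call == "absent"),
                  sum(calls$call == "ambiguous")))
}

cli_sexkmer <- function(rest) {
  o <- cli_opts(rest, list(
    optparse::make_option("--fastq-dir", dest = "fqdir"),
    optparse::make_option("--samples"),
    optparse::make_option("--population"),
    optparse::make_option("--target-sex", dest = "sex", default = "male"),
    optparse::make_option("--k", type = "integer", default = 31L),
    optparse::make_option("--reference", default = NULL),
    optparse::make_option("--out-prefix", dest = "prefix", default = "kmer")))
  sheet <- read_sample_sheet(o$samples)
  paths <- list.files(o$fqdir, pattern = "\\.fastq(\\.gz)?$",
                      full.names = TRUE)
  names(paths) <- sub("\\.fastq(\\.gz)?$", "", basename(paths))
  kmers <- sex_specific_kmers_stream(paths, sheet, o$population, o$sex,
                                     k = o$k)
  writeLines(paste0(">kmer", seq_along(kmers), "\n", kmers),
             paste0(o$prefix, "_specific.fa"))
  if (!is.null(o$reference)) {
    reference <- read_reference(o$reference)
    mapping <- map_kmers_to_genome(kmers, reference, max_mismatch = 1)
    wins <- make_windows(setNames(Biostrings::width(reference),
                                  names(reference)), 1e4)
    kw <- kmer_window_density(mapping$hits, wins)
    write_tsv_prov(kw[kw$n_kmers > 0, ], paste0(o$prefix, "_windows.tsv"))
  }
  message(sprintf("%d sex-specific k-mer(s)", length(kmers)))
}
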