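## Reference-free sex-specific k-mer detector
##
## Canonical 31-mers are tallied per sample (C++ backend); a k-mer is
## sex-specific for a target sex within a population iff every
## opposite-sex individual has at most `opposite_max` copies (sequencing
## error allowance), every target-sex individual has at least `target_min`
## copies, and the target-sex copy sum is strictly greater than
## `target_sum_min_exclusive`. Retained k-mers are anchored to the genome
## by exact match (optionally with one mismatch, needed for k-mers carrying
## an alternate allele) and counted in 10-kb windows; unmapped k-mers are
## first-class output — a male-limited insert absent from a female-derived
## reference can only appear there.

#' Per-individual thresholds of the sex-specific k-mer rule
#'
#' Defaults follow the published rule: opposite sex <= 2 copies each,
#' target sex >= 1 copy each, and target-sex sum strictly greater than 7.
#'
#' @param opposite_max maximum copies per opposite-sex individual.
#' @param target_min minimum copies per target-sex individual.
#' @param target_sum_min_exclusive the target-sex copy sum must exceed
#'   this value (strict inequality, i.e. sum >= 8 under the default).
#' @return A `sex_kmer_rule` list.
#' @export
sex_kmer_rule <- function(opposite_max = 2, target_min = 1,
                          target_sum_min_exclusive = 7) {
  if (any(c(opposite_max, target_min, target_sum_min_exclusive) < 0))
    stopf("rule thresholds must be >= 0")
  structure(list(opposite_max = opposite_max, target_min = target_min,
                 target_sum_min_exclusive = target_sum_min_exclusive),
            class = "sex_kmer_rule")
}

#' Count canonical k-mers per sample
#'
#' Every k-base window of every read is canonicalized (lexicographic
#' minimum of the k-mer and its reverse complement) and tallied; windows
#' containing a non-ACGT base are skipped. Suitable for test-scale inputs;
#' whole-cohort scans use the streaming path in [sex_specific_kmers()].
#'
#' @param reads named list of per-sample read sets; each element is a
#'   character vector of read sequences or a FASTQ path.
#' @param k odd k-mer length (default 31; even k is rejected because a
#'   k-mer could equal its own reverse complement).
#' @return A `kmer_count_set`: list(`k`, `counts` = data.table with column
#'   `kmer` and one count column per sample (0 = absent), `samples`).
#' @export
count_kmers <- function(reads, k = 31) {
  if (k %% 2 == 0) stopf("k must be odd (even k allows canonical ties)")
  if (k > 31) stopf("k must be <= 31")
  if (is.null(names(reads))) stopf("reads must be a named list (samples)")
  per <- lapply(reads, function(r) {
    if (is.character(r) && length(r) == 1 && file.exists(r))
      r <- read_fastq(r)
    if (!length(r)) {
      warnf("empty read set")
      return(data.table(kmer = character(), count = integer()))
    }
    as.data.table(cpp_count_kmers(r, as.integer(k)))
  })
  master <- sort(unique(unlist(lapply(per, `[[`, "kmer"))))
  counts <- data.table(kmer = master)
  for (sm in names(per)) {
    v <- integer(length(master))
    v[match(per[[sm]]$kmer, master)] <- per[[sm]]$count
    counts[[sm]] <- v
  }
  structure(list(k = k, counts = counts, samples = names(reads)),
            class = "kmer_count_set")
}

# rule predicate on a target-sex count matrix and opposite-sex count matrix
# (rows = k-mers); returns logical vector
kmer_rule_keep <- function(target_counts, opposite_counts, rule) {
  apply_min <- function(m) do.call(pmin, as.data.frame(m))
  apply_max <- function(m) do.call(pmax, as.data.frame(m))
  apply_max(opposite_counts) <= rule$opposite_max &
    apply_min(target_counts) >= rule$target_min &
    rowSums(target_counts) > rule$target_sum_min_exclusive
}

#' Sex-specific k-mers within one population
#'
#' @param counts a `kmer_count_set` from [count_kmers()].
#' @param sheet a [sample_sheet()] for the counted samples.
#' @param population population to analyze (>= 3 samples per sex required,
#'   the published inclusion criterion).
#' @param target_sex `"male"` or `"female"`.
#' @param rule a [sex_kmer_rule()].
#' @return character vector of retained canonical k-mers, with a
#'   `counts` attribute (the retained rows of the count table).
#' @export
sex_specific_kmers <- function(counts, sheet, population,
                               target_sex = "male",
                               rule = sex_kmer_rule()) {
  stopifnot(inherits(counts, "kmer_count_set"))
  opp_sex <- setdiff(c("male", "female"), target_sex)
  ids <- function(sx) sheet$sample[sheet$population == population &
                                     sheet$sex == sx &
                                     sheet$sample %in% counts$samples]
  tgt <- ids(target_sex)
  opp <- ids(opp_sex)
  if (length(tgt) < 3 || length(opp) < 3)
    stopf(paste("population '%s' needs >= 3 samples per sex",
                "(inclusion criterion); got %d %s / %d %s"),
          population, length(tgt), target_sex, length(opp), opp_sex)
  ct <- counts$counts
  keep <- kmer_rule_keep(as.matrix(ct[, tgt, with = FALSE]),
                         as.matrix(ct[, opp, with = FALSE]), rule)
  out <- ct$kmer[keep]
  attr(out, "counts") <- ct[keep]
  out
}

#' Streaming sex-specific k-mer scan over per-sample read sets
#'
#' Memory-bounded whole-cohort equivalent of [count_kmers()] +
#' [sex_specific_kmers()]: candidate k-mers are fixed from the first
#' target-sex sample (any retained k-mer must occur >= `target_min` times
#' in every target-sex sample, so this loses nothing when
#' `target_min >= 1`), then every other sample is counted against the
#' candidates only.
#'
#' @param read_source function(sample_id) returning that sample's reads
#'   (character vector), or a named list/vector of FASTQ paths.
#' @param sheet a [sample_sheet()].
#' @param population,target_sex,rule as in [sex_specific_kmers()].
#' @param k odd k-mer size (default 31).
#' @return As [sex_specific_kmers()].
#' @export
sex_specific_kmers_stream <- function(read_source, sheet, population,
                                      target_sex = "male",
                                      rule = sex_kmer_rule(), k = 31) {
  if (k %% 2 == 0) stopf("k must be odd (even k allows canonical ties)")
  if (rule$target_min < 1)
    stopf("the streaming path requires target_min >= 1")
  get_reads <- if (is.function(read_source)) read_source else {
    paths <- unlist(read_source)
    function(sm) read_fastq(paths[[sm]])
  }
  opp_sex <- setdiff(c("male", "female"), target_sex)
  tgt <- sheet$sample[sheet$population == population & sheet$sex == target_sex]
  opp <- sheet$sample[sheet$population == population & sheet$sex == opp_sex]
  if (length(tgt) < 3 || length(opp) < 3)
    stopf("population '%s' needs >= 3 samples per sex", population)
  tr <- kmer_tracker_new(as.integer(k))
  first <- kmer_tracker_count_sample(tr, get_reads(tgt[1]), init = TRUE)
  min_t <- sum_t <- first
  alive <- first >= rule$target_min
  for (sm in tgt[-1]) {
    v <- kmer_tracker_count_sample(tr, get_reads(sm))
    min_t <- pmin(min_t, v)
    sum_t <- sum_t + v
    alive <- alive & min_t >= rule$target_min
  }
  ## prune before/after each opposite-sex pass: once a candidate fails any
  ## per-individual bound it can never be retained, and shrinking the
  ## table makes the remaining scans cache-resident
  prune <- function() {
    keep <- which(alive)
    kmer_tracker_prune(tr, keep)
    min_t <<- min_t[keep]
    sum_t <<- sum_t[keep]
    alive <<- alive[keep]
    keep
  }
  prune()
  for (sm in opp) {
    v <- kmer_tracker_count_sample(tr, get_reads(sm))
    alive <- alive & v <= rule$opposite_max
    prune()
  }
  keep <- which(sum_t > rule$target_sum_min_exclusive)
  out <- kmer_tracker_keys(tr, keep)
  ord <- order(out)
  out <- out[ord]
  attr(out, "counts") <- data.table(kmer = out)
  out
}

# thin wrapper so init and count share one entry point
kmer_tracker_count_sample <- function(tr, reads, init = FALSE) {
  if (init) kmer_tracker_init(tr, reads) else kmer_tracker_count(tr, reads)
}

#' Anchor k-mers to the reference genome
#'
#' Exact-match search of each k-mer and its reverse complement against the
#' reference; with `max_mismatch = 1`, every single-substitution neighbor
#' is also searched (needed to anchor k-mers carrying an alternate SNP
#' allele to a reference that holds the reference allele). Unmapped k-mers
#' are first-class output: for an XY system with a male-limited insert
#' absent from a female-derived reference, they are the insert signal.
#'
#' @param kmers character vector of k-mers.
#' @param reference a `DNAStringSet`.
#' @param max_mismatch 0 (exact, default) or 1.
#' @return list(`hits` = data.table(kmer, chrom, pos (1-based start),
#'   strand), `unmapped` = character vector).
#' @export
map_kmers_to_genome <- function(kmers, reference, max_mismatch = 0) {
  empty <- data.table(kmer = character(), chrom = character(),
                      pos = integer(), strand = character())
  if (!length(kmers)) return(list(hits = empty, unmapped = character()))
  if (!max_mismatch %in% c(0, 1)) stopf("max_mismatch must be 0 or 1")
  kmers <- as.character(kmers)
  k <- nchar(kmers[1])
  if (any(nchar(kmers) != k)) stopf("k-mers must have equal length")
  ## queries live in canonical space: the reference is scanned window by
  ## window and each window's canonical form is looked up in the query
  ## set, so a k-mer and its reverse complement match together by
  ## construction (neighbors of the reverse complement are reverse
  ## complements of neighbors, hence share canonical forms)
  if (max_mismatch == 1) {
    nb <- kmer_mismatch_neighbors(kmers)
    query <- data.table(origin = nb$origin, canon = cpp_canonical(nb$kmer))
  } else {
    query <- data.table(origin = seq_along(kmers),
                        canon = cpp_canonical(kmers))
  }
  query <- unique(query)
  uq <- unique(query$canon)
  query[, uqi := match(canon, uq)]
  ref_chr <- as.character(reference)
  hits <- list()
  for (cn in names(reference)) {
    m <- cpp_scan_genome(ref_chr[cn], uq, as.integer(k))
    if (!length(m$idx)) next
    hits[[cn]] <- data.table(uqi = m$idx, chrom = cn, pos = m$pos)
  }
  hits <- rbindlist(hits)
  if (!nrow(hits)) return(list(hits = empty, unmapped = kmers))
  hits <- merge(hits, query[, .(uqi, origin)], by = "uqi",
                allow.cartesian = TRUE)
  hits <- unique(hits[, .(kmer = kmers[origin], chrom, pos)])
  ## strand: the window matches the k-mer forward within max_mismatch ->
  ## "+", otherwise it matched the reverse complement -> "-"
  wseq <- substring(ref_chr[hits$chrom], hits$pos, hits$pos + k - 1)
  hits[, strand := ifelse(hamming_dist(wseq, kmer) <= max_mismatch,
                          "+", "-")]
  setorder(hits, chrom, pos)
  list(hits = hits[, .(kmer, chrom, pos, strand)],
       unmapped = setdiff(kmers, hits$kmer))
}

# per-pair Hamming distance between equal-length strings
hamming_dist <- function(a, b) {
  vapply(seq_along(a), function(i)
    sum(charToRaw(a[i]) != charToRaw(b[i])), 0L)
}

# all single-substitution neighbors (plus the k-mer itself);
# returns data.table(origin = index into input, kmer)
kmer_mismatch_neighbors <- function(kmers) {
  k <- nchar(kmers[1])
  bases <- c("A", "C", "G", "T")
  out <- list(data.table(origin = seq_along(kmers), kmer = kmers))
  for (p in seq_len(k)) {
    cur <- substr(kmers, p, p)
    for (b in bases) {
      changed <- cur != b
      if (!any(changed)) next
      v <- kmers[changed]
      substr(v, p, p) <- b
      out[[length(out) + 1]] <- data.table(origin = which(changed), kmer = v)
    }
  }
  rbindlist(out)
}

#' Sex-specific k-mer density in genomic windows
#'
#' @param hits the `hits` table from [map_kmers_to_genome()].
#' @param windows window table from [make_windows()] (default width for the
#'   published procedure is 10 kb).
#' @return `windows` with an `n_kmers` count column.
#' @export
kmer_window_density <- function(hits, windows) {
  cnt <- count_per_window(data.table(chrom = hits$chrom, pos = hits$pos),
                          windows)
  names(cnt)[names(cnt) == "n_variants"] <- "n_kmers"
  cnt
}
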