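## Windowed Tajima's D
##
## The standard Tajima (1989) estimator, computed per fixed-width window
## from genotype-derived allele counts. With unphased diploid genotypes,
## the mean pairwise difference at a site with j alternate copies among
## n = 2 * (non-missing diploids) chromosomes is 2 j (n - j) / (n (n - 1)),
## exact for a random union of gametes. The normalizing constants use the
## minimum per-site n across a window's usable sites (a conservative choice;
## the published tool's per-site-n handling is unstated).

#' Tajima's D normalizing constants
#'
#' @param n number of sequences (chromosomes), `n >= 4`.
#' @return list with `n, a1, a2, b1, b2, c1, c2, e1, e2` following the
#'   standard definitions (`a1 = sum 1/i`, `a2 = sum 1/i^2` for
#'   `i = 1..n-1`, `b1 = (n+1)/(3(n-1))`,
#'   `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#'   `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#'   `e2 = c2/(a2 + a1^2)`).
#' @export
tajima_constants <- function(n) {
  if (n < 4) stopf("Tajima constants need n >= 4 sequences")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a2 + a1^2)
  stopifnot(e1 > 0, e2 > 0)
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D for one population
#'
#' Per window of `window_bp` (0-based half-open, tiling each chromosome):
#' S = count of sites polymorphic within the population, pi = sum over
#' sites of `2 j (n - j) / (n (n - 1))`, and
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))`. Windows with S = 0 have
#' undefined D (NA) and are excluded from the mean. Sites with fewer than
#' 4 called chromosomes are skipped (count in attribute `n_skipped`).
#'
#' @param tab a [genotype_table()].
#' @param population population name.
#' @param window_bp window width in bp (default 10000, as published).
#' @return list(`windows` = data.frame(chrom, start, end, n, S, pi, D),
#'   `mean_D` = unweighted mean over windows with defined D).
#' @export
tajimas_d_windows <- function(tab, population, window_bp = 10000) {
  ids <- tab$sheet$sample[tab$sheet$population == population]
  if (!length(ids)) stopf("population '%s' has no samples", population)
  bi <- which(is_biallelic(tab))
  d <- tab$dos[bi, ids, drop = FALSE]
  s <- tab$sites[bi]
  n_chr <- 2 * rowSums(!is.na(d))
  j_alt <- rowSums(d, na.rm = TRUE)
  usable <- n_chr >= 4
  n_skipped <- sum(!usable)
  dt <- data.table(chrom = s$chrom, pos = s$pos, n = n_chr, j = j_alt)[usable]
  dt[, window := floor((pos - 1) / window_bp)]
  win <- dt[, {
    nw <- min(n)
    poly <- j > 0 & j < n
    pi_w <- sum(2 * j * (n - j) / (n * (n - 1)))
    .(start = window * window_bp, end = (window + 1) * window_bp,
      n = nw, S = sum(poly), pi = pi_w)
  }, by = .(chrom, window)]
  win[, D := NA_real_]
  defined <- win$S >= 1 & win$n >= 4
  if (any(defined)) {
    win$D[defined] <- vapply(which(defined), function(r) {
      ct <- tajima_constants(win$n[r])
      S <- win$S[r]
      (win$pi[r] - S / ct$a1) / sqrt(ct$e1 * S + ct$e2 * S * (S - 1))
    }, 0)
  }
  out <- as.data.frame(win[, .(chrom, start, end, n, S, pi, D)])
  res <- list(windows = out,
              mean_D = if (any(!is.na(out$D))) mean(out$D, na.rm = TRUE)
                       else NA_real_)
  attr(res, "n_skipped") <- n_skipped
  res
}
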