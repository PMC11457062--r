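## small shared helpers (not exported)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a per-stage seed from a master seed
#'
#' A single master seed fans out to per-stage seeds via a fixed affine map
#' modulo 2^31 - 1 (a Lehmer-style scramble), so each pipeline stage is
#' independently reproducible without sharing RNG state.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 1) or stage name from the fixed
#'   stage table used by [run_demo()].
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stages <- c(reference = 1L, cohort = 2L, sexregion = 3L, reads = 4L,
              filter = 5L, diversity = 6L, windows = 7L, dapc = 8L,
              sexlink = 9L, demo = 10L)
  if (is.character(stage)) {
    if (!stage %in% names(stages)) stopf("unknown stage '%s'", stage)
    stage <- stages[[stage]]
  }
  m <- 2147483647 # 2^31 - 1, prime
  # all arithmetic in doubles stays exact below 2^53
  x <- (abs(as.numeric(master)) %% m) * 48271 + as.numeric(stage) * 69621 + 1
  as.integer(x %% (m - 1) + 1)
}

# round-half-up to integer (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

# standard provenance header written at the top of every output file
provenance_header <- function(seed = NA, params = list()) {
  ver <- as.character(utils::packageVersion("pikescan"))
  p <- if (length(params))
    paste(sprintf("%s=%s", names(params), vapply(params, function(z)
      paste(format(z), collapse = ","), "")), collapse = " ")
  else ""
  c(sprintf("# pikescan v%s", ver),
    sprintf("# seed=%s %s", format(seed), p))
}

# write a data.frame as TSV with provenance comment lines
write_tsv_prov <- function(x, path, seed = NA, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# evaluate an expression with a locally seeded RNG, restoring state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
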