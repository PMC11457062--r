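## DAPC machinery from first principles
##
## PCA of the (mean-imputed, centered) 0/1/2 genotype matrix, a BIC-driven
## k-means cluster search, linear discriminant analysis on the retained
## principal components, and a Ward-clustering loading selector. The BIC is
## the standard k-means form n*ln(WSS/n) + k*ln(n) (the published toolchain
## does not print its exact formula); k-means uses seeded multiple restarts
## for determinism under a master seed. Missing genotypes are mean-imputed
## before PCA — a simple default shared with the source ecosystem, and a
## documented limitation.

#' PCA of a genotype matrix
#'
#' @param tab a [genotype_table()], or a numeric samples x variants matrix
#'   of allele dosages.
#' @param n_pc number of principal components to retain (default 24, the
#'   published choice); truncated to the matrix rank with a warning.
#' @param scale scale variant columns to unit variance (default FALSE; the
#'   published configuration is not stated, unscaled is the default mode).
#' @return list(`scores` (samples x n_pc), `rotation` (variants x n_pc),
#'   `sdev`, `center`, `explained` (variance fractions), `kept_sites`
#'   (indices of non-constant variant columns)).
#' @export
genotype_pca <- function(tab, n_pc = 24, scale = FALSE) {
  X <- dosage_matrix(tab)
  if (nrow(X) < 2) stopf("need >= 2 samples")
  ## mean-impute missing entries per variant
  mu <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- mu[nas[, 2]]
  keep <- which(apply(X, 2, function(v) stats::var(v) > 0))
  if (!length(keep)) stopf("all variant columns are constant")
  Xk <- X[, keep, drop = FALSE]
  pr <- prcomp(Xk, center = TRUE, scale. = scale)
  rank <- sum(pr$sdev > 1e-9)
  if (n_pc > rank) {
    warnf("n_pc = %d exceeds rank %d; truncated", n_pc, rank)
    n_pc <- rank
  }
  list(scores = pr$x[, seq_len(n_pc), drop = FALSE],
       rotation = pr$rotation[, seq_len(n_pc), drop = FALSE],
       sdev = pr$sdev, center = pr$center,
       explained = pr$sdev^2 / sum(pr$sdev^2),
       kept_sites = keep)
}

# samples x variants dosage matrix from a genotype_table (or pass-through)
dosage_matrix <- function(tab) {
  if (inherits(tab, "genotype_table")) {
    X <- t(tab$dos)
    storage.mode(X) <- "double"
    colnames(X) <- paste0(tab$sites$chrom, ":", tab$sites$pos)
    X
  } else {
    as.matrix(tab)
  }
}

#' BIC-driven k-means cluster search
#'
#' Runs seeded k-means (multiple restarts, best within-cluster sum of
#' squares kept) for each k and records BIC = n*ln(WSS/n) + k*ln(n);
#' the selected k minimizes BIC.
#'
#' @param scores samples x dims score matrix (all PCs, per the published
#'   procedure).
#' @param k_max largest k to evaluate (`1 <= k_max < n_samples`).
#' @param nstart k-means restarts per k (default 10).
#' @param seed RNG seed.
#' @return list(`k` = selected k, `bic` = named numeric per k,
#'   `clusters` = assignment under the selected k).
#' @export
find_clusters <- function(scores, k_max, nstart = 10, seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k_max < 1) stopf("k_max must be >= 1")
  if (k_max >= n) stopf("k_max must be < n_samples")
  bic <- setNames(numeric(k_max), seq_len(k_max))
  assign <- vector("list", k_max)
  with_seed(seed, {
    for (k in seq_len(k_max)) {
      km <- kmeans(scores, centers = k, nstart = nstart, iter.max = 100)
      wss <- max(sum(km$withinss), 1e-12)
      bic[k] <- n * log(wss / n) + k * log(n)
      assign[[k]] <- km$cluster
    }
  })
  k_sel <- as.integer(which.min(bic))
  list(k = k_sel, bic = bic, clusters = assign[[k_sel]])
}

#' Linear discriminant analysis on retained principal components
#'
#' Discriminant axes maximize the between/within variance ratio on the PC
#' scores (eigenvectors of W^-1 B); a singular within-group scatter is
#' ridge-regularized with a logged epsilon. Per-variant loadings are the
#' composition of PC rotations and discriminant coefficients.
#'
#' @param scores samples x n_pc PC score matrix.
#' @param groups factor/character group labels (at least 2 groups, each
#'   with at least 2 samples).
#' @param n_df discriminant functions to retain (default 3, the published
#'   choice; capped at min(n_groups - 1, n_pc)).
#' @param rotation optional variants x n_pc PC rotation matrix; when given,
#'   per-variant loadings are returned.
#' @return A `dapc_model`: list(`coef` (n_pc x n_df), `df_scores`,
#'   `group_means`, `groups`, `loadings` (variants x n_df, absolute
#'   values), `assignments`, `accuracy`, `ridge`).
#' @export
lda_fit <- function(scores, groups, n_df = 3, rotation = NULL) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  tabg <- table(groups)
  if (length(tabg) < 2) stopf("need >= 2 groups")
  if (any(tabg < 2)) stopf("every group needs >= 2 samples")
  n_df <- min(n_df, length(tabg) - 1, ncol(scores))
  gm <- rowsum(scores, groups) / as.vector(tabg[sort(unique(groups))])
  centered <- scores - gm[groups, , drop = FALSE]
  W <- crossprod(centered) / nrow(scores)
  overall <- colMeans(scores)
  dev <- gm - matrix(overall, nrow(gm), ncol(gm), byrow = TRUE)
  B <- crossprod(dev * sqrt(as.vector(tabg[rownames(gm)])), dev *
                   sqrt(as.vector(tabg[rownames(gm)]))) / nrow(scores)
  ridge <- 0
  Winv <- tryCatch(solve(W), error = function(e) NULL)
  if (is.null(Winv) || !all(is.finite(Winv)) ||
      kappa(W) > 1e10) {
    ridge <- 1e-6 * mean(diag(W))
    Winv <- solve(W + diag(ridge, ncol(W)))
  }
  eg <- eigen(Winv %*% B)
  coef <- Re(eg$vectors[, seq_len(n_df), drop = FALSE])
  ## normalize axes to unit within-group variance
  for (a in seq_len(ncol(coef))) {
    sca <- sqrt(drop(t(coef[, a]) %*% W %*% coef[, a]))
    if (sca > 0) coef[, a] <- coef[, a] / sca
  }
  rownames(coef) <- colnames(scores)
  colnames(coef) <- paste0("DF", seq_len(n_df))
  df_scores <- scores %*% coef
  centers <- rowsum(df_scores, groups) / as.vector(tabg[sort(unique(groups))])
  assignments <- assign_to_centroids(df_scores, centers)
  model <- list(coef = coef, df_scores = df_scores, group_means = centers,
                groups = groups, ridge = ridge,
                assignments = assignments,
                accuracy = mean(assignments == groups))
  if (!is.null(rotation)) {
    ld <- abs(rotation %*% coef)
    rownames(ld) <- rownames(rotation)
    model$loadings <- ld
  }
  structure(model, class = "dapc_model")
}

assign_to_centroids <- function(x, centers) {
  x <- as.matrix(x)
  d2 <- vapply(rownames(centers), function(g)
    rowSums((x - matrix(centers[g, ], nrow(x), ncol(x), byrow = TRUE))^2),
    numeric(nrow(x)))
  d2 <- matrix(d2, nrow = nrow(x),
               dimnames = list(NULL, rownames(centers)))
  rownames(centers)[max.col(-d2)]
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d discriminant function(s), %d group(s), %s",
              ncol(x$coef), length(unique(x$groups)),
              sprintf("training accuracy %.2f\n", x$accuracy)))
  invisible(x)
}

#' Select structural variants from discriminant loadings
#'
#' 1-D Ward agglomerative clustering of absolute loadings into 2 clusters;
#' the cluster with the higher mean is the "structural" (high-contribution)
#' set, mirroring the snpzip procedure.
#'
#' @param loadings numeric vector of per-variant loadings for one axis
#'   (absolute values are taken).
#' @return integer indices of the selected variants (named if `loadings`
#'   is named); empty with a warning when all loadings are equal.
#' @export
snpzip_select <- function(loadings) {
  if (!length(loadings)) stopf("empty loadings")
  al <- abs(as.numeric(loadings))
  if (length(al) == 1) return(1L)
  if (diff(range(al)) == 0) {
    warnf("all loadings equal; no structural set")
    return(integer(0))
  }
  hc <- hclust(dist(al), method = "ward.D2")
  cl <- cutree(hc, k = 2)
  means <- tapply(al, cl, mean)
  sel <- which(cl == as.integer(names(which.max(means))))
  if (!is.null(names(loadings))) names(sel) <- names(loadings)[sel]
  sel
}

#' Full DAPC of a genotype table
#'
#' PCA, then LDA on the retained components with the given group labels;
#' per-variant loadings are mapped back through the PC rotation.
#'
#' @param tab a [genotype_table()] or dosage matrix.
#' @param groups group label per sample (e.g. population or sex).
#' @param n_pc,n_df retained PCs and discriminant functions (defaults 24, 3).
#' @param scale passed to [genotype_pca()].
#' @return A `dapc_model` with `loadings`, plus `pca` and `kept_sites`.
#' @export
dapc <- function(tab, groups, n_pc = 24, n_df = 3, scale = FALSE) {
  pca <- genotype_pca(tab, n_pc = n_pc, scale = scale)
  model <- lda_fit(pca$scores, groups, n_df = n_df, rotation = pca$rotation)
  model$pca <- pca
  model$kept_sites <- pca$kept_sites
  model
}

#' Leave-one-out assignment accuracy of DAPC
#'
#' Refits PCA + LDA without each sample in turn and assigns the held-out
#' sample to the nearest group centroid in discriminant space.
#'
#' @inheritParams dapc
#' @return fraction of samples assigned to their true group.
#' @export
dapc_loo_accuracy <- function(tab, groups, n_pc = 24, n_df = 3) {
  X <- dosage_matrix(tab)
  groups <- as.character(groups)
  hits <- vapply(seq_len(nrow(X)), function(i) {
    Xi <- X[-i, , drop = FALSE]
    gi <- groups[-i]
    mu <- colMeans(Xi, na.rm = TRUE)
    nas <- which(is.na(Xi), arr.ind = TRUE)
    if (nrow(nas)) Xi[nas] <- mu[nas[, 2]]
    keep <- which(apply(Xi, 2, function(v) stats::var(v) > 0))
    pr <- prcomp(Xi[, keep, drop = FALSE], center = TRUE)
    npc <- min(n_pc, sum(pr$sdev > 1e-9))
    sc <- pr$x[, seq_len(npc), drop = FALSE]
    m <- suppressWarnings(lda_fit(sc, gi, n_df = n_df))
    x_new <- X[i, keep]
    nax <- is.na(x_new)
    if (any(nax)) x_new[nax] <- mu[keep][nax]
    sc_new <- (x_new - pr$center) %*% pr$rotation[, seq_len(npc), drop = FALSE]
    df_new <- sc_new %*% m$coef
    assign_to_centroids(df_new, m$group_means) == groups[i]
  }, TRUE)
  mean(hits)
}
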