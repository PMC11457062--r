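# DAPC machinery

# two clearly separated groups of dosage vectors
make_two_cluster_matrix <- function(n_per = 6, n_var = 40, seed = 5) {
  set.seed(seed)
  p1 <- rep(c(0.9, 0.1), each = n_var / 2)
  p2 <- rep(c(0.1, 0.9), each = n_var / 2)
  X <- rbind(
    t(replicate(n_per, rbinom(n_var, 2, p1))),
    t(replicate(n_per, rbinom(n_var, 2, p2))))
  rownames(X) <- sprintf("s%02d", seq_len(2 * n_per))
  X
}

test_that("genotype_pca separates clusters and handles edge cases", {
  X <- make_two_cluster_matrix()
  pca <- genotype_pca(X, n_pc = 5)
  grp <- rep(1:2, each = 6)
  # PC1 separates the groups: silhouette-like criterion > 0
  pc1 <- pca$scores[, 1]
  expect_true(max(pc1[grp == 1]) < min(pc1[grp == 2]) ||
                max(pc1[grp == 2]) < min(pc1[grp == 1]))
  expect_true(all(diff(pca$explained[1:5]) <= 1e-12))
  # duplicate sample -> identical scores
  X2 <- rbind(X, X[1, , drop = FALSE])
  pca2 <- genotype_pca(X2, n_pc = 3)
  expect_equal(unname(pca2$scores[13, ]), unname(pca2$scores[1, ]))
  # n_pc beyond rank truncates with warning
  expect_warning(p3 <- genotype_pca(X[1:3, 1:10], n_pc = 10), "rank")
  expect_lte(ncol(p3$scores), 2)
  expect_error(genotype_pca(matrix(1, 4, 5)), "constant")
})

test_that("PCA reconstruction error is non-increasing in n_pc", {
  X <- make_two_cluster_matrix(seed = 6)
  Xc <- scale(X, scale = FALSE)
  pca <- genotype_pca(X, n_pc = 10)
  err <- vapply(1:10, function(k) {
    R <- pca$scores[, 1:k, drop = FALSE] %*%
      t(pca$rotation[, 1:k, drop = FALSE])
    sum((Xc - R)^2)
  }, 0)
  expect_true(all(diff(err) <= 1e-8))
})

test_that("find_clusters selects k by BIC", {
  # scores as in real use ("all principal components kept"): cluster
  # separation lives in the leading dims, noise spreads over many trailing
  # dims — the regime where the k-means BIC has its minimum at the true k
  set.seed(9)
  n_dim <- 50
  mk_cluster <- function(n, shift) {
    m <- matrix(rnorm(n * n_dim), ncol = n_dim)
    m[, 1:2] <- m[, 1:2] + rep(shift, each = n)
    m
  }
  sc <- rbind(mk_cluster(20, c(0, 0)), mk_cluster(20, c(12, 0)),
              mk_cluster(20, c(0, 12)))
  cs <- find_clusters(sc, k_max = 6, seed = 4)
  expect_equal(cs$k, 3L)
  expect_true(all(is.finite(cs$bic)))
  # deterministic under fixed seed
  cs2 <- find_clusters(sc, k_max = 6, seed = 4)
  expect_identical(cs$bic, cs2$bic)
  # single cluster -> k = 1 (40 samples, 39 score dims, as from a PCA
  # keeping all components)
  one <- matrix(rnorm(40 * 39), ncol = 39)
  expect_equal(find_clusters(one, k_max = 4, seed = 1)$k, 1L)
  expect_error(find_clusters(sc, k_max = 0), ">= 1")
  expect_error(find_clusters(sc, k_max = 60), "< n_samples")
})

test_that("lda_fit discriminates real structure, collapses under permutation", {
  X <- make_two_cluster_matrix(n_per = 8, seed = 12)
  grp <- rep(c("g1", "g2"), each = 8)
  pca <- genotype_pca(X, n_pc = 6)
  m <- lda_fit(pca$scores, grp, n_df = 1, rotation = pca$rotation)
  expect_equal(m$accuracy, 1)
  expect_equal(nrow(m$loadings), ncol(X))
  # permuted labels: discrimination collapses (2 retained PCs so training
  # accuracy cannot be inflated by overfitting many axes to random labels)
  m2 <- lda_fit(pca$scores[, 1:2], grp, n_df = 1)
  set.seed(3)
  accs <- replicate(10, {
    suppressWarnings(
      lda_fit(pca$scores[, 1:2], sample(grp), n_df = 1)$accuracy)
  })
  expect_gt(m2$accuracy - mean(accs), 0.3)
  # identical distributions -> near-chance assignment
  set.seed(30)
  Xnull <- matrix(rbinom(16 * 40, 2, 0.5), nrow = 16)
  pn <- genotype_pca(Xnull, n_pc = 6)
  mn <- lda_fit(pn$scores, grp, n_df = 1)
  expect_lt(mn$accuracy, 0.95)
  expect_error(lda_fit(pca$scores, rep("g", 16)), ">= 2 groups")
  expect_error(lda_fit(pca$scores, c("a", rep("b", 15))), ">= 2 samples")
})

test_that("planted diagnostic variants rank in the top loadings", {
  set.seed(17)
  n_per <- 8
  n_var <- 60
  p <- matrix(runif(n_var, 0.3, 0.7), 2, n_var, byrow = TRUE)
  p[1, 1:5] <- 0.02   # variants 1-5 diagnostic between groups
  p[2, 1:5] <- 0.98
  X <- rbind(
    t(replicate(n_per, rbinom(n_var, 2, p[1, ]))),
    t(replicate(n_per, rbinom(n_var, 2, p[2, ]))))
  grp <- rep(c("a", "b"), each = n_per)
  m <- suppressWarnings(dapc(X, grp, n_pc = 6, n_df = 1))
  top5 <- order(m$loadings[, 1], decreasing = TRUE)[1:5]
  expect_setequal(top5, 1:5)
  # snpzip on these loadings recovers the diagnostics
  sel <- m$kept_sites[snpzip_select(m$loadings[, 1])]
  expect_true(all(1:5 %in% sel))
})

test_that("snpzip_select: hand-run Ward on 5 points and edge cases", {
  expect_setequal(snpzip_select(c(0.9, 0.8, 0.01, 0.02, 0.01)), 1:2)
  expect_equal(snpzip_select(0.4), 1L)
  expect_warning(sel <- snpzip_select(rep(0.3, 5)), "equal")
  expect_length(sel, 0)
  # bimodal loadings split at the gap between modes
  set.seed(2)
  lo <- c(runif(20, 0, 0.05), runif(5, 0.6, 0.7))
  expect_setequal(snpzip_select(lo), 21:25)
})

test_that("DAPC assigns synthetic cohort samples to their populations", {
  co <- three_pop_cohort()
  tab <- genotype_table(co$vcf, co$sheet)
  acc <- suppressWarnings(
    dapc_loo_accuracy(tab, tab$sheet$population, n_pc = 10, n_df = 2))
  expect_gte(acc, 0.95)
  # selected k on all PCs is stable across restarts for separated data
  pca <- suppressWarnings(genotype_pca(tab, n_pc = 17))
  ks <- vapply(1:10, function(s)
    find_clusters(pca$scores, k_max = 6, seed = s)$k, 0L)
  expect_equal(length(unique(ks)), 1L)
})
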