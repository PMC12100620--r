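# Normalization, PCA, SNN clustering, quality metrics and marker detection.

norm_mat <- function(m) {
  dimnames(m) <- list(sprintf("k%03d", seq_len(nrow(m))),
                      sprintf("bc%03d", seq_len(ncol(m))))
  m
}

test_that("log-normalization matches its closed form and keeps zeros", {
  m <- norm_mat(matrix(c(1, 1, 0, 3), nrow = 2))
  norm <- log_normalize(m)
  expect_equal(norm[1, 1], log(5001), tolerance = 1e-12)
  expect_equal(norm[2, 1], log(5001), tolerance = 1e-12)
  expect_equal(norm[1, 2], 0)
  # single-entry cell: value independent of the count
  expect_equal(norm[2, 2], log(1 + 10000))
  m2 <- norm_mat(matrix(c(0, 0, 0, 7), nrow = 2))
  expect_warning(n2 <- log_normalize(m2), "zero counts")
  expect_equal(ncol(n2), 1L)
  expect_error(log_normalize(norm_mat(matrix(0, 2, 2))), "all cells")
})

test_that("log-normalization is invariant to per-cell count scaling", {
  set.seed(18)
  m <- norm_mat(matrix(rpois(60, 3), nrow = 6))
  scaled <- m
  scaled[, 2] <- scaled[, 2] * 5L
  expect_equal(as.matrix(log_normalize(m))[, 2],
               as.matrix(log_normalize(scaled))[, 2])
})

test_that("variable features rank by variance with deterministic ties", {
  set.seed(19)
  m <- matrix(1, nrow = 3, ncol = 10)
  m[2, ] <- c(rep(0, 5), rep(8, 5))     # bimodal, highest variance
  m[3, ] <- seq(0.1, 1, length.out = 10)
  m <- norm_mat(m)
  feats <- select_variable_features(m, 2)
  expect_equal(feats[1], "k002")
  expect_false("k001" %in% feats)        # constant feature ranked last
  expect_equal(length(select_variable_features(m, 99)), 3L)
})

test_that("PCA embedding matches the eigendecomposition oracle", {
  set.seed(20)
  for (rep in 1:20) {
    n_cells <- sample(6:15, 1)
    n_feat <- sample(3:8, 1)
    x <- matrix(rnorm(n_feat * n_cells), nrow = n_feat)
    x <- norm_mat(x)
    n_pcs <- sample(1:min(n_feat, n_cells - 1), 1)
    got <- scale_and_pca(x, n_pcs = n_pcs, clip_max = Inf)
    mu <- rowMeans(x); sdv <- apply(x, 1, sd)
    z <- t((x - mu) / sdv)
    want <- oracle_pca_scores(z, n_pcs)
    expect_equal(abs(unname(got)), abs(unname(want)), tolerance = 1e-8)
  }
})

test_that("PCA handles collinear data, rank deficiency and sign fixing", {
  x <- norm_mat(rbind(seq(1, 10), 2 * seq(1, 10) + 3))
  emb <- suppressWarnings(scale_and_pca(x, n_pcs = 2))
  # two perfectly collinear features: one PC carries all variance
  expect_equal(ncol(emb), 1L)
  expect_warning(scale_and_pca(x, n_pcs = 2), "rank")
  expect_error(scale_and_pca(norm_mat(matrix(1:2, ncol = 1))), "2 cells")
  # deterministic: repeated runs give identical (not sign-flipped) scores
  set.seed(21)
  y <- norm_mat(matrix(rnorm(50), nrow = 5))
  expect_identical(scale_and_pca(y, n_pcs = 3), scale_and_pca(y, n_pcs = 3))
})

blob_embedding <- function(centers, n_per, sd = 0.1) {
  do.call(rbind, lapply(seq_along(centers), function(i) {
    cbind(rnorm(n_per, centers[[i]][1], sd), rnorm(n_per, centers[[i]][2], sd))
  }))
}

test_that("SNN clustering separates well-separated blobs", {
  set.seed(22)
  emb <- blob_embedding(list(c(0, 0), c(10, 10)), 50)
  rownames(emb) <- sprintf("c%03d", seq_len(nrow(emb)))
  res <- snn_cluster(emb, seed = 0)
  truth <- rep(1:2, each = 50)
  expect_equal(length(unique(res$labels)), 2L)
  expect_equal(ari(res$labels, truth), 1)

  # all points identical: a single cluster
  same <- matrix(1, nrow = 30, ncol = 2)
  rownames(same) <- sprintf("c%03d", seq_len(30))
  expect_equal(length(unique(snn_cluster(same, seed = 0)$labels)), 1L)

  expect_error(snn_cluster(emb[1:10, ], k_neighbors = 20), "at least")
})

test_that("three planted blobs are recovered across seeds", {
  set.seed(23)
  emb <- blob_embedding(list(c(0, 0), c(10, 0), c(0, 10)), 40)
  rownames(emb) <- sprintf("c%03d", seq_len(nrow(emb)))
  truth <- rep(1:3, each = 40)
  aris <- vapply(1:10, function(s) {
    res <- snn_cluster(emb, seed = s)
    ari(res$labels, truth)
  }, numeric(1))
  expect_true(all(aris >= 0.95))
})

test_that("Davies-Bouldin matches hand values and the loop oracle", {
  emb <- cbind(c(0, 1, 10, 11), 0)
  labels <- c(0, 0, 1, 1)
  expect_equal(davies_bouldin(emb, labels), 0.1)

  pointmass <- cbind(c(0, 0, 5, 5), 0)
  expect_equal(davies_bouldin(pointmass, labels), 0)

  set.seed(24)
  for (rep in 1:10) {
    emb <- matrix(rnorm(60), ncol = 2)
    labels <- sample(1:3, 30, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(davies_bouldin(emb, labels), oracle_dbi(emb, labels))
  }
  expect_error(davies_bouldin(emb, rep(1, 30)), "2 clusters")
})

test_that("silhouette matches the hand example and cluster::silhouette", {
  emb <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  labels <- c(0, 0, 1, 1)
  s <- silhouette_coef(emb, labels)
  expect_equal(s, 0.9293, tolerance = 1e-4)

  set.seed(25)
  for (rep in 1:10) {
    emb <- matrix(rnorm(80), ncol = 2)
    labels <- sample(1:3, 40, replace = TRUE)
    if (length(unique(labels)) < 2) next
    want <- mean(cluster::silhouette(labels, dist(emb))[, "sil_width"])
    expect_equal(silhouette_coef(emb, labels), want, tolerance = 1e-12)
  }

  # random labels on a single blob: silhouette near zero
  emb <- matrix(rnorm(200), ncol = 2)
  expect_lt(abs(silhouette_coef(emb, sample(1:2, 100, TRUE))), 0.1)
})

test_that("DBI and SC move oppositely for correct vs random splits", {
  set.seed(26)
  better_dbi <- 0; better_sc <- 0
  for (s in 1:10) {
    emb <- blob_embedding(list(c(0, 0), c(8, 8)), 30)
    truth <- rep(1:2, each = 30)
    rnd <- sample(truth)
    better_dbi <- better_dbi + (davies_bouldin(emb, truth) <
                                  davies_bouldin(emb, rnd))
    better_sc <- better_sc + (silhouette_coef(emb, truth) >
                                silhouette_coef(emb, rnd))
  }
  expect_equal(better_dbi, 10)
  expect_equal(better_sc, 10)
})

test_that("marker detection gates, scores and ranks features", {
  set.seed(27)
  n <- 40
  labels <- rep(0:1, each = 20)
  m <- matrix(0, nrow = 3, ncol = n)
  m[1, labels == 0] <- rpois(20, 20) + 5   # on in cluster 0, off elsewhere
  m[2, ] <- rpois(n, 10) + 1               # uninformative, everywhere
  m[3, sample(which(labels == 0), 2)] <- 5 # below min.pct in both groups
  m <- norm_mat(m)
  norm <- log_normalize(m)
  res <- find_markers(norm, labels)
  expect_true("k001" %in% res$kmer[res$cluster == 0])
  r1 <- res[res$kmer == "k001" & res$cluster == 0, ]
  expect_equal(r1$pct_in, 1)
  expect_equal(r1$pct_out, 0)
  expect_gte(r1$adjusted_p, r1$p_value)
  expect_false("k003" %in% res$kmer)          # min.pct gate
  expect_true(all(pmax(res$pct_in, res$pct_out) >= 0.25))
  expect_true(all(res$log_fc >= 0.25))
  expect_true(!is.unsorted(res$adjusted_p))
  expect_error(find_markers(norm, rep(0, n)), "2 clusters")
})

test_that("marker fold change follows the expm1-mean formula", {
  set.seed(28)
  labels <- rep(0:1, each = 15)
  vals <- c(rlnorm(15, 2, 0.2), rlnorm(15, 0.2, 0.2))
  norm <- norm_mat(matrix(vals, nrow = 1))
  res <- find_markers(norm, labels, min_pct = 0, logfc_threshold = 0)
  want <- log(mean(expm1(vals[1:15])) + 1) - log(mean(expm1(vals[16:30])) + 1)
  expect_equal(res$log_fc[res$cluster == 0], want, tolerance = 1e-12)
})
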