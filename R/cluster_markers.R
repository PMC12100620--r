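# Normalization, PCA, shared-nearest-neighbour clustering, clustering
# quality metrics and marker K-mer detection on the cell-by-HCK matrix.

#' Log-normalize a cell-by-HCK count matrix
#'
#' Per cell j and HCK i with count c and cell total t:
#' `ln(1 + scale_factor * c / t)`. Zero counts map to zero exactly, so
#' sparsity is preserved. Cells with zero total counts are dropped with a
#' warning.
#'
#' @param m Features-by-cells count matrix (sparse `dgCMatrix` or dense).
#' @param scale_factor Library-size scale factor (default 10000).
#' @return Features-by-cells `dgCMatrix` of normalized values.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  totals <- Matrix::colSums(m)
  if (all(totals == 0)) stop("all cells have zero counts")
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero counts dropped")
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  percell <- rep.int(totals, diff(m@p))
  m@x <- log1p(m@x / percell * scale_factor)
  m
}

#' Select the most variable HCK features
#'
#' Ranks features by the variance of their normalized values across cells
#' (ties broken lexicographically by feature name) and keeps the top
#' `nfeatures`.
#'
#' @param norm Normalized features-by-cells matrix from [log_normalize()].
#' @param nfeatures Number of features to keep (default 6000).
#' @return Character vector of selected feature names, variance-descending.
#' @export
select_variable_features <- function(norm, nfeatures = 6000) {
  stopifnot(nfeatures >= 1)
  n <- ncol(norm)
  if (n < 2L) stop("need at least 2 cells to rank feature variance")
  mu <- Matrix::rowMeans(norm)
  ssq <- Matrix::rowSums(norm^2)
  v <- (ssq - n * mu^2) / (n - 1)
  ord <- order(-v, rownames(norm))
  rownames(norm)[ord][seq_len(min(nfeatures, nrow(norm)))]
}

#' Scale features and embed cells by PCA
#'
#' Each selected feature is z-scored across cells (values clipped at +10),
#' then cells are projected onto the top principal components of the scaled
#' matrix. Each component's sign is fixed so its largest-magnitude loading
#' is positive, making the embedding deterministic.
#'
#' @param norm Normalized features-by-cells matrix.
#' @param features Feature subset to use (default: all rows).
#' @param n_pcs Number of principal components (default 30; silently
#'   reduced to the matrix rank with a warning).
#' @param clip_max Upper clip for z-scores (default 10).
#' @return Cells-by-PCs numeric score matrix (rownames = barcodes).
#' @export
scale_and_pca <- function(norm, features = rownames(norm), n_pcs = 30,
                          clip_max = 10) {
  if (ncol(norm) < 2L) stop("PCA needs at least 2 cells")
  x <- as.matrix(norm[features, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all selected features are constant")
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  z[z > clip_max] <- clip_max
  pr <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  avail <- sum(pr$sdev > pr$sdev[1] * 1e-8)
  if (n_pcs > avail) {
    warning("requested ", n_pcs, " PCs but rank is ", avail)
    n_pcs <- avail
  }
  rot <- pr$rotation[, seq_len(n_pcs), drop = FALSE]
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  for (c in seq_len(n_pcs)) {
    j <- which.max(abs(rot[, c]))
    if (rot[j, c] < 0) {
      rot[, c] <- -rot[, c]
      scores[, c] <- -scores[, c]
    }
  }
  rownames(scores) <- colnames(norm)
  scores
}

#' Shared-nearest-neighbour graph clustering
#'
#' k-nearest neighbours by Euclidean distance in the embedding; the SNN
#' edge weight between two cells is the Jaccard overlap of their neighbour
#' sets (each set includes the cell itself); edges below `prune` are
#' removed; communities are found by modularity optimization (Louvain) at
#' the given resolution with a fixed seed. Labels are 0-based, ordered by
#' decreasing cluster size.
#'
#' @param embedding Cells-by-dims numeric matrix.
#' @param k_neighbors Neighbourhood size (default 20).
#' @param resolution Modularity resolution (default 0.5).
#' @param prune Minimum Jaccard weight kept (default 1/15).
#' @param seed Random seed for community detection.
#' @return A `cluster_result`: list with `labels` (named integer vector),
#'   `embedding`, `resolution`, `n_pcs`, `k_neighbors`.
#' @export
snn_cluster <- function(embedding, k_neighbors = 20, resolution = 0.5,
                        prune = 1 / 15, seed = 0) {
  n <- nrow(embedding)
  if (n < k_neighbors + 1L) {
    stop("need at least k_neighbors + 1 = ", k_neighbors + 1L, " cells")
  }
  d <- as.matrix(stats::dist(embedding))
  # neighbour sets: self plus the k nearest others (ties by index)
  nb <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ], decreasing = FALSE)
    ord <- ord[ord != i]
    c(i, ord[seq_len(k_neighbors)])
  })
  memb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) memb[i, nb[[i]]] <- TRUE
  shared <- tcrossprod(memb * 1)              # |A intersect B|
  sizes <- rowSums(memb)
  uni <- outer(sizes, sizes, "+") - shared    # |A union B|
  w <- shared / uni
  w[w < prune] <- 0
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(comm)
  sz <- table(raw)
  relabel <- stats::setNames(seq_along(sz) - 1L,
                             names(sort(sz, decreasing = TRUE)))
  labels <- as.integer(relabel[as.character(raw)])
  names(labels) <- rownames(embedding)
  structure(list(labels = labels, embedding = embedding,
                 resolution = resolution, n_pcs = ncol(embedding),
                 k_neighbors = k_neighbors),
            class = "cluster_result")
}

cluster_labels <- function(labels) {
  if (inherits(labels, "cluster_result")) labels$labels else labels
}

#' Davies-Bouldin index of a clustering
#'
#' Mean over clusters of the worst (largest) ratio
#' `(s_i + s_j) / d_ij`, with `s_i` the mean Euclidean distance of cluster
#' i's points to their centroid and `d_ij` the distance between centroids.
#' Lower is better.
#'
#' @param embedding Cells-by-dims matrix.
#' @param labels Cluster labels (vector or `cluster_result`).
#' @return DBI (numeric >= 0).
#' @export
davies_bouldin <- function(embedding, labels) {
  labels <- cluster_labels(labels)
  cl <- sort(unique(labels))
  k <- length(cl)
  if (k < 2L) stop("Davies-Bouldin index needs at least 2 clusters")
  cent <- t(vapply(cl, function(c) colMeans(embedding[labels == c, , drop = FALSE]),
                   numeric(ncol(embedding))))
  s <- vapply(seq_len(k), function(i) {
    pts <- embedding[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - rep(cent[i, ], each = nrow(pts)))^2)))
  }, numeric(1))
  dm <- as.matrix(stats::dist(cent))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (s[i] + s[j]) / dm[i, j], numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Silhouette coefficient of a clustering
#'
#' Mean over points of `(b - a) / max(a, b)` with `a` the mean distance to
#' the point's own cluster (excluding itself) and `b` the smallest mean
#' distance to another cluster; singleton clusters score 0. Higher is
#' better; values lie between -1 and 1.
#'
#' @param embedding Cells-by-dims matrix.
#' @param labels Cluster labels (vector or `cluster_result`).
#' @return SC (numeric between -1 and 1).
#' @export
silhouette_coef <- function(embedding, labels) {
  labels <- cluster_labels(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("silhouette needs at least 2 clusters")
  d <- as.matrix(stats::dist(embedding))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]),
                    function(c) mean(d[i, labels == c]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Marker K-mers per cluster (Wilcoxon rank-sum test)
#'
#' For every cluster and every HCK expressed (normalized value > 0) in at
#' least `min_pct` of the cluster's cells or of the remaining cells, a
#' two-sided Wilcoxon rank-sum test compares normalized values inside
#' versus outside the cluster. The fold change is
#' `ln(mean(expm1(in)) + 1) - ln(mean(expm1(out)) + 1)`. Only positive
#' markers with `log_fc >= logfc_threshold` are kept. P-values receive a
#' Bonferroni correction over features x clusters tests.
#'
#' @param norm Normalized features-by-cells matrix from [log_normalize()].
#' @param labels Cluster labels (vector aligned with columns, or a
#'   `cluster_result`).
#' @param min_pct Minimum expression fraction gate (default 0.25).
#' @param logfc_threshold Minimum natural-log fold change (default 0.25).
#' @return Data.frame with columns `kmer`, `cluster`, `p_value`,
#'   `adjusted_p`, `log_fc`, `pct_in`, `pct_out`, sorted by adjusted p then
#'   fold change.
#' @export
find_markers <- function(norm, labels, min_pct = 0.25,
                         logfc_threshold = 0.25) {
  labels <- cluster_labels(labels)
  stopifnot(length(labels) == ncol(norm))
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("marker detection needs at least 2 clusters")
  x <- as.matrix(norm)
  n_tests <- nrow(x) * length(cl)
  out <- list()
  for (c in cl) {
    inc <- labels == c
    pct_in <- rowMeans(x[, inc, drop = FALSE] > 0)
    pct_out <- rowMeans(x[, !inc, drop = FALSE] > 0)
    gate <- pmax(pct_in, pct_out) >= min_pct
    if (!any(gate)) next
    mean_in <- rowMeans(expm1(x[gate, inc, drop = FALSE]))
    mean_out <- rowMeans(expm1(x[gate, !inc, drop = FALSE]))
    log_fc <- log(mean_in + 1) - log(mean_out + 1)
    keep <- log_fc >= logfc_threshold
    if (!any(keep)) next
    feats <- rownames(x)[gate][keep]
    p <- vapply(feats, function(f) {
      suppressWarnings(stats::wilcox.test(x[f, inc], x[f, !inc],
                                          alternative = "two.sided")$p.value)
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      kmer = feats, cluster = c, p_value = unname(p),
      adjusted_p = pmin(unname(p) * n_tests, 1),
      log_fc = unname(log_fc[keep]),
      pct_in = unname(pct_in[gate][keep]),
      pct_out = unname(pct_out[gate][keep]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(kmer = character(), cluster = integer(),
                      p_value = numeric(), adjusted_p = numeric(),
                      log_fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$adjusted_p, -res$log_fc), ]
  rownames(res) <- NULL
  res
}
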