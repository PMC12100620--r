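# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and its vectorized idioms): plain loops and closed forms only.

oracle_count_kmers <- function(seqs, K) {
  env <- new.env()
  for (s in seqs) {
    L <- nchar(s)
    if (L < K) next
    for (j in seq_len(L - K + 1)) {
      w <- substr(s, j, j + K - 1)
      if (grepl("[^ACGT]", w)) next
      env[[w]] <- (if (is.null(env[[w]])) 0L else env[[w]]) + 1L
    }
  }
  ks <- ls(env)
  stats::setNames(vapply(ks, function(k) env[[k]], integer(1)), ks)
}

oracle_cell_vector <- function(reads, kmers, K) {
  out <- stats::setNames(integer(length(kmers)), kmers)
  for (s in reads) {
    L <- nchar(s)
    if (L < K) next
    for (j in seq_len(L - K + 1)) {
      w <- substr(s, j, j + K - 1)
      if (w %in% kmers) out[w] <- out[w] + 1L
    }
  }
  out
}

# exhaustive max-|slope| scan over adjacent log-log differences within the
# central 80% of the log-rank range, first index wins
oracle_knee <- function(x, y) {
  u <- log10(x)
  v <- log10(y)
  lo <- u[1] + 0.1 * (u[length(u)] - u[1])
  hi <- u[1] + 0.9 * (u[length(u)] - u[1])
  best <- -Inf
  best_i <- NA_integer_
  for (i in seq_len(length(x) - 1)) {
    if (u[i] < lo || u[i] > hi) next
    slope <- abs((v[i + 1] - v[i]) / (u[i + 1] - u[i]))
    if (slope > best + 1e-12) {
      best <- slope
      best_i <- i
    }
  }
  x[best_i]
}

# recursive leaf-to-root sum
oracle_aggregate <- function(taxids, tree) {
  direct <- stats::setNames(numeric(nrow(tree)), as.character(tree$node_id))
  for (t in taxids) {
    if (t == 0) next
    direct[as.character(t)] <- direct[as.character(t)] + 1
  }
  root <- tree$node_id[tree$parent_id == tree$node_id | tree$parent_id == 0]
  recurse <- function(node) {
    kids <- tree$node_id[tree$parent_id == node & tree$node_id != node]
    direct[as.character(node)] + sum(vapply(kids, recurse, numeric(1)))
  }
  stats::setNames(vapply(tree$node_id, recurse, numeric(1)),
                  as.character(tree$node_id))
}

# exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# assignments (tie-free data only)
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_obs <- sum(outer(x, y, ">"))
  r <- rank(c(x, y))
  subsets <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- if (u_obs > n1 * n2 / 2) 2 * mean(u_all >= u_obs) else
    2 * mean(u_all <= u_obs)
  min(p, 1)
}

# exact hypergeometric upper tail P[X >= k] by choose() summation
oracle_hyper_tail <- function(k, K_bg, N_bg, n) {
  i <- k:min(n, K_bg)
  if (k > min(n, K_bg)) return(0)
  sum(choose(K_bg, i) * choose(N_bg - K_bg, n - i)) / choose(N_bg, n)
}

# PCA scores via eigendecomposition of the (feature-centred) scatter matrix
# on an already-scaled cells-by-features matrix
oracle_pca_scores <- function(z, n_pcs) {
  e <- eigen(crossprod(z) / (nrow(z) - 1), symmetric = TRUE)
  (z %*% e$vectors)[, seq_len(n_pcs), drop = FALSE]
}

oracle_dbi <- function(emb, labels) {
  cl <- sort(unique(labels))
  k <- length(cl)
  cent <- list(); s <- numeric(k)
  for (i in seq_len(k)) {
    pts <- emb[labels == cl[i], , drop = FALSE]
    cent[[i]] <- colMeans(pts)
    tot <- 0
    for (r in seq_len(nrow(pts))) tot <- tot + sqrt(sum((pts[r, ] - cent[[i]])^2))
    s[i] <- tot / nrow(pts)
  }
  acc <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      worst <- max(worst, (s[i] + s[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2)))
    }
    acc <- acc + worst
  }
  acc / k
}

# brute-force group-by deduplication: max mean quality, earliest on ties,
# output by first occurrence
oracle_dedup_rows <- function(ids, quals) {
  qa <- vapply(quals, function(q) mean(utf8ToInt(q) - 33), numeric(1))
  keep <- integer()
  for (id in unique(ids)) {
    rows <- which(ids == id)
    keep <- c(keep, rows[which.max(qa[rows])])
  }
  keep
}

# standard-genetic-code translation written from an explicit codon table
oracle_translate <- function(dna) {
  codons <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  n <- nchar(dna) %/% 3
  paste(vapply(seq_len(n), function(i) {
    codons[[substr(dna, 3 * i - 2, 3 * i)]]
  }, character(1)), collapse = "")
}

oracle_revcomp <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(dna, "")[[1]]]), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# adjusted Rand index between two labelings (closed form from the
# contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# tiny simulated experiment shared by module tests
small_sim <- function(seed = 11, ...) {
  args <- list(n_species = 2L, cells_per_species = 10L, reads_per_cell = 50L,
               genome_len = 300L, read_len = 80L, n_noise_barcodes = 40L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  simulate_community(do.call(sim_config, args))
}
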