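# End-to-end convenience wrapper: raw paired reads to clusters, markers and
# per-cell annotation. Each stage is an exported function; this function
# only chains them with the standard defaults.

#' Run the reference-free smRNA-seq pipeline
#'
#' Chains whitelisting, barcode/UMI extraction, quality deduplication,
#' K-mer counting, rank-curve knee detection, HCK selection, cell-by-HCK
#' matrix construction, normalization, PCA, SNN clustering and marker
#' detection; when a classification table and taxonomy are supplied,
#' per-cell species annotation is added.
#'
#' @param r1,r2 Paired read records (data.frames from [read_fastq()]).
#' @param classifications Optional per-read classification table
#'   (see [read_classifications()]).
#' @param taxonomy Optional `taxonomy_table`.
#' @param k K-mer length (default 12).
#' @param set_cell_number Force the whitelist size (default: knee of the
#'   barcode rank curve).
#' @param expect_cells Cap on barcodes scanned for the whitelist knee.
#' @param topkmer Number of HCKs for the matrix (default: knee of the
#'   K-mer rank curve).
#' @param nfeatures Variable features for PCA (default 6000).
#' @param n_pcs Principal components (default 30).
#' @param k_neighbors SNN neighbourhood size (default 20; reduced when few
#'   cells).
#' @param resolution Community-detection resolution (default 0.5).
#' @param min_pct,logfc_threshold Marker gates (defaults 0.25, 0.25).
#' @param seed Seed for community detection.
#' @return List with `whitelist`, `clean_reads`, `spectrum`, `kmer_curve`,
#'   `kmer_knee`, `hck`, `matrix`, `normalized`, `embedding`, `clusters`,
#'   `markers`, `dbi`, `silhouette`, and (if inputs given) `annotation`.
#' @export
run_pipeline <- function(r1, r2, classifications = NULL, taxonomy = NULL,
                         k = 12L, set_cell_number = NULL,
                         expect_cells = 10000L, topkmer = NULL,
                         nfeatures = 6000L, n_pcs = 30L, k_neighbors = 20L,
                         resolution = 0.5, min_pct = 0.25,
                         logfc_threshold = 0.25, seed = 0L) {
  pattern <- default_bc_pattern()
  wl <- build_whitelist(r1, pattern, expect_cells = expect_cells,
                        set_cell_number = set_cell_number)
  clean <- extract_reads(r1, r2, pattern, wl)
  clean <- dedup_reads(clean)
  spec <- count_kmers(clean$seq, k)
  curve <- rank_curve(spec)
  knee <- knee_point(curve)
  n_hck <- if (is.null(topkmer)) knee else min(topkmer, length(spec$counts))
  hck <- select_hck(spec, n_hck, clean$seq)
  m <- build_cell_matrix(clean, hck)
  norm <- log_normalize(m)
  feats <- select_variable_features(norm, nfeatures)
  npc <- min(n_pcs, ncol(norm) - 1L)
  emb <- scale_and_pca(norm, feats, n_pcs = npc)
  kn <- min(k_neighbors, nrow(emb) - 1L)
  clusters <- snn_cluster(emb, k_neighbors = kn, resolution = resolution,
                          seed = seed)
  n_cl <- length(unique(clusters$labels))
  markers <- if (n_cl >= 2L) {
    find_markers(norm, clusters, min_pct = min_pct,
                 logfc_threshold = logfc_threshold)
  } else NULL
  out <- list(whitelist = wl, clean_reads = clean, spectrum = spec,
              kmer_curve = curve, kmer_knee = knee, hck = hck, matrix = m,
              normalized = norm, embedding = emb, clusters = clusters,
              markers = markers,
              dbi = if (n_cl >= 2L) davies_bouldin(emb, clusters) else NA_real_,
              silhouette = if (n_cl >= 2L) silhouette_coef(emb, clusters)
                           else NA_real_)
  if (!is.null(classifications) && !is.null(taxonomy)) {
    keep <- classifications$barcode %in% colnames(m)
    out$annotation <- annotate_cells(classifications[keep, , drop = FALSE],
                                     taxonomy)
  }
  out
}
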