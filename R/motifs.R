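# Marker K-mer to motif conversions: six-frame translation with the
# full-length retention rule, and hypergeometric GO enrichment from a
# user-supplied motif-to-GO mapping.

#' Six-frame translation of marker K-mers
#'
#' Each K-mer is translated in the three forward frames and the three
#' frames of its reverse complement (standard genetic code, complete codons
#' only). Only peptides of the full length K/3 (frames +1 and -1 when K is
#' a multiple of 3) that contain no stop codon are retained: for the
#' default K = 12, exactly the stop-free 4-amino-acid peptides.
#'
#' @param kmers Character vector of A/C/G/T K-mers (one length).
#' @return Data.frame with columns `aa_seq`, `frame` (one of `+1 +2 +3 -1
#'   -2 -3`), `source_kmer`; zero rows (with a warning) when K is not a
#'   multiple of 3.
#' @export
six_frame_translate <- function(kmers) {
  if (length(kmers) == 0L) {
    return(data.frame(aa_seq = character(), frame = character(),
                      source_kmer = character(), stringsAsFactors = FALSE))
  }
  if (any(grepl("[^ACGT]", kmers))) stop("K-mers must be over A/C/G/T")
  K <- unique(nchar(kmers))
  if (length(K) > 1L) stop("K-mers must share one length")
  if (K %% 3L != 0L) {
    warning("K = ", K, " is not a multiple of 3; no frame yields a ",
            "full-length peptide")
    return(data.frame(aa_seq = character(), frame = character(),
                      source_kmer = character(), stringsAsFactors = FALSE))
  }
  target_len <- K %/% 3L
  fwd <- kmers
  rev <- revcomp(kmers)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  code <- Biostrings::GENETIC_CODE  # standard code; '*' marks stops
  out <- list()
  for (f in seq_along(frames)) {
    src <- if (f <= 3L) fwd else rev
    off <- ((f - 1L) %% 3L) + 1L
    n_codons <- (K - off + 1L) %/% 3L
    starts <- off + 3L * (seq_len(n_codons) - 1L)
    aa_mat <- vapply(starts, function(s)
      code[substring(src, s, s + 2L)], character(length(src)))
    aa <- if (n_codons == 0L) character(length(src)) else
      apply(matrix(aa_mat, nrow = length(src)), 1L, paste, collapse = "")
    keep <- nchar(aa) == target_len & !grepl("*", aa, fixed = TRUE)
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        aa_seq = aa[keep], frame = frames[f], source_kmer = kmers[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(aa_seq = character(), frame = character(),
                      source_kmer = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # stable order: by input K-mer, then frame order as listed above
  res <- res[order(match(res$source_kmer, kmers), match(res$frame, frames)), ]
  rownames(res) <- NULL
  res
}

#' GO term enrichment of a marker set by the hypergeometric test
#'
#' For each GO term, the upper-tail hypergeometric probability of observing
#' at least `k` annotated markers among `n` drawn from a background of
#' `N_bg` features of which `K_bg` carry the term. P-values are adjusted by
#' Benjamini-Hochberg (or Bonferroni).
#'
#' @param marker_terms Named list: marker -> character vector of GO ids.
#' @param background_terms Named list: feature -> character vector of GO
#'   ids; must contain every marker.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return Data.frame with columns `go_id`, `k`, `n`, `K_bg`, `N_bg`,
#'   `p_value`, `adjusted_p`, sorted by adjusted then raw p-value.
#' @export
go_enrich <- function(marker_terms, background_terms, adjust = "BH") {
  if (!all(names(marker_terms) %in% names(background_terms))) {
    stop("marker(s) absent from the background: ",
         paste(utils::head(setdiff(names(marker_terms),
                                   names(background_terms))), collapse = ", "))
  }
  n <- length(marker_terms)
  N_bg <- length(background_terms)
  terms <- sort(unique(unlist(background_terms)))
  res <- lapply(terms, function(term) {
    K_bg <- sum(vapply(background_terms, function(t) term %in% t, logical(1)))
    k <- sum(vapply(marker_terms, function(t) term %in% t, logical(1)))
    p <- stats::phyper(k - 1L, K_bg, N_bg - K_bg, n, lower.tail = FALSE)
    data.frame(go_id = term, k = k, n = n, K_bg = K_bg, N_bg = N_bg,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = adjust)
  out <- out[order(out$adjusted_p, out$p_value, out$go_id), ]
  rownames(out) <- NULL
  out
}

#' Read a feature-to-GO mapping table
#'
#' Two tab-separated columns without header: feature id (marker K-mer or
#' motif id) and a comma-separated list of GO ids.
#'
#' @param path Path to the TSV.
#' @return Named list: feature -> character vector of GO ids.
#' @export
read_go_mapping <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(lapply(strsplit(df[[2]], ","), trimws), df[[1]])
}
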