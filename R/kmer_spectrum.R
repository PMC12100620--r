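# K-mer scanning/counting over reads and K-mer frequency-spectrum analysis,
# including the optimal-K rule.

# All sliding windows of length K over each sequence, as a data.table with
# the originating sequence index. Windows containing any non-ACGT symbol are
# skipped entirely (no phantom K-mers).
extract_windows <- function(seqs, K) {
  K <- as.integer(K)
  L <- nchar(seqs)
  nw <- pmax(L - K + 1L, 0L)
  idx <- rep.int(seq_along(seqs), nw)
  if (length(idx) == 0L) {
    return(data.table::data.table(idx = integer(), kmer = character()))
  }
  starts <- sequence(nw)
  km <- substring(seqs[idx], starts, starts + K - 1L)
  dirty <- grepl("[^ACGT]", seqs, perl = TRUE)
  if (any(dirty)) {
    check <- dirty[idx]
    bad <- logical(length(km))
    bad[check] <- grepl("[^ACGT]", km[check], perl = TRUE)
    idx <- idx[!bad]
    km <- km[!bad]
  }
  data.table::data.table(idx = idx, kmer = km)
}

# reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Count K-mers across a set of sequences
#'
#' Every length-K window of every sequence containing only A/C/G/T
#' increments the count of that K-mer; windows overlapping any other symbol
#' are skipped; sequences shorter than K contribute nothing. Counting is on
#' the forward strand by default (stranded cDNA); `canonical = TRUE` pools a
#' K-mer with its reverse complement and keys the pair by the
#' lexicographically smaller of the two.
#'
#' @param seqs Character vector of nucleotide sequences (or a read
#'   data.frame with a `seq` column).
#' @param K K-mer length (>= 1).
#' @param canonical Pool reverse-complement pairs?
#' @return A `kmer_spectrum`: list with `K` and `counts` (named integer
#'   vector, all counts >= 1).
#' @export
count_kmers <- function(seqs, K, canonical = FALSE) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  K <- as.integer(K)
  if (is.na(K) || K <= 0L) stop("K must be a positive integer")
  win <- extract_windows(seqs, K)
  if (canonical && nrow(win)) {
    rc <- revcomp(win$kmer)
    win$kmer <- pmin(win$kmer, rc)
  }
  kmer <- NULL # data.table NSE
  tab <- win[, .N, by = kmer]
  counts <- stats::setNames(tab$N, tab$kmer)
  structure(list(K = K, counts = counts, canonical = canonical),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("K-mer spectrum: K =", x$K, "|", length(x$counts), "distinct K-mers |",
      format(sum(as.numeric(x$counts)), big.mark = ","), "occurrences\n")
  invisible(x)
}

#' K-mer frequency histogram of a spectrum
#'
#' Bins the spectrum by occurrence count: `n_kmers[x]` is the number of
#' distinct K-mers detected exactly `x` times.
#'
#' @param spec A `kmer_spectrum`.
#' @return A `spectrum_histogram`: list with `K`, `frequency` (ascending)
#'   and `n_kmers`.
#' @export
spectrum_histogram <- function(spec) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  if (length(spec$counts) == 0L) stop("empty spectrum")
  tab <- table(spec$counts)
  structure(list(K = spec$K,
                 frequency = as.integer(names(tab)),
                 n_kmers = as.integer(tab)),
            class = "spectrum_histogram")
}

histogram_mode <- function(histo) {
  # argmax of n_kmers over frequency; ties resolved to the smaller frequency
  ord <- order(histo$frequency)
  f <- histo$frequency[ord]
  n <- histo$n_kmers[ord]
  f[which.max(n)]
}

#' Select the optimal K from frequency histograms at several K values
#'
#' Returns the smallest K whose histogram peaks at frequency `x = 1`
#' (singletons dominate, the signature of ~1x random-primed coverage). If no
#' candidate qualifies, the largest K provided is returned with a warning.
#'
#' @param histos Named list mapping K (names coercible to integer) to
#'   `spectrum_histogram` objects.
#' @return The selected K (integer).
#' @export
select_optimal_k <- function(histos) {
  if (length(histos) == 0L) stop("no histograms supplied")
  ks <- as.integer(names(histos))
  if (anyNA(ks)) stop("histogram list must be named by K")
  ord <- order(ks)
  for (i in ord) {
    if (histogram_mode(histos[[i]]) == 1L) return(ks[i])
  }
  warning("no K has its frequency peak at x = 1; returning the largest K")
  max(ks)
}
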