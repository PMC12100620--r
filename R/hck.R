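# K-mer rank-curve construction, knee-point detection and HCK selection.
# The same knee detector serves the barcode rank plot in preprocessing.

#' Rank curve of a named count vector
#'
#' Items are sorted by count descending (ties broken lexicographically by
#' name, so the curve is deterministic); the curve value at rank x is the
#' cumulative mean count of the top-x items.
#'
#' @param counts Named integer/numeric vector of counts.
#' @return A `rank_curve` data.frame with columns `rank`, `item`, `count`,
#'   `cum_mean` (non-increasing).
#' @export
rank_curve_from_counts <- function(counts) {
  if (length(counts) == 0L) stop("empty counts")
  nm <- names(counts)
  if (is.null(nm)) nm <- as.character(seq_along(counts))
  ord <- order(-as.numeric(counts), nm)
  cs <- as.numeric(counts[ord])
  out <- data.frame(rank = seq_along(cs), item = nm[ord], count = cs,
                    cum_mean = cumsum(cs) / seq_along(cs),
                    stringsAsFactors = FALSE)
  class(out) <- c("rank_curve", "data.frame")
  out
}

#' K-mer rank curve of a spectrum
#'
#' @param spec A `kmer_spectrum`.
#' @return A `rank_curve`; see [rank_curve_from_counts()].
#' @export
rank_curve <- function(spec) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  rank_curve_from_counts(spec$counts)
}

#' Knee point of a rank curve
#'
#' Rank and cumulative mean count are transformed to log10 scales and
#' first-order finite differences (adjacent-point slopes) are taken within
#' the central 80% of the log-rank range. The knee is the rank at the first
#' slope of maximum absolute value. On a flat curve (all slopes zero) the
#' first rank inside the window is returned with a warning.
#'
#' @param curve A `rank_curve` (length >= 5, all values positive).
#' @return Integer knee rank.
#' @export
knee_point <- function(curve) {
  n <- nrow(curve)
  if (is.null(n) || n < 5L) stop("rank curve must have at least 5 points")
  y <- curve$cum_mean
  if (any(y <= 0)) stop("rank curve values must be positive (log undefined)")
  u <- log10(curve$rank)
  v <- log10(y)
  d <- diff(v) / diff(u)
  span <- u[n] - u[1L]
  lo <- u[1L] + 0.1 * span
  hi <- u[1L] + 0.9 * span
  # a slope indexed i spans ranks i..i+1; keep slopes whose left point is
  # inside the central window
  win <- which(u[-n] >= lo & u[-n] <= hi)
  if (length(win) == 0L) win <- seq_len(n - 1L)
  if (all(abs(d[win]) < .Machine$double.eps^0.5)) {
    warning("flat rank curve; knee undefined, returning first interior rank")
    return(as.integer(curve$rank[win[1L]]))
  }
  # first slope within numerical tolerance of the maximum (exactly tied
  # slopes differ by float noise after the log/division round trip)
  a <- abs(d[win])
  i <- win[which(a >= max(a) * (1 - 1e-9))[1L]]
  as.integer(curve$rank[i])
}

#' Select high-frequency conserved K-mers (HCKs)
#'
#' Takes the top-N K-mers of the descending count sort (ties lexicographic)
#' and computes, for each, its total occurrence count `T` and its read
#' incidence `A` (number of reads containing it at least once) in one pass
#' over the reads.
#'
#' @param spec A `kmer_spectrum`.
#' @param N Number of HCKs to keep (1 <= N <= distinct K-mers), typically
#'   the knee rank of the K-mer rank curve.
#' @param reads Character vector of read sequences (or read data.frame).
#' @return An `hck_set`: list with `K`, `kmers` (descending by count), `T`,
#'   `A`, `N`.
#' @export
select_hck <- function(spec, N, reads) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  if (is.data.frame(reads)) reads <- reads$seq
  N <- as.integer(N)
  if (is.na(N) || N < 1L || N > length(spec$counts)) {
    stop("N must be between 1 and the number of distinct K-mers (",
         length(spec$counts), ")")
  }
  curve <- rank_curve(spec)
  kmers <- curve$item[seq_len(N)]
  Tk <- as.integer(curve$count[seq_len(N)])
  win <- extract_windows(reads, spec$K)
  idx <- kmer <- NULL # data.table NSE
  hits <- unique(win[kmer %in% kmers], by = c("idx", "kmer"))
  atab <- hits[, .N, by = kmer]
  A <- stats::setNames(integer(N), kmers)
  A[atab$kmer] <- atab$N
  structure(list(K = spec$K, kmers = kmers,
                 T = stats::setNames(Tk, kmers), A = A, N = N),
            class = "hck_set")
}

#' @export
print.hck_set <- function(x, ...) {
  cat("HCK set: K =", x$K, "| N =", x$N, "K-mers | depth range [",
      min(x$T), ",", max(x$T), "]\n")
  invisible(x)
}
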