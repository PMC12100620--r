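# Construction of the sparse cell-by-HCK occurrence matrix.

#' HCK occurrence vector for one cell
#'
#' Counts, for each HCK, the total number of sliding-window matches across
#' the cell's reads (overlapping matches all count; windows containing
#' non-ACGT symbols are skipped).
#'
#' @param reads Character vector of the cell's read sequences (or a read
#'   data.frame).
#' @param hck An `hck_set`.
#' @return Named integer vector over `hck$kmers`.
#' @export
cell_vector <- function(reads, hck) {
  stopifnot(inherits(hck, "hck_set"))
  if (length(hck$kmers) == 0L) stop("empty HCK set")
  if (is.data.frame(reads)) reads <- reads$seq
  v <- stats::setNames(integer(length(hck$kmers)), hck$kmers)
  if (length(reads) == 0L) return(v)
  win <- extract_windows(reads, hck$K)
  m <- match(win$kmer, hck$kmers)
  m <- m[!is.na(m)]
  if (length(m)) {
    t <- tabulate(m, nbins = length(hck$kmers))
    v[] <- t
  }
  v
}

#' Build the cell-by-HCK matrix
#'
#' Reads are grouped into cells by the barcode (first 20 characters of the
#' `<barcode>_<UMI>` identifier); each cell contributes one HCK occurrence
#' vector. Cells are processed in chunks of `chunk_cells` whose partial
#' matrices are merged; the result is independent of the chunk size and of
#' read order within a cell. Cells without any HCK content are kept as
#' explicit zero columns so that columns stay aligned with the whitelist.
#'
#' @param reads Read records with `identifier` set (output of
#'   [dedup_reads()]).
#' @param hck An `hck_set`.
#' @param chunk_cells Number of cells per processing chunk (default 1000).
#' @return A features-by-cells `dgCMatrix` (rows = HCKs in `hck$kmers`
#'   order, columns = barcodes by first appearance), with attribute `K`.
#' @export
build_cell_matrix <- function(reads, hck, chunk_cells = 1000L) {
  stopifnot(inherits(hck, "hck_set"))
  if (length(hck$kmers) == 0L) stop("empty HCK set")
  if (nrow(reads) == 0L) stop("no reads")
  if (anyNA(reads$identifier)) {
    stop("record without identifier at row ",
         which(is.na(reads$identifier))[1L])
  }
  barcode <- substring(reads$identifier, 1L, BARCODE_LEN)
  cells <- unique(barcode)  # order of first appearance
  cell_of <- match(barcode, cells)
  n_hck <- length(hck$kmers)
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  chunk_starts <- seq(1L, length(cells), by = as.integer(chunk_cells))
  for (cs in chunk_starts) {
    ce <- min(cs + chunk_cells - 1L, length(cells))
    rows <- which(cell_of >= cs & cell_of <= ce)
    win <- extract_windows(reads$seq[rows], hck$K)
    if (nrow(win) == 0L) next
    win$cell <- cell_of[rows][win$idx]
    win$h <- match(win$kmer, hck$kmers)
    win <- win[!is.na(win$h)]
    if (nrow(win) == 0L) next
    cell <- h <- NULL # data.table NSE
    agg <- win[, .N, by = .(cell, h)]
    trip_i[[length(trip_i) + 1L]] <- agg$h
    trip_j[[length(trip_j) + 1L]] <- agg$cell
    trip_x[[length(trip_x) + 1L]] <- agg$N
  }
  m <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(n_hck, length(cells)),
                            dimnames = list(hck$kmers, cells))
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  attr(m, "K") <- hck$K
  m
}
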