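# Barcode whitelisting, barcode/UMI extraction and quality-based
# deduplication of barcode+UMI PCR copies.

#' Parse a barcode/UMI pattern string
#'
#' The pattern is a run of `C` (cell barcode positions) followed by a run of
#' `N` (UMI positions), e.g. 20 `C`s then 8 `N`s for a 20 bp barcode with an
#' 8 bp UMI. Whitespace is ignored.
#'
#' @param pattern String over `{C, N}`.
#' @return A list with `pattern`, `n_barcode`, `n_umi`.
#' @export
parse_bc_pattern <- function(pattern) {
  p <- gsub("[[:space:]]", "", pattern)
  if (!nzchar(p)) stop("empty barcode pattern")
  if (!grepl("^C+N*$", p)) {
    stop("barcode pattern must be a run of C followed by a run of N, got '",
         pattern, "'")
  }
  n_bc <- sum(strsplit(p, "")[[1]] == "C")
  list(pattern = p, n_barcode = n_bc, n_umi = nchar(p) - n_bc)
}

default_bc_pattern <- function() {
  parse_bc_pattern(paste0(strrep("C", BARCODE_LEN), strrep("N", UMI_LEN)))
}

#' Build a cell barcode whitelist from R1 reads
#'
#' Counts reads per barcode prefix and keeps the deepest barcodes. With
#' `set_cell_number` given, exactly that many barcodes are kept (the paper
#' workflow: the forced number corresponds to the knee of the barcode rank
#' plot). Otherwise the knee of the barcode rank curve (cumulative mean
#' count on log-log scales, maximum absolute slope in the central 80% of the
#' log-rank range; see [knee_point()]) sets the cut.
#'
#' @param r1 R1 read records (data.frame from [read_fastq()]) or a character
#'   vector of R1 sequences.
#' @param pattern Parsed barcode pattern, see [parse_bc_pattern()].
#' @param expect_cells Upper bound on the number of barcodes scanned for the
#'   knee; it never changes counting.
#' @param set_cell_number If given, force the whitelist to the top this-many
#'   barcodes and skip knee detection.
#' @return A list of class `barcode_whitelist`: `barcodes`, `counts`
#'   (non-increasing), `knee_index`.
#' @export
build_whitelist <- function(r1, pattern = default_bc_pattern(),
                            expect_cells = 10000L, set_cell_number = NULL) {
  seqs <- if (is.data.frame(r1)) r1$seq else r1
  if (length(seqs) == 0L) stop("no R1 reads")
  plen <- pattern$n_barcode + pattern$n_umi
  if (any(nchar(seqs) < plen)) {
    stop("R1 read shorter than the barcode pattern (", plen, " bp)")
  }
  bc <- substring(seqs, 1L, pattern$n_barcode)
  tab <- table(bc)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  if (!is.null(set_cell_number)) {
    n_keep <- min(set_cell_number, length(counts))
    if (n_keep < set_cell_number) {
      warning("only ", length(counts), " distinct barcodes; set_cell_number ",
              set_cell_number, " capped")
    }
    knee <- n_keep
  } else {
    scan <- counts[seq_len(min(length(counts), expect_cells))]
    if (length(scan) < 5L) {
      warning("fewer than 5 barcodes; knee detection degenerate, keeping all")
      knee <- length(scan)
    } else {
      knee <- knee_point(rank_curve_from_counts(scan))
    }
  }
  structure(list(barcodes = names(counts)[seq_len(knee)],
                 counts = counts, knee_index = knee),
            class = "barcode_whitelist")
}

#' Extract whitelisted reads, moving barcode and UMI into the header
#'
#' For each read pair whose R1 barcode is on the whitelist, the R2 record is
#' emitted with `_<barcode>_<UMI>` appended to its header, so that the
#' record's 29-character deduplication identifier is `<barcode>_<UMI>`.
#' Non-whitelisted pairs are dropped; order is preserved.
#'
#' @param r1,r2 Paired read records (same length, same order).
#' @param pattern Parsed barcode pattern.
#' @param whitelist A `barcode_whitelist` or character vector of barcodes.
#' @return R2 read records with `identifier` set.
#' @export
extract_reads <- function(r1, r2, pattern = default_bc_pattern(),
                          whitelist) {
  if (nrow(r1) != nrow(r2)) {
    stop("R1/R2 pairing error: ", nrow(r1), " vs ", nrow(r2), " records")
  }
  wl <- if (inherits(whitelist, "barcode_whitelist")) whitelist$barcodes else whitelist
  bc <- substring(r1$seq, 1L, pattern$n_barcode)
  umi <- substring(r1$seq, pattern$n_barcode + 1L,
                   pattern$n_barcode + pattern$n_umi)
  keep <- bc %in% wl
  out <- r2[keep, , drop = FALSE]
  if (any(keep)) {
    out$header <- paste0(out$header, "_", bc[keep], "_", umi[keep])
    out$identifier <- paste0(bc[keep], "_", umi[keep])
  }
  rownames(out) <- NULL
  out
}

#' Mean Phred score of a quality string
#'
#' Phred-33 encoding: score of character `c` is `ord(c) - 33`. The mean is
#' over all positions.
#'
#' @param qual Character vector of quality strings.
#' @return Numeric vector of mean scores (>= 0).
#' @export
q_avg <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) stop("empty quality string")
    v <- utf8ToInt(q)
    if (any(v < 33L)) stop("quality character below Phred-33 offset")
    mean(v - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deduplicate reads sharing a barcode+UMI identifier
#'
#' Keeps exactly one record per distinct identifier: the one with maximal
#' mean Phred score. Because replacement requires a strictly greater score,
#' ties keep the earlier record. Output is ordered by first occurrence of
#' each identifier.
#'
#' @param reads Read records with `identifier` set on every row.
#' @return Deduplicated read records, with a `q_avg` column added.
#' @export
dedup_reads <- function(reads) {
  if (nrow(reads) == 0L) return(cbind(reads, q_avg = numeric(0)))
  if (anyNA(reads$identifier)) {
    stop("record without identifier at row ", which(is.na(reads$identifier))[1L])
  }
  qa <- q_avg(reads$qual)
  dt <- data.table::data.table(row = seq_len(nrow(reads)),
                               identifier = reads$identifier, qavg = qa)
  # strict '>' update rule: among equal scores the earliest row wins
  best <- dt[order(-qavg, row)][!duplicated(identifier)]
  first_seen <- dt[!duplicated(identifier), .(identifier, first = row)]
  best <- merge(best, first_seen, by = "identifier", sort = FALSE)
  best <- best[order(first)]
  out <- reads[best$row, , drop = FALSE]
  out$q_avg <- best$qavg
  rownames(out) <- NULL
  out
}
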