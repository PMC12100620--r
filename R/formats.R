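# Readers and writers for every external format the pipeline touches.
# All other modules do file I/O exclusively through this file.

BARCODE_LEN <- 20L
UMI_LEN <- 8L
ID_LEN <- BARCODE_LEN + 1L + UMI_LEN  # <20bp barcode>_<8bp UMI>
ID_REGEX <- "^[ACGTN]{20}_[ACGTN]{8}$"

open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Parse FASTQ records from a character vector of lines
#'
#' Strict 4-line-per-record FASTQ. The deduplication identifier
#' (`<20bp barcode>_<8bp UMI>`, 29 characters) is taken from the end of the
#' header line when present; otherwise the identifier is `NA`.
#'
#' @param lines Character vector of FASTQ lines (no trailing newline chars).
#' @return A data.frame with columns `header`, `seq`, `qual`, `identifier`.
#' @export
parse_fastq <- function(lines) {
  # tolerate a single trailing empty line from text editors
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    return(data.frame(header = character(), seq = character(),
                      qual = character(), identifier = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: number of lines (", length(lines),
         ") is not a multiple of 4")
  }
  at <- seq(1L, length(lines), by = 4L)
  h <- lines[at]
  s <- lines[at + 1L]
  p <- lines[at + 2L]
  q <- lines[at + 3L]
  bad <- which(!startsWith(h, "@"))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], ": header does not start with '@'")
  }
  bad <- which(!startsWith(p, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L],
         ": separator line does not start with '+'")
  }
  bad <- which(nchar(s) != nchar(q))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L],
         ": sequence and quality lengths differ")
  }
  header <- substring(h, 2L)
  identifier <- fastq_identifier(header)
  data.frame(header = header, seq = s, qual = q, identifier = identifier,
             stringsAsFactors = FALSE)
}

# last 29 characters of the header when they match <barcode>_<UMI>, else NA
fastq_identifier <- function(header) {
  n <- nchar(header)
  id <- ifelse(n >= ID_LEN, substring(header, n - ID_LEN + 1L, n), NA_character_)
  id[!is.na(id) & !grepl(ID_REGEX, id)] <- NA_character_
  id
}

#' Read a FASTQ file (optionally gzip-compressed)
#'
#' @param path Path to a `.fastq`/`.fq` file, `.gz` accepted.
#' @return A data.frame of read records; see [parse_fastq()].
#' @export
read_fastq <- function(path) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  parse_fastq(readLines(con))
}

#' Write read records as FASTQ
#'
#' @param reads Data.frame with columns `header`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("header", "seq", "qual") %in% names(reads)))
  con <- open_text(path, "wt")
  on.exit(close(con))
  n <- nrow(reads)
  lines <- character(4L * n)
  if (n) {
    lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads$header)
    lines[seq(2L, 4L * n, by = 4L)] <- reads$seq
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- reads$qual
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a Jellyfish-dump-style K-mer count FASTA
#'
#' Dialect: each record is a header line holding a positive integer count
#' followed by one sequence line holding the K-mer.
#'
#' @param path Path to the dump file.
#' @return A data.frame with columns `kmer` and `count`, in file order.
#' @export
read_jellyfish_dump <- function(path) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (length(lines) %% 2L != 0L) stop("malformed K-mer dump: odd number of lines")
  if (length(lines) == 0L) {
    return(data.frame(kmer = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  h <- lines[seq(1L, length(lines), by = 2L)]
  k <- lines[seq(2L, length(lines), by = 2L)]
  if (any(!startsWith(h, ">"))) stop("malformed K-mer dump: header without '>'")
  counts <- suppressWarnings(as.integer(substring(h, 2L)))
  if (anyNA(counts)) stop("malformed K-mer dump: count header is not an integer")
  if (any(counts < 1L)) stop("malformed K-mer dump: count must be >= 1")
  if (length(unique(nchar(k))) > 1L) stop("malformed K-mer dump: mixed K lengths")
  data.frame(kmer = k, count = counts, stringsAsFactors = FALSE)
}

#' Write a K-mer spectrum in the Jellyfish-dump dialect
#'
#' @param spectrum A `kmer_spectrum` (see [count_kmers()]) or a named integer
#'   vector of counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jellyfish_dump <- function(spectrum, path) {
  counts <- if (inherits(spectrum, "kmer_spectrum")) spectrum$counts else spectrum
  con <- open_text(path, "wt")
  on.exit(close(con))
  n <- length(counts)
  lines <- character(2L * n)
  if (n) {
    lines[seq(1L, 2L * n, by = 2L)] <- paste0(">", as.integer(counts))
    lines[seq(2L, 2L * n, by = 2L)] <- names(counts)
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write a cell-by-HCK matrix as a MatrixMarket triad
#'
#' Writes `matrix.mtx` (coordinate integer general, 1-based, features are
#' rows and cells are columns), `features.tsv` (one HCK per line) and
#' `barcodes.tsv` (one barcode per line), the standard single-cell triad.
#'
#' @param m A features-by-cells sparse or dense integer matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_matrix_dir <- function(m, dir) {
  if (is.null(dim(m)) || nrow(m) == 0L || ncol(m) == 0L) {
    stop("cannot write an empty matrix (no features or no cells)")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry feature (row) and barcode (column) names")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    "TsparseMatrix")
  i <- tm@i + 1L
  j <- tm@j + 1L
  x <- tm@x
  keep <- x != 0
  i <- i[keep]; j <- j[keep]; x <- x[keep]
  ord <- order(j, i)
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             "%",
             paste(nrow(m), ncol(m), length(i)),
             if (length(i)) paste(i[ord], j[ord], format(x[ord], scientific = FALSE,
                                                         trim = TRUE)))
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket cell-by-HCK triad
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @return A features-by-cells `dgCMatrix` with dimnames.
#' @export
read_matrix_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- readLines(file.path(dir, "features.tsv"))
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(feats) || ncol(m) != length(bcs)) {
    stop("matrix dimensions do not match features/barcodes files")
  }
  dimnames(m) <- list(feats, bcs)
  methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
}

#' Write K-mers as a MEME minimal motif file
#'
#' Each K-mer becomes one MOTIF block whose letter-probability matrix is the
#' one-hot encoding of its bases (alphabet order A, C, G, T).
#'
#' @param kmers Character vector of equal-length K-mers over A/C/G/T.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(kmers, path) {
  if (length(kmers)) {
    if (length(unique(nchar(kmers))) > 1L) stop("K-mers must share one length")
    if (any(grepl("[^ACGT]", kmers))) {
      stop("K-mers must be unambiguous (A/C/G/T only); found other symbols")
    }
  }
  header <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "")
  blocks <- unlist(lapply(kmers, function(km) {
    w <- nchar(km)
    base <- match(strsplit(km, "")[[1]], c("A", "C", "G", "T"))
    rows <- vapply(base, function(b) {
      p <- c("0.000000", "0.000000", "0.000000", "0.000000")
      p[b] <- "1.000000"
      paste0(" ", paste(p, collapse = " "))
    }, character(1))
    c(paste("MOTIF", km),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 1 E= 0", w),
      rows, "")
  }))
  writeLines(c(header, blocks), path)
  invisible(path)
}

#' Read a MEME minimal motif file written by [write_meme_motifs()]
#'
#' Returns the per-motif probability matrices; used to verify that exported
#' motifs are valid one-hot PWMs.
#'
#' @param path Path to a MEME minimal motif file.
#' @return Named list of w-by-4 numeric matrices (columns A, C, G, T).
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    name <- sub("^MOTIF ", "", lines[s])
    wline <- lines[s + 1L]
    w <- as.integer(sub(".* w= *([0-9]+).*", "\\1", wline))
    rows <- lines[(s + 2L):(s + 1L + w)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), " +"), as.numeric))
    colnames(mat) <- c("A", "C", "G", "T")
    out[[name]] <- mat
  }
  out
}

#' Read a taxonomy tree table
#'
#' Four tab-separated columns with header: `node_id`, `parent_id`, `rank`,
#' `name`. Exactly one root (its parent is itself or 0); parent pointers must
#' be acyclic.
#'
#' @param path Path to the TSV.
#' @return A validated data.frame (a `taxonomy_table`).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- c("node_id", "parent_id", "rank", "name")[seq_len(ncol(df))]
  validate_taxonomy(df)
}

#' Validate a taxonomy table
#'
#' @param df Data.frame with columns `node_id`, `parent_id`, `rank`, `name`.
#' @return The data.frame, invisibly classed as `taxonomy_table`.
#' @export
validate_taxonomy <- function(df) {
  stopifnot(all(c("node_id", "parent_id", "rank", "name") %in% names(df)))
  ranks <- c("root", "domain", "phylum", "class", "order", "family",
             "genus", "species")
  if (!all(df$rank %in% ranks)) {
    stop("unknown taxonomic rank(s): ",
         paste(setdiff(df$rank, ranks), collapse = ", "))
  }
  if (anyDuplicated(df$node_id)) stop("duplicate node ids in taxonomy")
  is_root <- df$parent_id == df$node_id | df$parent_id == 0L
  if (sum(is_root) != 1L) stop("taxonomy must have exactly one root")
  if (!all(df$parent_id[!is_root] %in% df$node_id)) {
    stop("taxonomy parent id not present as a node")
  }
  # acyclicity: walk every node to the root
  parent <- stats::setNames(df$parent_id, df$node_id)
  root <- df$node_id[is_root]
  for (v in df$node_id) {
    seen <- integer()
    while (v != root) {
      if (v %in% seen) stop("cycle detected in taxonomy at node ", v)
      seen <- c(seen, v)
      v <- parent[[as.character(v)]]
    }
  }
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Write a taxonomy tree table
#' @param df A taxonomy table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(df, path) {
  utils::write.table(df[, c("node_id", "parent_id", "rank", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-read taxonomic classifications
#'
#' Accepts the 5-column classifier read-output dialect (status C/U, read id,
#' assigned taxon id, read length, LCA mapping); only the read id and taxon
#' id columns are used. The cell barcode is recovered from the read
#' identifier suffix (`<barcode>_<UMI>`).
#'
#' @param path Path to the TSV (no header).
#' @return Data.frame with columns `read_id`, `taxid`, `barcode`.
#' @export
read_classifications <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("classification table needs >= 3 columns")
  out <- data.frame(read_id = as.character(df[[2]]),
                    taxid = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  out$barcode <- classification_barcode(out$read_id)
  out
}

classification_barcode <- function(read_id) {
  id <- fastq_identifier(read_id)
  substring(id, 1L, BARCODE_LEN)
}

#' Write per-read classifications in the 5-column dialect
#'
#' @param df Data.frame with columns `read_id` and `taxid`; `taxid` 0 is
#'   written with status `U` (unclassified), otherwise `C`.
#' @param path Output path.
#' @param read_len Read length to report in column 4.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(df, path, read_len = 100L) {
  status <- ifelse(df$taxid == 0L, "U", "C")
  out <- data.frame(status, df$read_id, df$taxid, read_len, "0:0")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a K-mer frequency histogram in the two-column histo dialect
#'
#' @param histo A `spectrum_histogram` (see [spectrum_histogram()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histo <- function(histo, path) {
  utils::write.table(data.frame(histo$frequency, histo$n_kmers), path,
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a two-column K-mer frequency histogram
#'
#' @param path Path to a histo file (frequency, number of K-mers).
#' @param K K-mer length to attach, if known.
#' @return A `spectrum_histogram`.
#' @export
read_histo <- function(path, K = NA_integer_) {
  df <- utils::read.table(path, col.names = c("frequency", "n_kmers"))
  structure(list(K = K, frequency = as.integer(df$frequency),
                 n_kmers = as.integer(df$n_kmers)),
            class = "spectrum_histogram")
}

#' Write peptides as FASTA
#'
#' @param peptides Data.frame from [six_frame_translate()] (columns
#'   `aa_seq`, `frame`, `source_kmer`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(peptides, path) {
  n <- nrow(peptides)
  lines <- character(2L * n)
  if (n) {
    lines[seq(1L, 2L * n, by = 2L)] <-
      paste0(">", peptides$source_kmer, "_frame", peptides$frame)
    lines[seq(2L, 2L * n, by = 2L)] <- peptides$aa_seq
  }
  writeLines(lines, path)
  invisible(path)
}
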