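# External format readers/writers: FASTQ, K-mer dump, MatrixMarket triad,
# MEME motifs, taxonomy and classification tables.

test_that("FASTQ parsing extracts records and the 29-char identifier", {
  bc <- strrep("A", 20)
  lines <- c(paste0("@r1 ", bc, "_CCCCCCCC"), "ACGT", "+", "IIII")
  rec <- parse_fastq(lines)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$identifier, paste0(bc, "_CCCCCCCC"))
  expect_equal(rec$seq, "ACGT")

  expect_equal(nrow(parse_fastq(character())), 0L)

  # headers without the barcode_UMI suffix leave the identifier unset
  plain <- parse_fastq(c("@read_one", "ACGT", "+", "IIII"))
  expect_true(is.na(plain$identifier))
})

test_that("malformed FASTQ records fail with the record index", {
  expect_error(parse_fastq(c("@r1", "ACGT", "+", "III")), "record 1")
  expect_error(parse_fastq(c("r1", "ACGT", "+", "IIII")), "record 1")
  expect_error(parse_fastq(c("@r1", "ACGT", "x", "IIII")), "record 1")
  expect_error(parse_fastq(c("@r1", "ACGT", "+", "IIII", "@r2", "AC", "+",
                             "I")), "record 2")
  expect_error(parse_fastq(c("@r1", "ACGT", "+")), "multiple of 4")
})

test_that("FASTQ write/read round-trips, with and without gzip", {
  set.seed(1)
  reads <- data.frame(
    header = c(paste0("r1_", strrep("G", 20), "_ACGTACGT"), "r2 plain"),
    seq = c("ACGTN", "TTTT"), qual = c("II!#5", "IIII"),
    stringsAsFactors = FALSE)
  for (ext in c(".fastq", ".fastq.gz")) {
    path <- tempfile(fileext = ext)
    write_fastq(reads, path)
    back <- read_fastq(path)
    expect_equal(back$header, reads$header)
    expect_equal(back$seq, reads$seq)
    expect_equal(back$qual, reads$qual)
    unlink(path)
  }
})

test_that("K-mer dump dialect parses and rejects malformed input", {
  path <- tempfile()
  writeLines(c(">5", "ACGTACGTACGT"), path)
  df <- read_jellyfish_dump(path)
  expect_equal(df, data.frame(kmer = "ACGTACGTACGT", count = 5L,
                              stringsAsFactors = FALSE))

  writeLines(c(">5", "ACGTACGTACGT", ">2", "ACGTACGTACGTA"), path)
  expect_error(read_jellyfish_dump(path), "mixed K")
  writeLines(c(">0", "AAAAAAAAAAAA"), path)
  expect_error(read_jellyfish_dump(path), ">= 1")
  writeLines(c(">x", "AAAAAAAAAAAA"), path)
  expect_error(read_jellyfish_dump(path), "integer")
  unlink(path)
})

test_that("K-mer dump write/read preserves the (kmer, count) multiset", {
  set.seed(2)
  km <- unique(replicate(30, random_dna_str(8)))
  counts <- stats::setNames(sample(1:50, length(km), replace = TRUE), km)
  path <- tempfile()
  write_jellyfish_dump(counts, path)
  back <- read_jellyfish_dump(path)
  expect_equal(stats::setNames(back$count, back$kmer), counts)
  unlink(path)
})

test_that("MatrixMarket triad writes coordinate integer format and round-trips", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 2, 3),
                            x = c(3, 1, 2, 7), dims = c(2, 3),
                            dimnames = list(c("AAAA", "CCCC"),
                                            c("bc1", "bc2", "bc3")))
  dir <- tempfile()
  write_matrix_dir(m, dir)
  lines <- readLines(file.path(dir, "matrix.mtx"))
  expect_equal(lines[1], "%%MatrixMarket matrix coordinate integer general")
  expect_equal(lines[3], "2 3 4")
  back <- read_matrix_dir(dir)
  expect_equal(as.matrix(back), as.matrix(m))
  unlink(dir, recursive = TRUE)

  empty <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(2, 0),
                                dimnames = list(c("A", "B"), character()))
  expect_error(write_matrix_dir(empty, tempfile()), "empty")
})

test_that("MatrixMarket round-trip is lossless on random sparse matrices", {
  set.seed(3)
  for (rep in 1:5) {
    nr <- sample(2:15, 1); nc <- sample(2:15, 1)
    m <- Matrix::Matrix(matrix(rpois(nr * nc, 0.8), nr), sparse = TRUE)
    dimnames(m) <- list(paste0("k", seq_len(nr)), paste0("b", seq_len(nc)))
    dir <- tempfile()
    write_matrix_dir(m, dir)
    expect_equal(as.matrix(read_matrix_dir(dir)), as.matrix(m))
    unlink(dir, recursive = TRUE)
  }
})

test_that("MEME motif export is a one-hot PWM per K-mer", {
  path <- tempfile()
  write_meme_motifs("ACGT", path)
  pwm <- read_meme_motifs(path)[["ACGT"]]
  expect_equal(unname(pwm), rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                  c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_true(all(rowSums(pwm) == 1))

  write_meme_motifs(character(), path)
  expect_length(read_meme_motifs(path), 0L)
  expect_match(readLines(path)[1], "MEME version")

  expect_error(write_meme_motifs("ACNT", path), "unambiguous")
  unlink(path)
})

test_that("random K-mer sets export to parseable one-hot PWMs", {
  set.seed(4)
  kms <- unique(replicate(10, random_dna_str(12)))
  path <- tempfile()
  write_meme_motifs(kms, path)
  pwms <- read_meme_motifs(path)
  expect_equal(names(pwms), kms)
  for (km in kms) {
    pwm <- pwms[[km]]
    expect_equal(nrow(pwm), 12L)
    expect_true(all(rowSums(pwm) == 1))
    rebuilt <- paste(colnames(pwm)[apply(pwm, 1, which.max)], collapse = "")
    expect_equal(rebuilt, km)
  }
  unlink(path)
})

test_that("taxonomy table validation enforces the tree invariants", {
  tree <- data.frame(node_id = c(1L, 2L, 3L),
                     parent_id = c(1L, 1L, 2L),
                     rank = c("root", "genus", "species"),
                     name = c("root", "G1", "S1"), stringsAsFactors = FALSE)
  expect_s3_class(validate_taxonomy(tree), "taxonomy_table")
  path <- tempfile()
  write_taxonomy(tree, path)
  expect_equal(read_taxonomy(path)$node_id, tree$node_id)
  unlink(path)

  two_roots <- tree; two_roots$parent_id[2] <- 2L
  expect_error(validate_taxonomy(two_roots), "exactly one root")
  cyc <- tree; cyc$parent_id <- c(1L, 3L, 2L)
  expect_error(validate_taxonomy(cyc), "cycle")
  badrank <- tree; badrank$rank[3] <- "strain"
  expect_error(validate_taxonomy(badrank), "rank")
})

test_that("classification table round-trips and recovers barcodes", {
  bc <- strrep("T", 20)
  df <- data.frame(read_id = c(paste0("m1_", bc, "_AAAAAAAA"),
                               paste0("m2_", bc, "_CCCCCCCC")),
                   taxid = c(201L, 0L), stringsAsFactors = FALSE)
  path <- tempfile()
  write_classifications(df, path)
  raw <- utils::read.delim(path, header = FALSE)
  expect_equal(as.character(raw$V1), c("C", "U"))
  back <- read_classifications(path)
  expect_equal(back$taxid, df$taxid)
  expect_equal(back$barcode, c(bc, bc))
  unlink(path)
})
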