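# Synthetic microbial community and smRNA-seq read generator.
# Provides ground truth for every pipeline stage: species genomes sharing
# planted conserved blocks, barcoded cells, PCR duplicates, substitution
# errors, Phred-33 qualities, empty-droplet noise barcodes, and a
# classifier-style per-read table over a toy taxonomy.

#' Simulation configuration
#'
#' Defaults describe the package's reference study conditions: a 5-species
#' community of 50 cells each at 200 reads per cell, 100 bp reads drawn
#' from 1 kb circular genomes (~20x per-cell coverage), three 60 bp
#' conserved blocks shared verbatim by all species plus one 60 bp
#' species-specific marker block, 10% PCR duplication, a 0.1% per-base
#' substitution error rate, and 500 empty-droplet barcodes at a fixed
#' shallow depth of 2 reads.
#'
#' @param n_species Number of species.
#' @param cells_per_species Cells per species.
#' @param reads_per_cell Molecules (distinct barcode+UMI) per cell.
#' @param read_len Read length (nt).
#' @param genome_len Genome length per species (nt); genomes are circular.
#' @param n_conserved_blocks Number of conserved blocks shared by all
#'   species.
#' @param conserved_block_len Length of each conserved block (nt).
#' @param specific_block_len Length of the species-specific marker block.
#' @param pcr_dup_rate Expected fraction of molecules receiving an extra
#'   PCR copy (same barcode+UMI, fresh errors, possibly lower quality).
#' @param error_rate Per-base substitution probability.
#' @param n_noise_barcodes Number of empty-droplet barcodes.
#' @param noise_reads_per_barcode Reads per noise barcode (fixed depth).
#' @param genus_fraction Fraction of classified molecules degraded to the
#'   genus level in the classification table.
#' @param unclassified_fraction Fraction of molecules left unclassified.
#' @param k K-mer length used for the planted K-mer ground truth.
#' @param seed Random seed; the whole simulation is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_species = 5L, cells_per_species = 50L,
                       reads_per_cell = 200L, read_len = 100L,
                       genome_len = 1000L, n_conserved_blocks = 3L,
                       conserved_block_len = 60L, specific_block_len = 60L,
                       pcr_dup_rate = 0.1, error_rate = 0.001,
                       n_noise_barcodes = 500L, noise_reads_per_barcode = 2L,
                       genus_fraction = 0.2, unclassified_fraction = 0.1,
                       k = 12L, seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              cells_per_species = as.integer(cells_per_species),
              reads_per_cell = as.integer(reads_per_cell),
              read_len = as.integer(read_len),
              genome_len = as.integer(genome_len),
              n_conserved_blocks = as.integer(n_conserved_blocks),
              conserved_block_len = as.integer(conserved_block_len),
              specific_block_len = as.integer(specific_block_len),
              barcode_len = BARCODE_LEN, umi_len = UMI_LEN,
              pcr_dup_rate = pcr_dup_rate, error_rate = error_rate,
              n_noise_barcodes = as.integer(n_noise_barcodes),
              noise_reads_per_barcode = as.integer(noise_reads_per_barcode),
              genus_fraction = genus_fraction,
              unclassified_fraction = unclassified_fraction,
              k = as.integer(k), seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_species >= 1L, cells_per_species >= 1L, reads_per_cell >= 1L,
              read_len >= 1L, genome_len >= read_len,
              n_conserved_blocks >= 0L, pcr_dup_rate >= 0, pcr_dup_rate < 1,
              error_rate >= 0, error_rate < 1, n_noise_barcodes >= 0L,
              genus_fraction >= 0, unclassified_fraction >= 0,
              genus_fraction + unclassified_fraction < 1)
    blocks_nt <- n_conserved_blocks * conserved_block_len + specific_block_len
    if (blocks_nt > genome_len) stop("planted blocks exceed genome length")
  })
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# distinct K-mers of a linear sequence
kmers_of <- function(seq, K) {
  L <- nchar(seq)
  if (L < K) return(character())
  unique(substring(seq, seq_len(L - K + 1L), K:L))
}

# n random barcodes, pairwise Hamming distance >= 2
random_barcodes <- function(n, len) {
  gen <- function(m) vapply(seq_len(m), function(i) random_dna(len), character(1))
  bc <- gen(n)
  repeat {
    m <- matrix(utf8ToInt(paste(bc, collapse = "")), nrow = n, byrow = TRUE)
    ham <- matrix(0L, n, n)
    for (j in seq_len(len)) ham <- ham + outer(m[, j], m[, j], "!=")
    diag(ham) <- len
    bad <- unique(which(ham < 2L, arr.ind = TRUE)[, 1])
    if (length(bad) == 0L) return(bc)
    bc[bad] <- gen(length(bad))
  }
}

# substitution errors at the configured per-base rate
apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  len <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), len, error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  seqs
}

# Phred-33 quality strings with per-base scores uniform on [lo, hi]
random_quals <- function(n, len, lo, hi) {
  q <- matrix(sample(lo:hi, n * len, replace = TRUE) + 33L, nrow = n)
  vapply(seq_len(n), function(i) intToUtf8(q[i, ]), character(1))
}

sim_taxonomy <- function(n_species) {
  shared <- data.frame(
    node_id = 1:6, parent_id = c(1L, 1:5),
    rank = c("root", "domain", "phylum", "class", "order", "family"),
    name = c("root", "Bacteria", "Simulibacterota", "Simulibacteriia",
             "Simulibacteriales", "Simulibacteriaceae"),
    stringsAsFactors = FALSE)
  genera <- data.frame(node_id = 100L + seq_len(n_species), parent_id = 6L,
                       rank = "genus",
                       name = sprintf("Simulibacter_g%02d", seq_len(n_species)),
                       stringsAsFactors = FALSE)
  species <- data.frame(node_id = 200L + seq_len(n_species),
                        parent_id = 100L + seq_len(n_species),
                        rank = "species",
                        name = sprintf("Simulibacter_species_%02d",
                                       seq_len(n_species)),
                        stringsAsFactors = FALSE)
  validate_taxonomy(rbind(shared, genera, species))
}

# genomes: random background with the shared conserved blocks and one
# species-specific block implanted in random order at random offsets.
# Construction guarantees (regenerated until they hold): within a genome
# every K-mer occurs exactly once, so K-mer depth is proportional to the
# number of species carrying it; marker-block K-mers occur in one species
# only. The cross-species conserved K-mer set (present in >= 2 genomes) is
# returned as ground truth; it is the planted-block K-mers plus the
# block-edge windows that species happen to share through matching flanks.
build_genomes <- function(cfg, conserved_blocks, specific_blocks) {
  K <- cfg$k
  for (attempt in seq_len(50L)) {
    genomes <- vapply(seq_len(cfg$n_species), function(s) {
      blocks <- c(conserved_blocks, specific_blocks[s])
      blocks <- blocks[sample.int(length(blocks))]
      bg_total <- cfg$genome_len - sum(nchar(blocks))
      cuts <- sort(sample.int(bg_total + 1L, length(blocks), replace = TRUE)) - 1L
      pieces <- character(2L * length(blocks) + 1L)
      prev <- 0L
      bg <- random_dna(bg_total)
      for (b in seq_along(blocks)) {
        pieces[2L * b - 1L] <- substr(bg, prev + 1L, cuts[b])
        pieces[2L * b] <- blocks[b]
        prev <- cuts[b]
      }
      pieces[length(pieces)] <- substr(bg, prev + 1L, bg_total)
      paste(pieces, collapse = "")
    }, character(1))
    cons_k <- unique(unlist(lapply(conserved_blocks, kmers_of, K = K)))
    spec_k <- lapply(seq_len(cfg$n_species), function(s) {
      setdiff(kmers_of(specific_blocks[s], K), cons_k)
    })
    # circular genomes: every window, including the wrap-around junction
    circ <- paste0(genomes, substring(genomes, 1L, K - 1L))
    gk <- lapply(circ, function(g) substring(g, seq_len(cfg$genome_len),
                                             seq_len(cfg$genome_len) + K - 1L))
    ok <- all(vapply(seq_len(cfg$n_species), function(s) {
      anyDuplicated(gk[[s]]) == 0L &&
        all(cons_k %in% gk[[s]]) &&
        all(spec_k[[s]] %in% gk[[s]]) &&
        !any(unlist(spec_k[-s]) %in% gk[[s]])
    }, logical(1)))
    if (ok) {
      presence <- table(unlist(lapply(gk, unique)))
      shared <- names(presence)[presence >= 2L]
      allsp <- names(presence)[presence == cfg$n_species]
      return(list(genomes = genomes, block_kmers = cons_k,
                  conserved_kmers = shared, allspecies_kmers = allsp,
                  specific_kmers = spec_k))
    }
  }
  stop("could not build genomes with uniquely planted blocks")
}

#' Simulate a synthetic microbial community smRNA-seq experiment
#'
#' Builds the community genomes, cells and reads described by a
#' [sim_config()] and returns paired R1/R2 read records, a per-molecule
#' classification table, the taxonomy used, and the full ground truth.
#' Byte-identical across runs with the same config.
#'
#' @param cfg A `sim_config`.
#' @return A list of class `smrna_sim`: `r1`, `r2` (read data.frames),
#'   `classifications` (read_id, taxid, barcode), `taxonomy`, and `truth`
#'   (barcode -> species, molecule table, planted blocks and K-mer sets,
#'   genomes, config).
#' @export
simulate_community <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  taxonomy <- sim_taxonomy(cfg$n_species)
  conserved_blocks <- vapply(seq_len(cfg$n_conserved_blocks),
                             function(i) random_dna(cfg$conserved_block_len),
                             character(1))
  specific_blocks <- vapply(seq_len(cfg$n_species),
                            function(i) random_dna(cfg$specific_block_len),
                            character(1))
  g <- build_genomes(cfg, conserved_blocks, specific_blocks)

  n_cells <- cfg$n_species * cfg$cells_per_species
  all_bc <- random_barcodes(n_cells + cfg$n_noise_barcodes, cfg$barcode_len)
  cell_bc <- all_bc[seq_len(n_cells)]
  noise_bc <- all_bc[n_cells + seq_len(cfg$n_noise_barcodes)]
  cell_species <- rep(seq_len(cfg$n_species), each = cfg$cells_per_species)

  umi_alphabet <- c("A", "C", "G", "T")
  encode_umi <- function(ints, len) { # ints in [0, 4^len)
    out <- character(length(ints))
    for (p in seq_len(len)) {
      out <- paste0(out, umi_alphabet[(ints %% 4L) + 1L])
      ints <- ints %/% 4L
    }
    out
  }
  # molecules: distinct barcode+UMI per cell (UMIs drawn without replacement)
  mol_cell <- rep(seq_len(n_cells), each = cfg$reads_per_cell)
  mol_umi <- unlist(lapply(seq_len(n_cells), function(i) {
    encode_umi(sample.int(4L^cfg$umi_len, cfg$reads_per_cell) - 1L,
               cfg$umi_len)
  }))
  mol_species <- cell_species[mol_cell]
  mol_bc <- cell_bc[mol_cell]
  if (cfg$n_noise_barcodes > 0L) {
    n_noise_mol <- cfg$n_noise_barcodes * cfg$noise_reads_per_barcode
    noise_cellidx <- rep(seq_len(cfg$n_noise_barcodes),
                         each = cfg$noise_reads_per_barcode)
    noise_umi <- unlist(lapply(seq_len(cfg$n_noise_barcodes), function(i) {
      encode_umi(sample.int(4L^cfg$umi_len, cfg$noise_reads_per_barcode) - 1L,
                 cfg$umi_len)
    }))
    mol_bc <- c(mol_bc, noise_bc[noise_cellidx])
    mol_umi <- c(mol_umi, noise_umi)
    mol_species <- c(mol_species, sample.int(cfg$n_species, n_noise_mol,
                                             replace = TRUE))
  }
  n_mol <- length(mol_bc)
  is_noise <- c(rep(FALSE, n_cells * cfg$reads_per_cell),
                rep(TRUE, n_mol - n_cells * cfg$reads_per_cell))

  # circular sampling: reads wrap around the genome end
  circ <- paste0(g$genomes, substring(g$genomes, 1L, cfg$read_len - 1L))
  mol_start <- sample.int(cfg$genome_len, n_mol, replace = TRUE)
  mol_seq <- substring(circ[mol_species], mol_start,
                       mol_start + cfg$read_len - 1L)
  mol_header <- sprintf("m%06d", seq_len(n_mol))
  mol_id <- paste0(mol_bc, "_", mol_umi)

  # raw reads: one sequencing pass per molecule plus PCR duplicates that
  # share the molecule's barcode, UMI and header but are re-sequenced with
  # fresh errors and (possibly lower) qualities
  n_dup <- stats::rbinom(1L, n_mol, cfg$pcr_dup_rate)
  dup_of <- if (n_dup > 0L) sample.int(n_mol, n_dup, replace = TRUE) else integer()
  src <- c(seq_len(n_mol), dup_of)
  is_dup <- c(rep(FALSE, n_mol), rep(TRUE, n_dup))
  r2_seq <- apply_errors(mol_seq[src], cfg$error_rate)
  r2_qual <- character(length(src))
  r2_qual[!is_dup] <- random_quals(n_mol, cfg$read_len, 30L, 40L)
  if (n_dup > 0L) r2_qual[is_dup] <- random_quals(n_dup, cfg$read_len, 20L, 40L)
  ord <- sample.int(length(src))
  src <- src[ord]; is_dup <- is_dup[ord]
  r2 <- data.frame(header = mol_header[src], seq = r2_seq[ord],
                   qual = r2_qual[ord], identifier = NA_character_,
                   stringsAsFactors = FALSE)
  r1 <- data.frame(header = mol_header[src],
                   seq = paste0(mol_bc[src], mol_umi[src]),
                   qual = random_quals(length(src),
                                       cfg$barcode_len + cfg$umi_len, 30L, 40L),
                   identifier = NA_character_, stringsAsFactors = FALSE)

  # classification table: one row per molecule; a configurable fraction is
  # degraded to the genus level, another left unclassified
  u <- stats::runif(n_mol)
  taxid <- 200L + mol_species
  taxid[u < cfg$genus_fraction + cfg$unclassified_fraction] <-
    100L + mol_species[u < cfg$genus_fraction + cfg$unclassified_fraction]
  taxid[u < cfg$unclassified_fraction] <- 0L
  classifications <- data.frame(
    read_id = paste0(mol_header, "_", mol_id),
    taxid = taxid, barcode = mol_bc, stringsAsFactors = FALSE)

  truth <- list(
    barcode_species = stats::setNames(
      taxonomy$name[match(200L + cell_species, taxonomy$node_id)], cell_bc),
    barcode_species_id = stats::setNames(200L + cell_species, cell_bc),
    noise_barcodes = noise_bc,
    molecules = data.frame(header = mol_header, barcode = mol_bc,
                           umi = mol_umi, identifier = mol_id,
                           species = mol_species, is_noise = is_noise,
                           true_seq = mol_seq, stringsAsFactors = FALSE),
    conserved_blocks = conserved_blocks,
    specific_blocks = specific_blocks,
    block_kmers = g$block_kmers,
    conserved_kmers = g$conserved_kmers,
    allspecies_kmers = g$allspecies_kmers,
    specific_kmers = g$specific_kmers,
    genomes = g$genomes,
    taxonomy = taxonomy,
    config = cfg)
  structure(list(r1 = r1, r2 = r2, classifications = classifications,
                 taxonomy = taxonomy, truth = truth),
            class = "smrna_sim")
}

#' Write a simulated experiment to disk
#'
#' @param sim Output of [simulate_community()].
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(r1 = file.path(dir, "R1.fastq.gz"),
                r2 = file.path(dir, "R2.fastq.gz"),
                classifications = file.path(dir, "classifications.tsv"),
                taxonomy = file.path(dir, "taxonomy.tsv"))
  write_fastq(sim$r1, paths$r1)
  write_fastq(sim$r2, paths$r2)
  write_classifications(sim$classifications, paths$classifications,
                        read_len = sim$truth$config$read_len)
  write_taxonomy(sim$taxonomy, paths$taxonomy)
  invisible(paths)
}
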