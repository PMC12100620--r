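# Per-cell taxonomic annotation: leaf-to-root read aggregation, greedy
# root-to-leaf voting, and confidence/abundance filtering.

tax_root <- function(tree) {
  tree$node_id[tree$parent_id == tree$node_id | tree$parent_id == 0L]
}

# nodes ordered so every child precedes its parent
tax_depth_order <- function(tree) {
  root <- tax_root(tree)
  parent <- stats::setNames(tree$parent_id, as.character(tree$node_id))
  depth <- vapply(tree$node_id, function(v) {
    d <- 0L
    while (v != root) {
      v <- parent[[as.character(v)]]
      d <- d + 1L
    }
    d
  }, integer(1))
  tree$node_id[order(-depth)]
}

#' Aggregate one cell's read classifications over the taxonomy tree
#'
#' Reads assigned directly to a node are summed leaf-to-root: the cumulative
#' count of a node is its direct count plus the cumulative counts of its
#' children. Unclassified reads (taxon id 0) contribute to no node (they
#' still count toward the cell total in [annotate_cells()]).
#'
#' @param classifications Data.frame for one cell with a `taxid` column.
#' @param tree A `taxonomy_table` (see [read_taxonomy()]).
#' @return Named numeric vector: cumulative read count per node id.
#' @export
aggregate_counts <- function(classifications, tree) {
  taxid <- classifications$taxid
  taxid <- taxid[taxid != 0L]
  if (!all(taxid %in% tree$node_id)) {
    stop("classification refers to unknown node id(s): ",
         paste(utils::head(setdiff(taxid, tree$node_id)), collapse = ", "))
  }
  cum <- stats::setNames(numeric(nrow(tree)), as.character(tree$node_id))
  if (length(taxid)) {
    tab <- table(taxid)
    cum[names(tab)] <- as.numeric(tab)
  }
  parent <- stats::setNames(tree$parent_id, as.character(tree$node_id))
  root <- tax_root(tree)
  for (v in tax_depth_order(tree)) {
    if (v == root) next
    p <- as.character(parent[[as.character(v)]])
    cum[p] <- cum[p] + cum[[as.character(v)]]
  }
  cum
}

#' Greedy root-to-leaf species call
#'
#' Starting at the root, repeatedly descend to the child with the largest
#' cumulative read count (ties go to the lexicographically smallest name),
#' stopping at species rank. If, before reaching species rank, the current
#' node has no child with a positive cumulative count, the cell is left
#' unassigned (`NA`).
#'
#' @param cumulative Output of [aggregate_counts()].
#' @param tree A `taxonomy_table`.
#' @return Species node id, or `NA_integer_` if unassigned.
#' @export
root_to_leaf_path <- function(cumulative, tree) {
  node <- tax_root(tree)
  repeat {
    rank <- tree$rank[tree$node_id == node]
    if (length(rank) != 1L) stop("malformed tree at node ", node)
    if (rank == "species") return(node)
    kids <- tree$node_id[tree$parent_id == node & tree$node_id != node]
    if (length(kids) == 0L) return(NA_integer_)
    kc <- cumulative[as.character(kids)]
    if (all(kc <= 0)) return(NA_integer_)
    knames <- tree$name[match(kids, tree$node_id)]
    best <- order(-kc, knames)[1L]
    node <- kids[best]
  }
}

#' Annotate cells with species calls and confidence filters
#'
#' Per cell: the greedy root-to-leaf path picks a species; the confidence
#' `fraction_total_reads` is the species' cumulative classified reads
#' divided by the cell's total reads (classified plus unclassified); cells
#' pass the fraction filter only when strictly above `fraction_threshold`.
#' Community level: a species annotating fewer than `abundance_threshold` of
#' the fraction-passing cells fails the abundance filter. The final `label`
#' is the species name iff both filters pass, else `NA`.
#'
#' @param classifications Data.frame with columns `barcode` and `taxid`
#'   covering all cells (see [read_classifications()]).
#' @param tree A `taxonomy_table`.
#' @param fraction_threshold Per-cell confidence cut (default 0.5, strict).
#' @param abundance_threshold Minimum fraction of fraction-passing cells a
#'   species must annotate (default 0.001, i.e. 0.1%).
#' @return Data.frame with one row per cell: `barcode`, `species_id`,
#'   `species_name`, `fraction_total_reads`, `passed_fraction_filter`,
#'   `passed_abundance_filter`, `label`.
#' @export
annotate_cells <- function(classifications, tree, fraction_threshold = 0.5,
                           abundance_threshold = 0.001) {
  if (nrow(classifications) == 0L) stop("no classifications")
  if (is.null(classifications$barcode)) stop("classifications need a barcode column")
  split_cells <- split(classifications, classifications$barcode)
  res <- lapply(names(split_cells), function(bc) {
    cl <- split_cells[[bc]]
    cum <- aggregate_counts(cl, tree)
    sp <- root_to_leaf_path(cum, tree)
    frac <- if (is.na(sp)) 0 else cum[[as.character(sp)]] / nrow(cl)
    data.frame(barcode = bc, species_id = sp,
               species_name = if (is.na(sp)) NA_character_ else
                 tree$name[match(sp, tree$node_id)],
               fraction_total_reads = frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$passed_fraction_filter <- out$fraction_total_reads > fraction_threshold
  passing <- out$passed_fraction_filter & !is.na(out$species_id)
  n_pass <- sum(passing)
  sp_cells <- table(out$species_id[passing])
  low <- names(sp_cells)[as.numeric(sp_cells) / max(n_pass, 1L) < abundance_threshold]
  out$passed_abundance_filter <- !is.na(out$species_id) &
    !(as.character(out$species_id) %in% low)
  out$label <- ifelse(out$passed_fraction_filter & out$passed_abundance_filter,
                      out$species_name, NA_character_)
  rownames(out) <- NULL
  out
}

#' Write a per-cell annotation report
#'
#' @param annotation Output of [annotate_cells()].
#' @param path Output path (TSV with header).
#' @return `path`, invisibly.
#' @export
write_annotation_report <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
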