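#' Build a tryptic peptide-to-taxa index
#'
#' Digests every protein with the same tryptic rule as the simulator and
#' maps each I/L-equated peptide to the set of taxa whose proteome
#' contains it. Contaminant entries contribute their own taxon, so a
#' peptide unique to a contaminant protein maps to the contaminant
#' lineage (mirroring a search against target plus contaminant
#' databases).
#'
#' @param proteins Protein tibble with `taxon_id` assignments.
#' @param max_missed,min_len,max_len Digestion parameters, see
#'   [tryptic_digest()].
#' @return A `peptide_index`: named list mapping I/L-equated peptide
#'   keys to sorted character vectors of taxon ids.
#' @export
build_peptide_index <- function(proteins, max_missed = 2L, min_len = 7L,
                                max_len = 45L) {
  keys <- character()
  taxa <- character()
  for (i in seq_len(nrow(proteins))) {
    pep <- tryptic_digest(proteins$sequence[[i]], max_missed = max_missed,
                          min_len = min_len, max_len = max_len)$peptide
    if (!length(pep)) next
    pep <- unique(il_key(pep))
    keys <- c(keys, pep)
    taxa <- c(taxa, rep.int(proteins$taxon_id[[i]], length(pep)))
  }
  idx <- lapply(split(taxa, keys), function(t) sort(unique(t)))
  structure(idx, class = "peptide_index")
}

#' Look up the taxa containing a peptide
#'
#' @param index A `peptide_index`.
#' @param peptide Peptide sequence (I/L equivalence applied internally).
#' @return Character vector of taxon ids; empty if the peptide is
#'   absent from the index.
#' @export
index_taxa <- function(index, peptide) {
  hit <- index[[il_key(peptide)]]
  if (is.null(hit)) character() else hit
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon.
#'
#' @param taxa Non-empty character vector of taxon ids.
#' @param tree A `taxonomy_tree`.
#' @return A single taxon id.
#' @export
lca <- function(taxa, tree) {
  taxa <- unique(taxa)
  if (length(taxa) == 0L) abort("lca of an empty taxon set is undefined")
  unknown <- setdiff(taxa, names(tree$parent))
  if (length(unknown)) abort(sprintf("unknown taxon: %s", unknown[[1L]]))
  # Root-to-node paths; the LCA is the last element of their common prefix.
  paths <- lapply(taxa, function(t) rev(taxon_lineage(tree, t)))
  common <- paths[[1L]]
  for (p in paths[-1L]) {
    k <- min(length(common), length(p))
    same <- common[seq_len(k)] == p[seq_len(k)]
    depth <- if (all(same)) k else which(!same)[1L] - 1L
    common <- common[seq_len(depth)]
  }
  common[[length(common)]]
}

#' Classify a peptide or protein source from its LCA
#'
#' Classification against a sample's input ingredient:
#' `input_ingredient` when the LCA lies on the ingredient's lineage at
#' the specificity rank or a more specific one; `non_specific` when the
#' LCA lies on the lineage but above the specificity rank; and
#' `contaminant` when the ingredient is not in the LCA's subtree at all
#' (the identification cannot derive from the ingredient).
#'
#' @param lca_node LCA taxon id.
#' @param ingredient Ingredient taxon id.
#' @param tree A `taxonomy_tree`.
#' @param specificity_rank Rank at or below which an on-lineage LCA
#'   counts as ingredient-specific (default `"family"`, inclusive).
#' @return One of `"input_ingredient"`, `"non_specific"`,
#'   `"contaminant"`.
#' @export
classify_source <- function(lca_node, ingredient, tree,
                            specificity_rank = "family") {
  stopifnot(specificity_rank %in% TAXON_RANKS)
  lineage <- taxon_lineage(tree, ingredient)
  if (!lca_node %in% lineage) {
    # lca could still be *below* the ingredient (e.g. subspecies).
    if (ingredient %in% taxon_lineage(tree, lca_node)) {
      return("input_ingredient")
    }
    return("contaminant")
  }
  lca_rank <- tree$nodes$rank[match(lca_node, tree$nodes$taxon_id)]
  if (match(lca_rank, TAXON_RANKS) >= match(specificity_rank, TAXON_RANKS)) {
    "input_ingredient"
  } else {
    "non_specific"
  }
}

#' Assign LCAs and source classes across samples
#'
#' For every evidence row, the peptide's LCA over the taxa containing it
#' is classified against the sample's ingredient. Proteins (grouped by
#' leading razor accession) are classified from the LCA of the union of
#' their peptides' taxon sets. A top-N table per sample mirrors the
#' "most abundant proteins" summaries of degradation studies: ordered
#' by distinct peptide-row count, descending, ties broken
#' lexicographically by accession.
#'
#' @param evidence Filtered evidence tibble.
#' @param index A `peptide_index` over the reference proteomes.
#' @param tree A `taxonomy_tree`.
#' @param design Design tibble supplying each sample's ingredient.
#' @param specificity_rank See [classify_source()].
#' @param top_n Number of proteins in the per-sample top table.
#' @return List with tibbles `peptides` (per-row LCA and class),
#'   `proteins` (per sample x razor protein) and `top_proteins`.
#' @export
assign_sample_sources <- function(evidence, index, tree, design,
                                  specificity_rank = "family", top_n = 5L) {
  ingredient_of <- setNames(design$ingredient, design$sample_id)
  uniq_pep <- unique(evidence$sequence)
  taxa_sets <- lapply(uniq_pep, function(p) index_taxa(index, p))
  names(taxa_sets) <- uniq_pep
  lca_of <- vapply(taxa_sets, function(t) {
    if (length(t) == 0L) NA_character_ else lca(t, tree)
  }, character(1L))

  classify1 <- function(node, ingredient) {
    if (is.na(node)) return("unassigned")
    if (is.na(ingredient)) return("unassigned")
    classify_source(node, ingredient, tree, specificity_rank)
  }
  pep_lca <- unname(lca_of[evidence$sequence])
  pep_class <- mapply(classify1, pep_lca,
                      unname(ingredient_of[evidence$sample_id]))
  rank_of <- setNames(tree$nodes$rank, tree$nodes$taxon_id)
  peptides <- tibble::tibble(
    sample_id = evidence$sample_id,
    sequence = evidence$sequence,
    lca = pep_lca,
    lca_rank = ifelse(is.na(pep_lca), NA_character_,
                      unname(rank_of[pep_lca])),
    source_class = unname(pep_class)
  )

  prot <- evidence |>
    dplyr::group_by(.data$sample_id, .data$leading_razor_protein) |>
    dplyr::summarise(
      peptide_count = dplyr::n(),
      psm_total = sum(.data$psm_count),
      taxa = list(sort(unique(unlist(taxa_sets[unique(.data$sequence)])))),
      .groups = "drop"
    )
  prot$lca <- vapply(prot$taxa, function(t) {
    if (length(t) == 0L) NA_character_ else lca(t, tree)
  }, character(1L))
  prot$source_class <- unname(mapply(
    classify1, prot$lca, unname(ingredient_of[prot$sample_id])
  ))
  proteins <- prot |>
    dplyr::select(!"taxa") |>
    dplyr::rename(accession = "leading_razor_protein")

  top_proteins <- proteins |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$peptide_count), .data$accession,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup()

  list(peptides = peptides, proteins = proteins, top_proteins = top_proteins)
}
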