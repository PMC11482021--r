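#' Read a reference proteome from FASTA
#'
#' Parses a standard FASTA file of amino-acid sequences into the protein
#' table used throughout the package. The accession is the first
#' whitespace-delimited token of each header. Taxon and category
#' assignments are taken from a sidecar table (accession, taxon_id,
#' category) rather than parsed out of headers, because header
#' conventions vary between databases.
#'
#' @param path Path to a FASTA file.
#' @param meta Optional sidecar: either a path to a TSV with columns
#'   `accession`, `taxon_id`, `category`, or a data frame with those
#'   columns. `category` must be `"target"` or `"contaminant"`
#'   (contaminant entries play the role of a cRAP-style laboratory
#'   contaminant database). When absent, all proteins are `"target"`
#'   with unknown taxon.
#' @return A tibble with columns `accession`, `sequence`, `taxon_id`,
#'   `category`, in file order.
#' @export
read_fasta <- function(path, meta = NULL) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) abort(sprintf("FASTA file is empty: %s", path))
  accession <- sub("\\s.*$", "", names(seqs))
  dup <- accession[duplicated(accession)]
  if (length(dup)) {
    abort(sprintf("duplicate accession in FASTA: %s", dup[[1L]]))
  }
  sequence <- toupper(as.character(seqs))
  off <- .canonical_violation(sequence)
  bad <- which(!is.na(off))
  if (length(bad)) {
    i <- bad[[1L]]
    abort(sprintf(
      "non-canonical residue '%s' at zero-based position %d in entry '%s'",
      substr(sequence[[i]], off[[i]] + 1L, off[[i]] + 1L),
      off[[i]], accession[[i]]
    ))
  }
  proteins <- tibble::tibble(
    accession = accession,
    sequence = unname(sequence),
    taxon_id = NA_character_,
    category = "target"
  )
  if (!is.null(meta)) {
    if (is.character(meta)) {
      meta <- readr::read_tsv(meta, col_types = readr::cols(.default = "c"))
    }
    meta <- tibble::as_tibble(meta)
    need <- c("accession", "taxon_id", "category")
    miss <- setdiff(need, names(meta))
    if (length(miss)) {
      abort(sprintf("protein sidecar is missing column(s): %s",
                    paste(miss, collapse = ", ")))
    }
    if (!all(meta$category %in% c("target", "contaminant"))) {
      abort("protein category must be 'target' or 'contaminant'")
    }
    idx <- match(proteins$accession, meta$accession)
    if (anyNA(idx)) {
      abort(sprintf("no sidecar entry for accession '%s'",
                    proteins$accession[which(is.na(idx))[1L]]))
    }
    proteins$taxon_id <- meta$taxon_id[idx]
    proteins$category <- meta$category[idx]
  }
  proteins
}

#' Write a protein table to FASTA (plus optional sidecar)
#'
#' @param proteins Protein tibble as returned by [read_fasta()].
#' @param path Output FASTA path.
#' @param meta_path Optional path for the taxon/category sidecar TSV.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, meta_path = NULL, width = 60L) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$accession))
  Biostrings::writeXStringSet(aa, path, width = width)
  if (!is.null(meta_path)) {
    readr::write_tsv(
      tibble::tibble(
        accession = proteins$accession,
        taxon_id = proteins$taxon_id,
        category = proteins$category
      ),
      meta_path
    )
  }
  invisible(path)
}

#' Parse a modification string into typed positional modifications
#'
#' The dialect is `"<token>@<pos>"` entries joined by `";"`, with
#' zero-based positions into the peptide, e.g.
#' `"Deamidation (NQ)@3;Oxidation (M)@0"`. An empty string means no
#' modifications.
#'
#' @param modifications Character vector of modification strings.
#' @param sequences Peptide sequences of equal length (used to validate
#'   positions and residue compatibility).
#' @return A list of tibbles with columns `type` (one of
#'   `r paste(names(MOD_TOKENS), collapse = ", ")`) and `pos`.
#' @export
parse_modifications <- function(modifications, sequences) {
  stopifnot(length(modifications) == length(sequences))
  modifications[is.na(modifications)] <- ""
  purrr::map2(modifications, sequences, function(m, s) {
    if (!nzchar(m)) {
      return(tibble::tibble(type = character(), pos = integer()))
    }
    toks <- strsplit(m, ";", fixed = TRUE)[[1L]]
    at <- regexpr("@", toks, fixed = TRUE)
    if (any(at < 0L)) {
      abort(sprintf("malformed modification token: '%s'",
                    toks[which(at < 0L)[1L]]))
    }
    name <- substr(toks, 1L, at - 1L)
    pos <- suppressWarnings(as.integer(substring(toks, at + 1L)))
    type <- names(MOD_TOKENS)[match(name, MOD_TOKENS)]
    bad <- which(is.na(type) | is.na(pos))
    if (length(bad)) {
      abort(sprintf("malformed modification token: '%s'", toks[bad[[1L]]]))
    }
    n <- nchar(s)
    if (any(pos < 0L | pos >= n)) {
      abort(sprintf(
        "modification position out of range in '%s' for peptide '%s'",
        m, s
      ))
    }
    res <- substring(s, pos + 1L, pos + 1L)
    for (i in seq_along(type)) {
      allowed <- MOD_RESIDUES[[type[[i]]]]
      if (is.null(allowed)) {
        if (pos[[i]] != 0L) {
          abort(sprintf(
            "modification '%s' must sit at position 0 (peptide '%s')",
            name[[i]], s
          ))
        }
      } else if (!res[[i]] %in% allowed) {
        abort(sprintf(
          "modification '%s' at position %d is incompatible with residue '%s' in peptide '%s'",
          name[[i]], pos[[i]], res[[i]], s
        ))
      }
    }
    tibble::tibble(type = type, pos = pos)
  })
}

.EVIDENCE_COLS <- c(
  "Sample", "Sequence", "Modifications", "Proteins",
  "Leading razor protein", "MS/MS count"
)

#' Read a peptide evidence table
#'
#' Reads the documented search-engine-style evidence dialect: a TSV with
#' columns `Sample`, `Sequence`, `Modifications`, `Proteins` (accessions
#' joined by `";"`), `Leading razor protein` and `MS/MS count`. All
#' rows are validated: canonical sequences, parseable modification
#' tokens compatible with their residues, razor protein contained in the
#' protein list, and positive PSM counts.
#'
#' @param path Path to the evidence TSV.
#' @return A tibble with columns `sample_id`, `sequence`,
#'   `modifications` (token string), `protein_ids` (list column),
#'   `leading_razor_protein`, `psm_count`.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) abort(sprintf("evidence file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  miss <- setdiff(.EVIDENCE_COLS, names(raw))
  if (length(miss)) {
    abort(sprintf("evidence table is missing required column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  ev <- tibble::tibble(
    sample_id = raw$Sample,
    sequence = toupper(raw$Sequence),
    modifications = dplyr::coalesce(raw$Modifications, ""),
    protein_ids = strsplit(dplyr::coalesce(raw$Proteins, ""), ";", fixed = TRUE),
    leading_razor_protein = raw$`Leading razor protein`,
    psm_count = as.integer(raw$`MS/MS count`)
  )
  validate_evidence(ev)
}

#' Validate an evidence tibble against the data-model invariants
#'
#' @param evidence Evidence tibble (see [read_evidence()] for columns).
#' @return The validated tibble, invisibly identical to the input.
#' @export
validate_evidence <- function(evidence) {
  assert_canonical(evidence$sequence, "peptide")
  if (any(is.na(evidence$psm_count) | evidence$psm_count <= 0L)) {
    i <- which(is.na(evidence$psm_count) | evidence$psm_count <= 0L)[1L]
    abort(sprintf(
      "PSM count must be a positive integer (row %d, peptide '%s')",
      i, evidence$sequence[[i]]
    ))
  }
  ok_razor <- mapply(
    function(p, r) length(p) > 0L && r %in% p,
    evidence$protein_ids, evidence$leading_razor_protein
  )
  if (!all(ok_razor)) {
    i <- which(!ok_razor)[1L]
    abort(sprintf(
      "leading razor protein '%s' is not among the protein ids (row %d)",
      evidence$leading_razor_protein[[i]], i
    ))
  }
  parse_modifications(evidence$modifications, evidence$sequence)
  evidence
}

#' Write an evidence tibble in the documented TSV dialect
#'
#' @param evidence Evidence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  out <- tibble::tibble(
    Sample = evidence$sample_id,
    Sequence = evidence$sequence,
    Modifications = evidence$modifications,
    Proteins = vapply(evidence$protein_ids, paste, "", collapse = ";"),
    `Leading razor protein` = evidence$leading_razor_protein,
    `MS/MS count` = evidence$psm_count
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a taxonomy tree
#'
#' The format is a TSV with columns `taxon_id`, `parent_id`, `name`,
#' `rank`; exactly one row (the root) has `taxon_id == parent_id`.
#'
#' @param path Path to the taxonomy TSV.
#' @return A `taxonomy_tree` object: list with a `nodes` tibble and a
#'   named `parent` character vector.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(sprintf("taxonomy file not found: %s", path))
  nodes <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  miss <- setdiff(c("taxon_id", "parent_id", "name", "rank"), names(nodes))
  if (length(miss)) {
    abort(sprintf("taxonomy table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  taxonomy_tree(nodes)
}

#' Construct and validate a taxonomy tree
#'
#' @param nodes Data frame with columns `taxon_id`, `parent_id`, `name`,
#'   `rank`.
#' @return A validated `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  if (anyDuplicated(nodes$taxon_id)) {
    abort(sprintf("duplicate taxon_id: %s",
                  nodes$taxon_id[duplicated(nodes$taxon_id)][1L]))
  }
  if (!all(nodes$rank %in% TAXON_RANKS)) {
    abort(sprintf("unknown rank: %s",
                  setdiff(nodes$rank, TAXON_RANKS)[1L]))
  }
  root <- nodes$taxon_id[nodes$taxon_id == nodes$parent_id]
  if (length(root) != 1L) {
    abort(sprintf("taxonomy must have exactly one root, found %d",
                  length(root)))
  }
  orphan <- setdiff(nodes$parent_id, nodes$taxon_id)
  if (length(orphan)) {
    abort(sprintf("orphan parent reference: %s", orphan[[1L]]))
  }
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  # Walk each node to the root; a walk longer than the node count is a cycle.
  n <- nrow(nodes)
  for (id in nodes$taxon_id) {
    cur <- id
    steps <- 0L
    while (cur != root) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > n) {
        abort(sprintf("taxonomy contains a cycle through node '%s'", id))
      }
    }
  }
  structure(list(nodes = nodes, parent = parent, root = root),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, root '%s'\n",
              nrow(x$nodes), x$root))
  invisible(x)
}

#' Write a taxonomy tree
#'
#' @param tree A `taxonomy_tree`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tree, path) {
  readr::write_tsv(tree$nodes, path)
  invisible(path)
}

#' Path from a taxon to the root (self first)
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_id A taxon id present in the tree.
#' @return Character vector of taxon ids from `taxon_id` up to the root.
#' @export
taxon_lineage <- function(tree, taxon_id) {
  if (!taxon_id %in% names(tree$parent)) {
    abort(sprintf("unknown taxon: %s", taxon_id))
  }
  out <- taxon_id
  cur <- taxon_id
  while (cur != tree$root) {
    cur <- tree$parent[[cur]]
    out <- c(out, cur)
  }
  out
}

#' Read per-protein residue annotation tracks
#'
#' One row per accession with a scalar melting temperature and four
#' packed per-residue tracks: `ss8` is a string over the eight-state
#' alphabet `G,H,I,E,B,T,S,L`; `rsa`, `disorder` and `amyloid` are
#' comma-separated numbers in `[0, 1]`. Every track must have exactly
#' the length of the protein sequence.
#'
#' @param path Path to the annotation TSV.
#' @param proteins Protein tibble the annotations refer to.
#' @return A `residue_annotations` object: a named list (by accession) of
#'   lists with elements `ss8`, `rsa`, `disorder`, `amyloid`,
#'   `tm_celsius`.
#' @export
read_annotations <- function(path, proteins) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("accession", "tm_celsius", "ss8", "rsa", "disorder", "amyloid")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("annotation table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  ann <- lapply(seq_len(nrow(raw)), function(i) {
    list(
      ss8 = raw$ss8[[i]],
      rsa = as.numeric(strsplit(raw$rsa[[i]], ",", fixed = TRUE)[[1L]]),
      disorder = as.numeric(strsplit(raw$disorder[[i]], ",", fixed = TRUE)[[1L]]),
      amyloid = as.numeric(strsplit(raw$amyloid[[i]], ",", fixed = TRUE)[[1L]]),
      tm_celsius = as.numeric(raw$tm_celsius[[i]])
    )
  })
  names(ann) <- raw$accession
  residue_annotations(ann, proteins)
}

#' Construct and validate a residue annotation set
#'
#' @param annotations Named list (by accession) of lists with `ss8`,
#'   `rsa`, `disorder`, `amyloid`, `tm_celsius`.
#' @param proteins Protein tibble providing sequence lengths.
#' @return A validated `residue_annotations` object.
#' @export
residue_annotations <- function(annotations, proteins) {
  lens <- setNames(nchar(proteins$sequence), proteins$accession)
  for (acc in names(annotations)) {
    if (!acc %in% names(lens)) {
      abort(sprintf("annotations refer to unknown accession '%s'", acc))
    }
    a <- annotations[[acc]]
    n <- lens[[acc]]
    track_len <- c(
      ss8 = nchar(a$ss8), rsa = length(a$rsa),
      disorder = length(a$disorder), amyloid = length(a$amyloid)
    )
    bad <- which(track_len != n)
    if (length(bad)) {
      abort(sprintf(
        "annotation track '%s' for '%s' has length %d but the protein has %d residues",
        names(track_len)[bad[[1L]]], acc, track_len[[bad[[1L]]]], n
      ))
    }
    if (grepl(sprintf("[^%s]", paste(SS8_ALPHABET, collapse = "")), a$ss8)) {
      abort(sprintf("ss8 track for '%s' contains a character outside {%s}",
                    acc, paste(SS8_ALPHABET, collapse = ",")))
    }
    for (tr in c("rsa", "disorder", "amyloid")) {
      v <- a[[tr]]
      if (anyNA(v) || any(v < 0 | v > 1)) {
        abort(sprintf("track '%s' for '%s' must lie in [0, 1]", tr, acc))
      }
    }
    if (is.na(a$tm_celsius)) {
      abort(sprintf("missing melting temperature for '%s'", acc))
    }
  }
  structure(annotations, class = "residue_annotations")
}

#' @export
print.residue_annotations <- function(x, ...) {
  cat(sprintf("<residue_annotations> %d proteins\n", length(x)))
  invisible(x)
}

#' Write residue annotations
#'
#' Numeric tracks are serialised at full precision so a write/read
#' round-trip reproduces the values exactly.
#'
#' @param annotations A `residue_annotations` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  fmt <- function(v) paste(vapply(v, format, "", digits = 17), collapse = ",")
  out <- tibble::tibble(
    accession = names(annotations),
    tm_celsius = vapply(annotations, function(a) format(a$tm_celsius, digits = 17), ""),
    ss8 = vapply(annotations, function(a) a$ss8, ""),
    rsa = vapply(annotations, function(a) fmt(a$rsa), ""),
    disorder = vapply(annotations, function(a) fmt(a$disorder), ""),
    amyloid = vapply(annotations, function(a) fmt(a$amyloid), "")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a sample design table
#'
#' Columns: `sample_id`, `ingredient` (taxon id, empty for washes),
#' `matrix` (`fresh`, `foodcrust`, `ceramic` or `wash`), `burial`
#' (`unburied`/`buried`), `replicate`, `cofire_group` (shared by samples
#' cooked over the same fire; empty if none) and `run_order` (injection
#' sequence position).
#'
#' @param path Path to the design TSV.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("design file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("sample_id", "ingredient", "matrix", "burial", "replicate",
            "cofire_group", "run_order")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("design table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  design <- tibble::tibble(
    sample_id = raw$sample_id,
    ingredient = dplyr::na_if(raw$ingredient, ""),
    matrix = raw$matrix,
    burial = raw$burial,
    replicate = as.integer(raw$replicate),
    cofire_group = dplyr::na_if(raw$cofire_group, ""),
    run_order = as.integer(raw$run_order)
  )
  validate_design(design)
}

#' Validate a design tibble
#'
#' @param design Design tibble (see [read_design()]).
#' @return The validated tibble.
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  if (anyDuplicated(design$sample_id)) {
    abort("duplicate sample_id in design")
  }
  if (!all(design$matrix %in% MATRIX_LEVELS)) {
    abort(sprintf("unknown matrix value: %s",
                  setdiff(design$matrix, MATRIX_LEVELS)[1L]))
  }
  if (!all(design$burial %in% BURIAL_LEVELS)) {
    abort(sprintf("unknown burial value: %s",
                  setdiff(design$burial, BURIAL_LEVELS)[1L]))
  }
  if (any(design$matrix == "fresh" & design$burial != "unburied")) {
    abort("fresh samples must be unburied")
  }
  if (any(design$matrix == "wash" & !is.na(design$ingredient))) {
    abort("wash samples must have no ingredient")
  }
  if (anyDuplicated(design$run_order)) {
    abort("run_order values must be unique")
  }
  design
}

#' Write a sample design table
#'
#' @param design Design tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}
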