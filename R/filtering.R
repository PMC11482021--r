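#' @name filtering
#' @title Evidence filtering ledger
#' @description
#' The filters applied to post-search evidence tables before any
#' characterisation: search-parameter filters (length, missed
#' cleavages), laboratory contaminant removal, machine carry-over
#' removal against the preceding blank wash, sample-level exclusion by
#' cross-contaminant load, and the per-protein spectral-support rule.
#' Every filter is contractive and idempotent; the pipeline applies
#' them in a fixed, documented order because the filters do not commute.
NULL

.stage_report <- function(stage, rows_in, rows_out) {
  tibble::tibble(stage = stage, rows_in = rows_in, rows_out = rows_out,
                 rows_removed = rows_in - rows_out)
}

.removed_rows <- function(evidence, drop, reason) {
  tibble::tibble(
    sample_id = evidence$sample_id[drop],
    sequence = evidence$sequence[drop],
    reason = rep.int(reason, sum(drop))
  )
}

#' Search-parameter filters: minimum length and missed cleavages
#'
#' Retains rows whose peptide is at least `min_len` residues long and
#' carries at most `max_missed` missed tryptic cleavages.
#'
#' @param evidence Evidence tibble.
#' @param min_len Minimum peptide length (default 7).
#' @param max_missed Maximum missed cleavages (default 2).
#' @return List with the filtered `evidence`, a one-stage `report`
#'   tibble and the `removed` rows with reason codes.
#' @export
apply_search_filters <- function(evidence, min_len = 7L, max_missed = 2L) {
  n_in <- nrow(evidence)
  if (n_in == 0L) {
    return(list(evidence = evidence,
                report = .stage_report("search_filters", 0L, 0L),
                removed = .removed_rows(evidence, logical(0), character(0))))
  }
  too_short <- nchar(evidence$sequence) < min_len
  too_missed <- count_missed_cleavages(evidence$sequence) > max_missed
  drop <- too_short | too_missed
  removed <- dplyr::bind_rows(
    .removed_rows(evidence, too_short, "below_min_length"),
    .removed_rows(evidence, !too_short & too_missed, "excess_missed_cleavages")
  )
  list(evidence = evidence[!drop, , drop = FALSE],
       report = .stage_report("search_filters", n_in, sum(!drop)),
       removed = removed)
}

# TRUE for peptides occurring (I/L-equated substring) in any of the
# given protein sequences. Sequences are joined with a separator that
# cannot occur in a peptide, so one fixed-pattern scan suffices.
.occurs_in <- function(peptides, protein_sequences) {
  if (length(protein_sequences) == 0L || length(peptides) == 0L) {
    return(rep(FALSE, length(peptides)))
  }
  haystack <- il_key(paste(protein_sequences, collapse = "#"))
  vapply(il_key(peptides), function(p) grepl(p, haystack, fixed = TRUE),
         logical(1L), USE.NAMES = FALSE)
}

#' Remove laboratory contaminant peptides
#'
#' Removes every row whose peptide occurs (I/L-equated) in any
#' contaminant-category protein. Peptides shared between a contaminant
#' and a target protein are removed too: the conservative rule, since
#' such identifications cannot be distinguished from contamination.
#'
#' @param evidence Evidence tibble.
#' @param proteins Protein tibble including `category = "contaminant"`
#'   entries (a cRAP-style database).
#' @return List with `evidence`, `report`, `removed`.
#' @export
remove_contaminants <- function(evidence, proteins) {
  n_in <- nrow(evidence)
  contam_seq <- proteins$sequence[proteins$category == "contaminant"]
  drop <- if (n_in == 0L) logical(0) else
    .occurs_in(evidence$sequence, contam_seq)
  list(evidence = evidence[!drop, , drop = FALSE],
       report = .stage_report("contaminant_removal", n_in, sum(!drop)),
       removed = .removed_rows(evidence, drop, "contaminant_match"))
}

#' Remove machine carry-over against the preceding wash
#'
#' For every non-wash sample, removes peptides whose exact sequence was
#' observed in the blank wash immediately preceding the sample in the
#' injection order. Samples with no preceding wash are passed through
#' unchanged and noted in the report.
#'
#' @param evidence Evidence tibble (washes included as rows).
#' @param design Design tibble with `run_order` and wash samples.
#' @return List with `evidence`, `report`, `removed` and
#'   `no_preceding_wash` (sample ids passed through unchanged).
#' @export
carryover_filter <- function(evidence, design) {
  n_in <- nrow(evidence)
  washes <- design[design$matrix == "wash", , drop = FALSE]
  run_of <- setNames(design$run_order, design$sample_id)
  drop <- rep(FALSE, n_in)
  no_wash <- character()
  for (sid in unique(evidence$sample_id)) {
    d <- design[design$sample_id == sid, , drop = FALSE]
    if (nrow(d) == 0L || d$matrix == "wash") next
    prior <- washes[washes$run_order < d$run_order, , drop = FALSE]
    if (nrow(prior) == 0L) {
      no_wash <- c(no_wash, sid)
      next
    }
    wash_id <- prior$sample_id[which.max(prior$run_order)]
    wash_pep <- evidence$sequence[evidence$sample_id == wash_id]
    rows <- evidence$sample_id == sid
    drop[rows] <- evidence$sequence[rows] %in% wash_pep
  }
  list(evidence = evidence[!drop, , drop = FALSE],
       report = .stage_report("carryover_removal", n_in, sum(!drop)),
       removed = .removed_rows(evidence, drop, "wash_carryover"),
       no_preceding_wash = no_wash)
}

#' Sample exclusion by cross-contaminant peptide load
#'
#' A peptide in a cooked sample is a *known cross-contaminant* when it
#' occurs (I/L-equated) in a co-fired partner's ingredient proteome and
#' not in the sample's own ingredient proteome. Peptides present in
#' both proteomes are ambiguous, not known contaminants, and are never
#' counted. The percentage is computed over unique peptide rows, and
#' samples above the threshold are excluded from property
#' characterisation; the boundary is inclusive (a sample at exactly the
#' threshold is kept).
#'
#' @param evidence Evidence tibble (post carry-over filtering).
#' @param design Design tibble with `cofire_group` and `ingredient`.
#' @param proteins Protein tibble with taxon assignments.
#' @param threshold Exclusion threshold in percent (default 2).
#' @return List with `samples` (tibble: `sample_id`, `total_peptides`,
#'   `crosscontam_peptides`, `crosscontam_pct`, `included`),
#'   `included_samples` and a one-stage `report`.
#' @export
crosscontam_exclude <- function(evidence, design, proteins, threshold = 2) {
  target <- proteins[proteins$category == "target", , drop = FALSE]
  seq_of_taxon <- split(target$sequence, target$taxon_id)
  out <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, , drop = FALSE]
    if (d$matrix == "wash") next
    rows <- evidence[evidence$sample_id == d$sample_id, , drop = FALSE]
    total <- nrow(rows)
    partners <- design$ingredient[
      !is.na(design$cofire_group) & !is.na(d$cofire_group) &
        design$cofire_group == d$cofire_group &
        design$sample_id != d$sample_id
    ]
    partners <- setdiff(unique(partners[!is.na(partners)]), d$ingredient)
    if (length(partners) == 0L || total == 0L || is.na(d$ingredient)) {
      n_cc <- 0L
    } else {
      in_partner <- .occurs_in(rows$sequence,
                               unlist(seq_of_taxon[partners], use.names = FALSE))
      in_own <- .occurs_in(rows$sequence,
                           seq_of_taxon[[d$ingredient]])
      n_cc <- sum(in_partner & !in_own)
    }
    pct <- if (total == 0L) 0 else 100 * n_cc / total
    out[[length(out) + 1L]] <- tibble::tibble(
      sample_id = d$sample_id, total_peptides = total,
      crosscontam_peptides = n_cc, crosscontam_pct = pct,
      included = pct <= threshold
    )
  }
  samples <- dplyr::bind_rows(out)
  list(
    samples = samples,
    included_samples = samples$sample_id[samples$included],
    report = .stage_report("crosscontam_exclusion",
                           nrow(samples), sum(samples$included))
  )
}

#' Per-protein spectral support filter
#'
#' Retains, per sample, the leading-razor proteins whose summed PSM
#' count across the sample's rows reaches `min_psm`. The default of 2
#' encodes the ">1 peptide spectral match" support rule; a stricter
#' value (e.g. 3, "greater than two PSMs") can be requested.
#'
#' @param evidence Evidence tibble.
#' @param min_psm Minimum summed PSM count (default 2).
#' @return List with `proteins` (tibble: `sample_id`, `accession`,
#'   `psm_total`, `peptide_rows`, `supported`), the supported subset
#'   `supported_proteins`, and a `report`.
#' @export
protein_support_filter <- function(evidence, min_psm = 2L) {
  if (nrow(evidence) == 0L) {
    empty <- tibble::tibble(sample_id = character(), accession = character(),
                            psm_total = integer(), peptide_rows = integer(),
                            supported = logical())
    return(list(proteins = empty, supported_proteins = empty,
                report = .stage_report("protein_support", 0L, 0L)))
  }
  tab <- evidence |>
    dplyr::group_by(.data$sample_id,
                    accession = .data$leading_razor_protein) |>
    dplyr::summarise(psm_total = sum(.data$psm_count),
                     peptide_rows = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(supported = .data$psm_total >= min_psm)
  list(proteins = tab,
       supported_proteins = tab[tab$supported, , drop = FALSE],
       report = .stage_report("protein_support", nrow(tab),
                              sum(tab$supported)))
}

#' Run the full filtering ledger in its documented order
#'
#' Filters do not commute (carry-over removal changes cross-contaminant
#' percentages, contaminant removal changes carry-over sets), so the
#' pipeline fixes the order: search filters, contaminant removal,
#' carry-over removal, cross-contamination exclusion, protein support.
#' The report records the stages in execution order.
#'
#' @param evidence Evidence tibble.
#' @param proteins Protein tibble (targets plus contaminants).
#' @param design Design tibble.
#' @param min_len,max_missed See [apply_search_filters()].
#' @param min_psm See [protein_support_filter()].
#' @param crosscontam_threshold See [crosscontam_exclude()].
#' @return A `filter_report`-style list: filtered `evidence`, staged
#'   `report`, `removed` rows with reasons, per-sample `samples`
#'   inclusion table, `included_samples`, and the per-sample
#'   `supported_proteins`.
#' @export
filter_pipeline <- function(evidence, proteins, design,
                            min_len = 7L, max_missed = 2L, min_psm = 2L,
                            crosscontam_threshold = 2) {
  s1 <- apply_search_filters(evidence, min_len = min_len,
                             max_missed = max_missed)
  s2 <- remove_contaminants(s1$evidence, proteins)
  s3 <- carryover_filter(s2$evidence, design)
  s4 <- crosscontam_exclude(s3$evidence, design, proteins,
                            threshold = crosscontam_threshold)
  s5 <- protein_support_filter(s3$evidence, min_psm = min_psm)
  list(
    evidence = s3$evidence,
    report = dplyr::bind_rows(s1$report, s2$report, s3$report,
                              s4$report, s5$report),
    removed = dplyr::bind_rows(s1$removed, s2$removed, s3$removed),
    samples = s4$samples,
    included_samples = s4$included_samples,
    supported_proteins = s5$supported_proteins,
    no_preceding_wash = s3$no_preceding_wash
  )
}
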