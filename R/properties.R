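#' Kyte-Doolittle hydropathy scale
#'
#' The per-residue hydropathy constants of Kyte & Doolittle (1982), the
#' scale conventionally meant by "GRAVY". Positive values are
#' hydrophobic.
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
kyte_doolittle <- function() {
  c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  )
}

# Fast per-character lookup table indexed by UTF-8 code.
.kd_table <- local({
  kd <- c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  )
  tbl <- rep(NA_real_, 128L)
  tbl[vapply(names(kd), utf8ToInt, 0L)] <- kd
  tbl
})

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues of each peptide.
#'
#' @param sequence Character vector of peptides (canonical residues).
#' @return Numeric vector of GRAVY scores.
#' @export
gravy <- function(sequence) {
  assert_canonical(sequence, "peptide")
  vapply(sequence, function(s) mean(.kd_table[utf8ToInt(s)]),
         numeric(1L), USE.NAMES = FALSE)
}

#' IPC_peptide pKa set
#'
#' The peptide-optimised pKa values of the IPC isoelectric-point
#' calculator (Kozlowski 2016, IPC_peptide set): terminal amine and
#' carboxyl groups plus the seven ionisable side chains.
#'
#' @return Named numeric vector with entries `NTerm`, `CTerm`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y`.
#' @export
ipc_peptide_pka <- function() {
  c(
    NTerm = 9.564, CTerm = 2.383,
    C = 9.439, D = 3.887, E = 4.317, H = 6.018,
    K = 10.517, R = 12.503, Y = 10.071
  )
}

.ionizable_counts <- function(sequence) {
  cnt <- function(ch) {
    nchar(sequence) - nchar(gsub(ch, "", sequence, fixed = TRUE))
  }
  cbind(
    NTerm = rep(1L, length(sequence)), CTerm = rep(1L, length(sequence)),
    C = cnt("C"), D = cnt("D"), E = cnt("E"), H = cnt("H"),
    K = cnt("K"), R = cnt("R"), Y = cnt("Y")
  )
}

#' Net peptide charge at a given pH
#'
#' Henderson-Hasselbalch charge model: the sum of protonated fractions
#' of the basic groups (N-terminus, H, K, R) minus the deprotonated
#' fractions of the acidic groups (C-terminus, C, D, E, Y).
#'
#' @param sequence Character vector of peptides.
#' @param pH A single pH value.
#' @param pka Named pKa set, see [ipc_peptide_pka()].
#' @return Numeric vector of net charges.
#' @export
peptide_charge <- function(sequence, pH, pka = ipc_peptide_pka()) {
  assert_canonical(sequence, "peptide")
  counts <- .ionizable_counts(sequence)
  .charge_from_counts(counts, pH, pka)
}

.charge_from_counts <- function(counts, pH, pka) {
  pos_groups <- c("NTerm", "H", "K", "R")
  neg_groups <- c("CTerm", "C", "D", "E", "Y")
  q <- 0
  for (g in pos_groups) {
    q <- q + counts[, g] / (1 + 10^(pH - pka[[g]]))
  }
  for (g in neg_groups) {
    q <- q - counts[, g] / (1 + 10^(pka[[g]] - pH))
  }
  q
}

#' Peptide isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge is zero, found
#' by bisection on `[0, 14]`. Net charge is strictly decreasing in pH
#' under this model, so the root is unique.
#'
#' @param sequence Character vector of peptides.
#' @param pka Named pKa set (default [ipc_peptide_pka()]).
#' @param tol Bisection tolerance on pH (default `1e-4`).
#' @return Numeric vector of pI values in `[0, 14]`.
#' @export
isoelectric_point <- function(sequence, pka = ipc_peptide_pka(),
                              tol = 1e-4) {
  assert_canonical(sequence, "peptide")
  counts <- .ionizable_counts(sequence)
  lo <- rep(0, length(sequence))
  hi <- rep(14, length(sequence))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    q <- .charge_from_counts(counts, mid, pka)
    dec <- q > 0          # charge still positive: root lies above mid
    lo[dec] <- mid[dec]
    hi[!dec] <- mid[!dec]
  }
  (lo + hi) / 2
}

#' Pooled amino-acid composition
#'
#' Residue counts pooled over a set of peptides, normalised to sum to 1.
#'
#' @param sequence Non-empty character vector of peptides.
#' @return Named numeric vector of relative frequencies over the 20
#'   canonical residues.
#' @export
aa_composition <- function(sequence) {
  if (length(sequence) == 0L) abort("empty peptide subset")
  assert_canonical(sequence, "peptide")
  counts <- aa_count_matrix(sequence)
  total <- colSums(counts)
  total / sum(total)
}

# Counts of each canonical residue per peptide (n x 20 integer matrix).
aa_count_matrix <- function(sequence) {
  out <- vapply(AA_CANONICAL, function(a) {
    nchar(sequence) - nchar(gsub(a, "", sequence, fixed = TRUE))
  }, integer(length(sequence)))
  if (length(sequence) == 1L) out <- matrix(out, nrow = 1L,
                                            dimnames = list(NULL, AA_CANONICAL))
  out
}

#' Deamidation flag per evidence row
#'
#' @param evidence Evidence tibble.
#' @return Logical vector: does the row carry at least one
#'   deamidation (NQ) modification?
#' @export
is_deamidated <- function(evidence) {
  grepl(MOD_TOKENS[["deamidation_NQ"]], evidence$modifications, fixed = TRUE)
}

#' Proportion of deamidated peptide rows
#'
#' @param evidence Evidence tibble (possibly a subset).
#' @return Fraction of rows carrying at least one deamidation (NQ)
#'   modification; `NA` for an empty subset.
#' @export
deamidation_proportion <- function(evidence) {
  if (nrow(evidence) == 0L) return(NA_real_)
  mean(is_deamidated(evidence))
}

#' Locate a peptide in its parent protein
#'
#' Matching equates isoleucine and leucine (isobaric residues). The
#' leftmost occurrence is returned when the peptide occurs more than
#' once.
#'
#' @param peptide Peptide sequence.
#' @param protein_sequence Parent protein sequence.
#' @param accession Optional accession used in error messages.
#' @return Zero-based half-open interval as `c(start, end)`.
#' @export
map_peptide <- function(peptide, protein_sequence, accession = NULL) {
  hit <- regexpr(il_key(peptide), il_key(protein_sequence), fixed = TRUE)
  if (hit < 0L) {
    abort(sprintf("peptide '%s' does not occur in protein %s",
                  peptide, if (is.null(accession)) "sequence" else
                    sprintf("'%s'", accession)))
  }
  c(start = hit - 1L, end = hit - 1L + nchar(peptide))
}

# Tie-break priority for the dominant secondary-structure class.
SS8_PRIORITY <- c("H", "E", "L", "T", "S", "G", "B", "I")

#' Structural summary of a peptide over its annotation tracks
#'
#' Slices the parent protein's per-residue tracks over the peptide's
#' mapped interval and summarises them: the modal secondary-structure
#' class (ties broken by the fixed priority H > E > L > T > S > G > B >
#' I), the fractions of residues classified deep / intermediate /
#' exposed by relative solvent accessibility, a disorder summary and an
#' amyloid-propensity summary.
#'
#' @param peptide Peptide sequence.
#' @param protein_sequence Parent protein sequence.
#' @param annotation Annotation entry for the parent protein (an element
#'   of a `residue_annotations` object).
#' @param rsa_thresholds Length-2 numeric `(low, high)`: residues with
#'   RSA below `low` are deep, above `high` exposed, otherwise
#'   intermediate. Default `c(0.10, 0.40)`.
#' @param disorder_summary `"mean"` (default) or `"max"`.
#' @param amyloid_summary `"max"` (default) or `"mean"`.
#' @return List with `ss_dominant`, `rsa_class_fractions` (named
#'   length-3, sums to 1), `disorder_mean`, `amyloid_max`.
#' @export
peptide_structure_summary <- function(peptide, protein_sequence, annotation,
                                      rsa_thresholds = c(0.10, 0.40),
                                      disorder_summary = c("mean", "max"),
                                      amyloid_summary = c("max", "mean")) {
  disorder_summary <- match.arg(disorder_summary)
  amyloid_summary <- match.arg(amyloid_summary)
  iv <- map_peptide(peptide, protein_sequence)
  idx <- seq.int(iv[["start"]] + 1L, iv[["end"]])
  if (max(idx) > length(annotation$rsa)) {
    abort("peptide interval exceeds annotation track length")
  }
  ss <- strsplit(substr(annotation$ss8, idx[1L], idx[length(idx)]),
                 "", fixed = TRUE)[[1L]]
  tab <- table(factor(ss, levels = SS8_PRIORITY))
  ss_dominant <- SS8_PRIORITY[which.max(tab)]  # which.max takes the first
                                               # maximum, i.e. the priority order
  rsa <- annotation$rsa[idx]
  frac <- c(
    deep = mean(rsa < rsa_thresholds[[1L]]),
    intermediate = mean(rsa >= rsa_thresholds[[1L]] & rsa <= rsa_thresholds[[2L]]),
    exposed = mean(rsa > rsa_thresholds[[2L]])
  )
  dis <- annotation$disorder[idx]
  amy <- annotation$amyloid[idx]
  list(
    ss_dominant = ss_dominant,
    rsa_class_fractions = frac,
    disorder_mean = if (disorder_summary == "mean") mean(dis) else max(dis),
    amyloid_max = if (amyloid_summary == "max") max(amy) else mean(amy)
  )
}

#' Compute the full per-peptide property table
#'
#' One property record per evidence row. Sequence-derived properties
#' (length, GRAVY, pI, residue counts, deamidation flag) are always
#' computed; structural properties and the melting temperature are
#' inherited from the leading razor protein and are `NA` when that
#' protein has no annotations.
#'
#' @param evidence Filtered evidence tibble.
#' @param proteins Protein tibble resolving razor accessions.
#' @param annotations Optional `residue_annotations`.
#' @param pka pKa set for the isoelectric point.
#' @param rsa_thresholds RSA class thresholds, see
#'   [peptide_structure_summary()].
#' @return A tibble with one row per evidence row: identification
#'   columns, `length`, `gravy`, `pi`, `is_deamidated`, twenty `n_*`
#'   residue-count columns, `ss_dominant`, `rsa_deep`,
#'   `rsa_intermediate`, `rsa_exposed`, `disorder_mean`, `amyloid_max`,
#'   `tm_celsius`.
#' @export
annotate_properties <- function(evidence, proteins, annotations = NULL,
                                pka = ipc_peptide_pka(),
                                rsa_thresholds = c(0.10, 0.40)) {
  seqs <- evidence$sequence
  uniq <- unique(seqs)
  pi_map <- setNames(isoelectric_point(uniq, pka = pka), uniq)
  gravy_map <- setNames(gravy(uniq), uniq)
  counts <- aa_count_matrix(seqs)
  colnames(counts) <- paste0("n_", AA_CANONICAL)

  prot_seq <- setNames(proteins$sequence, proteins$accession)
  out <- tibble::tibble(
    sample_id = evidence$sample_id,
    sequence = seqs,
    leading_razor_protein = evidence$leading_razor_protein,
    psm_count = evidence$psm_count,
    length = nchar(seqs),
    gravy = unname(gravy_map[seqs]),
    pi = unname(pi_map[seqs]),
    is_deamidated = is_deamidated(evidence)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))

  n <- nrow(evidence)
  ss_dominant <- rep(NA_character_, n)
  rsa_deep <- rsa_int <- rsa_exp <- rep(NA_real_, n)
  disorder_mean <- amyloid_max <- tm <- rep(NA_real_, n)
  if (!is.null(annotations)) {
    key <- paste(seqs, evidence$leading_razor_protein, sep = "\r")
    first <- !duplicated(key)
    cache <- new.env(parent = emptyenv())
    for (i in which(first)) {
      acc <- evidence$leading_razor_protein[[i]]
      if (is.null(annotations[[acc]]) || !acc %in% names(prot_seq)) next
      s <- peptide_structure_summary(
        seqs[[i]], prot_seq[[acc]], annotations[[acc]],
        rsa_thresholds = rsa_thresholds
      )
      assign(key[[i]], s, envir = cache)
    }
    for (i in seq_len(n)) {
      s <- cache[[key[[i]]]]
      if (is.null(s)) next
      ss_dominant[[i]] <- s$ss_dominant
      rsa_deep[[i]] <- s$rsa_class_fractions[["deep"]]
      rsa_int[[i]] <- s$rsa_class_fractions[["intermediate"]]
      rsa_exp[[i]] <- s$rsa_class_fractions[["exposed"]]
      disorder_mean[[i]] <- s$disorder_mean
      amyloid_max[[i]] <- s$amyloid_max
      tm[[i]] <- annotations[[evidence$leading_razor_protein[[i]]]]$tm_celsius
    }
  }
  out$ss_dominant <- ss_dominant
  out$rsa_deep <- rsa_deep
  out$rsa_intermediate <- rsa_int
  out$rsa_exposed <- rsa_exp
  out$disorder_mean <- disorder_mean
  out$amyloid_max <- amyloid_max
  out$tm_celsius <- tm
  out
}
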