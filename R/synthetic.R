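#' Survival-model parameters for the extractome simulator
#'
#' Peptide retention across the fresh-to-cooked and cooked-to-buried
#' transitions follows a logistic model in peptide hydropathy and
#' length: `P(retained) = plogis(beta0 + beta_gravy * GRAVY + beta_len *
#' length)`. The defaults encode the qualitative degradation pattern of
#' experimental foodcrust studies: cooking retains most peptides, burial
#' is strongly attritional, ceramics yield a small fraction of the
#' foodcrust signal, hydrophobic peptides survive preferentially
#' (`beta_gravy > 0`) and long peptides are disfavoured
#' (`beta_len < 0`), and heating drives N/Q deamidation.
#'
#' @param beta0_cook Baseline log-odds of retention through cooking.
#' @param beta0_bury Baseline log-odds of retention through burial.
#' @param beta_gravy Effect of peptide GRAVY on retention log-odds.
#' @param beta_len Effect of peptide length on retention log-odds.
#' @param ceramic_yield Multiplicative detection probability for the
#'   ceramic matrix relative to foodcrust, in `[0, 1]`.
#' @param deamidation_rate_cook Per-N/Q-residue deamidation probability
#'   induced by heating, in `[0, 1]`.
#' @param deamidation_rate_base Baseline per-N/Q-residue deamidation
#'   probability in fresh samples.
#' @param crosscontam_frac Fraction of a co-fired sample's peptide rows
#'   injected from the partner ingredient's detected peptides.
#' @param contam_peptides_per_sample Number of keratin-like laboratory
#'   contaminant peptides injected per sample.
#' @param detect_rate Rate constant of the fresh detection model
#'   `P(detect) = 1 - exp(-detect_rate * abundance)`.
#' @param abundance_sdlog Log-sd of the per-protein log-normal
#'   abundance.
#' @param psm_mean Mean of the geometric PSM-count distribution at unit
#'   abundance.
#' @param cook_inflation_frac Fraction of proteins whose PSM counts are
#'   inflated in cooked samples (heat-denaturation exposing cleavage
#'   sites).
#' @param cook_inflation_factor PSM multiplier for inflated proteins.
#' @param wash_carryover_frac Fraction of the preceding run's peptides
#'   that appear in a blank wash.
#' @param seed Integer seed; identical parameters and seed give a
#'   byte-identical bundle.
#' @return A validated `survival_params` list.
#' @export
survival_params <- function(beta0_cook = 2,
                            beta0_bury = 0,
                            beta_gravy = 0.6,
                            beta_len = -0.08,
                            ceramic_yield = 0.02,
                            deamidation_rate_cook = 0.3,
                            deamidation_rate_base = 0.02,
                            crosscontam_frac = 0.01,
                            contam_peptides_per_sample = 25L,
                            detect_rate = 0.35,
                            abundance_sdlog = 1.5,
                            psm_mean = 3,
                            cook_inflation_frac = 0.1,
                            cook_inflation_factor = 3,
                            wash_carryover_frac = 0.01,
                            seed = 1L) {
  p <- list(
    beta0_cook = beta0_cook, beta0_bury = beta0_bury,
    beta_gravy = beta_gravy, beta_len = beta_len,
    ceramic_yield = ceramic_yield,
    deamidation_rate_cook = deamidation_rate_cook,
    deamidation_rate_base = deamidation_rate_base,
    crosscontam_frac = crosscontam_frac,
    contam_peptides_per_sample = as.integer(contam_peptides_per_sample),
    detect_rate = detect_rate, abundance_sdlog = abundance_sdlog,
    psm_mean = psm_mean,
    cook_inflation_frac = cook_inflation_frac,
    cook_inflation_factor = cook_inflation_factor,
    wash_carryover_frac = wash_carryover_frac,
    seed = as.integer(seed)
  )
  for (nm in c("ceramic_yield", "deamidation_rate_cook",
               "deamidation_rate_base", "crosscontam_frac",
               "cook_inflation_frac", "wash_carryover_frac")) {
    if (is.na(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      abort(sprintf("'%s' must lie in [0, 1]", nm))
    }
  }
  if (p$contam_peptides_per_sample < 0L) {
    abort("'contam_peptides_per_sample' must be non-negative")
  }
  structure(p, class = "survival_params")
}

# Background amino-acid frequencies used for random protein sequences
# (typical vertebrate proteome composition, normalised).
.AA_BACKGROUND <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
  G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
  M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
  S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032
)

# Eight-state secondary-structure background ratio
# (alpha-helix : beta-strand : irregular : beta-turn : high-curvature
#  loop : 3-10 helix : beta-bridge : pi-helix = 34:21:20:11:9:4:1:0).
.SS8_BACKGROUND <- c(H = 34, E = 21, L = 20, T = 11, S = 9, G = 4,
                     B = 1, I = 0) / 100

.random_sequence <- function(n) {
  paste(sample(names(.AA_BACKGROUND), n, replace = TRUE,
               prob = .AA_BACKGROUND), collapse = "")
}

.mutate_sequence <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(res)) < rate)
  for (i in hit) {
    alt <- setdiff(names(.AA_BACKGROUND), res[[i]])
    res[[i]] <- sample(alt, 1L,
                       prob = .AA_BACKGROUND[alt] / sum(.AA_BACKGROUND[alt]))
  }
  paste(res, collapse = "")
}

.random_annotation <- function(len) {
  list(
    ss8 = paste(sample(names(.SS8_BACKGROUND), len, replace = TRUE,
                       prob = .SS8_BACKGROUND), collapse = ""),
    rsa = round(rbeta(len, 2.0, 2.5), 4),
    disorder = round(rbeta(len, 1.2, 3.5), 4),
    amyloid = round(rbeta(len, 1.1, 4.0), 4),
    tm_celsius = round(max(20, rnorm(1L, 55, 8)), 2)
  )
}

#' Generate a synthetic reference: proteomes, taxonomy, annotations
#'
#' Builds `n_taxa` ingredient species, each in its own family, with the
#' families split between two kingdoms, plus a separate contaminant
#' lineage carrying keratin-like laboratory contaminant proteins. A
#' `shared_fraction` of each taxon's proteins are orthologs copied
#' across all taxa with a small per-site substitution rate, so some
#' tryptic peptides are identical across taxa and resolve to
#' non-specific LCAs. Annotation tracks are drawn per residue:
#' secondary structure from the 34:21:20:11:9:4:1:0 background ratio,
#' RSA/disorder/amyloid from beta distributions, melting temperature
#' from a normal distribution.
#'
#' @param n_taxa Number of ingredient taxa (>= 2).
#' @param proteins_per_taxon Proteins per ingredient proteome.
#' @param shared_fraction Fraction of each proteome that is orthologous
#'   across all taxa, in `[0, 1]`.
#' @param mean_length Mean protein length (lengths are normal with 20%
#'   coefficient of variation, floored at 60).
#' @param subst_rate Per-site substitution rate applied to ortholog
#'   copies (0 gives identical copies).
#' @param contam_proteins Number of contaminant proteins.
#' @param seed Integer seed.
#' @return A `reference_set`: list with `proteins`, `taxonomy`,
#'   `annotations` and `ingredient_taxa`.
#' @export
generate_reference <- function(n_taxa = 3L, proteins_per_taxon = 40L,
                               shared_fraction = 0.3, mean_length = 250L,
                               subst_rate = 0.02, contam_proteins = 3L,
                               seed = 1L) {
  if (n_taxa < 2L) abort("'n_taxa' must be at least 2")
  if (is.na(shared_fraction) || shared_fraction < 0 || shared_fraction > 1) {
    abort("'shared_fraction' must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  species <- paste0("S", seq_len(n_taxa))
  families <- paste0("F", seq_len(n_taxa))
  kingdom_of <- paste0("K", 1L + (seq_len(n_taxa) - 1L) %% 2L)
  nodes <- dplyr::bind_rows(
    tibble::tibble(taxon_id = "ROOT", parent_id = "ROOT",
                   name = "root", rank = "root"),
    tibble::tibble(taxon_id = c("K1", "K2", "KC"),
                   parent_id = "ROOT",
                   name = c("Kingdom 1", "Kingdom 2",
                            "Contaminant kingdom"),
                   rank = "kingdom"),
    tibble::tibble(taxon_id = families, parent_id = kingdom_of,
                   name = paste("Family", seq_len(n_taxa)),
                   rank = "family"),
    tibble::tibble(taxon_id = "FC", parent_id = "KC",
                   name = "Contaminant family", rank = "family"),
    tibble::tibble(taxon_id = species, parent_id = families,
                   name = paste("Species", seq_len(n_taxa)),
                   rank = "species"),
    tibble::tibble(taxon_id = "SC", parent_id = "FC",
                   name = "Contaminant species", rank = "species")
  )
  taxonomy <- taxonomy_tree(nodes)

  n_shared <- round(shared_fraction * proteins_per_taxon)
  n_unique <- proteins_per_taxon - n_shared
  draw_len <- function(k) {
    pmax(60L, as.integer(round(rnorm(k, mean_length, 0.2 * mean_length))))
  }
  rows <- list()
  # Ortholog groups: one base sequence, one (possibly mutated) copy per taxon.
  ort_len <- draw_len(n_shared)
  for (g in seq_len(n_shared)) {
    base <- .random_sequence(ort_len[[g]])
    for (t in seq_len(n_taxa)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        accession = sprintf("%s_ORT%03d", species[[t]], g),
        sequence = .mutate_sequence(base, subst_rate),
        taxon_id = species[[t]], category = "target",
        is_ortholog = TRUE, ortholog_group = g
      )
    }
  }
  for (t in seq_len(n_taxa)) {
    uq_len <- draw_len(n_unique)
    for (j in seq_len(n_unique)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        accession = sprintf("%s_UNQ%03d", species[[t]], j),
        sequence = .random_sequence(uq_len[[j]]),
        taxon_id = species[[t]], category = "target",
        is_ortholog = FALSE, ortholog_group = NA_integer_
      )
    }
  }
  for (k in seq_len(contam_proteins)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      accession = sprintf("CONT_KRT%02d", k),
      sequence = .random_sequence(draw_len(1L)),
      taxon_id = "SC", category = "contaminant",
      is_ortholog = FALSE, ortholog_group = NA_integer_
    )
  }
  proteins <- dplyr::bind_rows(rows)

  ann <- lapply(nchar(proteins$sequence), .random_annotation)
  names(ann) <- proteins$accession
  annotations <- residue_annotations(ann, proteins)

  structure(
    list(proteins = proteins, taxonomy = taxonomy,
         annotations = annotations, ingredient_taxa = species),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d proteins, %d ingredient taxa\n",
              nrow(x$proteins), length(x$ingredient_taxa)))
  invisible(x)
}

#' Digest a reference into the simulator's candidate peptide tables
#'
#' Performs the tryptic digestion once and precomputes everything the
#' simulator needs per candidate peptide (GRAVY, length, N/Q positions,
#' origin protein, cross-taxon sharing), so repeated simulations from
#' one reference are cheap.
#'
#' @param reference A `reference_set`.
#' @param max_missed,min_len,max_len Digestion parameters.
#' @return A `reference_digest` list: `by_taxon` (candidate tibble per
#'   ingredient taxon), `contaminants` (candidate tibble), and
#'   `protein_ids_of` (exact-sequence map to all containing
#'   accessions).
#' @export
digest_reference <- function(reference, max_missed = 2L, min_len = 7L,
                             max_len = 45L) {
  pr <- reference$proteins
  digests <- lapply(seq_len(nrow(pr)), function(i) {
    d <- tryptic_digest(pr$sequence[[i]], max_missed = max_missed,
                        min_len = min_len, max_len = max_len)
    if (nrow(d)) d$accession <- pr$accession[[i]]
    d
  })
  all_pep <- dplyr::bind_rows(digests)
  all_pep$taxon_id <- pr$taxon_id[match(all_pep$accession, pr$accession)]
  all_pep$category <- pr$category[match(all_pep$accession, pr$accession)]
  protein_ids_of <- lapply(split(all_pep$accession, all_pep$peptide),
                           function(a) sort(unique(a)))

  # I/L-equated peptide sets per ingredient taxon, for sharing flags.
  il_sets <- lapply(reference$ingredient_taxa, function(t) {
    unique(il_key(all_pep$peptide[all_pep$taxon_id == t]))
  })
  names(il_sets) <- reference$ingredient_taxa

  candidate_table <- function(sub) {
    sub <- sub[order(sub$peptide, sub$accession), , drop = FALSE]
    sub <- sub[!duplicated(sub$peptide), , drop = FALSE]  # origin = first
                                                          # accession alphabetically
    nq_pos <- gregexpr("[NQ]", sub$peptide)
    nq_pos <- lapply(nq_pos, function(m) if (m[[1L]] < 0L) integer() else
      as.integer(m) - 1L)
    shared_n <- rowSums(vapply(
      il_sets, function(s) il_key(sub$peptide) %in% s,
      logical(nrow(sub))
    ))
    tibble::tibble(
      peptide = sub$peptide,
      origin_accession = sub$accession,
      gravy = gravy(sub$peptide),
      length = nchar(sub$peptide),
      nq = lengths(nq_pos),
      nq_pos = nq_pos,
      in_all_taxa = shared_n == length(il_sets)
    )
  }
  by_taxon <- lapply(reference$ingredient_taxa, function(t) {
    candidate_table(all_pep[all_pep$taxon_id == t &
                              all_pep$category == "target", , drop = FALSE])
  })
  names(by_taxon) <- reference$ingredient_taxa
  contaminants <- candidate_table(
    all_pep[all_pep$category == "contaminant", , drop = FALSE]
  )
  structure(list(by_taxon = by_taxon, contaminants = contaminants,
                 protein_ids_of = protein_ids_of),
            class = "reference_digest")
}

#' Lay out a sample design with interleaved blank washes
#'
#' One fresh sample per ingredient, and `replicates` cooked samples per
#' ingredient, matrix and burial state. All cooked samples of one
#' replicate share a co-firing group (they were cooked over the same
#' fire), which is what injects field cross-contamination. A blank
#' machine wash is inserted after every sample in the injection order.
#'
#' @param ingredients Character vector of ingredient taxon ids.
#' @param replicates Cooked replicates per condition (default 3).
#' @param matrices Cooked matrices to include (subset of
#'   `c("foodcrust", "ceramic")`).
#' @param include_fresh Include one fresh sample per ingredient.
#' @param buried Include buried counterparts of each cooked sample.
#' @param washes Interleave blank washes.
#' @return A validated design tibble.
#' @export
make_design <- function(ingredients, replicates = 3L,
                        matrices = c("foodcrust", "ceramic"),
                        include_fresh = TRUE, buried = TRUE,
                        washes = TRUE) {
  stopifnot(all(matrices %in% c("foodcrust", "ceramic")))
  rows <- list()
  for (ing in ingredients) {
    if (include_fresh) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("%s_fresh_r1", ing), ingredient = ing,
        matrix = "fresh", burial = "unburied", replicate = 1L,
        cofire_group = NA_character_
      )
    }
    for (m in matrices) {
      for (b in if (buried) BURIAL_LEVELS else "unburied") {
        for (r in seq_len(replicates)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = sprintf("%s_%s_%s_r%d", ing, m, b, r),
            ingredient = ing, matrix = m, burial = b, replicate = r,
            cofire_group = sprintf("fire%d", r)
          )
        }
      }
    }
  }
  design <- dplyr::bind_rows(rows)
  if (washes) {
    wash <- tibble::tibble(
      sample_id = sprintf("wash_run%02d", seq_len(nrow(design))),
      ingredient = NA_character_, matrix = "wash", burial = "unburied",
      replicate = 1L, cofire_group = NA_character_
    )
    n <- nrow(design)
    design <- dplyr::bind_rows(design, wash)
    # sample 1, wash 1, sample 2, wash 2, ...
    design$run_order <- c(seq_len(n) * 2L - 1L, seq_len(n) * 2L)
    design <- design[order(design$run_order), , drop = FALSE]
  } else {
    design$run_order <- seq_len(nrow(design))
  }
  validate_design(design)
}

# Deterministic per-sample, per-stage substream seed (< 2^31).
.stage_seed <- function(seed, run, stage) {
  as.integer((abs(as.numeric(seed)) %% 100000) * 20011 +
               run * 131 + stage) %% 2147483647L
}

.mod_string <- function(positions) {
  if (length(positions) == 0L) return("")
  paste0(MOD_TOKENS[["deamidation_NQ"]], "@", positions, collapse = ";")
}

#' Simulate an extractome bundle
#'
#' For every sample in the design: the ingredient proteome is digested;
#' each protein receives a log-normal abundance; peptides are detected
#' in the fresh state with probability `1 - exp(-detect_rate *
#' abundance)`; cooked samples pass the fresh-detected peptides through
#' a logistic retention draw in GRAVY and length (and buried samples
#' through a second such draw); ceramic detection is thinned by
#' `ceramic_yield`; heating deamidates each N/Q residue of a retained
#' peptide with probability `deamidation_rate_cook`; PSM counts are
#' geometric with abundance-scaled mean, inflated for a random subset
#' of proteins in cooked samples. Keratin-like contaminant peptides are
#' injected into every sample, co-fired samples receive a fraction of
#' their partner ingredients' detected peptides, and each blank wash
#' carries a small subsample of the immediately preceding run.
#'
#' Every random draw comes from a per-sample, per-stage substream
#' seeded from `params$seed` and the sample's run order, and each
#' retention stage draws one uniform per candidate peptide whether or
#' not it is still alive; coefficients therefore only move thresholds
#' (common random numbers), making retained sets monotone in the
#' baseline log-odds.
#'
#' @param reference A `reference_set`.
#' @param design A design tibble (see [make_design()]).
#' @param params A `survival_params` object.
#' @param digest Optional precomputed [digest_reference()] result.
#' @return An `extractome_bundle`: list with `proteins`, `taxonomy`,
#'   `annotations`, `design`, `evidence`, `truth` and `params`.
#' @export
simulate_extractome <- function(reference, design,
                                params = survival_params(),
                                digest = NULL) {
  stopifnot(inherits(reference, "reference_set"),
            inherits(params, "survival_params"))
  design <- validate_design(design)
  if (is.null(digest)) digest <- digest_reference(reference)
  need <- unique(design$ingredient[!is.na(design$ingredient)])
  unknown <- setdiff(need, names(digest$by_taxon))
  if (length(unknown)) {
    abort(sprintf("unknown ingredient taxon: %s", unknown[[1L]]))
  }
  proteins_by_taxon <- split(
    reference$proteins$accession[reference$proteins$category == "target"],
    reference$proteins$taxon_id[reference$proteins$category == "target"]
  )
  design <- design[order(design$run_order), , drop = FALSE]

  # ---- pass 1: endogenous detection + contaminant injection -----------
  sample_rows <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, , drop = FALSE]
    if (d$matrix == "wash") next
    cand <- digest$by_taxon[[d$ingredient]]
    np <- nrow(cand)
    accs <- proteins_by_taxon[[d$ingredient]]
    cooked <- d$matrix %in% c("foodcrust", "ceramic")

    set.seed(.stage_seed(params$seed, d$run_order, 1L))
    abundance <- setNames(rlnorm(length(accs), 0, params$abundance_sdlog),
                          accs)
    a_pep <- unname(abundance[cand$origin_accession])

    set.seed(.stage_seed(params$seed, d$run_order, 2L))
    u_detect <- runif(np)
    set.seed(.stage_seed(params$seed, d$run_order, 3L))
    u_cook <- runif(np)
    set.seed(.stage_seed(params$seed, d$run_order, 4L))
    u_bury <- runif(np)
    set.seed(.stage_seed(params$seed, d$run_order, 5L))
    u_ceramic <- runif(np)
    set.seed(.stage_seed(params$seed, d$run_order, 6L))
    u_psm <- runif(np)
    set.seed(.stage_seed(params$seed, d$run_order, 7L))
    u_deam <- runif(sum(cand$nq))
    set.seed(.stage_seed(params$seed, d$run_order, 8L))
    u_inflate <- setNames(runif(length(accs)), accs)

    alive <- u_detect < (1 - exp(-params$detect_rate * a_pep))
    if (cooked) {
      p_cook <- plogis(params$beta0_cook + params$beta_gravy * cand$gravy +
                         params$beta_len * cand$length)
      alive <- alive & (u_cook < p_cook)
      if (d$burial == "buried") {
        p_bury <- plogis(params$beta0_bury + params$beta_gravy * cand$gravy +
                           params$beta_len * cand$length)
        alive <- alive & (u_bury < p_bury)
      }
      if (d$matrix == "ceramic") {
        alive <- alive & (u_ceramic < params$ceramic_yield)
      }
    }

    # Deamidation: one uniform per N/Q residue of every candidate.
    rate <- if (cooked) params$deamidation_rate_cook else
      params$deamidation_rate_base
    offsets <- cumsum(cand$nq) - cand$nq
    mods <- rep("", np)
    hit_rows <- which(alive & cand$nq > 0L)
    for (j in hit_rows) {
      u <- u_deam[offsets[[j]] + seq_len(cand$nq[[j]])]
      mods[[j]] <- .mod_string(cand$nq_pos[[j]][u < rate])
    }

    mu <- params$psm_mean * a_pep
    if (cooked) {
      inflated <- u_inflate[cand$origin_accession] < params$cook_inflation_frac
      mu <- mu * ifelse(inflated, params$cook_inflation_factor, 1)
    }
    psm <- 1L + qgeom(u_psm, prob = 1 / (1 + mu))

    keep <- which(alive)
    rows <- tibble::tibble(
      sample_id = d$sample_id,
      sequence = cand$peptide[keep],
      modifications = mods[keep],
      leading_razor_protein = cand$origin_accession[keep],
      psm_count = psm[keep],
      origin = "endogenous",
      origin_taxon = d$ingredient,
      in_all_taxa = cand$in_all_taxa[keep]
    )

    # Laboratory contaminant injection (not thinned by ceramic yield:
    # contamination enters during extraction, not cooking).
    nc <- min(params$contam_peptides_per_sample, nrow(digest$contaminants))
    if (nc > 0L) {
      set.seed(.stage_seed(params$seed, d$run_order, 9L))
      pick <- sample.int(nrow(digest$contaminants), nc)
      cpsm <- 1L + qgeom(runif(nc), prob = 0.5)
      crow <- tibble::tibble(
        sample_id = d$sample_id,
        sequence = digest$contaminants$peptide[pick],
        modifications = "",
        leading_razor_protein = digest$contaminants$origin_accession[pick],
        psm_count = cpsm,
        origin = "contaminant",
        origin_taxon = "SC",
        in_all_taxa = FALSE
      )
      crow <- crow[!crow$sequence %in% rows$sequence, , drop = FALSE]
      rows <- dplyr::bind_rows(rows, crow)
    }
    sample_rows[[d$sample_id]] <- rows
  }

  # ---- pass 2: co-firing cross-contamination --------------------------
  if (params$crosscontam_frac > 0) {
    injected <- list()
    for (i in seq_len(nrow(design))) {
      d <- design[i, , drop = FALSE]
      if (d$matrix == "wash" || is.na(d$cofire_group) ||
          !d$matrix %in% c("foodcrust", "ceramic")) next
      partners <- design$sample_id[
        !is.na(design$cofire_group) &
          design$cofire_group == d$cofire_group &
          design$sample_id != d$sample_id &
          design$ingredient != d$ingredient
      ]
      partners <- partners[!is.na(partners)]
      if (length(partners) == 0L) next
      pool <- dplyr::bind_rows(sample_rows[partners])
      pool <- pool[pool$origin == "endogenous", , drop = FALSE]
      pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
      own <- sample_rows[[d$sample_id]]
      pool <- pool[!pool$sequence %in% own$sequence, , drop = FALSE]
      n_inj <- min(nrow(pool),
                   round(params$crosscontam_frac * nrow(own)))
      if (n_inj <= 0L) next
      set.seed(.stage_seed(params$seed, d$run_order, 10L))
      pick <- sample.int(nrow(pool), n_inj)
      inj <- pool[pick, , drop = FALSE]
      inj$sample_id <- d$sample_id
      inj$psm_count <- 1L
      inj$origin <- "crosscontam"
      injected[[d$sample_id]] <- inj
    }
    for (sid in names(injected)) {
      sample_rows[[sid]] <- dplyr::bind_rows(sample_rows[[sid]],
                                             injected[[sid]])
    }
  }

  # ---- pass 3: blank washes (carry-over from the preceding run) -------
  for (i in seq_len(nrow(design))) {
    d <- design[i, , drop = FALSE]
    if (d$matrix != "wash") next
    prev <- design[design$run_order < d$run_order &
                     design$matrix != "wash", , drop = FALSE]
    rows <- tibble::tibble(
      sample_id = character(), sequence = character(),
      modifications = character(), leading_razor_protein = character(),
      psm_count = integer(), origin = character(),
      origin_taxon = character(), in_all_taxa = logical()
    )
    if (nrow(prev) > 0L) {
      prev_id <- prev$sample_id[which.max(prev$run_order)]
      # only carry over if the previous run is adjacent in run order
      if (design$run_order[design$sample_id == prev_id] == d$run_order - 1L) {
        src <- sample_rows[[prev_id]]
        n_carry <- ceiling(params$wash_carryover_frac * nrow(src))
        if (nrow(src) > 0L && n_carry > 0L) {
          set.seed(.stage_seed(params$seed, d$run_order, 11L))
          pick <- sample.int(nrow(src), min(n_carry, nrow(src)))
          rows <- src[pick, , drop = FALSE]
          rows$sample_id <- d$sample_id
          rows$psm_count <- 1L
          rows$origin <- "carryover"
        }
      }
    }
    sample_rows[[d$sample_id]] <- rows
  }

  # ---- assemble evidence + truth --------------------------------------
  ordered_ids <- design$sample_id[order(design$run_order)]
  all_rows <- dplyr::bind_rows(sample_rows[
    ordered_ids[ordered_ids %in% names(sample_rows)]
  ])
  all_rows <- all_rows |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(.data$sequence, .by_group = TRUE) |>
    dplyr::ungroup()
  # restore run order as primary sort
  ord <- order(match(all_rows$sample_id, ordered_ids))
  all_rows <- all_rows[ord, , drop = FALSE]

  evidence <- tibble::tibble(
    sample_id = all_rows$sample_id,
    sequence = all_rows$sequence,
    modifications = all_rows$modifications,
    protein_ids = unname(digest$protein_ids_of[all_rows$sequence]),
    leading_razor_protein = all_rows$leading_razor_protein,
    psm_count = as.integer(all_rows$psm_count)
  )
  truth <- tibble::tibble(
    sample_id = all_rows$sample_id,
    sequence = all_rows$sequence,
    origin = all_rows$origin,
    origin_accession = all_rows$leading_razor_protein,
    origin_taxon = all_rows$origin_taxon,
    in_all_taxa = all_rows$in_all_taxa
  )
  structure(
    list(proteins = reference$proteins, taxonomy = reference$taxonomy,
         annotations = reference$annotations, design = design,
         evidence = evidence, truth = truth, params = params),
    class = "extractome_bundle"
  )
}

#' @export
print.extractome_bundle <- function(x, ...) {
  cat(sprintf("<extractome_bundle> %d evidence rows, %d samples\n",
              nrow(x$evidence), nrow(x$design)))
  invisible(x)
}

#' Write a bundle to a directory in the package's file formats
#'
#' Emits `proteins.fasta`, `proteins_meta.tsv`, `taxonomy.tsv`,
#' `annotations.tsv`, `design.tsv`, `evidence.tsv` and `truth.tsv`.
#'
#' @param bundle An `extractome_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(bundle$proteins, file.path(dir, "proteins.fasta"),
              meta_path = file.path(dir, "proteins_meta.tsv"))
  write_taxonomy(bundle$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_annotations(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_design(bundle$design, file.path(dir, "design.tsv"))
  write_evidence(bundle$evidence, file.path(dir, "evidence.tsv"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
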