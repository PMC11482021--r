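toy_inputs <- function() {
  proteins <- read_fasta(toy_file("proteins.fasta"),
                         meta = toy_file("proteins_meta.tsv"))
  list(
    proteins = proteins,
    evidence = read_evidence(toy_file("evidence.tsv")),
    design = read_design(toy_file("design.tsv")),
    taxonomy = read_taxonomy(toy_file("taxonomy.tsv"))
  )
}

test_that("search filters drop short and over-cleaved peptides", {
  ev <- minimal_evidence("S1", c("AAGTK", "AVLDEAT", "TIKDEKAMK",
                                 "TIKDEKAMKLLK"))
  # TIKDEKAMKLLK has internal K at 3, 6, 9 -> 3 missed cleavages
  out <- apply_search_filters(ev)
  expect_setequal(out$evidence$sequence, c("AVLDEAT", "TIKDEKAMK"))
  expect_equal(out$report$rows_in, 4L)
  expect_equal(out$report$rows_out, 2L)
  expect_setequal(out$removed$reason,
                  c("below_min_length", "excess_missed_cleavages"))

  empty <- apply_search_filters(ev[0, ])
  expect_equal(nrow(empty$evidence), 0L)
  expect_equal(empty$report$rows_in, 0L)
  expect_equal(empty$report$rows_removed, 0L)
})

test_that("contaminant removal is conservative about shared peptides", {
  proteins <- tibble::tibble(
    accession = c("TGT1", "KRT1"),
    sequence = c("AVLDEATMKSSLMDTYWK", "MMGYAVDLKSSLMDTYWK"),
    taxon_id = c("T1", "TC"),
    category = c("target", "contaminant")
  )
  ev <- minimal_evidence("S1", c("MMGYAVDLK",   # contaminant-only
                                 "SSLMDTYWK",   # shared -> removed
                                 "AVLDEATMK"),  # target-only
                         razor = "TGT1")
  out <- remove_contaminants(ev, proteins)
  expect_equal(out$evidence$sequence, "AVLDEATMK")
  expect_equal(out$report$rows_removed, 2L)
  # I/L equivalence: the isoleucine variant is still a contaminant match
  ev_il <- minimal_evidence("S1", "SSIMDTYWK", razor = "TGT1")
  expect_equal(nrow(remove_contaminants(ev_il, proteins)$evidence), 0L)
})

test_that("carry-over removal only consults the immediately preceding wash", {
  design <- tibble::tibble(
    sample_id = c("S1", "W1", "S2", "W2"),
    ingredient = c("T1", NA, "T1", NA),
    matrix = c("foodcrust", "wash", "foodcrust", "wash"),
    burial = "unburied", replicate = 1L,
    cofire_group = NA_character_,
    run_order = 1:4
  )
  ev <- dplyr::bind_rows(
    minimal_evidence("S1", c("AVLDEATMK", "GHSNTFELK")),
    minimal_evidence("W1", "AVLDEATMK"),
    minimal_evidence("S2", c("AVLDEATMK", "GHSNTFELK")),
    minimal_evidence("W2", "GHSNTFELK")
  )
  out <- carryover_filter(ev, design)
  s2 <- out$evidence$sequence[out$evidence$sample_id == "S2"]
  # AVLDEATMK was in W1 (preceding) -> removed; GHSNTFELK is only in W2
  # (after S2) -> retained
  expect_equal(s2, "GHSNTFELK")
  # S1 has no preceding wash -> untouched, and noted
  s1 <- out$evidence$sequence[out$evidence$sample_id == "S1"]
  expect_setequal(s1, c("AVLDEATMK", "GHSNTFELK"))
  expect_equal(out$no_preceding_wash, "S1")
  # no washes at all -> identity
  d2 <- design[design$matrix != "wash", ]
  ev2 <- ev[ev$sample_id %in% d2$sample_id, ]
  expect_equal(carryover_filter(ev2, d2)$evidence, ev2)
})

test_that("cross-contamination exclusion applies the inclusive 2% rule", {
  own_pep <- make_tryptic_peptides(98L)
  partner_pep <- make_tryptic_peptides(2L, len = 10L)
  shared_pep <- "CCWWYYHHK"
  proteins <- tibble::tibble(
    accession = c("OWN1", "PART1"),
    sequence = c(paste(c(own_pep, shared_pep), collapse = ""),
                 paste(c(partner_pep, shared_pep), collapse = "")),
    taxon_id = c("T_OWN", "T_PART"),
    category = "target"
  )
  design <- tibble::tibble(
    sample_id = c("A", "B", "C"),
    ingredient = c("T_OWN", "T_OWN", "T_PART"),
    matrix = "foodcrust", burial = "unburied", replicate = 1:3,
    cofire_group = "fire1", run_order = 1:3
  )
  # sample A: 98 own + 2 partner-unique = 100 rows -> exactly 2.0%
  evA <- minimal_evidence("A", c(own_pep, partner_pep), razor = "OWN1")
  # sample B: 97 own + 2 partner-unique = 99 rows -> 2.0202%
  evB <- minimal_evidence("B", c(own_pep[1:97], partner_pep),
                          razor = "OWN1")
  out <- crosscontam_exclude(dplyr::bind_rows(evA, evB), design, proteins)
  a <- out$samples[out$samples$sample_id == "A", ]
  b <- out$samples[out$samples$sample_id == "B", ]
  expect_equal(a$crosscontam_pct, 2)
  expect_true(a$included)
  expect_equal(b$crosscontam_pct, 100 * 2 / 99)
  expect_false(b$included)
  # a peptide present in both proteomes is ambiguous, never counted
  evS <- minimal_evidence("A", c(own_pep, shared_pep), razor = "OWN1")
  outS <- crosscontam_exclude(evS, design, proteins)
  expect_equal(outS$samples$crosscontam_peptides[
    outS$samples$sample_id == "A"], 0L)
})

test_that("samples without a co-firing group score zero cross-contamination", {
  proteins <- tibble::tibble(
    accession = "P1", sequence = "AVLDEATMK",
    taxon_id = "T1", category = "target"
  )
  design <- tibble::tibble(
    sample_id = "F1", ingredient = "T1", matrix = "fresh",
    burial = "unburied", replicate = 1L,
    cofire_group = NA_character_, run_order = 1L
  )
  ev <- minimal_evidence("F1", "AVLDEATMK")
  out <- crosscontam_exclude(ev, design, proteins)
  expect_equal(out$samples$crosscontam_pct, 0)
  expect_true(out$samples$included)
})

test_that("protein support requires the summed PSM threshold", {
  ev <- dplyr::bind_rows(
    minimal_evidence("S1", "AVLDEATMK", razor = "P1", psm = 1L),
    minimal_evidence("S1", c("GHSNTFELK", "LNVQPYDTR"), razor = "P2",
                     psm = 1L)
  )
  out <- protein_support_filter(ev, min_psm = 2L)
  expect_equal(out$supported_proteins$accession, "P2")
  # single PSM-2 row also suffices
  ev2 <- minimal_evidence("S1", "AVLDEATMK", razor = "P1", psm = 2L)
  expect_equal(protein_support_filter(ev2)$supported_proteins$accession,
               "P1")
  empty <- protein_support_filter(ev[0, ])
  expect_equal(nrow(empty$proteins), 0L)
})

test_that("filters are contractive and idempotent", {
  toy <- toy_inputs()
  s1 <- apply_search_filters(toy$evidence)
  expect_true(all(s1$evidence$sequence %in% toy$evidence$sequence))
  expect_equal(apply_search_filters(s1$evidence)$evidence, s1$evidence)
  s2 <- remove_contaminants(s1$evidence, toy$proteins)
  expect_equal(remove_contaminants(s2$evidence, toy$proteins)$evidence,
               s2$evidence)
  s3 <- carryover_filter(s2$evidence, toy$design)
  expect_equal(carryover_filter(s3$evidence, toy$design)$evidence,
               s3$evidence)
})

test_that("the toy fixture resolves to the frozen filtering ledger", {
  toy <- toy_inputs()
  out <- filter_pipeline(toy$evidence, toy$proteins, toy$design)
  expect_equal(out$report$stage,
               c("search_filters", "contaminant_removal",
                 "carryover_removal", "crosscontam_exclusion",
                 "protein_support"))
  expect_equal(out$report$rows_in, c(20L, 17L, 13L, 2L, 6L))
  expect_equal(out$report$rows_out, c(17L, 13L, 12L, 1L, 2L))
  expect_equal(nrow(out$evidence), 12L)
  expect_setequal(
    out$evidence$sequence[out$evidence$sample_id == "S_deer"],
    c("AVLDEATMK", "GHSNTFELK", "LNVQPYDTR")
  )
  expect_equal(sum(out$evidence$sample_id == "S_deer"), 4L)
  expect_setequal(
    out$evidence$sequence[out$evidence$sample_id == "S_chest"],
    c("QVNPLESGK", "TTIGFDHAK", "VVDSPNAGELTR", "GHSNTFELK",
      "TTIGFDHAKVVDSPNAGELTR")
  )
  expect_equal(out$included_samples, "S_deer")
  expect_equal(out$samples$crosscontam_pct[
    out$samples$sample_id == "S_chest"], 20)
  expect_equal(
    paste(out$supported_proteins$sample_id,
          out$supported_proteins$accession),
    c("S_chest CHST1", "S_deer DEER1")
  )
})
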