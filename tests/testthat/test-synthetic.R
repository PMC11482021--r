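test_that("survival parameter validation rejects out-of-range values", {
  expect_error(survival_params(ceramic_yield = 1.5), "ceramic_yield")
  expect_error(survival_params(deamidation_rate_cook = -0.1),
               "deamidation_rate_cook")
  expect_error(generate_reference(shared_fraction = 1.2),
               "shared_fraction")
  expect_error(generate_reference(n_taxa = 1L), "n_taxa")
})

test_that("shared_fraction 0 gives fully taxon-specific peptides", {
  ref <- generate_reference(n_taxa = 2L, proteins_per_taxon = 4L,
                            shared_fraction = 0, mean_length = 120L,
                            contam_proteins = 0L, seed = 5)
  idx <- build_peptide_index(ref$proteins)
  taxa_sets <- unname(lapply(idx, identity))
  expect_true(all(lengths(taxa_sets) == 1L))
  # every peptide's LCA is its species leaf
  for (k in head(names(idx), 25L)) {
    expect_equal(lca(idx[[k]], ref$taxonomy), idx[[k]][[1L]])
  }
})

test_that("full sharing with zero substitution sends every LCA to the root", {
  ref <- generate_reference(n_taxa = 3L, proteins_per_taxon = 3L,
                            shared_fraction = 1, subst_rate = 0,
                            mean_length = 120L, contam_proteins = 0L,
                            seed = 6)
  idx <- build_peptide_index(ref$proteins)
  expect_true(all(lengths(idx) == 3L))
  for (k in head(names(idx), 25L)) {
    expect_equal(lca(idx[[k]], ref$taxonomy), ref$taxonomy$root)
  }
})

test_that("generated secondary structure matches the background ratio", {
  ref <- generate_reference(n_taxa = 2L, proteins_per_taxon = 170L,
                            shared_fraction = 0, mean_length = 300L,
                            contam_proteins = 0L, seed = 9)
  ss <- paste(vapply(ref$annotations, function(a) a$ss8, ""),
              collapse = "")
  expect_gte(nchar(ss), 1e5)
  freq <- table(factor(strsplit(ss, "")[[1L]],
                       levels = c("H", "E", "L", "T", "S", "G", "B", "I")))
  prop <- as.numeric(freq) / nchar(ss)
  target <- c(0.34, 0.21, 0.20, 0.11, 0.09, 0.04, 0.01, 0.00)
  expect_true(all(abs(prop - target) <= 0.01))
})

test_that("simulation is deterministic under a fixed seed", {
  ref <- generate_reference(n_taxa = 2L, proteins_per_taxon = 10L,
                            mean_length = 150L, seed = 3)
  dig <- digest_reference(ref)
  des <- make_design(ref$ingredient_taxa, replicates = 2L)
  p <- survival_params(seed = 11L)
  b1 <- simulate_extractome(ref, des, p, digest = dig)
  b2 <- simulate_extractome(ref, des, p, digest = dig)
  expect_identical(b1$evidence, b2$evidence)
  expect_identical(b1$truth, b2$truth)
  # and a different seed changes the draw
  b3 <- simulate_extractome(ref, des, survival_params(seed = 12L),
                            digest = dig)
  expect_false(identical(b1$evidence, b3$evidence))
})

test_that("degenerate no-loss parameters recover the full digest", {
  ref <- generate_reference(n_taxa = 2L, proteins_per_taxon = 4L,
                            mean_length = 120L, contam_proteins = 0L,
                            seed = 8)
  dig <- digest_reference(ref)
  des <- make_design(ref$ingredient_taxa[1L], replicates = 1L,
                     washes = FALSE)
  p <- survival_params(
    beta0_cook = 50, beta0_bury = 50, beta_gravy = 0, beta_len = 0,
    ceramic_yield = 1, detect_rate = Inf, crosscontam_frac = 0,
    contam_peptides_per_sample = 0L, seed = 2L
  )
  b <- simulate_extractome(ref, des, p, digest = dig)
  full <- sort(dig$by_taxon[[ref$ingredient_taxa[1L]]]$peptide)
  for (sid in des$sample_id) {
    expect_equal(sort(b$evidence$sequence[b$evidence$sample_id == sid]),
                 full)
  }
})

test_that("zero ceramic yield leaves only injected material in ceramics", {
  ref <- generate_reference(n_taxa = 2L, proteins_per_taxon = 6L,
                            mean_length = 150L, seed = 4)
  des <- make_design(ref$ingredient_taxa, replicates = 1L,
                     matrices = "ceramic", include_fresh = FALSE,
                     buried = FALSE, washes = FALSE)
  p <- survival_params(ceramic_yield = 0, crosscontam_frac = 0.05,
                       contam_peptides_per_sample = 10L, seed = 21L)
  b <- simulate_extractome(ref, des, p)
  expect_gt(nrow(b$evidence), 0L)
  expect_true(all(b$truth$origin != "endogenous"))
})

test_that("buried peptide counts are monotone in the burial baseline", {
  ref <- generate_reference(n_taxa = 2L, proteins_per_taxon = 12L,
                            mean_length = 180L, seed = 13)
  dig <- digest_reference(ref)
  des <- make_design(ref$ingredient_taxa[1L], replicates = 2L,
                     matrices = "foodcrust", include_fresh = FALSE,
                     washes = FALSE)
  counts <- sapply(c(-1, 0, 1), function(b0) {
    p <- survival_params(beta0_bury = b0, crosscontam_frac = 0,
                         contam_peptides_per_sample = 0L, seed = 31L)
    b <- simulate_extractome(ref, des, p, digest = dig)
    buried <- des$sample_id[des$burial == "buried"]
    vapply(buried, function(s) sum(b$evidence$sample_id == s), 0L)
  })
  expect_true(all(counts[, 2L] >= counts[, 1L]))
  expect_true(all(counts[, 3L] >= counts[, 2L]))
})

test_that("a positive GRAVY coefficient enriches hydrophobic peptides", {
  ref <- generate_reference(n_taxa = 2L, proteins_per_taxon = 60L,
                            mean_length = 200L, seed = 17)
  des <- make_design(ref$ingredient_taxa[1L], replicates = 3L,
                     matrices = "foodcrust", include_fresh = FALSE,
                     washes = FALSE)
  p <- survival_params(beta_gravy = 0.8, crosscontam_frac = 0,
                       contam_peptides_per_sample = 0L, seed = 19L)
  b <- simulate_extractome(ref, des, p)
  pools <- state_gravy_pools(b)
  expect_gt(length(pools$foodcrust_buried), 100L)
  expect_gt(mean(pools$foodcrust_buried), mean(pools$foodcrust_unburied))
})

test_that("every evidence row is explained by exactly one truth record", {
  ref <- generate_reference(n_taxa = 3L, proteins_per_taxon = 8L,
                            mean_length = 150L, seed = 23)
  des <- make_design(ref$ingredient_taxa, replicates = 2L)
  b <- simulate_extractome(ref, des, survival_params(seed = 29L))
  expect_equal(nrow(b$truth), nrow(b$evidence))
  key_ev <- paste(b$evidence$sample_id, b$evidence$sequence)
  key_tr <- paste(b$truth$sample_id, b$truth$sequence)
  expect_false(any(duplicated(key_ev)))
  expect_identical(key_ev, key_tr)
})

test_that("wash samples carry a subsample of the immediately preceding run", {
  ref <- generate_reference(n_taxa = 2L, proteins_per_taxon = 20L,
                            mean_length = 200L, seed = 37)
  des <- make_design(ref$ingredient_taxa, replicates = 1L,
                     matrices = "foodcrust", buried = FALSE)
  b <- simulate_extractome(ref, des,
                           survival_params(wash_carryover_frac = 0.02,
                                           seed = 41L))
  washes <- des[des$matrix == "wash", , drop = FALSE]
  for (i in seq_len(nrow(washes))) {
    w <- washes[i, , drop = FALSE]
    prev_id <- des$sample_id[des$run_order == w$run_order - 1L]
    wseq <- b$evidence$sequence[b$evidence$sample_id == w$sample_id]
    pseq <- b$evidence$sequence[b$evidence$sample_id == prev_id]
    expect_true(all(wseq %in% pseq))
    expect_lte(length(wseq), ceiling(0.02 * length(pseq)) )
    expect_true(all(b$evidence$psm_count[
      b$evidence$sample_id == w$sample_id] == 1L))
  }
})

test_that("a bundle written to disk reads back equivalently", {
  ref <- generate_reference(n_taxa = 2L, proteins_per_taxon = 5L,
                            mean_length = 120L, seed = 43)
  des <- make_design(ref$ingredient_taxa, replicates = 1L)
  b <- simulate_extractome(ref, des, survival_params(seed = 47L))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  prot <- read_fasta(file.path(dir, "proteins.fasta"),
                     meta = file.path(dir, "proteins_meta.tsv"))
  expect_equal(prot$sequence, b$proteins$sequence)
  expect_equal(prot$category, b$proteins$category)
  ev <- read_evidence(file.path(dir, "evidence.tsv"))
  expect_equal(ev, b$evidence)
  expect_equal(read_design(file.path(dir, "design.tsv")), b$design)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$nodes, b$taxonomy$nodes)
})
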