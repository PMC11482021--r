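test_that("count matrices aggregate by razor protein and sample", {
  ev <- dplyr::bind_rows(
    minimal_evidence("S1", c("AVLDEATMK", "GHSNTFELK"), razor = "P1",
                     psm = c(2L, 3L)),
    minimal_evidence("S2", "AVLDEATMK", razor = "P2", psm = 4L)
  )
  m <- count_matrix(ev, mode = "psm_sum")
  expect_equal(m["P1", "S1"], 5L)
  expect_equal(m["P1", "S2"], 0L)
  expect_equal(m["P2", "S2"], 4L)
  expect_equal(sum(m), sum(ev$psm_count))
  m2 <- count_matrix(ev, mode = "peptide_rows")
  expect_equal(m2["P1", "S1"], 2L)
  expect_equal(sum(m2), nrow(ev))
})

test_that("identical columns merge first at height zero", {
  mat <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(9, 9, 9))
  hc <- hierarchical_cluster(mat, log_transform = FALSE)
  expect_equal(hc$height[[1L]], 0)
  expect_setequal(hc$merge[1L, ], c(-1L, -2L))
})

test_that("a hand-computed toy matrix merges the closest pair first", {
  # samples with single counts 0, 3, 4: distances 3, 4, 1
  mat <- matrix(c(0, 3, 4), nrow = 1L,
                dimnames = list("p", c("s1", "s2", "s3")))
  hc <- hierarchical_cluster(mat, log_transform = FALSE)
  expect_setequal(hc$merge[1L, ], c(-2L, -3L))
  expect_equal(hc$height[[1L]], 1)
  # average linkage: d(s1, {s2 s3}) = (3 + 4) / 2
  expect_equal(hc$height[[2L]], 3.5)
  expect_true(all(diff(hc$height) >= 0))
})

test_that("dendrograms are invariant under column permutation", {
  set.seed(55)
  mat <- matrix(rpois(60, 5), nrow = 10L)
  colnames(mat) <- paste0("s", 1:6)
  mat[, 4L] <- mat[, 2L]   # force an exact tie
  hc <- hierarchical_cluster(mat)
  perm <- sample(6L)
  hc_p <- hierarchical_cluster(mat[, perm])
  expect_equal(hc$height, hc_p$height, tolerance = 1e-12)
  for (k in 2:5) {
    part <- split(hc$labels, stats::cutree(hc, k = k))
    part_p <- split(hc_p$labels, stats::cutree(hc_p, k = k))
    expect_setequal(
      unname(vapply(part, function(g) paste(sort(g), collapse = ","), "")),
      unname(vapply(part_p, function(g) paste(sort(g), collapse = ","), ""))
    )
  }
  # single sample degenerates to a single leaf
  hc1 <- hierarchical_cluster(mat[, 1L, drop = FALSE])
  expect_equal(length(hc1$order), 1L)
  # Newick export round-trips through ape
  nwk <- dendrogram_newick(hc)
  expect_true(grepl("^\\(", nwk))
  expect_equal(sort(ape::read.tree(text = nwk)$tip.label),
               sort(colnames(mat)))
})

test_that("upset intersections partition the union", {
  out <- upset_intersections(list(A = c("p1", "p2"), B = "p2"))
  expect_equal(out$count[out$combo == "A"], 1L)
  expect_equal(out$count[out$combo == "A&B"], 1L)
  expect_false("B" %in% out$combo)
  expect_equal(sum(out$count), 2L)

  set.seed(56)
  sets <- lapply(1:4, function(i) {
    sample(paste0("e", 1:30), sample(5:30, 1L))
  })
  names(sets) <- c("W", "X", "Y", "Z")
  out <- upset_intersections(sets)
  expect_equal(sum(out$count), length(unique(unlist(sets))))
  # brute-force membership-bitmask oracle
  universe <- unique(unlist(sets))
  pattern <- vapply(universe, function(e) {
    paste(names(sets)[vapply(sets, function(s) e %in% s, TRUE)],
          collapse = "&")
  }, "")
  oracle <- table(pattern)
  expect_equal(setNames(out$count, out$combo)[names(oracle)],
               setNames(as.integer(oracle), names(oracle)))
})

test_that("the rank-sum statistic and exact p match hand computation", {
  # identical groups: no shift, exact p = 1
  w0 <- wilcoxon_rank_sum(c(1, 2), c(1, 2))
  expect_equal(w0$p_value, 1)
  # {1,2,3} vs {4,5,6}: smaller-group rank sum 6, exact two-sided p 0.1
  w1 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w1$statistic, 6)
  expect_equal(w1$p_value, 0.1)
  expect_equal(w1$method, "exact")
})

test_that("exact p-values agree with stats::wilcox.test when tie-free", {
  set.seed(57)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1L); n2 <- sample(2:6, 1L)
    x <- rnorm(n1); y <- rnorm(n2)
    ours <- wilcoxon_rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact p-values equal the permutation oracle, ties included", {
  perm_oracle <- function(x, y) {
    r <- rank(c(x, y))
    n1 <- length(x); N <- n1 + length(y)
    swap <- length(y) < n1
    na <- if (swap) length(y) else n1
    idx <- if (swap) (n1 + 1):N else 1:n1
    w <- sum(r[idx])
    W <- utils::combn(N, na, function(s) sum(r[s]))
    min(1, 2 * min(mean(W <= w + 1e-9), mean(W >= w - 1e-9)))
  }
  set.seed(58)
  for (rep in 1:15) {
    n1 <- sample(2:6, 1L); n2 <- sample(2:6, 1L)
    x <- sample(1:4, n1, replace = TRUE)   # heavy ties
    y <- sample(2:5, n2, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, perm_oracle(x, y))
  }
})

test_that("state comparisons run the omnibus and pairwise tests", {
  set.seed(59)
  values <- c(rnorm(15), rnorm(15, 1), rnorm(15, 2))
  groups <- rep(c("fresh", "cooked", "buried"), each = 15L)
  out <- compare_states(values, groups,
                        pairs = list(c("fresh", "cooked"),
                                     c("cooked", "buried")))
  expect_equal(out$test, c("kruskal_wallis", "wilcoxon_rank_sum",
                           "wilcoxon_rank_sum"))
  expect_equal(out$p_value[[1L]],
               stats::kruskal.test(values, factor(groups))$p.value)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  # empty group is skipped and noted
  out2 <- compare_states(values, groups,
                         pairs = list(c("fresh", "missing_state")))
  expect_match(out2$note[[2L]], "skipped")
})

test_that("per-residue case reports add coverage over overlapping peptides", {
  proteins <- tibble::tibble(
    accession = "P1", sequence = "MKVLDEATGW",
    taxon_id = "T1", category = "target"
  )
  ann <- residue_annotations(list(
    P1 = list(ss8 = "HHHHEELLTT", rsa = c(rep(0.05, 5), rep(0.9, 5)),
              disorder = rep(0.4, 10), amyloid = seq(0.05, 0.5, length.out = 10),
              tm_celsius = 52)
  ), proteins)
  design <- tibble::tibble(
    sample_id = c("C1", "B1"),
    ingredient = "T1", matrix = "foodcrust",
    burial = c("unburied", "buried"), replicate = 1L,
    cofire_group = NA_character_, run_order = 1:2
  )
  ev <- dplyr::bind_rows(
    minimal_evidence("C1", "MKVL", razor = "P1", psm = 2L),
    minimal_evidence("C1", "VLDE", razor = "P1", psm = 1L),
    minimal_evidence("B1", "DEATGW", razor = "P1", psm = 3L)
  )
  rep_tab <- protein_case_report("P1", ev, proteins, ann, design)
  expect_equal(nrow(rep_tab), 10L)
  cooked <- rep_tab$count_foodcrust_unburied
  buried <- rep_tab$count_foodcrust_buried
  # MKVL covers 0..3 with 2; VLDE covers 2..5 with 1 -> overlap adds
  expect_equal(cooked, c(2, 2, 3, 3, 1, 1, 0, 0, 0, 0))
  expect_equal(buried, c(0, 0, 0, 0, 3, 3, 3, 3, 3, 3))
  expect_equal(sum(cooked) + sum(buried),
               sum(ev$psm_count * nchar(ev$sequence)))
  expect_equal(rep_tab$rsa_class,
               c(rep("deep", 5), rep("exposed", 5)))
  expect_error(protein_case_report("P1", ev[0, ], proteins, ann, design),
               "absent")
})
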