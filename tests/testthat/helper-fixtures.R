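# Shared fixtures and independent oracles. Oracles are written from
# the definitions, not by calling the implementation under test.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

toy_file <- function(name) {
  system.file("extdata", "toy", name, package = "crustome")
}

# Distinct tryptic peptides: no internal K/R, terminal K, length >= 7.
make_tryptic_peptides <- function(n, len = 8L) {
  base <- setdiff(AA20, c("K", "R", "P"))
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(len - 1L)
    for (d in seq_len(len - 1L)) {
      digits[[d]] <- i %% length(base) + 1L
      i <- i %/% length(base)
    }
    paste0(paste(base[digits], collapse = ""), "K")
  }, "")
}

rand_peptides <- function(n, min_len = 7L, max_len = 40L) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, sample(min_len:max_len, 1L), replace = TRUE),
          collapse = "")
  }, "")
}

# Independent Kyte-Doolittle lookup for the GRAVY oracle.
KD_ORACLE <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

gravy_oracle <- function(s) {
  res <- strsplit(s, "", fixed = TRUE)[[1L]]
  sum(KD_ORACLE[res]) / length(res)
}

# Independent charge model for the pI grid-scan oracle (IPC_peptide
# constants typed here on their own).
PI_PKA <- list(
  nterm = 9.564, cterm = 2.383,
  pos = c(H = 6.018, K = 10.517, R = 12.503),
  neg = c(C = 9.439, D = 3.887, E = 4.317, Y = 10.071)
)

charge_oracle <- function(s, pH) {
  res <- strsplit(s, "", fixed = TRUE)[[1L]]
  q <- 1 / (1 + 10^(pH - PI_PKA$nterm)) - 1 / (1 + 10^(PI_PKA$cterm - pH))
  for (a in names(PI_PKA$pos)) {
    q <- q + sum(res == a) / (1 + 10^(pH - PI_PKA$pos[[a]]))
  }
  for (a in names(PI_PKA$neg)) {
    q <- q - sum(res == a) / (1 + 10^(PI_PKA$neg[[a]] - pH))
  }
  q
}

# Grid scan at 0.0001 pH steps: the pH where the net charge changes sign.
pi_grid_oracle <- function(s, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- charge_oracle(s, grid)
  i <- which(q <= 0)[1L]
  if (is.na(i)) return(14)
  if (i == 1L) return(0)
  (grid[i - 1L] + grid[i]) / 2
}

# Random rooted taxonomy: node i's parent is a uniform earlier node.
rand_taxonomy <- function(n_nodes) {
  ids <- paste0("N", seq_len(n_nodes))
  parent <- c("N1", ids[vapply(2:n_nodes, function(i) {
    sample.int(i - 1L, 1L)
  }, 0L)])
  taxonomy_tree(tibble::tibble(
    taxon_id = ids, parent_id = parent, name = ids,
    rank = c("root", rep("species", n_nodes - 1L))
  ))
}

# Brute-force LCA: intersect root-paths, take the deepest common node.
lca_bruteforce <- function(taxa, tree) {
  path_up <- function(id) {
    out <- id
    while (id != tree$root) {
      id <- tree$parent[[id]]
      out <- c(out, id)
    }
    out
  }
  paths <- lapply(unique(taxa), path_up)
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(id) length(path_up(id)), 0L)
  common[[which.max(depths)]]
}

# Minimal valid evidence tibble builder.
minimal_evidence <- function(sample_id, sequence, razor = "P1",
                             psm = 1L, mods = "") {
  n <- length(sequence)
  tibble::tibble(
    sample_id = rep_len(sample_id, n),
    sequence = sequence,
    modifications = rep_len(mods, n),
    protein_ids = lapply(rep_len(razor, n), identity),
    leading_razor_protein = rep_len(razor, n),
    psm_count = as.integer(rep_len(psm, n))
  )
}

# Deduplicated per-state peptide GRAVY pools for rank testing: a peptide
# detected in any replicate of a state is one observation.
state_gravy_pools <- function(bundle, matrix_type = "foodcrust") {
  ev <- bundle$evidence
  des <- bundle$design
  state_of <- setNames(paste(des$matrix, des$burial, sep = "_"),
                       des$sample_id)
  ev$state <- unname(state_of[ev$sample_id])
  keep <- ev$state %in% paste(matrix_type, c("unburied", "buried"), sep = "_")
  ev <- ev[keep, c("state", "sequence")]
  ev <- ev[!duplicated(ev), , drop = FALSE]
  split(gravy(ev$sequence), ev$state)
}
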