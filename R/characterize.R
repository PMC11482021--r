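#' Protein-by-sample count matrix
#'
#' Cells hold either summed PSM counts (`psm_sum`, the default reading
#' of per-protein "peptide count") or distinct peptide rows
#' (`peptide_rows`), grouped by leading razor protein. Absent proteins
#' get 0. Column order follows the design (washes excluded) when a
#' design is given, otherwise order of appearance.
#'
#' @param evidence Filtered evidence tibble.
#' @param design Optional design tibble fixing the column order.
#' @param mode `"psm_sum"` or `"peptide_rows"`.
#' @return An integer matrix, rows = accessions (sorted), columns =
#'   sample ids.
#' @export
count_matrix <- function(evidence, design = NULL,
                         mode = c("psm_sum", "peptide_rows")) {
  mode <- match.arg(mode)
  samples <- if (is.null(design)) unique(evidence$sample_id) else
    design$sample_id[design$matrix != "wash"]
  accs <- sort(unique(evidence$leading_razor_protein))
  mat <- matrix(0L, nrow = length(accs), ncol = length(samples),
                dimnames = list(accs, samples))
  ev <- evidence[evidence$sample_id %in% samples, , drop = FALSE]
  if (nrow(ev)) {
    val <- if (mode == "psm_sum") ev$psm_count else rep(1L, nrow(ev))
    agg <- tapply(val, list(ev$leading_razor_protein, ev$sample_id), sum)
    mat[rownames(agg), colnames(agg)] <-
      ifelse(is.na(agg), 0L, as.integer(agg))
  }
  mat
}

.dist_columns <- function(mat, metric) {
  if (metric == "euclidean") {
    as.matrix(stats::dist(t(mat), method = "euclidean"))
  } else {
    d <- 1 - stats::cor(mat)
    d[is.na(d)] <- 0
    diag(d) <- 0
    d
  }
}

#' Agglomerative hierarchical clustering with a deterministic tie-break
#'
#' Average-linkage clustering of the matrix columns (samples) under
#' Euclidean or correlation (1 - Pearson) distance. Counts are
#' log2(x + 1)-transformed before the distance computation by default,
#' so heavy-tailed spectral counts do not dominate. Ties in the merge
#' distance are broken by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest leaf label),
#' which makes the dendrogram invariant under column permutations.
#'
#' @param mat Numeric matrix (proteins x samples).
#' @param metric `"euclidean"` (default) or `"correlation"`.
#' @param log_transform Apply `log2(x + 1)` before distances.
#' @param cluster `"columns"` (default) or `"rows"`.
#' @return An object of class `hclust` (plottable, convertible with
#'   [dendrogram_newick()]).
#' @export
hierarchical_cluster <- function(mat, metric = c("euclidean", "correlation"),
                                 log_transform = TRUE,
                                 cluster = c("columns", "rows")) {
  metric <- match.arg(metric)
  cluster <- match.arg(cluster)
  if (cluster == "rows") mat <- t(mat)
  if (log_transform) mat <- log2(mat + 1)
  labels <- colnames(mat)
  n <- ncol(mat)
  if (n < 1L) abort("nothing to cluster")
  if (n == 1L) {
    return(structure(
      list(merge = matrix(integer(), 0L, 2L), height = numeric(),
           order = 1L, labels = labels, method = "average",
           dist.method = metric),
      class = "hclust"
    ))
  }
  D <- .dist_columns(mat, metric)
  active <- seq_len(n)
  id <- -seq_len(n)              # hclust convention: negatives are leaves
  repr <- labels                 # smallest leaf label per cluster
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    pairs <- utils::combn(active, 2L)
    dvals <- D[cbind(pairs[1L, ], pairs[2L, ])]
    dmin <- min(dvals)
    tied <- which(dvals <= dmin + 1e-9 * max(1, abs(dmin)))
    if (length(tied) > 1L) {
      key <- vapply(tied, function(k) {
        lab <- sort(c(repr[pairs[1L, k]], repr[pairs[2L, k]]))
        paste(lab, collapse = "\r")
      }, "")
      best <- tied[order(key)[1L]]
    } else {
      best <- tied
    }
    i <- pairs[1L, best]; j <- pairs[2L, best]
    merge[s, ] <- sort(c(id[i], id[j]))
    height[s] <- D[i, j]
    # Lance-Williams update for average linkage; the merged cluster
    # lives in slot i.
    for (k in setdiff(active, c(i, j))) {
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    repr[i] <- min(repr[i], repr[j])
    id[i] <- s
    active <- setdiff(active, j)
  }
  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(merge[node, 1L]), leaf_order(merge[node, 2L]))
  }
  structure(
    list(merge = merge, height = height,
         order = leaf_order(n - 1L), labels = labels,
         method = "average", dist.method = metric),
    class = "hclust"
  )
}

#' Serialise a dendrogram to Newick
#'
#' @param hc An `hclust` object.
#' @param file Optional path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
dendrogram_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' Exclusive set intersections (UpSet-style)
#'
#' Partitions the union of the named sets by exact membership pattern,
#' as an UpSet plot does: each element is counted once, under the
#' combination of every set containing it. Exclusive counts therefore
#' sum to the size of the union.
#'
#' @param sets Named list of character vectors.
#' @return A tibble with `combo` (set names joined by `"&"`), `degree`,
#'   `count` and a `members` list column, sorted by decreasing count
#'   then combo.
#' @export
upset_intersections <- function(sets) {
  if (length(sets) == 0L || is.null(names(sets)) ||
      any(!nzchar(names(sets)))) {
    abort("'sets' must be a non-empty named list")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) {
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(NULL, names(sets)))
  }
  combo <- apply(membership, 1L, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  out <- tibble::tibble(element = universe, combo = combo) |>
    dplyr::group_by(.data$combo) |>
    dplyr::summarise(degree = lengths(strsplit(.data$combo[[1L]], "&",
                                               fixed = TRUE)),
                     count = dplyr::n(),
                     members = list(sort(.data$element)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$combo)
  out
}

#' Two-sample Wilcoxon rank-sum test (exact enumeration for small n)
#'
#' The statistic is the rank sum of the smaller group (the first group
#' when sizes are equal), with average ranks for ties. For combined
#' sample sizes up to `exact_limit` the two-sided p-value is computed by
#' exhaustive enumeration of all group assignments (valid under ties)
#' with the doubling rule `p = min(1, 2 * min(P(W <= w), P(W >= w)))`;
#' larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric observation vectors.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` chooses exact when `length(x) + length(y) <=
#'   exact_limit`.
#' @param exact_limit Combined-size ceiling for the exact method
#'   (default 20).
#' @return List with `statistic`, `p_value`, `n1`, `n2`, `method` and
#'   the direction estimate `shift` (difference of group medians,
#'   smaller-group minus other).
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL, exact_limit = 20L) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  n1 <- length(x); n2 <- length(y)
  swap <- n2 < n1
  a <- if (swap) y else x
  b <- if (swap) x else y
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  if (is.null(exact)) exact <- N <= exact_limit
  if (exact) {
    cmb <- utils::combn(N, na)
    W <- colSums(matrix(r[cmb], nrow = na))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(W <= w + eps), mean(W >= w - eps)))
    method <- "exact"
  } else {
    mu <- na * (N + 1) / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal_tie_corrected"
  }
  list(statistic = w, p_value = p, n1 = n1, n2 = n2, method = method,
       shift = stats::median(a) - stats::median(b))
}

#' Compare a property across sample states
#'
#' One omnibus Kruskal-Wallis test across all states followed by
#' pairwise two-sided Wilcoxon rank-sum tests for the designated state
#' pairs (all pairs by default). Pairs with an empty group are skipped
#' and noted. Raw p-values are reported (as degradation studies
#' conventionally do), with a Benjamini-Hochberg column for the
#' pairwise tests.
#'
#' @param values Numeric vector of per-peptide property values.
#' @param groups Character/factor vector of state labels, same length.
#' @param pairs Optional list of length-2 character vectors naming the
#'   pairwise comparisons; default all pairs of observed states.
#' @param exact_limit Passed to [wilcoxon_rank_sum()].
#' @return A tibble of test results: `test`, `group1`, `group2`,
#'   `statistic`, `p_value`, `p_bh`, `n1`, `n2`, `method`, `note`.
#' @export
compare_states <- function(values, groups, pairs = NULL,
                           exact_limit = 20L) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lev <- unique(groups)
  if (length(lev) < 2L) abort("need at least two states to compare")
  kw <- kruskal.test(values, factor(groups, levels = lev))
  rows <- list(tibble::tibble(
    test = "kruskal_wallis", group1 = paste(lev, collapse = "|"),
    group2 = NA_character_,
    statistic = unname(kw$statistic), p_value = kw$p.value,
    n1 = length(values), n2 = NA_integer_,
    method = "chisq_approx", note = NA_character_
  ))
  if (is.null(pairs)) {
    pairs <- utils::combn(lev, 2L, simplify = FALSE)
  }
  for (pr in pairs) {
    g1 <- values[groups == pr[[1L]]]
    g2 <- values[groups == pr[[2L]]]
    if (length(g1) == 0L || length(g2) == 0L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        test = "wilcoxon_rank_sum", group1 = pr[[1L]], group2 = pr[[2L]],
        statistic = NA_real_, p_value = NA_real_,
        n1 = length(g1), n2 = length(g2),
        method = NA_character_, note = "skipped: empty group"
      )
      next
    }
    wt <- wilcoxon_rank_sum(g1, g2, exact_limit = exact_limit)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      test = "wilcoxon_rank_sum", group1 = pr[[1L]], group2 = pr[[2L]],
      statistic = wt$statistic, p_value = wt$p_value,
      n1 = wt$n1, n2 = wt$n2, method = wt$method, note = NA_character_
    )
  }
  out <- dplyr::bind_rows(rows)
  is_w <- out$test == "wilcoxon_rank_sum" & !is.na(out$p_value)
  out$p_bh <- NA_real_
  out$p_bh[is_w] <- stats::p.adjust(out$p_value[is_w], method = "BH")
  out
}

#' Per-residue case report for one protein
#'
#' Overlays per-residue peptide coverage (summed PSM counts of every
#' peptide overlapping each position, split by sample state) with the
#' protein's property tracks: local-window GRAVY, amyloid propensity,
#' secondary structure and RSA class.
#'
#' @param accession Protein accession.
#' @param evidence Filtered evidence tibble.
#' @param proteins Protein tibble.
#' @param annotations A `residue_annotations` (may omit this protein).
#' @param design Design tibble mapping samples to states.
#' @param window Half-width (residues) of the local GRAVY window
#'   (default 1: a 3-residue window).
#' @param rsa_thresholds RSA class thresholds.
#' @return A tibble with one row per residue: `position` (zero-based),
#'   `residue`, one `count_<matrix>_<burial>` column per non-wash state
#'   observed in the design, `gravy_window`, `amyloid`, `ss8`,
#'   `rsa_class`.
#' @export
protein_case_report <- function(accession, evidence, proteins, annotations,
                                design, window = 1L,
                                rsa_thresholds = c(0.10, 0.40)) {
  if (!accession %in% proteins$accession) {
    abort(sprintf("unknown accession '%s'", accession))
  }
  pseq <- proteins$sequence[[match(accession, proteins$accession)]]
  L <- nchar(pseq)
  ev <- evidence[evidence$leading_razor_protein == accession, , drop = FALSE]
  if (nrow(ev) == 0L) {
    abort(sprintf("protein '%s' is absent from every evidence table",
                  accession))
  }
  state_of <- setNames(paste(design$matrix, design$burial, sep = "_"),
                       design$sample_id)
  states <- unique(state_of[design$sample_id[design$matrix != "wash"]])
  cov <- matrix(0L, nrow = L, ncol = length(states),
                dimnames = list(NULL, states))
  for (i in seq_len(nrow(ev))) {
    st <- state_of[[ev$sample_id[[i]]]]
    if (is.na(st) || !st %in% states) next
    iv <- map_peptide(ev$sequence[[i]], pseq, accession)
    idx <- seq.int(iv[["start"]] + 1L, iv[["end"]])
    cov[idx, st] <- cov[idx, st] + ev$psm_count[[i]]
  }
  pos <- seq_len(L) - 1L
  lo <- pmax(0L, pos - window)
  hi <- pmin(L - 1L, pos + window)
  gravy_window <- gravy(substring(pseq, lo + 1L, hi + 1L))
  ann <- annotations[[accession]]
  if (is.null(ann)) {
    amyloid <- rep(NA_real_, L)
    ss8 <- rep(NA_character_, L)
    rsa_class <- rep(NA_character_, L)
  } else {
    amyloid <- ann$amyloid
    ss8 <- strsplit(ann$ss8, "", fixed = TRUE)[[1L]]
    rsa_class <- dplyr::case_when(
      ann$rsa < rsa_thresholds[[1L]] ~ "deep",
      ann$rsa > rsa_thresholds[[2L]] ~ "exposed",
      TRUE ~ "intermediate"
    )
  }
  out <- tibble::tibble(
    position = pos,
    residue = strsplit(pseq, "", fixed = TRUE)[[1L]]
  )
  for (st in states) out[[paste0("count_", st)]] <- cov[, st]
  out$gravy_window <- gravy_window
  out$amyloid <- amyloid
  out$ss8 <- ss8
  out$rsa_class <- rsa_class
  out
}
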