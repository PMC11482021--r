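#' In silico tryptic digestion
#'
#' Cleaves after lysine (K) or arginine (R) except when the next residue
#' is proline (the classical trypsin proline rule), and emits every
#' peptide spanning `0..max_missed` internal cleavage sites whose length
#' falls within `[min_len, max_len]`. Positions are zero-based;
#' intervals are half-open `[start, start + nchar(peptide))`.
#'
#' @param sequence A single amino-acid string (canonical residues).
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @param min_len Minimum peptide length (default 7, the conventional
#'   identification floor).
#' @param max_len Maximum peptide length (default 45).
#' @return A tibble with columns `peptide`, `start`, `missed`.
#' @export
tryptic_digest <- function(sequence, max_missed = 2L, min_len = 7L,
                           max_len = 45L) {
  stopifnot(length(sequence) == 1L, max_missed >= 0L, min_len >= 1L)
  if (is.na(sequence) || !nzchar(sequence)) {
    return(tibble::tibble(peptide = character(), start = integer(),
                          missed = integer()))
  }
  assert_canonical(sequence)
  n <- nchar(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  # Cleavage after position i (1-based) when residue i is K/R and i+1 is
  # not P; the chain terminus is a boundary, not a cleavage site.
  cut_after <- which(res[-n] %in% c("K", "R") & res[-1L] != "P")
  bounds <- c(0L, cut_after, n)                 # zero-based segment bounds
  nseg <- length(bounds) - 1L
  starts <- integer()
  ends <- integer()
  missed <- integer()
  for (m in 0:min(max_missed, nseg - 1L)) {
    i <- seq_len(nseg - m)
    starts <- c(starts, bounds[i])
    ends <- c(ends, bounds[i + m + 1L])
    missed <- c(missed, rep.int(m, length(i)))
  }
  len <- ends - starts
  keep <- len >= min_len & len <= max_len
  tibble::tibble(
    peptide = substring(sequence, starts[keep] + 1L, ends[keep]),
    start = starts[keep],
    missed = missed[keep]
  )
}

#' Count missed tryptic cleavage sites in a peptide
#'
#' Internal K/R positions not followed by proline; the terminal residue
#' is never a missed cleavage.
#'
#' @param sequence Character vector of peptides.
#' @return Integer vector of missed-cleavage counts.
#' @export
count_missed_cleavages <- function(sequence) {
  assert_canonical(sequence, "peptide")
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n < 2L) return(0L)
    res <- strsplit(s, "", fixed = TRUE)[[1L]]
    sum(res[-n] %in% c("K", "R") & res[-1L] != "P")
  }, integer(1L), USE.NAMES = FALSE)
}
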