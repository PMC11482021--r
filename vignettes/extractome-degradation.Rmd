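---
title: "Modelling protein degradation in foodcrust and ceramic extractomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling protein degradation in foodcrust and ceramic extractomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crustome)
```

## The problem

Cooking residues on ceramic vessels are one of the few places where
dietary proteins survive into the archaeological record. What is
recovered from a foodcrust or a ceramic sherd — the *extractome* — is
not the ingredient proteome: it is the subset that survived cooking,
entrapment, months or millennia of burial, and the extraction and
identification chain. Interpreting such data requires knowing how that
subset is biased. `crustome` implements the analysis chain used to
characterise this bias in experimental cooking residues, together with
a generative model of the degradation process, so that every analysis
step can be validated against known ground truth.

This vignette is the package's account of the science: the models, the
parameters that matter, what the simulator does and does not emulate,
and the numerical decisions taken where the procedure is conventional
but not fully standardised.

## The data model

Five objects flow through the pipeline:

* **Proteins** — accession, sequence (20 canonical residues, strictly
  validated), taxon, and a category separating genuine reference
  entries from laboratory contaminants (a cRAP-style database).
  Taxon/category come from a sidecar table rather than FASTA header
  parsing, because header conventions vary between databases.
* **Evidence** — one row per identified peptide per sample: sequence,
  modification tokens, candidate protein accessions, the leading razor
  protein (the single protein a shared peptide is attributed to under
  parsimony grouping), and a PSM count. Modifications use the dialect
  `"Type (residues)@pos"` with zero-based positions; deamidation must
  sit on N/Q, oxidation on M, and so on — violations are rejected at
  read time.
* **Taxonomy** — a rooted tree with ranks from root to subspecies,
  validated for a unique root, acyclicity and reachability.
* **Residue annotations** — per-protein tracks of eight-state
  secondary structure (G 3₁₀-helix, H α-helix, I π-helix, E β-strand,
  B β-bridge, T β-turn, S high-curvature loop, L irregular), relative
  solvent accessibility, disorder and amyloid propensity, all exactly
  as long as the protein, plus a scalar melting temperature (°C).
  These mimic the outputs of structure/stability predictors, which
  are consumed as inputs, never recomputed.
* **Sample design** — ingredient, matrix (fresh, foodcrust, ceramic,
  wash), burial state, replicate, co-firing group (samples cooked over
  the same fire) and injection run order.

All residue coordinates are zero-based with half-open intervals,
stated once and used everywhere.

## The filtering ledger

Post-search evidence is filtered in a fixed order:

1. **Search parameters** — peptide length ≥ 7, missed tryptic
   cleavages ≤ 2. Missed cleavages are internal K/R positions not
   followed by proline.
2. **Contaminant removal** — any peptide occurring (I/L-equated) in a
   contaminant-category protein is removed, *including* peptides shared
   with target proteins. The conservative rule reflects how keratins
   dominate low-yield ceramic extractomes: a shared identification
   cannot be distinguished from contamination.
3. **Carry-over removal** — peptides observed in the blank wash
   immediately preceding a sample in run order are removed from that
   sample. Matching is by exact sequence: carry-over is literally the
   same molecules. Samples with no preceding wash pass through and are
   noted.
4. **Cross-contamination exclusion** — samples cooked over a shared
   fire acquire peptides from the co-fired ingredient. A peptide is a
   *known* cross-contaminant when it occurs in a partner ingredient's
   proteome and not the sample's own (shared peptides are ambiguous
   and never counted). Samples whose known cross-contaminant fraction
   exceeds 2% of unique peptide rows are excluded from property
   characterisation; the boundary is inclusive, so exactly 2.0% is
   kept. Row proportions, not PSM-weighted proportions, are used —
   "concentration of the total peptide count" reads as a row fraction.
5. **Protein support** — proteins need a summed PSM count ≥ 2 within a
   sample (the ">1 spectral match" convention); a stricter threshold
   of 3 is available where the stricter "more than two PSMs" reading
   is wanted.

The filters are individually contractive and idempotent but do not
commute (carry-over removal changes cross-contaminant percentages), so
the pipeline order is part of the contract and is recorded in the
report.

## Per-peptide properties

* **GRAVY** is the mean Kyte–Doolittle hydropathy. The scale is the
  one conventionally meant by the acronym; it is exposed via
  `kyte_doolittle()` so no constant is hidden.
* **Isoelectric point** is the root of the Henderson–Hasselbalch net
  charge (positive fractions of N-terminus, H, K, R minus negative
  fractions of C-terminus, C, D, E, Y), found by bisection on
  pH ∈ [0, 14] to 10⁻⁴. Net charge is strictly decreasing in pH under
  this model, so the root is unique. The shipped pKa set is the
  IPC_peptide set; agreement is to this charge-model family, not to
  any external tool's full model.
* **Deamidation** is a row-level flag (≥ 1 N/Q deamidation token), and
  `deamidation_proportion()` the fraction of flagged rows — the bulk
  marker of heating/diagenesis.
* **Structural summaries** slice the razor protein's tracks over the
  peptide's mapped interval (leftmost occurrence, I/L-equated). The
  dominant secondary structure is the modal class with the fixed
  tie-break priority H > E > L > T > S > G > B > I; RSA residues are
  classed deep (< 0.10), intermediate, or exposed (> 0.40) — common
  solvent-accessibility conventions, configurable since the field has
  no canonical threshold for "deep". Disorder is summarised by the
  mean and amyloid propensity by the maximum (a single
  amyloid-competent stretch matters more than the average); both
  summaries are switchable because published analyses do not state
  which was used. Melting temperature is inherited from the razor
  protein, never computed.

## Source classification

Peptides are matched against a tryptic index of the reference
proteomes with I and L equated (isobaric residues are
indistinguishable in the underlying measurement). The lowest common
ancestor of the matching taxa is classified against the sample's
ingredient:

* **input ingredient** — the LCA lies on the ingredient's lineage at
  family rank or lower (the "family or lower" convention for
  ingredient-matching identifications);
* **non-specific** — on the lineage but above family;
* **contaminant** — the ingredient is not in the LCA's subtree, so the
  identification cannot derive from the ingredient.

Protein-level classes use the LCA of the union of the protein's
peptides' taxon sets (the "protein LCA" convention), with the
per-peptide table kept for audit. Matching is against the supplied
proteomes only, which can only make LCAs more specific than matching
against a comprehensive database would; this is stated rather than
silently reconciled.

## State comparisons

Counts per protein and sample come in two modes: summed PSMs (default,
matching how per-protein "peptide counts" are aggregated in
degradation studies) or distinct peptide rows. Before clustering,
counts are log2(x+1)-transformed so heavy-tailed spectral counts do
not dominate Euclidean distances; the transform and the metric
(Euclidean or correlation distance) are switchable because the
published phrase "Euclidean correlation" is ambiguous — Euclidean is
the default and the intent is not guessed. Clustering is
average-linkage agglomeration with a deterministic tie-break (merge
the pair whose smallest leaf labels are lexicographically smallest),
which makes dendrograms invariant under column permutation even with
exactly tied distances; the result is an ordinary `hclust` object.

Rank tests follow the two-tier convention: an omnibus Kruskal–Wallis
across states, then pairwise two-sided Wilcoxon rank-sum tests for the
designated transitions (fresh vs cooked, cooked vs buried). The
statistic reported is the rank sum of the smaller group. For combined
n ≤ 20 the p-value is exact by exhaustive enumeration of group
assignments — valid under ties, where the classical exact distribution
is not — with the doubling rule `p = min(1, 2·min(P(W≤w), P(W≥w)))`;
larger samples use the normal approximation with tie correction and
continuity correction. Pairwise p-values are reported raw, with a
Benjamini–Hochberg column alongside for users who want adjustment.

## The generative survival model

The simulator emits post-search evidence tables with the statistical
structure the analysis assumes:

1. The ingredient proteome is digested tryptically (cleave after K/R
   unless before P; up to 2 missed cleavages; length 7–45).
2. Each protein gets a log-normal abundance `a` (sdlog 1.5); a peptide
   is detected in the fresh state with probability
   `1 − exp(−0.35·a)`. The saturating form makes abundant proteins
   near-fully covered while low-abundance proteins contribute one or
   two peptides — the heterogeneity that makes protein counts fall
   under attrition.
3. Cooking retains a detected peptide with probability
   `plogis(beta0_cook + beta_gravy·GRAVY + beta_len·length)`;
   burial applies a second such draw with `beta0_bury`. Defaults
   (`beta0_cook = 2`, `beta0_bury = 0`, `beta_gravy = 0.6`,
   `beta_len = −0.08`) encode the qualitative pattern of experimental
   foodcrusts: cooking retains most peptides, burial is strongly
   attritional, hydrophobic peptides survive preferentially, and long
   peptides (20+ residues) rarely survive burial.
4. Ceramic detection is thinned by `ceramic_yield = 0.02`,
   reproducing the order-of-magnitude gap between foodcrust and
   ceramic yields; injected laboratory contaminants are *not* thinned
   (contamination enters at extraction), which is why keratins top
   ceramic tables.
5. Each N/Q residue of a retained cooked peptide deamidates with
   probability `deamidation_rate_cook = 0.3`; fresh samples use a
   0.02 baseline. The probability that a peptide with k N/Q residues
   carries ≥ 1 deamidation is therefore exactly `1 − 0.7^k`, which is
   the analytic check used in the tests.
6. PSM counts are geometric with mean `3·a`, and a random 10% of
   proteins get a 3× PSM inflation in cooked samples, emulating
   heat-denaturation making particular proteins more cleavable.
7. Co-fired samples receive 1% of a partner ingredient's detected
   peptides; each blank wash carries a 1% subsample of the
   immediately preceding run at PSM 1, giving the carry-over filter
   something real to remove.

Every random draw comes from a per-sample, per-stage substream seeded
from the bundle seed and the run order, and each retention stage draws
one uniform per candidate peptide whether or not the peptide is still
alive. Coefficients therefore only move thresholds under common random
numbers: raising `beta0_bury` can never lose a buried peptide, a
property the test suite asserts directly. Identical seeds give
byte-identical bundles.

**What the simulator does not emulate.** Spectra, retention times and
FDR/decoy competition are upstream of the data model; soil proteome
background is absent (as it is from the experimental design it
mirrors); degradation acts only through GRAVY and length — the other
carried properties (disorder, amyloid, Tm, RSA) are annotation
passengers in the default model, so passing tests show the analysis
recovers *encoded* biases, not that real burial acts through these two
variables alone. The post-burial *decline* in deamidated proportion
seen in real data (deamidated peptides being preferentially lost) is
not modelled: simulated buried samples plateau at the cooked rate.

## Study sizes and numerical choices

The simulation studies in the tests and the acceptance script use a
reference of 2 taxa × 150 proteins at mean length 200 (≈ 6,900
candidate tryptic peptides per taxon, ≈ 2,000–2,300 detected peptides
per cooked sample) with 3 replicates per state — comparable to one
ingredient's arm of a triplicated cooking experiment. Power to detect
the hydrophobic survival bias (`beta_gravy = 0.6`) at α = 0.05 is
essentially 1 at this size; the null calibration uses 500 replicates
with all effects zeroed.

One calibration subtlety is worth recording. State pools are
deduplicated to unique peptide sequences before rank testing (a
peptide detected in several replicates of a state is one observation,
not three — pooling rows would be pseudo-replication). Even after
deduplication, a peptide detected in *both* states contributes the
identical GRAVY value to both pools. These forced-split exact ties
slightly deflate the rank-statistic variance relative to the
tie-corrected null, making the test conservative: empirical size
≈ 0.01–0.03 at nominal 0.05, varying with the overlap the realized
proteome induces. This structure is inherent to
comparing detected subsets of one digest pool and is equally present
in the real analyses the package mirrors; it costs a little power and
never inflates false positives.

Other numerical decisions: bisection tolerance 10⁻⁴ pH (an order of
magnitude below the 0.01 agreement demanded of it); exact-test
enumeration ceiling at combined n = 20 (choose(20,10) ≈ 1.8 × 10⁵
assignments, instantaneous); clustering tie tolerance 10⁻⁹ relative;
empty sequences digest to empty tables; empty property subsets return
`NA` proportions rather than errors; a single-column matrix clusters
to a single-leaf tree.

## Limitations

The package consumes predictor outputs (structure, disorder, amyloid,
Tm) as given and inherits their errors; it cannot constrain absolute
retention rates (the experimental design it mirrors has one burial
duration and one climate), so simulator defaults reproduce orderings,
not magnitudes; and LCA specificity depends entirely on the supplied
reference proteomes — absent taxa make peptides look more specific
than they are, the same database-absence caveat that affects real
plant identifications.
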