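# crustome

Degradation analysis and simulation of foodcrust and ceramic
extractomes.

When food is cooked in ceramic vessels, proteins become entrapped in
the charred surface deposit (the *foodcrust*) and, to a much smaller
extent, in the ceramic matrix itself. The set of proteins actually
recovered from such a sample — its *extractome* — is a filtered,
biased image of the original ingredient proteome: cooking, burial and
the analytical chain all remove peptides, and they do not remove them
at random. `crustome` is an R package for studying that bias. It is
aimed at palaeoproteomics researchers who work with shotgun-proteomics
evidence tables from experimental or archaeological cooking residues
and want a reproducible, testable version of the standard analysis
chain.

The package covers:

* **I/O** for the pipeline's formats: reference proteomes (FASTA plus a
  taxon/category sidecar), search-engine-style peptide evidence tables
  (TSV), taxonomies, per-residue annotation tracks (secondary
  structure, RSA, disorder, amyloid propensity, melting temperature)
  and sample designs.
* **The filtering ledger**: minimum peptide length (7) and missed
  cleavages (≤ 2), cRAP-style laboratory contaminant removal, machine
  carry-over removal against the preceding blank wash, sample exclusion
  when known cross-contaminant peptides exceed 2% of the peptide count
  (inclusive boundary), and the per-protein spectral support rule
  (summed PSMs ≥ 2).
* **Per-peptide properties**: Kyte–Doolittle GRAVY, isoelectric point
  by a Henderson–Hasselbalch charge model (IPC_peptide pKa set, root
  found by bisection), amino-acid composition, deamidation state, and
  structural summaries sliced from the parent protein's annotation
  tracks.
* **Taxonomic source classification**: a tryptic peptide index with I/L
  equivalence, lowest-common-ancestor assignment, and classification of
  each peptide/protein as input ingredient (LCA at family rank or
  lower on the ingredient's lineage), non-specific (on the lineage but
  above family) or contaminant (off the lineage).
* **State comparisons**: protein-by-sample count matrices,
  average-linkage hierarchical clustering with a deterministic
  tie-break, UpSet-style exclusive intersections, Kruskal–Wallis and
  exact/tie-corrected Wilcoxon rank-sum tests, and per-protein
  coverage case reports.
* **A synthetic extractome simulator.** Peptide survival across the
  fresh→cooked and cooked→buried transitions follows a logistic model

  `P(retained) = plogis(beta0 + beta_gravy · GRAVY + beta_len · length)`

  with ceramic detection thinned by a yield factor, heating-induced
  N/Q deamidation (per-residue Bernoulli), geometric PSM counts,
  contaminant injection, co-firing cross-contamination and blank-wash
  carry-over. Ground truth is emitted for every evidence row, so every
  downstream stage of the package is testable without external data.

## Worked example

Simulate one ingredient cooked into foodcrust in triplicate (plus a
fresh sample and interleaved blank washes), run the filtering ledger,
and test whether buried peptides are more hydrophobic:

```r
library(crustome)

ref    <- generate_reference(n_taxa = 2, proteins_per_taxon = 40,
                             mean_length = 200, seed = 1)
design <- make_design(ref$ingredient_taxa[1], replicates = 3,
                      matrices = "foodcrust", include_fresh = TRUE)
bundle <- simulate_extractome(ref, design, survival_params(seed = 1))

filtered <- filter_pipeline(bundle$evidence, bundle$proteins, bundle$design)
filtered$report
#> # A tibble: 5 × 4
#>   stage                 rows_in rows_out rows_removed
#>   <chr>                   <int>    <int>        <int>
#> 1 search_filters           2270     2270            0
#> 2 contaminant_removal      2270     2094          176
#> 3 carryover_removal        2094     2092            2
#> 4 crosscontam_exclusion       7        7            0
#> 5 protein_support           252      212           40

props <- annotate_properties(filtered$evidence, bundle$proteins,
                             bundle$annotations)
st <- paste(bundle$design$matrix, bundle$design$burial, sep = "_")[
  match(props$sample_id, bundle$design$sample_id)]
keep <- st %in% c("fresh_unburied", "foodcrust_unburied", "foodcrust_buried")
compare_states(props$gravy[keep], st[keep],
               pairs = list(c("fresh_unburied", "foodcrust_unburied"),
                            c("foodcrust_unburied", "foodcrust_buried")))
#>   test              group1     group2 statistic  p_value    n1    n2
#> 1 kruskal_wallis    fresh_unb… <NA>        42.2 6.77e-10  2065    NA
#> 2 wilcoxon_rank_sum fresh_unb… foodc…  524518.  1.48e- 4   629  1164
#> 3 wilcoxon_rank_sum foodcrust… foodc…  220840.  3.68e- 5  1164   272

round(tapply(props$gravy[keep], st[keep], median), 3)
#>   foodcrust_buried foodcrust_unburied     fresh_unburied
#>              0.212              0.014             -0.142
```

The simulator's generative survival bias (`beta_gravy = 0.6` by
default) is recovered by the analysis: the omnibus Kruskal–Wallis test
rejects, both designated pairwise Wilcoxon comparisons reject, and the
median GRAVY rises from fresh (−0.14) through cooked foodcrust (0.01)
to buried foodcrust (0.21) — hydrophilic peptides are progressively
lost, hydrophobic ones survive. The search filters remove nothing here
because the simulator only emits peptides that already satisfy the
search parameters; the contaminant filter strips the injected
keratin-like peptides, and the carry-over filter removes wash
spill-over.

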