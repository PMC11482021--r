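Package: crustome
Title: Degradation Analysis and Simulation of Foodcrust and Ceramic Extractomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying protein survival in experimental cooking
    residues. Reads search-engine peptide evidence tables, reference
    proteomes, residue-level structural annotation tracks and sample
    designs; applies the identification-filtering ledger used in
    degradation studies (peptide length, missed cleavages, laboratory
    contaminants, machine carry-over, co-firing cross-contamination);
    computes per-peptide physicochemical properties (Kyte-Doolittle
    GRAVY, isoelectric point by a Henderson-Hasselbalch charge model,
    deamidation state, secondary structure, solvent accessibility,
    disorder, amyloid propensity, inherited melting temperature);
    assigns lowest-common-ancestor taxonomy and classifies peptide and
    protein sources as input ingredient, non-specific or contaminant;
    and compares fresh, cooked and buried states with exact rank tests,
    hierarchical clustering and UpSet-style intersections. A synthetic
    extractome simulator with a property-biased logistic survival model
    makes the whole pipeline exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
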