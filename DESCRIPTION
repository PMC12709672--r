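Package: amdniche
Title: Community Ecology of Acidophile Microbiomes: Occupancy, Microdiversity,
    Niche Proportionality and Assembly Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for 16S rRNA amplicon surveys of extreme
    environments such as acid mine drainage. Classifies amplicon sequence
    variants (ASVs) into abundance/occupancy categories including persistent
    abundant taxa and conditionally rare taxa; clusters ASVs into 98.7%
    identity OTUs and quantifies within-OTU effective microdiversity on
    rarefied counts; measures niche similarity between closely related ASVs
    as proportionality (rho) on centred log-ratio transformed counts with a
    permutation-calibrated FDR cutoff and models rho against nucleotide
    divergence; partitions community assembly into five ecological processes
    (homogeneous/heterogeneous selection, dispersal limitation, homogenizing
    dispersal, drift) with phylogenetic-bin null models (beta-NTI and
    modified Raup-Crick); and associates process importances with
    environmental gradients through Monte-Carlo cross-validated bivariate
    models with permutation p-values and Benjamini-Hochberg correction.
    Ships a synthetic-community generator with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    Biostrings,
    jsonlite
Suggests:
    picante,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
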