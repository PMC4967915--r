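Package: calyx
Title: Ligand Unbinding Energetics and Binding-Pocket Analytics for Lipocalin Calyx Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis machinery for ligand unbinding from lipocalin
    binding pockets, modelled on the apolipoprotein M / sphingosine-1-phosphate
    system. Provides overdamped Langevin sampling on analytic one-dimensional
    free-energy landscapes (unbiased, umbrella-biased, and constant-velocity
    moving-spring pulling), potential-of-mean-force reconstruction by the
    weighted histogram analysis method (WHAM) with window-level bootstrap
    errors, residue-wise aggregation of atom-pairwise force records (force
    distribution analysis), titratable-group bookkeeping (effective pKa from
    perturbation terms, Henderson-Hasselbalch protonated fractions, net proton
    exchange and isoelectric points), and structure analytics (Kabsch RMSD,
    windowed RMSF, calyx opening distances, tyrosine-gate metrics,
    hydrogen-bond occupancy, and grid-based cavity volumes split into upper
    and lower sub-pockets). A configuration-driven pipeline orchestrates the
    full synthetic study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
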