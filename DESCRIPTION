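Package: gblupsim
Title: Simulation-Based Evaluation of Pedigree, Genomic and Weighted
    Genomic Prediction in Multi-Breed Beef Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of multi-breed beef-cattle
    populations with a known quantitative-trait architecture, and
    evaluation of breeding-value prediction from the simulated data.
    Simulates 29-autosome genomes with uniformly placed biallelic
    markers and evenly spaced QTL, historical populations evolved under
    drift with recurrent mutation through a bottleneck and expansion,
    and recent generations under phenotypic or EBV-based selection with
    breed-specific founder counts and replacement rates.  Provides
    PLINK-compatible genotype input/output and quality control,
    pedigree (A, A-inverse) and genomic (VanRaden G, SNP-weighted G)
    relationship matrices, mixed-model-equation solvers (preconditioned
    conjugate gradients) for PBLUP, GBLUP and SNP-BLUP, two-pass
    window-weighted genomic prediction (wGBLUP), and a scenario-grid
    driver that measures prediction accuracy as the correlation between
    true and estimated breeding values across heritabilities, marker
    densities and reference-population sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
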