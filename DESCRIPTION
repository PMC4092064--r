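Package: rrbsim
Title: Simulation and Analysis of Reduced Representation Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Methylome", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for reduced representation bisulfite
    sequencing (RRBS) of CpG-island-bearing genomes. Generates synthetic
    genomes with CpG-dense islands at gene starts, a bimodal ground-truth
    methylome and coupled expression counts; performs in-silico MspI
    digestion, size selection and directional bisulfite read-pair
    simulation; trims reads (fill-in artifact removal and BWA-style quality
    trimming) and maps them with a three-letter bisulfite-aware paired-end
    aligner (unique FR pairs, 50 bp seed, at most one mismatch per mate,
    insert 150-250 bp); calls per-CpG methylation with coverage thresholds
    and bisulfite-conversion QC; and reproduces genome-wide methylome
    analyses: region methylation histograms, TSS meta-profiles (1000 bp
    sliding window, 50 bp step), TSS CpG-content classification,
    single-nucleotide histograms, expression-stratified profiles, paired
    t-tests and cross-method concordance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
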