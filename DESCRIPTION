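Package: shatterscan
Title: Detection of Genomic Catastrophes from Somatic Variant Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of catastrophic rearrangement processes in tumor
    genomes from somatic SNVs, structural-variant breakpoints and
    allele-specific copy-number segments: high-confidence evidence filtering
    and eight-way structural-variant classification, chromothripsis and
    breakage-fusion-bridge detection from copy-number oscillation,
    breakpoint clustering and join-orientation statistics, kataegis calling
    by exact piecewise-constant fitting of intermutation distances,
    96-trinucleotide-context mutation spectra, telomere-content estimation
    from sequencing reads, and reconstruction of candidate double-minute
    chromosomes as cycles in a breakpoint graph. Includes a synthetic
    tumor-cohort generator with truth labels so every detector is testable
    without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
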