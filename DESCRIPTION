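Package: sipreads
Title: Simulation of Metagenomic Stable-Isotope-Probing Read Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired-end shotgun sequencing read libraries as they
    would be recovered from density-gradient fractions of a DNA
    stable-isotope-probing (SIP) experiment. Reference genomes are sheared
    in silico into extraction fragments; each fragment's buoyant density is
    derived from its G+C content and isotope incorporation, its dispersion
    in an isopycnic CsCl gradient from a diffusion model, and its recovered
    abundance in a sequenced buoyant-density window from a lumen
    (normal-CDF) term plus a diffusive-boundary-layer contamination term
    driven by fixed-angle rotor tube geometry. Reads are allocated
    multinomially by length-weighted fragment abundance and serialized to
    paired multi-FASTA, with optional FASTQ conversion under a parametric
    per-cycle substitution and quality-score model. Includes generators for
    synthetic genomes, communities and gradient fraction sets, and a
    per-fraction genomic-DNA gradient-profile summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    parallel,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
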