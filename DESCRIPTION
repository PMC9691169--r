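Package: mitotick
Title: Comparative Mitogenomics of Hard Ticks
Version: 0.1.0
Authors@R:
    person("Mitotick", "Developers", email = "mitotick@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of hard-tick (Ixodidae)
    mitochondrial genomes: GenBank flat-file and FASTA input with
    normalization of gene names onto the canonical 37-gene + control-region
    vocabulary, base composition and strand-skew statistics, perfect
    microsatellite (SSR) mining with motif-class standardization, IUPAC
    degenerate motif (Tick-Box) scanning on both strands, Kimura
    two-parameter distances with threshold-based species-complex
    delimitation, variable-site and nucleotide-diversity profiling with
    sliding windows, circular gene-order rearrangement scoring (RF/RS)
    against the ancestral arthropod arrangement, and a seeded synthetic
    mitogenome generator that emits ground-truth logs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
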