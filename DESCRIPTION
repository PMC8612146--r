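Package: phageTF
Title: Survey of WhiB- and Lsr2-Type Transcription Factors in Actinobacteriophage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for surveying phage-encoded transcription
    factors (WhiB-like and Lsr2-like regulators) across actinobacteriophage
    genome collections. Includes post-processing of conserved-domain hit
    tables (cross-database collapsing, prevalence filtering, co-occurrence),
    an alignment-free whole-genome phylogeny (k-mer frequency profiles,
    Jensen-Shannon divergence, neighbor joining), a translated homology
    search with locus merging, extension and reciprocal-best-hit filtering,
    greedy identity clustering, genomic-context annotation with sliding
    window GC profiling and AT-dip detection, lifestyle/GC/genome-size group
    statistics, and a synthetic phage-genome generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
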