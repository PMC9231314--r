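Package: evescreen
Title: Endogenous Viral Element Discovery and Insect Virome Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico virome analysis toolkit for insect genome and
    transcriptome assemblies, built around the black soldier fly
    (Hermetia illucens) use case. Detects endogenous viral elements
    (EVEs) in host genome assemblies by six-frame translated homology
    search against a labeled viral protein set, merges nearby
    same-family hits into EVE calls, screens candidates against a host
    proteome (false positives) and for missing host flanks
    (contamination), and assigns orthologous locus labels across
    assemblies from flanking-sequence identity. A companion set of
    tools characterizes exogenous viruses from transcriptome contigs:
    ORF annotation with totivirus-style GAG/POL labeling, contig
    completeness triage, occupancy-based alignment trimming and
    concatenation for downstream phylogenetics, and TPM quantification
    of viral genes relative to a housekeeping gene. A synthetic-data
    generator plants sequence-degraded viral fragments at orthologous
    positions with full ground truth, so every screen is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
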