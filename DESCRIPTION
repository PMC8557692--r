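Package: flpsr
Title: Annotation of Compositionally Biased Regions in Protein and DNA Sequences
Version: 1.0.0
Authors@R: person("flpsr", "developers", role = c("aut", "cre"),
    email = "flpsr@example.org")
Description: Annotates compositionally biased (low-probability subsequence)
    regions in protein and DNA sequences by binomial P-value minimization.
    A quick scan over fixed windows seeds candidate contigs per residue
    type, each contig is minimized over subintervals to the lowest binomial
    tail probability under a background composition, overlapping
    single-residue regions are merged into multiple-residue regions, and
    minimum-length regions are trimmed. Includes precision modes that trade
    speed against sensitivity to mild, multi-residue skews, restriction
    lists, background-composition utilities, domain excision/masking with
    coordinate remapping for discontinuous regions, bias signatures,
    physico-chemical bias classes for proteins and the eight strand-paired
    bias classes for DNA, enrichment reporting, and an fLPS-style command
    line with long, short and one-line output formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
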