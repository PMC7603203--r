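Package: tpsinv
Title: Terpene Synthase Inventory Analysis for Fungal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating the terpene synthase (TS)
    inventory of fungal genomes, with Trichoderma as the motivating system.
    Implements scanning of aspartate-rich metal-binding motif grammars
    (DDxxD/DxDD families) with Class I / Class II / bifunctional fold calls,
    Kyte-Doolittle transmembrane helix detection, rule-based classification of
    TS proteins into functional groups from domain and motif evidence,
    reference-guided phylogenetic assignment (global pairwise alignment,
    neighbor-joining, nonparametric bootstrap), anchor-gene biosynthetic
    cluster extraction from GFF3 with cross-species synteny comparison, and a
    Livak 2^-ddCt relative-expression pipeline with per-gene ANOVA and Tukey
    post-hoc tests. A deterministic synthetic-data module generates protein
    panels with planted signatures, an anchored gene cluster locus, and qPCR
    Ct tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
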