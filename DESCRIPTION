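Package: m5Ccodon
Title: Codon Usage Bias, Translation Efficiency and tRNA m5C Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline linking codon usage bias, translation
    efficiency from paired mRNA-seq and ribosome profiling, and site-level
    tRNA 5-methylcytosine (m5C) quantified by bisulphite sequencing. Provides
    per-gene RSCU with over/under-representation classes, GC3s, Wright's
    effective number of codons (ENC) with the expected-ENC null curve,
    correspondence analysis of the genes-by-59-codon RSCU matrix, CPM-based
    translation efficiency with Welch differential calls and direction
    classification, per-cytosine bisulphite methylation rates projected onto
    tRNA secondary-structure regions, isodecoder-level condition comparisons
    and sequence-context matrices, delta-delta-Ct quantification for tRNA
    charging and fragment assays, and the UUG/CUG cluster grid with its
    explained-fraction statistic. A seeded synthetic-data generator emulates
    the assumed data structure so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
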