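Package: erfkit
Title: Classification, Comparative Genomics and Stress-Expression Analysis
    of AP2/ERF Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide characterization of the AP2/ERF
    transcription-factor superfamily. Implements rule-based assignment of
    genes to the six AP2/ERF subfamilies (ERF, DREB, AP2, ANT, RAV,
    Soloist) and twelve subgroups (A1-A4, B1-B4, AP2, ANT, RAV, Soloist)
    from domain architecture and diagnostic residues; e-value and overlap
    filtering of Pfam domain hits; position-specific conservation
    profiling of the AP2 domain over its secondary-structure divisions;
    reciprocal-best-hit orthology, collinear-block chaining, tandem-array
    detection and species-specificity counting; Nei-Gojobori (1986)
    synonymous substitution rate (Ks) estimation with Jukes-Cantor
    correction and duplication recency classification; FPKM computation,
    differential-expression calling, fuzzy c-means clustering of stress
    time courses, and GO enrichment by one-sided Fisher tests. A bundled
    synthetic-data generator produces labeled proteomes, gene models, CDS
    duplicate pairs, count matrices and GO annotations so every stage can
    be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    e1071,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
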