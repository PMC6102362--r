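Package: subtelscope
Title: Comparative Evolution of Subtelomeric Resistance-Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative inference of recent evolutionary events between two
    annotated haplotypes of a subtelomeric NBS-LRR (NL) disease-resistance
    gene cluster. Implements codon-aware Nei-Gojobori (NG86) Ka/Ks estimation
    with Jukes-Cantor correction, Ks-threshold calibration from low-copy
    anchor orthologs, collinear-block delineation, ortholog/paralog and
    pseudogene classification, lineage-resolved loss/duplication/
    pseudogenization calling, satellite and LTR-retroelement annotation with
    the intact/solo-LTR (I/S) ratio, segmental-duplication detection on
    repeat-masked sequence, and breakpoint-junction resolution with
    NHEJ-versus-HR repair-pathway classification. Includes a two-genotype
    locus simulator that emits FASTA/GFF3 plus a ground-truth event ledger,
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
SystemRequirements: NCBI BLAST+ (blastn on the PATH) for homology-search
    steps (satellite/LTR annotation, segmental-duplication detection).
Config/testthat/edition: 3
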