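Package: cneqc
Title: Assembly Completeness and Contiguity QC with Conserved Non-Exonic Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control of genome assemblies using conserved sequence
    elements. Implements standard assembly statistics (gap runs, contig
    extraction, N(x) values and curves, soft-masked fraction), completeness
    scoring by recovery of ultra-conserved and conserved non-exonic elements
    (CNEs) under alignment identity and coverage filters, a synteny-based
    contiguity statistic built on evolutionarily conserved pairs of
    neighboring CNEs, and a CNE derivation pipeline that merges conserved
    region calls, computes per-species alignment-support windows from a
    reference-anchored multiple alignment (MAF), classifies lineage-specific
    elements, and quantifies transposon overlap. A deterministic clade
    simulator with a planted ground truth makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: QualityControl, Alignment, SequenceMatching, Annotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
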