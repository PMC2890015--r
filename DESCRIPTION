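Package: fosmidann
Title: Gene-Neighborhood Annotation of Fosmid Insert Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates large-insert (fosmid) genomic clones from gene-dense
    plant genomes such as diploid strawberry (Fragaria vesca). Detects perfect
    microsatellites (SSRs) with SSRIT-style parameters and merges nearby
    tracts into operational marker loci; infers protein-coding gene sites
    from tabular protein-homology (blastx-style) hits under dual E-value
    cutoffs; tiers EST alignments by percent identity, classifies
    per-gene coverage, and builds exon/intron gene models from complete
    coverage; reconciles ab initio gene-prediction tracks against the
    evidence-based sites (unsupported predictions, gene mergers and splits,
    validated start/stop codons); detects tandem duplications and
    micro-colinearity with a reference gene order encoded by AGI-style locus
    codes; and computes gene, SSR, and map-distance density summaries. A
    seed-reproducible simulator generates fosmid-like inserts with planted
    genes, SSR tracts, and corrupted prediction tracks, with full ground
    truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
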