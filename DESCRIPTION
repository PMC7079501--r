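Package: clipView
Title: Interactive Visualization of iCLIP Crosslink Sites and RNA-Seq Coverage
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-centric visualization of protein-RNA interaction data.
    Reads gene annotation (BED12 or GTF), iCLIP crosslink-count tracks
    (BEDGRAPH), significant crosslink sites (BED6), per-transcript sequences
    (FASTA), RNA-seq coverage (BEDGRAPH) and splice-event annotations (BED6),
    validates the bundle for cross-file consistency, and serves a multi-user
    web dashboard in which genes are selected by free-text search and drawn
    5'->3' with exon/intron/UTR/CDS glyphs, strand-aware coloring, sequence
    heatmaps, and colored splice-event bars. Figures are described by a
    backend-agnostic declarative specification exportable as SVG, PNG or
    JSON. Includes a binary cache for fast restarts, optional password
    protection, a command-line launcher, and a seeded synthetic fixture
    generator producing complete miniature input bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    grid,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    httpuv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
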