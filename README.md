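# clipView

Gene-centric, web-shareable visualization of protein–RNA interaction data.

RNA-binding proteins (RBPs) contact their target RNAs at specific
nucleotides. iCLIP (individual-nucleotide-resolution crosslinking
immunoprecipitation) maps those contacts: reverse transcription truncates
at the crosslinked base, so each uniquely mapped read `[s, e)` is reduced
to the position one nucleotide upstream of its 5' end —

```
+ strand read:  crosslink site = s − 1
− strand read:  crosslink site = e
```

— and the per-position pile-up of truncated reads is the crosslink
signal. clipView takes the outputs of that upstream processing (crosslink
counts as BEDGRAPH, significant sites as BED6, gene annotation as BED12 or
GTF, optional per-transcript FASTA, RNA-seq coverage, splice events and
description tables; all optionally `.gz`/`.bz2`/`.zip`-compressed),
validates the bundle for cross-file consistency, and serves an interactive
multi-user dashboard: genes are selected by free-text search and drawn
5'→3' with exon/intron/UTR/CDS glyphs (thick coding boxes, half-height
UTRs, thin intron lines; same-strand models black, opposite-strand grey),
crosslink bars with significant-site lanes, sequence heatmaps, RNA-seq
area plots and colored splice-event bars (A3 blue, A5 red, RI green). It
is written for labs who want the convenience of a web genome browser
without uploading unpublished data anywhere: the dashboard runs on a lab
machine, is reachable by link (default port 8060), and can be
password-protected.

The package is aimed at bioinformaticians setting up the viewer and at
wet-lab scientists browsing it. All figure logic lives in a declarative
`FigureSpec` layer that is rendered to SVG/PNG/JSON, so every rendering
convention is unit-tested without a browser.

## Worked example

Generate a complete synthetic input bundle (two chromosomes, seven
transcript models, two iCLIP datasets with significant sites, two RNA-seq
samples with splice events, descriptions, sequences), load and validate
it, and build a figure:

```r
library(clipView)

d <- file.path(tempdir(), "demo_set")
generateFixtureBundle(fixtureSpec(seed = 1), d)
bundle <- loadBundle(fixtureLaunchConfig(d), useCache = FALSE)
bundle
#> DataBundle
#>   annotation sets: 1 (7 models in set 1)
#>   iCLIP tracks: 2 | site sets: 2 | RNA-seq tracks: 2 | event sets: 2
#>   sequences: 7 | descriptions: 7 | extended: 7

nrow(validateBundle(bundle))   # cross-file consistency report: no issues
#> [1] 0

index <- buildGeneIndex(bundle@annotations[[1]])
searchGenes("kin1", searchEntries(index, bundle@descriptions))
#> [1] "G003"
```

`"kin1"` matches no gene id — the hit comes from free-text search over the
supplied descriptions (G003 is described as a KIN1-like cold-inducible
protein). Build its oriented view and figure:

```r
view <- orientView(buildGenomeView(index, bundle, "G003"))
fig <- assembleFigure(view)
fig
#> FigureSpec 'G003 (+)' window [2922,3797): 4 panel(s)
#>   (iclip-signal, iclip-signal, sequence, gene-models)
glyphCount(fig)
#> [1] 905
```

The header carries the gene and its strand; panels follow the dashboard
order (one signal panel per iCLIP dataset with its significant-site lane,
the sequence heatmap, the gene models). The 905 glyphs become exactly 905
drawable SVG elements via `figureToSVG(fig)` / `exportFigure(fig, "PNG")`.

The glyph rules on a coding model — exons `[100,200)` and `[400,500)`,
CDS `[150,450)`:

```r
m <- GeneModel("tx1", "g1", "chr1", "+", c(100L, 400L), c(200L, 500L),
               150L, 450L)
geneModelGlyphs(m)[, c("kind", "xstart", "xend", "heightClass", "color")]
#>   kind xstart xend heightClass   color
#> 1  box    100  150        half #000000
#> 2  box    150  200        full #000000
#> 3 line    200  400        thin #000000
#> 4  box    400  450        full #000000
#> 5  box    450  500        half #000000
```

Half-height UTR, full-height CDS, thin intron — the five-glyph sequence a
coding gene model is drawn with.

To serve the bundle as a dashboard:

```r
serveDashboard(bundle, port = 8060, password = "lab-secret")
# or from a shell:
#   inst/scripts/clipview serve --bed12 demo_set/annotation.bed12 \
#       --map demo_set/tx2gene.tsv --iclip demo_set/iclip_rep1.bedgraph \
#       -desc demo_set/descriptions.tsv -pwd lab-secret
```

Routes: `/` (dashboard), `/search?q=`, `/figure.svg`, `/figure.png`,
`/figure.json`, `/details?gene=`, `/help`. Each browser session holds its
own selection state; the binary cache (`.clipview-cache/` beside the
inputs) makes restarts fast.

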