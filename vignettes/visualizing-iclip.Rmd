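---
title: "Visualizing iCLIP crosslink sites and RNA-seq coverage with clipView"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing iCLIP crosslink sites and RNA-seq coverage with clipView}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipView)
```

## The problem

RNA-binding proteins (RBPs) contact their target transcripts at specific
nucleotides. Individual-nucleotide-resolution crosslinking
immunoprecipitation (iCLIP) maps those contacts genome-wide: reverse
transcription truncates at the crosslinked nucleotide, so the position one
nucleotide upstream of each uniquely mapped read's 5' end is the crosslink
site, and the per-position pile-up of truncated reads is the crosslink
signal. After upstream processing (alignment, pile-up, statistical
filtering of significant sites), the day-to-day task is *looking at genes*:
a wet-lab scientist selects a transcript of interest and needs the
crosslink signal, the significant sites, the matching RNA-seq coverage and
splice events, and the exon/intron structure on one screen, drawn 5'→3' of
that gene, shareable with collaborators over a plain browser link without
uploading unpublished data to a public server.

clipView is that viewer, organised as testable layers: format readers with
a strict validator, a gene-centric genomics core, a declarative
track-specification layer that encodes every rendering convention, and a
thin multi-user web service that only translates figure specifications
into SVG/PNG.

## Data model and coordinate convention

All coordinates inside the package are **0-based half-open** `[start,
end)`. BED-family inputs (BED6, BED12, BEDGRAPH) are already in this
convention and are stored as-is; GTF's 1-based inclusive `[s, e]` is
converted to `[s-1, e)` at read time. One convention throughout removes
the classic off-by-one family of bugs at the cost of a single conversion
at the GTF boundary. Strand `"."` is kept as a first-class unstranded
value (`"*"`), never silently coerced to `"+"`.

The central classes are:

* `GeneModel` — one transcript isoform: ordered disjoint exon blocks, an
  optional CDS span, validity-checked (exons sorted, disjoint, spanning
  the model interval; CDS inside the interval).
* `CoverageTrack` — sparse non-negative signal as per-chromosome runs.
  Construction canonicalizes: runs sorted, zero-valued runs dropped (they
  equal the implicit background), adjacent equal-valued runs merged.
  Canonical form makes track equality a structural comparison.
* `DataBundle` — everything one dashboard serves. The minimal bundle is a
  single annotation set; every other member (descriptions, sequences,
  iCLIP tracks, site sets, RNA-seq tracks, event sets) is optional.
* `GenomeView` — one display window with everything clipped/sliced to it.
* `FigureSpec` / `TrackPanel` — the backend-agnostic figure description;
  the SVG writer, the PNG writer and the web layer consume it and nothing
  else, so the figure logic is tested without a browser.

## The crosslink pile-up rule

For a read `[s, e)` the crosslink position is one nucleotide upstream of
the read start *in read orientation*:

* `+` strand read → position `s - 1`;
* `-` strand read → position `e` (the read's 5' end is at `e - 1`).

The minus-strand half of this rule is stated only abstractly in most
protocol descriptions; `crosslinkPileup(rule = "ignore-strand")` provides
the alternative reading (`s - 1` regardless of strand) for comparison.
Reads whose crosslink position would be negative are dropped and counted
(`droppedReads` attribute). The pile-up conserves counts: the total track
signal equals the number of retained reads, and the result is invariant
under read order.

Pile-up is normally performed upstream of this tool; the implementation
(and its `pileup` CLI subcommand) exists as a tested reference of the rule
and for small ad-hoc datasets.

## Windows, orientation, and clipping

The display window for a gene is the union span of its isoforms extended
by `padding` bases on each side, floored at zero. The default padding is 0
(the window is exactly the gene span); screenshots of comparable tools
show roughly gene-spanning windows and no published padding value exists,
so the neutral choice is the span itself.

Views are built in genomic coordinates and then oriented 5'→3' of the
focus gene. For a plus-strand gene orientation is the identity. For a
minus-strand gene every dense array is reversed and every interval
`[s, e)` within the window `[w0, w1)` maps to `[w0 + (w1-e), w0 + (w1-s))`;
the window sequence is reverse-complemented (with `U` complemented to `A`,
`N` fixed). The mirror is an involution, which the test suite exercises
property-style: applying it twice restores the view bit-for-bit, and one
application preserves the multiset of array values and the total signal.

Models are clipped to the window when the view is built (exons clamped,
exons outside the window dropped, the CDS intersected with the clipped
span). This keeps every glyph inside the window and makes orientation an
exact involution. Two consequences are accepted and documented: a model
that overlaps the window only through an intron is omitted entirely, and
an intron line is not drawn out to the window edge for a partially visible
model. Both affect only windows much narrower than a gene, which the
default padding never produces.

Unstranded features follow the same mirror transformation as everything
else — they are displayed, never ambiguously re-oriented.

## Rendering conventions

The track-specification layer encodes the drawing rules; the renderers
only translate:

* **Gene models.** Introns are thin lines, exons thick boxes. For coding
  models the exon∩CDS pieces are full-height boxes and the exon∖CDS (UTR)
  pieces half-height boxes; non-coding models draw full-height exons. The
  worked example — exons `[100,200)` and `[400,500)` with CDS `[150,450)` —
  yields exactly five glyphs: half `[100,150)`, full `[150,200)`, thin line
  `[200,400)`, full `[400,450)`, half `[450,500)`. Height classes are
  `full = 1.0`, `half = 0.5`, `thin = 0.1` in panel-relative units —
  published descriptions say only "thicker/thinner", so the constants are
  explicit `ColorScheme` fields that can be overridden.
* **Strand coloring.** Models on the focus gene's strand are black
  (`#000000`), opposite-strand models grey (`#808080`); unstranded models
  count as same-strand. Geometry never depends on strand class, only
  color — a tested invariant.
* **iCLIP panels.** One bar per nonzero position of the dense count
  array; the sum of bar heights equals the sum of the array (no signal
  invented or lost). Significant sites are drawn as a bar lane *below*
  the signal: the published screenshots suggest a lane rather than
  markers on the signal, and this is flagged as an interpretation.
* **Sequence panel.** Heatmap mode (default), text mode, or hidden. Each
  base gets a fixed color (A, C, G, T, U, N all distinct; the `U` color is
  purely a lookup, no RNA/DNA logic).
* **RNA-seq panels.** Coverage as an area-glyph sequence (one glyph per
  maximal constant nonzero run — a step-area chart that keeps the glyph
  table flat). Event bars below have three modes: `uniform` (all default
  blue), `by-name` (class map: A3 blue, A5 red, RI green; unknown class
  names get deterministic fallback colors assigned by sorted name order),
  and `by-score` (linear RGB interpolation between two gradient endpoints
  over the min–max score range of the *displayed* events; equal scores map
  to the midpoint; a missing score in this mode is a contract error naming
  the event). Min–max normalization per figure is the package's choice;
  no published scale exists for the gradient.
* **Figure assembly.** Panel order mirrors the dashboard: per-dataset
  signal panels, then (iCLIP tab) the sequence panel, and the gene-models
  panel last; the header is `"<gene> (+)"` or `"<gene> (-)"`. Axis tick
  labels always report original genomic coordinates, also on mirrored
  views.

## The validator

Readers raise syntax errors with file and line number. The validator then
checks cross-file consistency and emits a deterministic report (ordered by
file, line, code) that *is* the output — it never throws. Published
descriptions of this class of tool state that inputs "must pass a
validator" without enumerating checks, so the catalogue here is this
package's own reconstruction, and severities follow one principle:
defects that would corrupt the display are errors, cross-file id
mismatches are warnings because partial bundles are an explicitly
supported use case.

| code | severity | meaning |
|------|----------|---------|
| `duplicate-transcript` | error | transcript id occurs twice in a set |
| `empty-annotation` | error | annotation set with no models |
| `chrom-unknown` | warning | track/site chromosome absent from annotation |
| `sequence-orphan` | warning | FASTA id matching no transcript |
| `sequence-missing` | warning | transcript without a FASTA record |
| `description-unknown-gene` | warning | description row for unknown gene |
| `site-outside-genes` | warning | BED6 record outside every gene span |

`--strict` promotes warnings to errors. Chromosome names are compared
literally (no `chr` aliasing): a mismatch surfaces as `chrom-unknown`
rather than being silently patched.

## Cache

Parsed objects are serialized beside the inputs (dot directory,
configurable) keyed by a fingerprint of the *raw* file bytes plus size and
modification time — recompressing a `.gz` input therefore invalidates the
entry, the simplest correct rule. A version field invalidates entries
across internal format changes. The cache can never block startup: corrupt
entries are discarded with a warning and the file reparsed; an unwritable
cache directory downgrades to parse-only. Cache files are private to the
package, not an interchange format, and deleting the directory is always
safe.

## The web service

The service is deliberately thin: every figure it returns is
`assembleFigure(orientView(buildGenomeView(...)))` on the session's state,
which the test suite asserts by comparing served JSON against a directly
computed specification. Sessions are cookie-keyed; each client holds an
independent `AppState` (pure `(state, event) → state` transitions, so an
event log replays to the same view), which is what makes the dashboard
multi-user. The optional password is a single shared secret checked by a
login form and remembered in the session — matching the granularity of
"restrict access to your group", not user management. TLS is a reverse
proxy's job and out of scope. The default port is 8060.

Figure export: SVG is generated directly from the `FigureSpec` (exactly
one drawable element per glyph, a structural property the tests count) and
PNG through the grid/cairo device from the same pixel layout, so the two
backends cannot drift.

## The synthetic fixture generator

`generateFixtureBundle()` emits a complete miniature bundle for a 2-chromosome
genome (~70 kb total, 6 genes plus an antisense partner overlapping gene 1,
1–2 isoforms each, 2 iCLIP datasets, 2 RNA-seq samples): annotation as both
BED12+map and equivalent GTF, per-transcript genomic-slice FASTA, iCLIP
BEDGRAPH with counts concentrated within ±4 nt of exon boundaries of
odd-numbered "target" genes, BED6 sites at the highest-count positions,
RNA-seq coverage with one gene carrying elevated intronic signal (a
retained-intron signature), splice-event BED6 (A3/A5/RI) with
floating-point scores, short and extended description tables, compressed
copies of the annotation, and a defect catalogue with exactly one broken
file per validator code. All randomness flows from one seed; the same
seed reproduces byte-identical files, which the tests check by digest.

What it emulates: structural consistency across all formats, strand
diversity, an antisense overlap, signal/site/annotation concordance. What
it does **not** emulate: truncation biology, replicate structure,
realistic splice ratios, or sequence composition (bases are uniform
random). Passing tests therefore demonstrate the machinery — parsing,
validation, windowing, orientation, rendering, serving — not biological
inference, which this tool deliberately leaves upstream.

One open interpretation: published format lists say "genomic sequence for
each transcript" without stating whether records are spliced or genomic.
clipView treats each FASTA record as the genomic slice of its transcript's
span (what a sequence display over a genomic window requires), keys
records by transcript id, and N-pads window positions no record covers.

## Numerical and degenerate-input choices

* Empty intervals (`start == end`) are rejected everywhere (half-open
  non-emptiness).
* BEDGRAPH overlapping runs are an error, not summed — two runs claiming
  one position is an upstream bug worth surfacing.
* Search ranking: exact id, id prefix, id substring, description
  substring; ties alphabetical by id; empty query returns the
  alphabetical head. Matching is case-insensitive and literal (no regex).
* Score gradients with a degenerate (single-valued) score range map
  everything to the midpoint color.
* `.zip` sources must contain exactly one member; anything else is a
  format error naming the archive.
* Fingerprint staleness is checked before version compatibility; either
  mismatch causes a silent reparse.

## Problem sizes in the test suite

The property suites run at sizes chosen to finish in seconds while giving
the estimators no room to hide: 200 random model sets for the BED12
round-trip and BED12/GTF agreement, 500 stranded reads against the
brute-force pile-up oracle, 100 random minus-strand views for the
orientation involution, 1000 random track/window pairs for coverage
slicing, and the full fixture bundle for validator, cache, serving and
SVG-structure checks.

## Known limitations

* No BAM/SAM, VCF or FASTA-index input; no genome-scale streaming — the
  tool targets the per-gene browsing workflow, with the cache absorbing
  restart cost.
* Significant-site determination and splice-event calling are upstream by
  design; this package visualizes their outputs.
* One annotation set is indexed per served dashboard (the first, by
  default).
* The mirror-clipping trade-offs described above for windows narrower
  than a gene.
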