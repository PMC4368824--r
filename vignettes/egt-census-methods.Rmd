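---
title: "Methods: a census of endosymbiotic gene transfer on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a census of endosymbiotic gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egtcensus)
```

## The problem

Plastids and mitochondria descend from bacterial endosymbionts, and their
genes have been relocating into the host nuclear genome ever since —
endosymbiotic gene transfer (EGT). A census of this process in a plant
genome has two complementary faces:

* **DNA-level**: segments of the plastome or chondriome found inside the
  nuclear genome (NUPTs and NUMTs), summarised as an *exchange rate* (the
  percentage of organelle-genome positions covered by at least one nuclear
  insertion), a size-class histogram of insertions, and a per-position
  *copy number* profile.
* **gene-level**: nuclear-encoded proteins whose gene trees place them
  within or sister to cyanobacteria (*cyanobacterial recruits*, the legacy
  of the plastid endosymbiont), cross-referenced with nuclear–plastid
  protein homology, EST-based expression evidence, GO term-abundance
  fingerprints rendered as Voronoi treemaps, and group-level statistics of
  genome measures.

`egtcensus` implements every stage of this census as tested, reusable
functions, together with seeded synthetic-data generators that emulate all
inputs with exact ground truth. All interval coordinates in the package are
0-based and half-open on the forward strand of the named sequence; they are
converted only at report boundaries (e.g. BED output).

## Detecting organelle insertions

The detector is a self-contained seed–chain–extend–align pipeline rather
than a wrapper around an external aligner, so that every step is
deterministic and directly testable against planted truth:

1. **Seeding** (`find_seed_matches`): every exact `word_size`-mer shared
   between the nuclear forward strand and the organelle forward or
   reverse-complement strand is reported; words containing `N` never match.
2. **Chaining**: colinear same-strand anchors whose gaps on both
   coordinates are at most `max_join_gap` (default 100 bp) are chained
   greedily; ties (an anchor extendable into two chains) are resolved by
   maximising chained anchor count, then leftmost organelle start. Chains
   are merged to maximality, where a merge requires either a true colinear
   continuation on *both* coordinates or full containment — a spurious
   anchor lying inside a chain's nuclear span but pointing elsewhere on the
   organelle must not inflate the span.
3. **Extension**: each chain is extended outwards by ungapped X-drop
   extension (drop-off 12), which recovers boundaries of diverged
   insertions whose outermost exact words start inside the segment.
4. **Banded global alignment**: the spanned region is aligned within a band
   of width `max(16, band_frac * span)` (default `band_frac = 0.2`) with
   match +1, mismatch −1, gap −2. The reported hit is the
   maximal-scoring contiguous stretch of that alignment path; this trims
   random flanks that a spurious chained anchor would otherwise drag in.
   Hits covering the same insertion after trimming are re-merged and
   realigned once. Identity is matched columns over all alignment columns.
5. **Filtering** (`filter_hits`): hits are retained when identity is
   *strictly* above 80 percent and the organelle span is at least 50 bp —
   the standard screen thresholds.

Coverage (`coverage_profile`) counts, per organelle position, the number of
retained hits whose organelle interval contains it; the exchange rate is
the fraction of positions with depth at least one, reported to 0.01
percent. Overlapping hits are *not* merged before the size histogram (each
chain is one countable NUPT/NUMT) while coverage uses depth over the
interval union: the exchange-rate and per-size-count summaries are not
mutually derivable, and this is the one consistent reading that supports
both. Circular organelle genomes are treated as linear by default; a
`circular` flag adds a `word_size − 1` wrap-around pad so hits crossing the
origin are found, affecting only those hits.

### Word size

The default `word_size = 50` is the standard setting for screens of recent,
high-identity transfers, and it is what the package uses unless told
otherwise. It is, however, analytically blind to diverged insertions: a
100 bp segment at 85 percent identity contains a clean 50-mer with
probability about `51 * 0.85^50` ≈ 1.5 percent. The synthetic benchmark in
the test-suite therefore runs the same detector at `word_size = 12`. The
choice of 12 over, say, 16 is also analytic: substitutions scattered over a
100–150 bp segment at 15 percent divergence occasionally clump so that no
16 bp window is clean, whereas at 12 every in-scope implant (identity ≥ 85
percent, length ≥ 100 bp) contains an exact word with overwhelming
probability. Random 12-mer noise between a 1 Mb nuclear genome and a 150 kb
organelle (~10⁴ shared words) is eliminated by the chain length and
identity filters: a lone 12 bp chain is far below the 50 bp minimum, and
chained noise cannot reach 80 percent identity.

## Protein homology and expression

BLAST-style search is implemented as an exact affine-gap Smith–Waterman
(Gotoh) behind a shared-`k`-mer prefilter (`prefilter_k = 4`): at desk
scale the quadratic DP is affordable, and exactness makes the score
testable against an independent implementation, which the test-suite does
on hundreds of random pairs. The substitution matrix defaults to BLOSUM62
with gap open 11 / extend 1; a gap of length *L* costs `11 + L`. One best
alignment per pair is kept (the census filters operate per hit pair), and
identity is computed over all alignment columns including gaps — the
convention the standard 25 percent identity cut assumes.

Significance uses the Karlin–Altschul form `E = K·m·n·exp(−λS)` with fixed
gapped-BLOSUM62 regime constants (λ = 0.267, K = 0.041). λ and K are
configuration constants, not fitted: only the threshold decision matters,
and both thresholds (`max_evalue = 1e-10`, `min_identity_pct = 25`) are
directly configurable.

Expression qualification follows the megablast idiom: a gene is considered
expressed when at least one alignment against the EST library, seeded by an
exact 28-mer on either strand (EST orientation is arbitrary), reaches an
E-value of at most 1e-10 over the whole library as search space, with
nucleotide constants λ = 1.28, K = 0.46 and +1/−2 scoring. No E-value or
word size is canonical for this step; both are exposed as arguments.

## Gene trees and origin classification

Families are represented by pairwise distances: the mismatch fraction *D*
of each Smith–Waterman alignment is corrected with the Kimura protein
formula `d = −ln(1 − D − D²/5)`, capped at 5.0 for `D ≥ 0.85` (or whenever
the logarithm's argument is non-positive). Trees are built by classical
neighbor joining; for additive matrices the unrooted topology equals the
generating tree exactly, which the suite verifies on 100 random six-taxon
trees. Negative NJ branch lengths are clamped to zero with the deficit
shifted to a sibling edge. A pairwise-distance NJ stand-in was chosen over
a maximum-likelihood pipeline because the package's contribution is the
tree-*consuming* classification logic, not tree inference; externally
produced ML trees in newick format drop in via `read_newick()`.

`classify_origin` treats the tree as unrooted. The query's sister set is
the smallest leaf set among the subtrees meeting the query's attachment
node, counting only leaves that are not query-species paralogs (recent
duplicates carry no signal about the donor lineage). When two sides tie in
size — unavoidable in small trees — the tie is broken deterministically and
rooting-invariantly by comparing the sides' sorted leaf-label vectors. The
call is a strict-majority-with-purity rule: *cyanobacterial* when the
cyanobacterial fraction of the sister set exceeds 1/2, *non-cyanobacterial*
when the sister set contains no cyanobacterial leaf at all, *ambiguous*
otherwise. No decision rule for reading gene trees is canonical; this one
is documented, deterministic, invariant under re-rooting (a property the
suite tests), and the supporting fraction is always reported so users can
re-threshold. Census tables are plain set algebra over three relations
(origin calls, nuclear–plastid homology pairs, the plastid proteome) plus
the expression map; distinct gene ids are counted, not gene copies.

## GO term abundance

Annotations are propagated by the true-path rule (each gene's term set is
closed under is_a/part_of ancestors within the term's namespace) and
optionally collapsed to most-specific GO-Slim ancestors. Each term
annotated in the study set is tested with the upper-tail hypergeometric
probability `P[X ≥ k]` for `X ~ Hypergeometric(N, K, n)`, computed in log
space from binomial coefficients and exact to better than 1e-12 against
exhaustive enumeration. Only over-representation is tested: the census
reports abundance fingerprints. Adjustment is Benjamini–Hochberg within
each namespace separately (the FDR-style family historically used by
term-abundance servers; Bonferroni and Hochberg are switchable and the
method is recorded in output headers), and a term is significant when its
adjusted p is strictly below `alpha = 0.05`. The background defaults to all
annotated genes of the proteome and is overridable. GAF evidence codes are
not filtered by default (no canonical choice exists); `exclude_evidence =
"IEA"` drops electronic annotations.

## Voronoi treemaps

The treemap is an additively weighted (power) Voronoi diagram: cell *i* is
the set of container points `x` with `|x − p_i|² − w_i` minimal, computed
by iterative half-plane clipping of the convex container, so cells are
convex and partition the container exactly (areas sum to the container area
to 1e-9 relative). The solver alternates Lloyd centroid moves with a
damped Newton-style weight update: since the power bisector between sites
at distance *d* shifts by `δ/(2d)` when one weight grows by `δ`, a weight
increment of about half the area deficit is a unit step, and damping 0.5
keeps the simultaneous updates stable. Weights are clamped below the
squared nearest-site distance (no site is swallowed) and recentred each
iteration. Convergence is declared when every cell's relative area error
is at most `max_area_error` (default 1 percent) and is typically reached in
60–150 iterations for up to 50 cells; the 500-iteration cap flags
non-convergence rather than failing. Hierarchies are laid out recursively,
each child level partitioning its parent's polygon, with a parent's weight
excess over its children shown as a residual cell. Cell size defaults to
the annotated gene count `k` per term (the fingerprint encodes abundance)
and can be switched to `−log10(p_adj)`. Colouring is a fixed two-endpoint
ramp over `−log10(p_adj)` with a visually distinct flat band for
non-significant terms and neutral grey for terms without a result row; the
SVG serialisation is byte-deterministic for identical seed and inputs.

## What the synthetic data emulates — and what it does not

* `gen_genome_with_implants` plants copies of random organelle intervals
  into an i.i.d.-uniform nuclear genome with exact per-copy truth:
  substitutions are uniform over the three alternative bases and never
  create indels, so the planted identity is exactly computable. Copies are
  separated by at least 200 bp so separate copies can never chain into one
  hit, and a 12 bp mismatch barrier is forced on both flanks of every copy
  so the planted interval coincides with the maximal-alignment interval —
  without it, a randomly matching flank base legitimately extends the
  detected hit and "boundary accuracy" is ill-posed.
* `gen_families` evolves a random ancestral protein along a fixed-topology
  tree with clean per-group clades (Poisson substitution counts per branch,
  uniform amino-acid replacement rather than an empirical matrix: the
  topology-recovery tests need additive-ish distances, not realistic
  substitution bias). Defaults are 3 taxa per group, 300 residues, 0.03
  expected substitutions per site per branch — low divergence, where the
  classification contract is exact. Mixed-sister families attach the query
  to a cyanobacterium–eukaryote cherry, which a correct classifier must
  flag ambiguous.
* `gen_go_universe` builds a root/slim/leaf DAG with uniform background
  annotation; a planted term's genes enter the study independently with
  probability `fold × study_frac`, so its expected study count is
  `fold × study_frac × K` (25 for the fold-5, K = 50, n = 100, N = 1000
  design the power tests use).
* `gen_ests` emits 1–3 fragments per expressed gene (150–400 bp, 1 percent
  substitution noise, random strand) and nothing for unexpressed genes.

Real genomes are none of these things: they have isochores, repeats,
pseudogenised and rearranged insertions with indels, gene families with
unequal rates and hidden paralogy, biased GO annotation, and EST libraries
with strong 3' bias. Passing the synthetic benchmarks therefore shows that
the algorithms implement their contracts exactly — recovery, calibration,
convergence — not that the defaults are optimal for any particular genome.

## Problem sizes and numerical choices

The test-suite and the acceptance script run, among others: implant
recovery on a 1 Mb nuclear genome against a 150 kb organelle with 100
implants (lengths 50–3,000 bp, identities 60–100 percent); exchange-rate
fidelity over 20 seeds at 300 kb/30 kb; 200 Smith–Waterman pairs against an
independent exact implementation; 100 six-taxon NJ recoveries; 200 null and
100 planted enrichment universes (N = 1000); 100 treemap layouts of up to
50 cells; and the bundled end-to-end study twice to confirm byte-identical
reruns. Degenerate inputs are defined, not accidental: empty hit sets give
all-zero coverage and histograms; a single treemap weight returns the
container; coincident equal-weight sites are separated by a seeded 1e-9
jitter; single-value groups report an RSD of 0 with a warning; a zero mean
is a hard error.

## Limitations

The detector does not date insertions, infer their mechanism, or decompose
genomes into collinear blocks; identity is its only divergence measure.
NJ on corrected pairwise distances degrades at high divergence where ML
methods retain signal — for diverged families, supply external ML trees.
The E-value constants are fixed rather than fitted per matrix, so absolute
E-values are approximate even though threshold decisions are stable. The
enrichment test conditions on annotation counts and inherits every bias of
the annotation source. The treemap solver handles up to a few hundred
cells comfortably but is quadratic in the number of sites per level.
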