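# egtcensus

A census of endosymbiotic gene transfer (EGT) in plant genomes, as a tested
R package. Plastids and mitochondria descend from bacterial endosymbionts,
and their DNA keeps relocating into the host nucleus. `egtcensus`
implements both faces of the census:

* **DNA level** — detect organelle-derived segments in a nuclear genome
  (NUPTs/NUMTs) with a seed–chain–extend–align detector (exact shared
  words, colinear chaining with a 100 bp gap budget, X-drop extension,
  banded global alignment, hits retained at identity > 80% and length
  ≥ 50 bp), and summarise them as the **exchange rate**
  (% of organelle positions covered by ≥ 1 insertion), a size-class
  histogram (50–99, …, ≥ 1000 bp), and a per-position copy-number profile.
* **Gene level** — classify nuclear genes as **cyanobacterial recruits**
  from gene trees (exact affine-gap Smith–Waterman, Karlin–Altschul
  E-values with the E ≤ 1e-10 / identity ≥ 25% screen, Kimura-corrected
  distances `d = -ln(1 - D - D²/5)`, neighbor joining, sister-clade
  composition calls), qualify expression from EST hits (megablast-style
  28-mer seeding), run GO term-abundance analysis (true-path propagation,
  GO-Slim mapping, exact hypergeometric upper tail, Benjamini–Hochberg per
  namespace, significance at p < 0.05), render term fingerprints as
  weight-proportional **Voronoi treemaps** (power diagrams with Lloyd
  moves and damped weight adaptation), and compute group-level means and
  relative standard deviations (100·sd/mean) of genome measures.

Every input the pipeline consumes can be simulated with exact ground truth
(`gen_genome_with_implants`, `gen_families`, `gen_go_universe`,
`gen_ests`), so each stage is testable without downloads. See the methods
vignette (`vignettes/egt-census-methods.Rmd`) for models, parameters and
design decisions.

## Worked example

Plant 25 organelle fragments (60–2000 bp, 85–100% identity) into a
synthetic 400 kb nuclear genome and census them:

```r
library(egtcensus)

g <- gen_genome_with_implants(organelle_len = 50000, nuclear_len = 400000,
                              n_implants = 25, length_range = c(60, 2000),
                              identity_range = c(85, 100), seed = 7)
hits <- detect_insertions(g$nuclear, g$organelle, class = "NUPT",
                          word_size = 12)
hits
#> 25 insertion hit(s)
#>    nuclear_id n_start n_end organelle_id o_start o_end strand length identity_pct ...
#> 1        nuc1    5128  6011         org1   34321 35204      -    883     86.65158
#> 2        nuc1   11134 12418         org1     245  1529      -   1284     91.51751
#> ...

coverage_profile(hits, g$organelle)
#> coverage of org1 (50000 bp): exchange 34.08%, max depth 3

size_histogram(hits)
#> 50–99  -199  -299  -399  -499  -999 ≥1000
#>     0     4     0     3     3     6     9

truth_exchange_rate(g$truth, 50000)
#> [1] 34.1
```

All 25 planted fragments are recovered as exactly one hit each; the
estimated exchange rate (34.08%) agrees with the planted coverage (34.1%)
to within the detector's boundary resolution. `word_size = 12` is the
sensitivity setting used for diverged implants; the package default (50)
is the standard screen setting for recent, high-identity transfers.

The full census — insertion detection for plastome and chondriome, recruit
screening, gene trees and origin calls, expression, enrichment, treemap
and group statistics — runs end-to-end from a YAML config:

```r
cfg <- make_synthetic_inputs("study_dir", seed = 42)  # writes all inputs + config.yaml
run_pipeline(cfg)                                     # 18 output files, deterministic
```

A thin command-line wrapper with per-stage subcommands ships at
`inst/scripts/egt-census`.

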