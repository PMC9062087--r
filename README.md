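# hicpair

Comparative analysis of paired Hi-C contact maps in R: how does the 3D
genome of a tumor cell line differ from its normal counterpart, and do
those structural differences line up with differential gene expression?

Chromatin architecture is organized at three nested scales, all visible in
a binned Hi-C contact matrix **W**: megabase **A/B compartments** (the
plaid pattern; A ≈ active, B ≈ inactive), sub-megabase **topologically
associating domains** (TADs, blocks of enriched self-contact separated by
insulating boundaries), and focal **chromatin loops** (point-to-point
contact between two anchors). Cancer genomes additionally carry structural
variants, including translocations that show up as rectangular hotspots of
inter-chromosomal (trans) contact. `hicpair` implements the complete
comparison between two conditions:

- **ICE balancing** — remove multiplicative per-bin bias b_i by iterating
  W_ij ← W_ij/(δ_i δ_j) until all unmasked marginals agree (CV < tol);
- **distance decay** — per-segment exponents α̂ from log–log OLS of mean
  contact vs genomic distance in (0.1–1], (1–10] and (10+, ∞) Mb segments,
  plus cumulative-contact curves and cis/trans ratios;
- **A/B compartments** at 500 kb — sign of the leading eigenvector of the
  per-chromosome correlation matrix of observed/expected contact, oriented
  against a reference activity track; per-bin switch classes
  (A2A/B2B/A2B/B2A) and the activation ratio
  len(B2A)/len(A2B);
- **insulation-score TADs** at 50 kb — mean contact in a sliding w×w
  square, boundaries at score valleys, cross-condition boundary matching,
  altered-TAD fractions and size statistics (Wilcoxon);
- **specific loops** — loops unique to one condition by *both* anchors
  (one-to-one matching), loop-length contrasts, genes at anchors;
- **translocations** at 40 kb — trans hotspot detection (marginal-
  normalized enrichment, box-filter seeding, half-maximum edges),
  **double-confirmation** against WGS breakpoints (an event is kept iff a
  span edge ± 1 bin contains a breakpoint), and masking of confirmed
  blocks before downstream analysis;
- **SV overlap enrichment** — χ² tests of whether condition-specific
  boundaries/anchors are hit by SVs more than the full feature set;
- **expression integration** — up/down and DEG/NDEG contingency tables
  (Pearson χ², no continuity correction) per compartment switch class, TAD
  stability and loop-anchor status.

A seeded synthetic generator (`generate_pair()`, `generate_expression()`)
produces paired matrices from the model
μ_ij = A·(d_ij·r)^α · plaid(i,j) · tad(i,j) · loop(i,j) · b_i·b_j with
Poisson counts, planted switches, boundary changes, specific loops,
translocations and a matched expression table — with machine-readable
ground truth, so every stage is validated quantitatively. Inputs follow
standard text formats: HiC-Pro triplet matrix + bin BED, BEDPE loops, TSV
gene/SV/breakpoint tables.

## Worked example

Simulate a paired dataset (3 chromosomes, 90 Mb, planted 16.6%/8.4%
compartment switches, ~600 kb TADs, 25% specific loops, one 8-fold
translocation with its WGS breakpoint) and run the full pipeline:

```r
library(hicpair)

cfg   <- synthetic_config(depth = 1e7, seed = 1)
pair  <- generate_pair(cfg)
genes <- generate_expression(pair$truth, seed = 1)
emit_files(pair, "sim", genes = genes)

side <- function(cond) list(
  compartment_matrix = sprintf("sim/%s_compartment.matrix", cond),
  compartment_bed    = sprintf("sim/%s_compartment.bed", cond),
  tad_matrix = sprintf("sim/%s_tad.matrix", cond),
  tad_bed    = sprintf("sim/%s_tad.bed", cond),
  trans_matrix = sprintf("sim/%s_trans.matrix", cond),
  trans_bed    = sprintf("sim/%s_trans.bed", cond),
  loops = sprintf("sim/%s_loops.bedpe", cond))
rc <- run_config(normal = side("normal"), tumor = side("tumor"),
                 genes = "sim/genes.tsv", breakpoints = "sim/breakpoints.tsv",
                 svs = "sim/svs.tsv", reference = "sim/reference_track.tsv",
                 out_dir = "out")
report <- run_full(rc)
```

This completes in well under a minute and prints (abridged):

```
fractions:                       A2A   B2B   A2B   B2A
                               0.430 0.250 0.099 0.221
activation ratio (genome):      2.24
boundaries (normal/tumor/shared): 146 / 136 / 129   median TAD: 600000 bp

translocations:
  chrom_a  start_a    end_a chrom_b start_b   end_b fold_enrichment  status
1    chr1 10040000 11200000    chr2   5e+06 5800000            7.61  double-confirmed

up/down by switch class:          up down   ratio
                        stable   107  109   0.98
                        A2B        8  158   0.05
                        B2A      204   41   4.98
DEG/NDEG ratio at loop anchors:  altered 3.11  vs  stable 1.59
```

Reading this: the called B2A/A2B genome fractions (22.1% / 9.9%) recover
the planted 16.6% / 8.4% targets up to block granularity, so activated
switches outnumber deactivated ones (activation ratio 2.24). The planted
chr1↔chr2 translocation is found with ~1-bin edge accuracy and is
double-confirmed by its breakpoint. Genes in B2A bins are predominantly
up-regulated (ratio 4.98 > 1), genes in A2B bins down-regulated
(0.05 < 1), and genes at specific-loop anchors are enriched for
differential expression relative to other genes (3.11 vs 1.59) — the
planted couplings between structure and expression, recovered end to end.

A command-line front end lives at `inst/cli/hicpair.R`
(`simulate`, `run-full`, `report` subcommands); the methods vignette
(`vignettes/hicpair-methods.Rmd`) documents every model, parameter and
design choice.

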