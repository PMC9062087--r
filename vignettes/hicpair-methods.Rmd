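---
title: "Comparative Hi-C analysis with hicpair: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative Hi-C analysis with hicpair: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicpair)
```

# Scope

`hicpair` compares the 3D genome of two conditions — typically a tumor cell
line against its normal counterpart — starting from binned Hi-C contact
matrices in the HiC-Pro sparse text dialect. It covers matrix balancing,
distance-decay analysis, A/B compartments and their switches, insulation-score
TAD boundaries, loop-list comparison, translocation detection with WGS
breakpoint confirmation, structural-variant overlap enrichment, and the
contingency statistics that join all three structural layers to differential
expression. A seeded generator produces paired synthetic datasets with
machine-readable planted truth, so every stage can be validated
quantitatively; all package tests run against that generator.

Upstream processing (read alignment, matrix building, loop calling, SV and
DE calling) is out of scope: matrices, loop BEDPEs, SV/breakpoint tables and
DE gene tables are consumed as inputs.

# Data model

Coordinates are 0-based half-open throughout; HiC-Pro's 1-based bin ids are
converted at the file boundary. A `bin_table` tiles an ordered chromosome set
at a fixed resolution (last bin per chromosome may be short). A
`contact_matrix` holds a symmetric sparse matrix over those bins with a
raw/normalized flag and a per-bin exclusion mask; on disk the upper triangle
is stored once, and duplicate pairs in an input file are treated as
corruption, not summed.

# Matrix balancing (ICE)

Multiplicative per-bin bias $b_i$ (mappability, GC, fragment density in real
data) is removed by iterative correction: bins with zero coverage or with
marginal below the 2% quantile of nonzero marginals are masked, then each
iteration divides entry $(i,j)$ by $\delta_i\delta_j$, where $\delta_i$ is
the bin's marginal relative to the mean marginal, accumulating $\delta$ into
the returned bias vector. Convergence is declared when the coefficient of
variation of unmasked marginals falls below `tol` (default `1e-5`, maximum
200 iterations). The CV-based statistic guarantees marginal equality at the
level downstream stages assume (CV below `1e-4`); on a noise-free instance
constructed as $b_i b_j T_{ij}$ from a balanced $T$, the planted bias is
recovered up to a global scale to machine precision.

# Distance decay

Expected contact by distance $E(d)$ is the mean over unmasked intra-
chromosomal pairs at bin distance $d$, zeros included. The decay curve pools
chromosomes, summarizes per-distance means in log-spaced bins (16 per
decade), and fits ordinary least squares in log10–log10 space within three
distance segments, (0.1–1 Mb], (1–10 Mb] and (10 Mb, $\infty$), giving the
per-segment decay exponent. Within each log bin both axes are averaged *in
log space* (geometric means): this is still a per-distance mean — so
pair-count differences between distances do not bias the slope — and it makes
the fit exactly collinear on an exact power law, which is the package's
numerical acceptance check. A segment with fewer than three populated bins
is flagged undefined rather than fitted; at 500 kb resolution the
(0.1–1 Mb] segment holds only two distances, which is why the pipeline fits
decay on the 50 kb matrix.

# A/B compartments

Per chromosome, the cis observed/expected block over unmasked bins is turned
into a Pearson correlation matrix of its columns; the leading eigenvector of
that matrix is the compartment signal, bins with positive values labeled A
and negative B. The eigenvector sign is arbitrary, so it is oriented against
a user-supplied reference activity track (non-negative correlation). On real
data gene density is the conventional choice; for synthetic runs the
generator emits its truth-derived activity track with *per-condition*
columns. The per-condition form matters: a track shared between conditions
(and especially gene density in the generator, where gene placement follows
DE classes rather than A-activity) can anti-correlate with a chromosome
whose switched fraction is large and silently flip every call on it.
Chromosomes with fewer than 10 informative bins are set to `NA` with a
warning; exact-zero eigenvector entries are `NA`; only the first eigenvector
is used.

Switch classes (`A2A`, `B2B`, `A2B`, `B2A`) come from per-bin label pairs on
identical bin tables; the activation ratio is switched-to-A length over
switched-to-B length, flagged `infinite`/`undefined` on empty denominators.
Switch fractions are reported as fractions of classified (non-`NA`) length.

# Insulation and TADs

The insulation score at bin $i$ is the mean contact in the $w\times w$
square spanning rows $i-w..i-1$ by columns $i+1..i+w$ ($w = 10$ bins,
i.e. 500 kb at 50 kb bins), normalized as log2 of its ratio to the
chromosome mean. Boundaries are valleys: with the delta track
$\Delta(i) = \text{mean}(s_{i+1..i+d}) - \text{mean}(s_{i-d..i-1})$
($d = 2$), a boundary sits where $\Delta$ crosses from negative to
non-negative, with strength equal to the delta rise across the valley;
boundaries weaker than 0.1 are dropped. These defaults follow the insulation
tool family's conventions and are exposed in the configuration.

Boundary sets are compared by greedy nearest-first one-to-one matching
within ±1 bin (one-bin jitter is below the method's localization accuracy);
unmatched boundaries are condition-specific. TADs are the intervals between
consecutive boundaries (plus chromosome-end flanks); a TAD is altered iff it
touches any condition-specific boundary from either condition, which covers
both a specific flanking boundary and a boundary of the other condition
falling inside the domain. Size contrasts between altered and stable TADs
use a two-sided Wilcoxon rank-sum test (normal approximation with tie
correction).

# Loops

Loop lists (BEDPE, intra-chromosomal, canonicalized anchor order) are
compared under the strict reading of specificity: a loop is shared only if a
single partner loop matches *both* anchors, each within the anchor
tolerance; one shared anchor is not enough. Matching is one-to-one, greedy
by total anchor distance; the default tolerance of 0 bins makes sharing
exact anchor-bin identity. An anchor-wise reading (an anchor being present
anywhere in the other set) was considered and rejected as looser than the
definition's wording; tolerance is exposed for robustness studies. Loop
length is the anchor midpoint separation; length contrasts use the Wilcoxon
rank-sum test. Genes overlap an anchor at ≥ 1 bp under half-open
coordinates.

# Translocations and structural variants

Inter-chromosomal rearrangements appear as rectangular trans-contact
hotspots. For each chromosome pair (unmasked bins only), the scan computes
entry-level enrichment over the expected row-by-column marginal product,
which removes per-bin trends — residual bias and the coupling that ICE
induces between trans rows and cis compartment structure. Because a hotspot
contributes to its own marginals (substantially, when it spans a sizable
share of a small matrix), the expectation is re-estimated after peeling out
the top 5% of box-filtered enrichment windows. Candidate regions are seeded
where box-filtered enrichment exceeds both half the fold threshold and a
median + 5 MAD noise bar, clustered, and localized by half-maximum crossings
of the span-restricted row- and column-mean profiles (tolerating single-bin
dropouts). A candidate is kept iff its block mean reaches `fold` (default 4)
times the background — the mean trans entry outside candidate blocks — and
both spans reach `min_span` (default 5) bins. The scan is deterministic, and
on seeded synthetic data recovers a planted 30×20-bin, 8-fold block with
edge error ≤ 1 bin in 20/20 replicates with no false positives on
translocation-free matrices; 4-fold blocks spanning ≥ 10 bins need roughly
2 counts per trans bin to reach the same reliability, below which misses are
counting-noise limited. Raw matrices with strong bias should be
ICE-normalized before scanning. At very low trans coverage (well under one
count per bin pair) spurious candidates and edge slop of a few bins are
expected; this is precisely the situation the double-confirmation rule is
for — unconfirmed candidates are reported but never masked.

Double confirmation implements the joint Hi-C × WGS rule literally: an event
is confirmed iff at least one of its four span edges, widened by ±1 bin,
contains the corresponding-chromosome position of a breakpoint on the same
chromosome pair (either orientation). Confirmed blocks are masked (entries
zeroed, block recorded) before downstream analysis, matching the study
design in which confirmed rearrangements must not contaminate compartment,
decay or TAD statistics; masking is block-level, not whole-chromosome.

SV overlap enrichment asks, per SV type, whether condition-specific
boundaries or loop anchors are hit by SVs more often than the full feature
set: a 2×2 Pearson chi-square (no continuity correction) of altered status
against SV overlap, with the affected fractions reported alongside.

# Expression integration

Genes are joined to structure by midpoint: the compartment switch class of
the bin containing the gene midpoint, altered-TAD membership of the
midpoint, and ≥ 1 bp overlap with specific-loop anchors (an `overlap`
assignment mode exists for the first two axes). Up/down counts per switch
class give the up/down ratio with each switched class tested 2×2 against
the stable (A2A ∪ B2B) group; DEG/NDEG contingencies per axis follow the
same pattern. Chi-square statistics are Pearson without continuity
correction, matching the study's reported tests; no multiple-testing
correction is applied across the handful of contingency tests, and
degenerate tables (zero margins) return statistic 0 rather than an error.
DE status defaults to adjusted p < 0.05 and |log2FC| ≥ 1 — the source
analyses do not state their cutoffs, so these conventional values are an
explicit, configurable choice.

# The synthetic generator

`generate_pair()` draws paired matrices from the multiplicative model
$\mu_{ij} = A\,(d_{ij}\cdot r)^{\alpha}\cdot\text{plaid}(i,j)\cdot
\text{tad}(i,j)\cdot\text{loop}(i,j)\cdot b_i b_j$ for cis ($d_{ij}$ the bin
distance, diagonal treated as $d = 1$), a flat background times biases for
trans, Poisson counts after scaling total expectation to the configured
depth. Defaults encode the study conditions: $\alpha = -1.2$; plaid boost
$k = 1.5$ for same-label bins with compartment blocks averaging ~4 Mb;
boundary spacing 8–16 bins at 50 kb so the median TAD is ~600 kb, matching
the published median; B2A and A2B switch targets of 16.6% and 8.4% of the
genome, the published switch fractions, realized by flipping whole blocks
(granularity of roughly one block); 10% of boundaries altered in the tumor
(half deleted, half shifted 3–5 bins); 40 loops per chromosome with 25%
specific to each condition; per-bin bias log-uniform in [0.5, 2] so ICE has
real work to do; trans background at 5% of the mean cis level (≈ 8–15%
trans fraction); one planted 30×20-bin translocation at 8-fold with its
breakpoints emitted for double-confirmation. Poisson (not negative-binomial)
noise is used deliberately: structure recovery, not overdispersion
robustness, is what the tests certify.

Two modeling choices deserve emphasis. Translocated blocks multiply the
trans background by a flat fold rather than imposing cis-like decay from the
breakpoint, so the planted fold is exactly the measurable block-to-
background ratio. Loop dots (3×3-bin Gaussian bumps, σ = 1 bin, fold 4) are
planted at full strength only at the loop-calling scale (10 kb) and diluted
by the bin-size ratio on coarser matrices: a focal 10 kb dot binned at
500 kb is diluted thousands-fold in reality, and planting undiluted fold-4
dots at coarse resolution lets 40 random dots dominate the compartment
eigenvector of a desk-scale chromosome. The linear (rather than quadratic)
dilution is a compromise that keeps dots visible in 50 kb
observed/expected maps while leaving compartment structure intact.

`generate_expression()` places genes per structural class (B2A, A2B,
stable, altered-TAD, specific-loop-anchor; 200 each by default) and draws
log2 fold changes from $N(\text{shift}, \sigma)$ with shifts +1.5 / −1.5 /
0 for the compartment classes and random-sign 1.5 for the TAD and loop
classes (alteration predicts differential expression, not its direction).
Adjusted p-values are BH-corrected two-sided normal tests of the realized
log2FC against the null spread. Genes of different classes may overlap in
the genome; capacity is checked against a minimum average spacing rather
than exclusive placement.

What the generator does *not* emulate — restriction-fragment structure,
copy-number gradients, overdispersed counts, mappability-correlated bias,
hg19-scale genomes and depths — bounds what passing tests mean: they certify
the algorithms against their own generative assumptions at desk scale
(≤ 3 chromosomes, ≤ 90 Mb, 10^6–10^7 counts per matrix), not performance on
any particular real library.

# Problem sizes and numerical conventions

The shipped tests and the acceptance script use 200-bin chromosomes at
500 kb for compartment checks, 600 bins at 50 kb for decay, 200 bins at
50 kb for boundaries, 900 bins at 40 kb for translocations, and the default
90 Mb genome for the end-to-end run; the full suite completes in about a
minute on one core. Ties and degenerate inputs resolve conservatively:
exact-zero eigenvector entries are `NA`, both bins adjacent to a block
junction are accepted as the insulation minimum, zero-margin contingency
tables return statistic 0, empty strata are flagged instead of tested, and
an all-masked matrix is an error. Determinism is part of the contract:
equal seeds give byte-identical generator output and byte-identical
pipeline reports.

# Limitations

Compartment calls on chromosomes shorter than ~50 compartment bins are
unreliable (too few bins for a stable correlation structure) and the
package only warns below 10 informative bins. The translocation scan
targets rectangular, roughly uniform hotspots; fusions producing strong
decay gradients from a point breakpoint would be localized less sharply.
Loop comparison operates purely on anchor coordinates — no signal-level
re-evaluation of loop calls. The DEG/NDEG and up/down analyses treat genes
independently, ignoring co-regulation within domains, exactly as the
source contingency analyses do.
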