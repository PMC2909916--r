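---
title: "Methods: microRNA promoter discovery and TF-miRNA network assembly"
author: "mipronet"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: microRNA promoter discovery and TF-miRNA network assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`mipronet` builds a microRNA-mediated regulatory network from genome-wide
RNA polymerase II (RPol II) and transcription-factor ChIP-seq signal in
three steps: (1) identify transcription start sites (TSSs) and promoter
regions of intergenic primary miRNA transcripts from the RPol II binding
shape; (2) identify collaborating transcription factors whose binding
motifs are enriched in the assayed factor's ChIP regions; (3) combine
promoter calls, binding instances and seed-match target prediction into
feedback and feed-forward network motifs. A fully seeded synthetic-data
generator with planted ground truth supports validation of every stage.

# The RPol II TSS shape model

Active promoters show a characteristic RPol II occupancy profile: a peak
at the TSS decaying upstream to a genomic background level and downstream
to a steady transcript-region level. The model carries exactly five
parameters, all in expected reads per bp except the decay rates:

| parameter | meaning | unit | default in the generator |
|---|---|---|---|
| `h_p` | peak intensity at the TSS | reads/bp | 0.3-1.2 by tier |
| `h_b` | steady background intensity | reads/bp | 0.1 |
| `h_t` | steady transcript-region intensity | reads/bp | 0.12-0.18 by tier |
| `lambda_p` | upstream (promoter-side) decay rate | 1/bp | 0.01 |
| `lambda_t` | downstream (transcript-side) decay rate | 1/bp | 0.002 |

The expected intensity at strand-oriented offset $x$ from the TSS is the
minimal continuous form carrying one parameter per named feature:

$$
\mu(x) = \begin{cases}
h_b + (h_p - h_b)\,e^{\lambda_p x} & x \le 0\\[2pt]
h_t + (h_p - h_t)\,e^{-\lambda_t x} & x > 0
\end{cases}
$$

with $\mu(0) = h_p$. Binned read counts are modelled as independent
Poisson draws with mean $w\,\mu(x_i)$ for bin width $w$ (default 50 bp; the
bin width used to summarise RPol II signal is a free choice and is exposed
in the configuration). The Poisson-per-bin likelihood is the simplest
generative model for binned read counts; overdispersion seen in real
ChIP-seq is deliberately not modelled (see Limitations).

**Fitting.** `fit_shape_params()` maximises the Poisson log-likelihood of
TSS-aligned training windows (default $-3{,}000..+10{,}000$ bp) over the
five parameters with bounded quasi-Newton (L-BFGS-B on log-parameters)
from a $3\times3\times3$ multi-start grid over $(h_p, \lambda_p,
\lambda_t)$; $h_b$ and $h_t$ start from the window flanks. The multi-start
plus a tight convergence tolerance (`factr = 1e4`, i.e. ~1e-12 relative)
makes the fit deterministic for fixed input and robust against the local
optima a single start can hit when the peak is weak. Training genes
follow the conventional filter: expressed, transcript longer than 10 kb,
and no neighbouring gene TSS within 10 kb; a seeded random quarter of the
eligible expressed genes trains the model and the rest are evaluated by
ROC.

**Scoring and scanning.** A candidate TSS is scored by the log-likelihood
ratio of the shape model centred there against the constant-background
model $h_b$. `scan_mirna_upstream()` evaluates every bin-aligned candidate
from the pre-miRNA 5' end to 10 kb upstream (strand-aware) and keeps the
argmax; exact ties break toward the candidate closest to the miRNA, which
makes the scan reproducible on flat signal.

**Promoter regions.** Around an accepted TSS the regulatory region is the
maximal contiguous run of bins exceeding
$h_b w + k\sqrt{h_b w}$ (Poisson mean plus $k$ s.d.; $k = 2$ by default),
clipped to 5,000 bp. The TSS bin is always included, so a forced call on
flat signal degrades to a single bin.

**Empirical FDR.** The false discovery rate of a candidate score $s$ is
estimated as the fraction of null scores at or above $s$ divided by the
fraction of candidate scores at or above $s$, clipped to $[0,1]$ and
monotonized so FDR never increases with score. Calls are accepted at FDR
$\le 0.2$. The null set matters: because the candidate statistic is a
*maximum over a 10-kb scan*, null scores computed from single windows
would be anti-conservative. The null is therefore built from the same
max-over-scan statistic, applied at random intergenic anchors placed
clear of every annotated feature by the full reach of the scan, pooled
with identically scanned unexpressed-gene TSSs. This is the package's
design choice for an estimator whose exact construction is otherwise
open; it is conservative-or-accurate by construction and is checked by a
mixture calibration test.

# Collaborating-factor enrichment

Binding potential of a factor at an $L$-bp window is the log-odds sum of
its position-specific score matrix, min-max normalised to $[0,1]$ so that
cutoffs are comparable across matrices of different length and
information content. Weights use a pseudocount of 0.8 per cell and
background base frequencies estimated from the background promoter set
(1,000-bp upstream sequences of genes whose promoter does not overlap any
ChIP region); promoter-matched background avoids the GC bias that random
intergenic sequence would introduce.

For each matrix, both strands of the ChIP regions and of the background
promoters are scanned over an ascending cutoff grid (0.60-1.00, step
0.01). The per-kb density of super-cutoff windows is computed for each
set (denominator: scanned positions, $\sum(\mathrm{len}-L+1)$), and the
density-ratio FDR is background density / ChIP density. A matrix is
enriched when some cutoff reaches FDR $\le 20\%$ — equivalently a 5x
density ratio — with at least 5 ChIP hits (a stability guard against
one-hit "enrichment"). Binding instances are then all windows at or above
the selected cutoff, overlapping windows included, which preserves
multi-site promoters.

One property of this estimator is worth stating: chance matches accrue at
the same per-bp rate in both sequence sets, so they dilute the measured
ratio toward 1. A motif planted at *exactly* 5x the background rate
therefore hovers at the FDR boundary, and only cutoffs high enough to
suppress chance matches (long and/or strongly specified matrices) reach
it cleanly. Enriched factors of near-identical consensus (Hamming
distance $\le 1$ on either orientation) are flagged, since their
enrichment may be a sequence-similarity artifact rather than independent
evidence — the classic situation of bZIP-family matrices resembling the
AP-1 core site.

# Region statistics

* **Overlap permutation test.** Each replicate places length-matched
  intervals uniformly in the eligible space (whole chromosomes by
  default; configurable to exclude assembly gaps). The per-region overlap
  probability `p_hat` is the mean overlap fraction across replicates and
  the p-value is the upper binomial tail
  $P(X \ge k),\, X \sim \mathrm{Bin}(n, \hat p)$. The test is
  seed-reproducible bit-exactly.
* **Co-occurrence.** Given $n$ promoter-overlapping ChIP regions carrying
  the assayed factor and $k$ of them also carrying the top cofactor, the
  p-value is the same binomial tail with $\hat p$ estimated as the
  cofactor hit rate in background promoter windows.
* **CpG islands** follow the standard definition: length above 200 bp, GC
  content at least 50%, observed/expected CpG above 0.6 with
  $\mathrm{obs/exp} = \#\mathrm{CpG}\cdot L /(\#C\cdot\#G)$, found by
  merging passing 200-bp windows and trimming until the merged region
  satisfies all three thresholds.
* **TSS profiles** tally, among genes with at least one binding site
  within $\pm 3$ kb of the TSS, the percentage of genes with a site in
  each 1-kb bin (gene-level tallies; a gene counts in every bin it has a
  site in).

# Target sites and network motifs

Seed matching implements the three canonical site types — 8mer (reverse
complement of miRNA positions 2-8 followed by A), 7mer-m8 (positions 2-8),
7mer-1A (positions 2-7 followed by A) — with strict type precedence: a
locus supporting an 8mer is only ever the 8mer. Conservation filtering of
sites is *not* implemented (it requires multi-genome alignments); an
optional conserved-region mask can be applied by the caller.

Edges are qualitative. A factor regulates a miRNA when the called
promoter region overlaps a ChIP region containing at least one instance
of that factor; a factor binds a gene when a ChIP region overlaps the
$-1{,}000..+500$ bp window around the gene's TSS; a miRNA represses a gene
when its UTR carries at least one seed site. Feedback motifs pair a
TF-regulated miRNA with a targeted focal gene (the assayed factor, its
partner components — JUN/FOS standing for AP-1 — or the upstream ligand
gene); the motif is an explicit cycle when the focal gene encodes a
component of one of its regulating factors. Feed-forward motifs are
(TF, miRNA, gene) triples with all three edges present. Both counting
conventions for feedback elements are available: per-(miRNA, gene) motif
rows, and the per-miRNA tally obtained by grouping them.

# The synthetic-data generator

The generator emulates every input the pipeline consumes and emits the
ground truth needed to score every stage. Its defaults are the study
conditions, chosen once:

* 60 coding genes and 40 miRNAs on two 2.6-Mb chromosomes; feature
  spacing 35 kb, comfortably above both the 10-kb isolation filter and the
  13-kb reach of the upstream scan, so intergenic space exists whose scan
  windows are pure background (intergenic miRNAs are, by selection,
  isolated in real genomes too).
* 60/40 expressed/unexpressed split with three equal expressed tiers. The
  tier shape parameters scale the above-background increments of the low
  tier (h_p 0.3, h_t 0.12 over h_b 0.1) by 1x/2x/4x. A per-gene lognormal
  signal scale (sdlog 1.5) emulates within-tier expression spread; without
  it every tier separates perfectly and tier-resolved ROC ordering would
  be untestable.
* Half the miRNAs are active, at high-tier strength with mild jitter
  (sdlog 0.25): detectable promoters are by construction the robustly
  transcribed subset. TSS-to-pre-miRNA distances are lognormal (median
  3,600 bp) truncated to 200-10,000 bp.
* ChIP regions (500 bp) cover every active miRNA promoter, a designated
  40% of expressed-gene promoters, and random intergenic positions.
  Planted instances reach 5x the background per-bp rate inside ChIP
  regions; bulk instances are sampled from the matrix columns (realistic
  score spread), while the loop-anchoring instances in promoter regions
  are consensus sites so the planted network is recoverable at any
  selected cutoff.
* Background sequence is uniform (25% each base); planted CpG segments
  raise GC to 60% with obs/exp lowered toward 0.8 by composition-
  preserving CG swaps. Note that uniform background is CpG-rich relative
  to real (CpG-depleted) genomes, so genome-scale island statistics are
  weaker discriminators on synthetic data than in practice; the island
  caller itself is validated on planted segments in AT-biased flanks.
* UTRs carry exactly the planted seed sites: mature sequences are drawn
  so that no miRNA's site pattern nests inside another's, and accidental
  matches in flanking sequence are removed by point mutations that never
  touch a planted span.

All randomness flows from one master seed through fixed per-stage derived
seeds; identical seeds give byte-identical bundles (checksummed in the
manifest).

What passing tests on this generator do **not** show: robustness to
overdispersed or mappability-biased coverage, to nucleosome-scale binding
shape variation, to non-uniform genomic base composition, or to the
paralogous motif redundancy of a real matrix library. The generator
validates the inference machinery, not those data pathologies.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: all-zero training coverage is
an error; flat training data collapses the three level parameters
together (the peak is nudged onto the boundary when within noise of it);
scans whose windows leave the chromosome drop those candidates; FDR
curves report 1 where both densities are zero; `N`-containing windows
score $-\infty$ and are excluded. Tie-breaks (closest candidate, leftmost
then plus-strand match) are fixed for reproducibility.

The shipped validation suite runs at deliberately desk-scale sizes chosen
to keep each study under a couple of minutes while leaving wide margins:
500 windows for parameter recovery (relative errors well inside 10%),
300 genes per tier against 900 unexpressed for the ROC study, 200 regions
for enrichment curves, 2,000 permutations for null calibration, and the
default generator bundle for the end-to-end run.

# Limitations

* The Poisson-per-bin likelihood ignores overdispersion; on real data the
  scores remain a useful ranking statistic but the likelihood-ratio scale
  is optimistic.
* Promoter calling is restricted to intergenic miRNAs; intragenic miRNA
  promoters are confounded by host-gene signal and are out of scope.
* The density-ratio FDR is a marginal estimate per matrix; no correction
  across the library is attempted.
* Seed matching reports all sites without conservation or context
  scoring; it recovers predicted-target *candidates*, not efficacy-ranked
  targets.
* Edge signs (activation vs repression) of TF edges are not inferred.
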