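---
title: "Correlated chemical probing of long RNAs: models and methods in ringmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated chemical probing of long RNAs: models and methods in ringmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Dimethyl sulfate (DMS) methylates the base-pairing face of accessible A and
C nucleotides in RNA. Under mutational profiling (MaP), reverse
transcription writes each adduct into the cDNA as a mutation, so a single
sequencing read carries the modification record of a single molecule. Two
nucleotides whose modifications co-occur (or mutually exclude) across
molecules more often than independence allows are communicating through
space - transiently unpaired together, or alternating between
conformations. We call one such significant pairwise correlation a RING
(RNA interaction group). For long RNAs the library is randomly primed and
paired-end; each molecule is observed only on the intervals its mates
cover, possibly with a gap between them.

`ringmapr` consumes per-read mutation records in a documented text format
(MRF: covered intervals, mutated positions, low-quality positions, 1-based
closed coordinates) and implements the full downstream analysis:
per-nucleotide reactivity, pairwise correlation detection, replicate
merging, and community structure of the correlation network. A paired-end
read simulator with analytic oracles makes every stage testable without
sequencing data.

## Pairwise counting without keeping reads in memory

For each ordered pair of positions $i < j$ the package maintains a
$2\times2$ contingency table over all quality-passing reads that cover
both $i$ and $j$:

|            | $j$ mutated | $j$ matched |
|------------|------------|-------------|
| $i$ mutated | $n_{11}$   | $n_{10}$    |
| $i$ matched | $n_{01}$   | $n_{00}$    |

Memory is $O(L^2)$ in the reference length $L$ and independent of the read
count. A naive update would enumerate all covered pairs of every read
($O(\mathrm{cov}^2)$ per read, prohibitive at 200,000 reads x 300 covered
bases). Instead the accumulator performs difference-array (rectangle)
updates: coverage-coverage counts via a two-dimensional difference array
(four corner updates per interval pair), mutation-coverage counts via
one-dimensional row/column difference arrays, and explicit increments only
for mutation-mutation pairs. Per-read work is
$O(k^2 + |M| k + |M|^2)$ for $k$ intervals and $|M|$ mutations; a single
integration pass recovers the dense count matrices. The result is exactly
equal to the naive recount (this is asserted against a brute-force oracle
in the test suite), only faster.

Positions with base quality at or below the phred cutoff (30 in the
upstream pipeline) are excised from coverage before counting, as are
masked positions, so neither contributes to any table. Mate gaps are
handled naturally: a pair is counted only when both positions are covered,
so "long stretches of incomplete information" cost nothing.

## Significance and strength

Each pair is tested with the Yates continuity-corrected chi-squared
statistic,

$$\chi^2 = \frac{N\,(\max(0, |n_{11}n_{00}-n_{10}n_{01}| - N/2))^2}
                 {R_1 R_2 C_1 C_2},$$

and scored with the signed phi coefficient
$\phi = (n_{11}n_{00}-n_{10}n_{01}) / \sqrt{R_1R_2C_1C_2}$ (the Pearson
correlation of the two binary outcomes; positive = co-modification,
negative = mutual exclusion). Pairs with $\chi^2$ strictly above 20 and
pairwise depth $N_{ij}$ at least `depth_min` are reported as rings. At the
criterion of 20 the 1-df upper-tail probability is $7.7\times10^{-6}$, so
the probability that a reported pair is independent is below $10^{-5}$.

Numerical conventions, chosen where the mathematics leaves latitude:

* the correction term is clamped at zero (the standard continuity-corrected
  definition), so near-independent tables cannot yield a positive
  statistic;
* the threshold is strict ("above 20"): a pair at exactly 20 is excluded;
* a table with any zero marginal has an undefined statistic and is treated
  as no evidence ($\chi^2 = 0$, $\phi$ undefined);
* no expected-cell minimum is imposed beyond `depth_min` - the published
  analysis used the single chi-squared criterion, and `depth_min`
  (default 10,000) is the package's guard against the statistic's
  unreliability at low counts. The empirical depth for *reliable*
  detection in the original protocol is about 50,000 reads between two
  locations; [detection_interval()] reports the maximum separation
  reaching any such depth, which with 500-700 nt inserts is what limits
  the reach of the method, not the RNA length.

Replicates are merged by intersection: a pair is kept only if it is
significant in both replicates with the same phi sign. The merged
statistics are deliberately conservative, order-independent combiners -
mean phi, minimum chi-squared, summed depth and cells. The published
method states only the intersection rule; the combiners are this package's
choice and are recorded in the output headers.

## Reactivity profiles and footprints

The conventional readout is the per-nucleotide mutation rate
(count/depth over quality-passing reads). Positions never covered report a
missing rate, not zero. A no-reagent control profile can be turned into a
position mask (`flag_high_background`): positions whose untreated rate
exceeds 0.03 at depth >= 100 - typically sequence polymorphisms - are
excluded from all counting. The 0.03/100 rule is a package default chosen
to separate polymorphism-scale signals (tens of percent) from background
(~0.1%); the original study reports the outcome of such a mask
(26 residues), not the rule.

Ligand footprints are detected by comparing two profiles. The published
analysis presents this visually; to make "notable difference" operational
the package standardizes the rate difference with a Poisson approximation,
$z = (r_a - r_b)/\sqrt{r_a/d_a + r_b/d_b}$, and calls a position protected
(or enhanced) when $|z| \ge 5$ *and* $|\Delta r| \ge 0.01$. The dual
threshold requires both statistical and practical significance: at typical
depths ($10^4$-$10^5$) a $5\sigma$ difference alone can be biologically
negligible, and a 0.01 rate change alone can be noise at low depth. Both
are configuration keys.

## The correlation network

Nucleotides become nodes, rings become undirected edges with weight
$|\phi|$; the sign is kept as an edge attribute. The magnitude is used
because the published strength filter ("greater than 0.015") concerns
strength, and because modularity optimization is ill-defined on negative
weights; whether negative-phi rings enter the network is a flag (included
by magnitude, by default). The graph is then filtered: edges with weight
$\le 0.015$ are removed, and the 3-core is taken (iterative removal of
nodes with fewer than 3 connections). Communities are found by Louvain
modularity maximization on edge weights at resolution 1.0 (all four values
as in the published analysis, which used Gephi). Gephi's exact tie-breaking
is unknowable, so determinism is pinned here instead: the run is seeded,
and community ids are relabeled 0, 1, ... by decreasing size with ties
broken by smallest member position, making partitions reproducible
bit-for-bit.

Node strength (weighted degree) is the sum of incident edge weights,
banded strong (> 0.25) / medium (0.1-0.25, both ends closed; the source
wording "between 0.1 and 0.25" leaves inclusivity open and "greater than
0.25" pins the top boundary) / weak (< 0.1). Edge strengths are banded by
the 50th and 75th percentiles of the weight distribution using the upper
nearest-rank convention (rank $\lfloor qn \rfloor + 1$, capped at $n$):
with weights $\{0.1, 0.2, 0.3, 0.4\}$ only 0.4 is strong and 0.3 is
medium, and when all weights tie every edge is strong. Percentile
thresholds are stored with the output so every category is recomputable;
with fewer than 4 edges ranking is meaningless and edges are `unranked`.
Cross-community edge extraction and condition-versus-condition edge
comparison (strengthened / weakened at $|\Delta w| \ge 0.01$, absent edges
counting as weight 0) operate on these graphs directly.

## The synthetic-data model

The simulator is a first-class module, not a fixture: it defines the
conditions under which the pipeline's statistical behaviour is verified.
Each molecule draws one binary occupancy factor per *block* of nucleotides
- the simplest generative model of an ensemble of conformations that
produces block-structured positive correlations with a closed-form phi. A
reactive member of block $k$ is modified with probability $b_i + f_k d_i$
(baseline plus increment when the factor is on), other reactive positions
with $b_i$, and every covered base is OR-folded with a symmetric
sequencing error $e$ and flagged low-quality with probability
`lowq_frac`. Read geometry: fragment start uniform, insert uniform on
[500, 700] nt, two 150-nt mates, so mates leave a 200-400 nt gap and
pair separations of roughly 150-200 nt are structurally unobservable -
a faithful property of the randomly primed protocol.

For same-block positions the expected observed correlation is

$$\phi_{ij} = \frac{p_k(1-p_k)\,d_i d_j\,(1-e)^2}
                   {\sqrt{r'_i(1-r'_i)\,r'_j(1-r'_j)}},
\qquad r' = r + e(1-r),$$

zero for uncoupled cross-block pairs; coupling two blocks with occupancy
correlation $\rho$ replaces $p(1-p)$ by the occupancy covariance. These
closed forms (`expected_phi`, `expected_rate`) are the oracles for the
calibration tests; detection efficiency is fixed at 1 so they stay exact.

The default scenario is a desk-scale stand-in for a 16S-rRNA-sized
molecule: $L = 1542$, four blocks of 40 reactive members laid out like the
small-subunit domains (body 1-560, platform 561-890, outer head and inner
head interleaved within 930-1380, the latter extended by spine members in
1397-1535 to exercise long-range pairs), occupancy 0.5, increment 0.3 over
baselines in 0.01-0.05, $e = 10^{-3}$, `lowq_frac` $2\times10^{-3}$,
200,000 fragments per replicate. This yields planted $\phi \approx 0.14$-
$0.17$ - intentionally larger than the 0.015 edge filter suggests for
in-cell effects, giving reliable detection at 200,000 fragments where the
real experiment needed tens of millions. The ligand variant adds the two
signatures of a spectinomycin-like binder: one focal position (the first
outer-head member) with modification probability scaled by 0.25, and
coupling of the two head blocks at $\rho = 0.8$, which strengthens
cross-domain edges without changing any marginal rate. The sequence, block
members and baselines are drawn once from a fixed internal RNG stream, so
both scenarios are constants.

What the simulator does *not* emulate: realistic per-base quality-score
distributions, PCR duplication, alignment artifacts, position-specific
error beyond planted SNP-like hot positions, multi-state (more than
binary) conformational ensembles, and detection efficiency below 1.
Passing tests therefore demonstrate that the statistics, counting and
graph machinery are correct and calibrated - not that in-cell effect
sizes of real data are recoverable at these depths.

## Problem sizes and reproducibility

The verification suite runs at deliberately chosen desk scales: null
calibration on a 60-nt fully covered reference at per-pair depth $10^5$
(1,770 pairs, expected false positives 0.014 at the criterion); domain
recovery over 10 independent two-replicate pipelines of 200,000 fragments
each, requiring the modal community count (communities with >= 10 nodes)
to equal the planted 4 and adjusted Rand index > 0.9 against planted
membership in at least 8 of 10 runs; oracle equivalence on 200 random
micro-fixtures ($L \le 30$, $\le 50$ reads), 1,000 random tables against
R's `chisq.test(correct = TRUE)` (whose correction is clamped exactly as
here) and exhaustive k-core peeling on graphs of up to 12 nodes. Every
random draw - simulation, Louvain - is seeded; identical seeds give
byte-identical MRF files and bit-identical partitions.

## Known limitations

* The MRF dialect is this package's own; the upstream mutation-string
  format it stands in for is not publicly specified, and SAM/BAM
  conversion is out of scope.
* No multiple-testing correction across pairs is applied, by design: the
  method's published criterion is the fixed chi-squared threshold.
* Phi magnitudes from merged replicates are means, not pooled-table
  estimates; pooling tables would weight replicates by depth and was
  rejected to keep replicates symmetric.
* Louvain is a greedy heuristic; different seeds can yield different
  partitions on ambiguous graphs. The seeded, relabeled output makes runs
  reproducible but not seed-independent.
* Reactivity profiles are raw mutation rates; normalization to SHAPE-like
  scales and structure prediction are out of scope.
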