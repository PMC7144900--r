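---
title: "Methods and design notes for hierarchical TAD calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for hierarchical TAD calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hictad)
```

# The model

`hictad` assumes two priors about chromatin folding: the genome of a
region is organized hierarchically (higher-order domains contain
lower-order ones), and adjacent genomic loci belong either to the same
self-interacting domain or to immediately adjacent ones. Under these
priors, TAD calling becomes *adjacency-constrained hierarchical
clustering* of matrix bins, and the whole dendrogram — not just one
cut — is the object of interest.

The pipeline is: filter low-coverage bins; replace the interaction
matrix by its Pearson-correlation (PCC) matrix and run PCA on it;
for every candidate count of leading components build the Euclidean
distance matrix of the scores and cluster it with CONISS; bound the
significant levels with the broken-stick model; score levels with the
Calinski–Harabasz (CH) index; choose the component count with the
highest mean CH and, within it, the level with maximal CH.

## CONISS

The dispersion of a cluster $C$ is defined from squared pairwise
distances, $D(C) = \sum_{i<j \in C} d_{ij}^2 / |C|$, which coincides
with the coordinate sum of squares when $d$ is Euclidean. At each step
the adjacent pair whose merge minimally increases total dispersion is
joined. Costs are maintained with the Ward/Lance–Williams recurrence
(an $O(n^2)$ algorithm); the test suite proves the recurrence
equivalent to a from-scratch $O(n^4)$ re-computation on hundreds of
random instances at $10^{-9}$ tolerance. Recorded heights are
*cumulative* dispersions, so they are monotone by construction even
though individual increments of constrained clusterings need not be.

**Tie-break.** Equal-cost adjacent pairs merge leftmost-first. This is
deterministic, independent of the (symmetric) input representation, and
matches a sequential scan. Ties are measure-zero for continuous data
but common in degenerate fixtures.

## Broken-stick bound

For a dendrogram over $n$ bins, the $g$-th split (cutting from $g-1$ to
$g$ groups) releases a fraction of the total dispersion; it is compared
with the expected size of the $g$-th largest piece of a unit stick
broken uniformly into $n$ pieces, $b_g = (1/n)\sum_{i=g}^{n} 1/i$. The
maximum significant group count $G$ is the largest $g$ such that the
observed fraction exceeds $b_g$ for **all** $2..g$ (first-crossing
rule; `first_crossing = FALSE` switches to the largest individually
significant $g$). The maximum level is $G-1$: level $L$ means $L+1$
domains. The first-crossing rule was chosen because the bound is meant
to delimit a *contiguous* range of usable levels — an isolated
significant split beyond a non-significant one would make intermediate
levels meaningless.

## CH scoring and the joint optimum

CH is computed on the retained PC scores (the same geometry the
clustering saw), not on the distance matrix: with $B$ the
size-weighted dispersion of cluster centroids around the grand centroid
and $W$ the within-cluster dispersion,
$CH = \frac{B/(k-1)}{W/(n-k)}$. It is undefined at $k = 1$ and $k = n$
(signalled as a distinct condition).

The mean CH of a dendrogram is taken over *its own* significant levels
(a variable number per component count). Ties in the mean go to the
smaller component count and ties in the level argmax to the smaller
level — parsimony in both cases. `min_tads` (default 2) excludes
shallow levels from the competition; setting it to 10 reproduces the
benchmark constraint of considering only levels with at least 10
domains.

A consequence worth knowing: on very clean, strongly blocked synthetic
matrices the 1-component dendrogram often wins, because its single
significant level has an enormous CH while multi-level dendrograms
average over weaker deep levels. The full sweep is retained in
`ch_matrix`, and cuts of deeper dendrograms (`coniss` +
`cut_coniss`) recover all planted levels within one bin; the winner
simply concentrates on the dominant scale. On noisy experimental maps
the balance shifts toward tens of components and many levels.

## Stability flag

Structureless matrices (e.g. permuted bins) occasionally produce an
isolated broken-stick crossing at a single component count. A real
hierarchical signal is detectable across essentially the whole sweep,
so the result carries `support` — the fraction of swept component
counts with at least one significant level — and is flagged
`stable = FALSE` below 50%. In our experiments structured matrices
show support ≈ 1.0 and permuted nulls ≈ 0.01, so the threshold is not
delicate.

# Preprocessing choices

* "Empty diagonal" means a diagonal entry that is 0 or missing: text
  matrices cannot reliably distinguish structural missingness from 0.
* The bad-column percentile (linear-interpolation definition, strict
  `<` comparison) is computed over **all** column sums by default;
  `over_all_columns = FALSE` excludes zero-diagonal columns from the
  reference distribution first. The difference is negligible unless
  many columns are empty.
* Centromere = longest run of all-zero columns, leftmost on ties.
* Matrices are validated for symmetry (relative tolerance $10^{-6}$)
  and then symmetrized by averaging with the transpose.
* After filtering, partitions are mapped back to original bins by
  attaching masked bins to the preceding domain (leading masked bins to
  the first domain), so every level tiles the full region.
* Internally bins are 1-based inclusive intervals (the R idiom); all
  emitted genomic coordinates are 0-based half-open BED. Only the
  external convention is part of the contract.

# Comparison statistics

**MoC** follows the printed two-case definition; both-single-domain
pairs score 1. Borders for the **overlap score** are internal
boundaries only — region ends are shared by construction and would
inflate the score. The overlap p-value simulates random fine partitions
with the observed domain count and counts scores `>=` the observed one
(add-one corrected). Because the score is discrete (one hit per coarse
border), ties make the p-value conservative when borders are few: with
$m$ coarse borders the score has $m+1$ levels and
$E[p] = 1/2 + E[P(\text{tie})]/2$. Calibration to 0.5 therefore holds
in the many-border regime (the acceptance test uses chromosome-scale
partitions, 200 vs 151 domains, where the measured mean null p-value
is 0.503).

**DiffT** sums $|p_{ij}-q_{ij}|$ over the full square matrix exactly as
the printed equation (diagonals always cancel). The implementation uses
an interval identity for the per-row sums —
$|P(i)| + |Q(i)| - 2|P(i)\cap Q(i)|$ — proven equal to the literal
double loop in the tests. Identical partitions yield an all-zero
profile flagged `identical` instead of 0/0. The permutation test draws
random partitions with Q's domain count, forbidding boundaries adjacent
to excluded (bad) bins while keeping $N$ fixed so profiles stay
comparable bin by bin; p-values use the add-one convention, so they
live in $[1/(n_{sim}+1), 1]$. The final bin's p-value is
deterministically 1 (every profile ends at exactly 1), which is why
calibration checks pool interior bins only. Low p at bin $b$ means the
observed profile is unusually *low* there, i.e. the topological
difference concentrates from $b$ onward — the minimum-p bins mark the
start of the divergent region.

# Enrichment metrics

The boundary profile uses 200 slots of 5 kb spanning ±500 kb; the
"0 kb" slot is the one whose $[0, 5\,\text{kb})$ offset range contains
the boundary. A peak counts for a slot on any ≥1 bp overlap. The fold
change compares the mean of the center slot ±1 slot against the mean of
two 100-kb flanks placed 400 kb away, minus one. "±1 bin" means 5-kb
slots for the fold change but matrix-resolution bins for boundary
occupancy, mirroring the two contexts in which the tolerance is used.

For the TAD-body state test, both tracks are coarse-grained to bins of
10% of the mean TAD size and the per-bin statistic is
$\log_{10}$(repressive/active) with a pseudocount equal to each track's
1st percentile of positive values (scale-adaptive, avoids $-\infty$).
The default per-bin null swaps, within each coarse bin, which track
each fine-resolution value belongs to (a paired permutation test): bins
where the two marks differ consistently get small p-values, p-values
are independent across bins, and they are uniform when the two signals
are exchangeable. BH is applied to the bins of each TAD and the TAD FDR
is the minimum adjusted p (Simes-like, so the null rate of
state-defined TADs matches the FDR threshold). An alternative
`region_shuffle` null — permuting coarse log-ratios across the region
and comparing magnitudes — is kept as an option, but it can only flag
bins more extreme than the region's typical ratio: when whole TADs are
coherently state-defined, every bin is "typical", the per-TAD BH floor
is about 1/#TADs, and the statistic collapses; that is why it is not
the default.

# The synthetic world

`generate_matrix` draws Poisson counts around
$E_{ij} = \text{base}\cdot\max(|i-j|,1)^{-\alpha}\cdot
\text{contrast}^{\text{depth}(i,j)}$, with depth the number of
hierarchy levels at which $i$ and $j$ share a domain. Defaults: 96
bins, two nested levels (2 → 4 domains), contrast 3 per depth, $\alpha
= 1$ (the typical intra-chromosomal decay regime), base 100 (deep
coverage, "low noise"), 2% zeroed columns. Upper-triangle draws are
mirrored, so matrices are exactly symmetric and reproducible at fixed
seed.

What the generator does **not** emulate: coverage and restriction-site
bias, normalization artifacts, over-dispersion beyond Poisson (a
negative-binomial hook would slot in where `rpois` is called),
compartment-scale checkerboards, and loops. A green recovery test
therefore establishes that the algorithm recovers nested block
structure under counting noise — not that it is robust to every
experimental artifact.

`generate_peaks` places boundary peaks with probability `hit_rate` and
background peaks per 5-kb slot with probability `background_rate`;
`generate_signal_tracks` assigns alternating repressed/active states to
TADs with lognormal noise. Both exist to give the enrichment metrics a
known truth.

# Numerical choices and degenerate inputs

* PCA: mean-centering only, no variance scaling; component signs are
  irrelevant (only distances are consumed downstream). PCA runs once
  per matrix; per-count distance matrices reuse the cached scores.
* Components with standard deviation below $10^{-8}$ of the leading one
  are treated as numerical rank deficiency and never offered.
* Fewer than 4 unmasked bins: hierarchy undefined, hard error.
* A dendrogram with zero total dispersion (all points identical) has no
  significant level.
* All permutation p-values use the add-one correction; all RNG flows
  through R's global stream so a single `set.seed` (or the `seed`
  arguments) makes any analysis bit-reproducible.

# Known limitations

* The $O(n^2)$ memory of dense matrices and the PC sweep make whole
  chromosome arms at fine resolution expensive; the CLI warns above
  15 000 bins and offers the centromere split.
* The broken-stick bound is a heuristic null; on matrices with strong
  distance decay but no blocks it can admit a level or two (the
  stability flag exists for this reason).
* MoC and overlap assume both partitions tile the same extent;
  partial-coverage callers must be harmonized upstream.
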