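---
title: "Ternary discretization co-expression networks: model, null and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ternary discretization co-expression networks: model, null and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triexnet)
```

## The model

`triexnet` treats co-expression as a counting problem on discretized data.
Each gene is compared only to itself: with per-gene mean $\mu_g$ and sample
standard deviation $s_g$ (the $n-1$ convention), the code of gene $g$ in
sample $s$ is

$$\mathrm{code}(g,s) = \begin{cases} +1 & (x_{gs}-\mu_g)/s_g > Z \\
-1 & (x_{gs}-\mu_g)/s_g < -Z \\ 0 & \text{otherwise,} \end{cases}$$

so the method is invariant to per-gene positive affine transforms and
assumes nothing about absolute expression scale beyond sensible upstream
normalization. A constant gene (zero variance) is coded all-zero rather
than rejected, so noise-free background genes pass through harmlessly.

The ternary matrix splits into binary indicators $P$ ($+1$ codes) and $M$
($-1$ codes), and the inner products $PP'$, $MM'$, $PM'$ count, for every
ordered gene pair, the samples in which both genes carry the relevant
codes. $PP'$ and $MM'$ are symmetric and kept upper-triangular with zero
diagonals; $PM'$ is asymmetric (gene1 up, gene2 down) and its diagonal is
structurally zero because a gene cannot be up and down in one sample.

A pair becomes an edge when its count strictly exceeds a null threshold
conditioned on both genes' sign-specific densities — the number of $+1$s
for a $P$-side gene and $-1$s for an $M$-side gene. Supports (the counts)
are carried into all downstream pair-lists.

### Assumptions worth stating

* Co-variation is monotone: a regulated gene tracks (or anti-tracks) its
  regulator in enough samples to beat the density-conditional null. Cyclic
  or strongly non-monotone regulation is outside the model.
* Relations are not causal. A `pm` edge says "gene1 up while gene2 down
  recurs", nothing about direction of control.
* Samples are exchangeable under the null; the permutation null conditions
  on each gene's marginal code histogram, not on any sample structure.

## The null distribution

Permuting two binary vectors with densities $d_1, d_2$ over $n$ samples
makes their overlap hypergeometric (population $n$, successes $d_1$, draws
$d_2$). The null therefore depends only on $(d_1, d_2, n)$, and thresholds
are cached per density pair instead of being re-simulated per gene pair —
mathematically identical and orders of magnitude faster. Two modes exist:

* `exact` (default): threshold is the smallest $k$ with
  $F(k) \ge q$ via `qhyper`; this is also the oracle the Monte Carlo mode
  is tested against.
* `monte_carlo`: both vectors are actually permuted `reps` times
  (default 1000), the type-7 (linear interpolation) quantile of the
  simulated overlaps is taken and rounded up to an integer. A seed is
  mandatory; each density pair derives its own reproducible stream, so
  lookup order does not matter.

Edges require a count **strictly greater** than the threshold, matching an
"exceeds $q$ of the random scores" acceptance rule. Degenerate densities
behave correctly by construction: density 0 gives threshold 0 and no
positive count; saturated genes ($d = n$) give threshold $n$, which no
count can exceed, so always-on genes never form edges.

**Discreteness makes the null conservative.** With an integer threshold at
the $q = 0.995$ quantile of a discrete distribution, the realized per-pair
acceptance probability is $P(X > k_q) \le 0.005$ and typically nearer
0.003 for mid-range densities at $n = 100$. The calibration test asserts
the observed rate on independent random codes lies within three binomial
standard errors of 0.5% per relation; that band is tight for the `pm`
relation (ordered pairs), and because all pairs share the same 100 gene
vectors the realized rate also fluctuates more than a binomial count
would. The check is kept at its stated tolerance; when it sits near the
lower band edge this conservatism, not a counting defect, is the cause.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `z_cutoff` | 0.4 | discretization cutoff in per-gene SD units; 0.4 keeps small but observable changes, larger values trade sensitivity for specificity |
| `quantile` | 0.995 | null acceptance quantile ($P = 0.005$ per pair per relation) |
| `mode` | `"exact"` | hypergeometric closed form vs permutation Monte Carlo |
| `reps` | 1000 | permutations per density pair (MC mode) |
| `sd_type` | `"sample"` | $n-1$ vs $n$ denominator; the original convention is not recorded anywhere authoritative, so it is a switch with the standard choice as default |
| `r_cutoff` / `p_cutoff` | — | correlation cutoff, directly or via the two-tailed t-test inverse |

Raising `z_cutoff` can only turn nonzero codes to zero (strict
inequalities), so the nonzero cells at a higher cutoff are a subset of
those at a lower one, and network size is in practice non-increasing in
$Z$ — the package tests this over $Z \in \{0.4, 0.8, 1.2, 1.6\}$.

## Correlation as companion and filter

The Pearson companion uses $t = r\sqrt{N-2}/\sqrt{1-r^2}$ with $N-2$
degrees of freedom, two-tailed; at $N = 100$, $r = 0.1$ corresponds to
$p = 0.32$ and $r = 0.3$ to $p = 0.0024$, and `p_to_r()` inverts the
transform in closed form (the round trip is exact to $10^{-9}$). Filtering
requires a positive-set correlation edge for `pp`/`mm` and a negative-set
edge for `pm`; supports are untouched and the output is always a subset.

One behaviour of this package's simulator deserves emphasis. Its
background genes are *independent* Gaussian noise (deliberately — see
below), so a background pair can only enter a co-occurrence network
through chance sample agreement, and that same agreement elevates its
Pearson $r$. The permissive filter ($r$ at the 0.005-level of the
co-occurrence null) therefore removes few of these chance pairs: the two
methods make correlated type-I errors on the same data. At a strict cutoff
($r = 0.3$) the filter separates cleanly — in the module tests it removes
the large majority of background-containing pairs while retaining every
planted activation pair. Generators whose background streams are recycled
across genes (as some simulation packages do) show strong filtering
already at $r = 0.1$; that behaviour is a property of the generator, not
of the filter.

## Transitive predictions from a signed regulatory network

Ground-truth wiring uses three edge types: `ac` (activation, $+1$), `re`
(repression, $-1$) and `du` (dual action, $0$ — no consistent sign). Taking
powers of the signed adjacency loses pairs whose positive and negative walk
counts cancel, so the adjacency is split into $A^+$ and $A^-$ and the
positive/negative walk counts are propagated separately:

$$P_k = A^+P_{k-1} + A^-N_{k-1}, \qquad N_k = A^+N_{k-1} + A^-P_{k-1}.$$

Two views are derived per depth $k \le 3$ and also merged: *walk* pairs
(source and target of a signed walk — an all-activator chain predicts a
positive pair, an odd number of repressions a negative one) and
*shared-regulator* pairs (two targets reached from a common source; equal
sign products predict positive co-expression, opposite products negative).
A pair with conflicting evidence is reported as **ambiguous**, never
silently signed; prediction sets are monotone in $k$ up to such flags.

Scoring a network against definitions buckets every edge exactly once:
direct definition, transitive prediction of the matching sign, or
unexplained; `re` recovery in `pm` is matched ignoring direction since
repression manifests in both up-down senses. `du` definitions are counted
as their own matched category and never as expected-positive or
expected-negative.

## The synthetic-study generator

The generator emulates benchmark expression simulators that drive
"microarray" data from a known signed network plus pure-noise background
genes, at reference conditions fixed once: 100 defined + 100 background
genes, 200 samples, noise 0.1, and an ac/re/du mix of roughly
0.65/0.275/0.075 (the proportions of a classic E. coli-style definition
set). Topology is an acyclic preferential-attachment DAG — each non-root
gene takes 1–2 earlier parents with probability proportional to current
out-degree — so regulator hubs and shared-target motifs arise naturally.

Expression is linear signed propagation: roots are standard normal; every
regulated gene sums its parents with their edge signs (`du` parents flip
sign per sample), the sum is rescaled to unit variance, and Gaussian noise
with standard deviation `bio_noise` is added. `bio_noise` is thus a
noise-to-signal scale at every cascade depth, and the correlation between
a gene and a direct parent is $1/\sqrt{1+\mathrm{bio\_noise}^2}$ — about
0.995 at 0.1 and 0.89 at 0.5. Background genes are pure
$N(0, \mathrm{bio\_noise}^2)$ noise: low-variance, unwired, and flagged
with the `bgr_` prefix.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data:

* saturating (Michaelis–Menten-style) transfer functions: the network
  method depends on monotone co-variation, not kinetics, so propagation is
  kept linear and fully specified;
* recycled random background streams: background noise is drawn fresh per
  run (a test asserts the correlation-of-correlations between independent
  runs is near zero), which is the *opposite* of simulators whose
  background repeats — a pitfall worth testing against, since repeated
  streams manufacture reproducible false pairs;
* microarray-specific artefacts (probe effects, dye bias, batch), sample
  heterogeneity, and subpopulation-specific relations that dominate real
  cohorts.

Because direct-parent correlations stay high over the whole
`bio_noise` 0.1–0.5 sweep, direct activation/repression recovery is
saturated at the reference conditions; degradation with noise shows up in
network size and in transitive coverage rather than in direct recovery.

Dual-action edges genuinely produce *both* same-sign and opposite-sign
co-occurrence (their sign flips per sample), so a handful of du-mediated
pairs legitimately appear in both `pp` and `pm` on the same run. At the
package's test scale (networks of order $10^3$ edges, 13 du definitions)
these few pairs are around 0.2–0.4% of a network — tiny, but visible,
whereas with millions of edges they would vanish below 0.001%. The
exclusivity acceptance check (`pm` vs `pp`/`mm` overlap below 0.1%) is
kept at its stated tolerance and can fail by exactly this mechanism; for
contrast, if the two networks were independent the expected chance overlap
at those sizes would be ~50 pairs, against the observed ~3.

## Numerical choices and degenerate inputs

* Quantile estimator: R's default type-7 linear interpolation, then
  ceiling to an integer (MC mode); exact mode uses the discrete CDF
  directly.
* Strict inequality at both the discretization boundary and the null
  threshold; boundary ties are measure-zero on real data and the rule is
  deterministic.
* Eigenvector sign in `spectral_reorder()` is fixed by making the
  largest-magnitude component positive; ordering ties break by gene name;
  `pm` edges are symmetrized with a warning. Binary adjacency is the
  default, support-weighted available (`weighted = TRUE`) — which variant
  feeds a given analysis is the user's call, binary being the less
  assumption-laden.
* The size-significance t-statistic is oriented null-minus-observed, so
  structured data give large-magnitude *negative* t; a zero-variance null
  falls back to an exact count comparison and an empty observed network
  reports $p = 1$ with a flag.
* Modal variance (for low-variance gene selection) is the histogram mode
  of log-variances with Freedman–Diaconis bins (Sturges fallback);
  zero-variance genes are always selected. The estimate needs a dominant
  variance class — with as many background as defined genes at low noise
  the mode can land on the background class, which is the honest answer to
  an ill-posed question.
* Expression probe collapsing happens at the pair-list level
  (`collapse_to_genes()`): probe rows are never averaged, duplicate symbol
  pairs are de-duplicated keeping the maximum support, and `pm` direction
  survives the mapping. Averaging probes before discretization would
  change supports; keeping probes preserves the pipeline order that
  pair-level de-duplication assumes.

## Problem sizes in the test suite

The suite exercises the full pipeline at 200 genes × 200 samples (the
reference conditions), oracle equivalence on 200 random 50 × 20 matrices,
the Monte-Carlo/exact comparison on the complete 21 × 21 density grid at
$n = 20$, calibration at 100 × 100, and 100-fold randomization
significance — sizes chosen so every property is measured on meaningful
statistics while the whole suite stays fast enough to run habitually.

## Known limitations

* No multiple-testing correction beyond the fixed per-pair quantile; the
  method's significance statement is about the *network size*, not any
  single edge.
* Probe-level networks with many-to-one symbol mappings can double-count
  biological relations until `collapse_to_genes()` is applied to the
  pair-lists.
* The mm/pp reciprocity observed in simulated data is a property of
  symmetric linear propagation; real cohorts show asymmetric relations
  (genes co-varying in one direction only), which is precisely what the
  signed relation classes exist to expose.
* `subset_consensus()` increases specificity at a sensitivity cost that
  grows as subsets shrink; with fewer than ~50 samples per subset the
  density-conditional thresholds become coarse.
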