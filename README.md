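# triexnet — co-expression networks from ternary-discretized expression data

`triexnet` builds gene co-expression networks for observational expression
studies (microarray or similar gene × sample matrices) by a deliberately
simple route: code every expression value as **up** (+1), **down** (−1) or
**unchanged** (0) relative to the gene's own mean, then ask which gene pairs
are up or down *together* in more samples than chance allows. The method is
aimed at biomarker work, where the goal is dense cliques of co-regulated
genes and a way to rank samples by how strongly a clique is switched on or
off — not causal regulatory inference.

Because the codes are signed, co-expression splits into three relation
classes that plain correlation cannot distinguish:

* **pp** — up-together,
* **mm** — down-together,
* **pm** — directed up-down (gene1 up while gene2 down).

## The method

For gene *g* with values *x(g,s)* across samples, compute per-gene z-scores
against the gene's own mean μ_g and (n−1) standard deviation s_g, and code

    code(g,s) = +1 if z > Z,  −1 if z < −Z,  0 otherwise       (default Z = 0.4)

The ternary matrix splits into binary indicator matrices **P** (codes = +1)
and **M** (codes = −1). Their inner products

    P·P′  (pp),   M·M′  (mm),   P·M′  (pm, asymmetric)

count, for every gene pair, the samples supporting each relation. A pair
becomes an edge when its count **strictly exceeds** the 0.995 quantile of a
permutation null that conditions on both genes' sign-specific densities
(number of +1s or −1s): permuting two fixed-density binary vectors makes
their overlap hypergeometric, so the null is computed either exactly
(`mode = "exact"`, the default) or by honest Monte Carlo permutation
(`mode = "monte_carlo"`, 1000 reps), cached per density pair.

Around that core the package provides:

* Pearson correlation networks with the t-test cutoff
  t = r·√(N−2)/√(1−r²), as an independent method and as a filter
  (`correlation_network()`, `correlation_filter()`, `r_to_p()`, `p_to_r()`);
* expected co-expression pairs — direct and transitive — from a signed
  ac/re/du regulatory network, with explicit sign-cancellation flagging
  (`transitive_predictions()`, `score_against_definitions()`);
* network comparison, reciprocity, whole-network randomization significance
  and spectral reordering (`intersect_pairlists()`, `reciprocal_pairs()`,
  `network_size_significance()`, `spectral_reorder()`);
* per-sample clique scores for stratification (`clique_sample_scores()`);
* a synthetic-study generator with known ground truth and pure-noise
  `bgr_` background genes (`simulation_config()`, `simulate_study()`);
* a command line (`inst/exec/triexnet`) wiring the steps into
  `simulate`, `build`, `correlate`, `filter`, `validate`, `compare`,
  `reciprocal`, `sizesig`, `reorder` and `stratify` subcommands.

## Worked example

Simulate a study at the reference conditions (100 regulated genes + 100
background genes, 200 samples, noise-to-signal 0.1), build the networks,
and validate them against the generator's own wiring:

```r
library(triexnet)

study <- simulate_study(simulation_config(seed = 1))
#> simulated_study: 200 gene(s) x 200 sample(s); 136 interaction(s); bio_noise = 0.1

nets <- build_networks(study$expr, z_cutoff = 0.4, quantile = 0.995)
#> triexnet networks (Z = 0.4 , quantile = 0.995 , exact null)
#>   pp: 991  mm: 969  pm: 1411 edges

score_against_definitions(nets$pp, nets$mm, nets$pm, study$truth)
#> validation against 136 definitions (ac: 96 du: 13 re: 27 ), transitive depth <= 3
#>  network n_edges ac_recovered du_recovered re_recovered ac_fraction re_fraction
#>       pp     991           95            3            0        0.99           0
#>       mm     969           95            2            0        0.99           0
#>       pm     801            0            2           27        0.00           1
#>  direct transitive unexplained bgr_edges
#>      98        782         111        52
#>      97        751         121        42
#>      29        575         197        96
```

The pp/mm networks recover 99% of the planted activations and none land in
pm, which instead recovers all 27 repressions — the signed relation classes
separate activation from repression cleanly. Most remaining edges are
explained by transitive (shared-regulator) predictions; the `unexplained`
column is dominated by pairs touching noise-only `bgr_` genes.

Is the observed network bigger than chance? Row-shuffling the discretized
matrix preserves every gene's code histogram but destroys co-occurrence:

```r
network_size_significance(nets$discretized, n_rand = 100, seed = 2)
#> network size significance: 3371 edges observed; null mean 260.8 over 100 shuffles
#>   t = -1800.598  p = 1.25609e-225  [ ok ]
```

Shuffled networks are ~8% of the observed size and the one-sample t-test
(null sizes minus observed, hence the large negative t) gives p ≈ 0.

Finally, reorder the pp network by the leading eigenvector of its adjacency
and score each sample on the top clique:

```r
so <- spectral_reorder(nets$pp)
#> spectral_order over 135 gene(s); leading eigenvalue 28.05
#>   head: g060 g042 g057 g050 g089 g058 g022 g041

scores <- clique_sample_scores(nets$discretized, so$ordering[1:8])
summary(scores)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   -8.00   -5.00    0.00   -0.08    5.00    8.00
```

Samples at −8 have the whole 8-gene clique switched off, samples at +8
fully on: the discretized matrix itself stratifies the cohort by module
state.

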