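---
title: "Methods: rates and correlates of axial body-plan evolution on fossil phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rates and correlates of axial body-plan evolution on fossil phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axevol)
library(ape)
library(dplyr)
```

# The scientific problem

Adult vertebral columns record the developmental processes that built them.
Three mechanisms generate differences in presacral axial organization among
amniotes: **somitogenesis** (how many somites, hence vertebrae, are
produced), **homeotic effects** (where the Hox-mediated boundary between
cervical and dorsal regions falls, i.e. how the presacral total is
partitioned between neck and trunk), and **post-patterning differential
growth** (how large the vertebrae of each region grow after patterning).
Each mechanism has an osteological proxy measurable on fossils:

| trait | definition | proxy for | units |
|---|---|---|---|
| `presacral_count` | cervical + dorsal count | somitogenesis | vertebrae |
| `count_ratio` | cervical / dorsal count | homeotic regionalization | – |
| `unit_length_ratio` | (neck/cervical) / (trunk/dorsal) | differential growth | – |
| `length_ratio` | neck length / trunk length | body proportions | – |

This package implements an analysis pipeline for asking, on a time-scaled
fossil phylogeny, (i) how the evolutionary *rate* of each trait varies among
branches (a variable-rate Brownian-motion model fit by reversible-jump
MCMC), and (ii) how evolutionary *changes* in the traits covary
(through-origin regressions of standardized phylogenetic independent
contrasts, plus a node-by-node decomposition of cervical vs dorsal change
into pure-homeotic and pure-somitogenetic components). Secondarily aquatic
Mesozoic reptiles — with presacral counts spanning roughly 19–94 and neck
lengths from ~14% to ~400% of trunk length — are the motivating system, and
the synthetic-data generator mimics that regime, but nothing in the code is
specific to it.

# Trait construction and count ambiguity

Vertebral counts are often ambiguous (a damaged cervical–dorsal transition),
recorded as integer ranges `[lo, hi]`. `resolve_ambiguous_counts()` draws a
count uniformly from each range, independently per taxon and replicate, and
repeats this (100 replicates in a production run) so the uncertainty
propagates into every downstream statistic. Point counts are never
perturbed. Each replicate's unit lengths use that replicate's resolved
counts, keeping every replicate internally consistent (so
`length_ratio = count_ratio * unit_length_ratio` holds exactly whenever all
three are computable — an identity the tests assert to 1e-12).

Missing measurements make a trait `NA` for that taxon, never zero, and taxa
are pruned per trait: a taxon missing neck length still contributes to the
count-based analyses. This mirrors real datasets in which counts are known
for more taxa than lengths.

**Analysis scale.** Whether traits should be analyzed raw or log-transformed
is decided by a diagnostic rather than by fiat: `scale_diagnostic()`
correlates the absolute standardized contrast at each internal node with the
contrasts algorithm's ancestral estimate at that node (Pearson correlation,
α = 0.05 — the conventional choice; the diagnostic's distributional
calibration under Brownian motion is verified by simulation in the test
suite). Variance growing with the trait value indicates a proportional
process and favors the log scale; `log_transform_traits()` applies it. A
constant trait yields zero contrasts and the diagnostic is reported as
`undefined` rather than as a number.

# Time-scaling cladograms against the fossil record

Fossil cladograms carry no branch durations. `hedman_timescale()` assigns
node ages using the consecutive-outgroup logic: successively older outgroup
first appearances `a_1 < a_2 < …` bound the ages of the divergences below
the ingroup root, each divergence being uniform between its outgroup's age
and the divergence above it, truncated above by a hard bound `t0`. The
ingroup root's marginal distribution is obtained by cascading these
conditional uniforms on a discrete grid (`n_bins = 1000` by default; the
cascade integral needs the grid, and 1000 bins make the discretization error
negligible next to the Monte Carlo error). All other internal nodes are
sampled root-to-tip, uniform between the parent's sampled age and the oldest
descendant tip — the continuous limit of per-bin sampling, so no grid is
needed below the root.

Design choices made here, since published descriptions leave them open:

* **`t0` default** is 20 Myr older than the oldest calibrating age; it must
  be explicit in any serious analysis and is a visible argument.
* **Joint vs marginal sampling**: nodes are sampled sequentially
  root-to-tip, each conditioned on its parent's sampled age, giving a valid
  joint sample (marginal per-node draws would allow parent–child age
  inversions).
* **Branch-duration floor**: contrasts need strictly positive durations. A
  floor of 0.001 Myr per branch is reserved *structurally* — each node's
  feasible lower bound is the oldest descendant tip age plus 0.001 Myr per
  intervening node — so durations are positive *and* ages remain exactly
  additive along paths (no post-hoc clamping that would break additivity).
* **Tip ages** are drawn uniformly over each taxon's narrowest known
  stratigraphic interval (`sample_tip_ages()`), resampled per tree so age
  uncertainty enters the tree set.
* **Polytomies are refused**: resolution is an upstream tree-inference
  problem, not a dating problem.

**Hard node-age constraints.** A node known to be too old (e.g. a clade
whose oldest certain fossils postdate its inferred divergence) can be capped
with `constrain_node_age(tree, node, max_age)` — e.g. a 208.5 Ma (start of
Rhaetian) cap. If the node is younger than the cap the tree is returned
unchanged. Otherwise the node is set to exactly `max_age` and all internal
node ages in its clade are compressed linearly between a pivot `P` (the
clade's oldest tip age) and the cap:
`age ↦ P + (age − P)·(max_age − P)/(old_age − P)`.
We considered rescaling only the branch-duration portions older than
`max_age`, but that scheme has no positive solution: every root-to-tip path
inside the clade contains the full interval between the cap and the old node
age, so preserving tip ages forces the compression factor to zero. The
linear age map is the isotropic compression that *does* exist: it preserves
tip ages exactly, preserves relative proportions among compressed segments,
keeps parent–child order (it is strictly monotone), and is idempotent.

# Variable-rate Brownian motion by reversible-jump MCMC

The rate model: a base Brownian variance σ²₀ applies at the root; an unknown
number *k* of shift points sit on branches, each carrying a multiplier; a
branch's rate σ²_b is σ²₀ times the product of multipliers on its root path
(shifts are inherited until overridden). The trait likelihood is the
REML/contrast form — each independent contrast is Gaussian with variance
equal to its cherry's summed rate-scaled branch lengths — which equals the
dense multivariate-normal likelihood up to elimination of the root state, so
no root parameter exists to sample. The pruning evaluation is O(n) per
likelihood call and implemented in C++; the test suite pins it against a
dense covariance-matrix oracle at 1e-8.

**Priors** (configurable via `rate_priors()`): k ~ Poisson(ln 2) truncated
at the branch count, putting half the prior mass on "no shifts" so shifts
must earn their place; shift positions uniform over branch subsets;
multipliers lognormal(0, 1.25); σ²₀ log-uniform on [1e-6, 1e6].

**Moves** (`rate_proposals()`, weights 30/20/10/10/20/10): multiplier
rescale and σ²₀ rescale (log-scale sliding windows), shift birth/death
(multiplier drawn from its prior, so the Metropolis–Hastings–Green ratio
reduces to λ/(k+1) and k/λ — the uniform placement prior cancels the
placement proposal), shift relocation, and multiplier swap. Relocation
proposes a uniformly chosen shift-free branch anywhere in the tree rather
than an adjacent branch: the global move is exactly symmetric (unit Hastings
ratio, no adjacency-count bookkeeping) and mixes across distant modes at
least as well. Correctness of the sampler is tested two ways: with fixed
dimension (birth/death weights zero) the sampled σ² posterior matches a
dense grid-normalized posterior to Kolmogorov–Smirnov distance < 0.05, and
with free dimension the posterior shift count on single-rate data stays at
or below the prior mean (no spurious-shift inflation).

**Protocol.** Production analyses use two independent chains of 5 million
generations, thinned, with the first quarter discarded
(`combine_chains(..., burnin_frac = 0.25)`) and effective sample sizes
(spectral estimate, `ess()`) expected above 1000 — the pipeline warns below
that. Simulation tests in this package run a "test profile" of 2×10⁵
generations on 48–64-tip trees, which the recovery checks show is ample at
those sizes: posterior σ²₀ tracks the realized REML estimate within a few
percent, and a clade simulated at 10× background rate is recovered (clade
vs background median branch-rate ratio > 3) in ≥ 90% of replicates.

**Clade rate comparisons.** `branch_rate_summary()` gives per-branch
posterior medians and credible intervals, classifying branches
above/below/at the tree-wide median (the phenogram red/blue/gray scheme; a
branch is "at" when its interval covers the tree-wide median).
`compare_clade_rates_ttest()` runs a Welch t-test on branch medians between
a focal clade (stem branch included, by convention — configurable via
`clade_partition()`) and the rest. Because branch medians are neither
independent nor homoscedastic this t-test is anticonservative, which is why
`permutation_test_posteriors()` exists: its statistic is the clade-vs-rest
difference in mean branch rate computed within each posterior sample and
averaged over samples, with the null built by permuting branch labels —
exact under branch exchangeability, and calibrated to type-I error
0.03–0.07 at α = 0.05 in the test suite. The calibration test constructs
exchangeable-rate posterior chains directly rather than running hundreds of
MCMC chains: branch exchangeability is precisely the null hypothesis of the
permutation test, so this isolates the test's calibration from sampler
noise.

# Contrast regressions, ANCOVA, and the pure-change decomposition

`standardized_pics()` computes Felsenstein's contrasts (pruning algorithm:
contrast x₁−x₂, SD √(v₁+v₂), weighted-mean ancestral value, parent branch
extended by v₁v₂/(v₁+v₂)); one standardized contrast per internal node.
`pic_ols()` regresses contrasts **through the origin** — contrasts have
arbitrary sign, so an intercept is meaningless — with
R² = 1 − RSS/Σy², and by default "positivizes" (flips each node's signs so
the first predictor's contrast is non-negative; R² and p are unaffected,
only slope signs are disambiguated). The battery run per tree: length ratio
on count ratio, length ratio on unit length ratio, the bivariate fit
(count + unit length ratio), and count ratio on presacral count, plus the
non-phylogenetic tip-value regression (`raw_ols()`, intercept retained).
Under bivariate Brownian motion with increment correlation ρ the
through-origin contrast R² estimates ρ²; the test suite verifies the mean
R² at ρ = 0.87 on 200-tip trees is 0.757 within ±0.02, and the null (ρ = 0)
mean matches the Beta(½,(m−1)/2) small-sample level 1/m.

`pic_ancova()` fits `y ~ 0 + x + x:period` and tests whether the contrast
regression slope differs between time periods. The period of a node is
assigned by clade membership by default (e.g. nodes inside vs outside a
focal crown radiation, matching split-subset analyses); an age rule (older
vs younger than 201.3 Ma, the Triassic–Jurassic boundary) and a custom
age-to-period function are also available, since the node sets the two
rules produce differ and the choice should be visible.

**Pure-change decomposition.** For the cervical contrast c and dorsal
contrast d at a node (the cervical contrast's orientation fixes the
dorsal's, because the *sign relationship* is the object of study): on the
raw scale, pure homeotic change keeps the presacral total constant, the
line d = −c; the perpendicular distance |c+d|/√2 measures co-occurring
somitogenetic change, and |c−d|/√2 is the magnitude along the homeotic
diagonal. On the log scale, pure somitogenetic change keeps the ratio
constant, the line d = c, with the roles of the two formulas exchanged.
`pure_change_decomposition()` reports both distances and classifies a node
as a "pure" change when the alternative-mechanism distance falls below
ε = 0.05 standardized units — a reporting threshold for a pattern that is
otherwise assessed visually; it is configurable and all distances are
returned so any other cut can be applied.

# The synthetic-data generator

`simulate_fossil_tree()` produces non-ultrametric trees by forward
birth–death simulation (via `ape::rlineage`, which retains extinct lineages
as dated tips), retrying until at least `n_tips` lineages exist and then
uniformly downsampling to exactly `n_tips` — the same downsampling-to-data
step real fossil analyses perform. Defaults (birth 0.1, death 0.08 per
lineage-Myr over a 180 Myr span) give the high-turnover, extinct-tip-rich
regime of Mesozoic marine reptile clades. Each tip gets a stratigraphic
interval of width uniform on 1–10 Myr positioned uniformly around its true
age (truncated at the present), matching the inputs the dating module
expects.

`simulate_multirate_bm()` and `simulate_correlated_traits()` provide ground
truth for the rate and regression machinery (per-branch Gaussian increments
with variance rate × duration; bivariate increments with correlation ρ).
`simulate_axial_specimens()` generates latent cervical and dorsal counts by
correlated Brownian motion *on the log scale* (cervical variance 2e-3,
dorsal 4e-4 per Myr: numerators of the ratio traits more variable than
denominators, as observed in the motivating clade), rounds them, nudges
totals minimally into the presacral envelope 19–94, builds neck/trunk
lengths as count × lognormal unit length, and then injects count ranges of
width 1–3 with probability 0.2 and deletes length measurements with
probability 0.2. The generator returns its ground truth so recovery is
testable end to end.

What passing tests on these data do **not** show about real data: the
generator evolves counts by a smooth diffusion with a single global
correlation, has no directional trends, no preservation biases correlated
with anatomy or age, no character-correlated extinction, and its
stratigraphic intervals are centered on the truth. Results on real fossil
datasets inherit none of those guarantees; the tests certify the machinery,
not the biology.

# Orchestration

`run_full_analysis()` executes the whole battery over a set of trees and
count-randomization replicates. The pairing of randomized datasets with
trees is **one-to-one by default** (replicate i on tree i — preserving one
analysis per tree, so 100 trees mean 100 analyses), with a fully crossed
design available (`pairing = "crossed"`). Per-cell seeds derive
deterministically from the manifest seed; identical manifests reproduce
outputs byte for byte, and `rlang::hash()` of the manifest is embedded in
every output table for provenance. Failures in a cell are recorded in
`$failures` with the tree and replicate ids and never silently dropped.
Per-tree p-values are reported raw (fractions of trees significant at α,
via `summarize_significance_fraction()`), with no multiple-testing
correction — the summaries across trees describe topology uncertainty, not
repeated tests of one hypothesis.

Problem sizes used by the test suite and the acceptance script — 64-tip
trees, 2×10⁵-generation chains, 50–500 simulation replicates — are the
package's test profile; production settings (100 trees, two 5×10⁶-generation
chains per trait per tree) are the defaults documented above and scale
linearly.

# Known limitations

* Only Brownian-motion rate variation is modeled: no Ornstein–Uhlenbeck,
  trends, or early bursts, and rates are univariate (no multivariate rate
  matrix or shared shift points across traits).
* The t-test on branch medians is anticonservative by construction and kept
  only because it is the conventional summary; the permutation test is the
  defensible one.
* The dating model treats outgroup ages as known and node densities as
  uniform between bounds; it propagates stratigraphic uncertainty but not
  outgroup-topology uncertainty.
* `constrain_node_age()` compresses the whole clade's internal ages, not
  only the super-cap portions (shown above to be impossible with fixed
  tips); ages just below the cap therefore shift slightly even though they
  did not violate it.
* Polytomies and missing branch lengths are refused rather than resolved.

```{r session}
sessionInfo()
```
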