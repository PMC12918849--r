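---
title: "Models and methods in phylodiscord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phylodiscord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodiscord)
```

phylodiscord packages the computational chain of a species-level
target-capture phylogenomic study: coalescent null distributions for
cytonuclear discordance, concordance statistics, bait-design locus
screening, phylogenetic trait–environment models, Brownian ancestral
reconstruction, and DEC range evolution. This vignette states each model,
its assumptions, the tunable parameters, and the numerical and design
choices that were genuinely open.

## The multispecies coalescent simulator

Gene trees are simulated by the censored coalescent: the species tree is
cut into populations bounded by speciation (and reticulation) events;
within a population carrying $k$ lineages, the next coalescence waits
$\mathrm{Exp}\!\binom{k}{2}$ in coalescent units ($2N$ generations), and
lineages that fail to coalesce are passed rootward; above the root
coalescence continues to a single lineage. For three taxa separated by an
internal branch of length $t$, the concordant topology has probability
$1 - \tfrac{2}{3}e^{-t}$ and each discordant resolution
$\tfrac{1}{3}e^{-t}$; the test suite checks the simulator against these
closed forms at 50 000 replicates and against a two-pass mixture oracle on
networks.

A species network adds reticulation edges $(\text{donor branch},
\text{recipient branch}, \tau, \gamma)$: each lineage present on the
recipient branch at time $\tau$ independently follows the minor (donor)
parent with inheritance probability $\gamma$. Because populations change
membership only at event boundaries, one simulation core (in C++) serves
both cases; the population graph is processed in topological order so
zero-length segments and simultaneous events are handled correctly.

Assumptions and choices:

* **Branch lengths are coalescent units directly**; no per-branch
  population sizes. This matches the quartet-based species-tree outputs
  the pipeline consumes.
* **One sample per species is the default.** Terminal branch lengths are
  then irrelevant to the topology distribution. Species trees with
  arbitrary terminal lengths (quartet methods) can be accommodated with
  `terminal_policy = "extend"`, which stretches pendant branches to the
  present; multi-sample simulation requires user-supplied terminal
  lengths. Ultrametricity is enforced with a relative tolerance of 1e-6
  of tree height, absorbing Newick round-off.
* **Gamma estimation** (`estimate_gamma`) minimizes the L2 distance
  between observed and simulated topology-frequency vectors over a grid
  (default 0.01–0.99 in steps of 0.02, 5000 simulated trees per grid
  point with a fixed per-point seed so the objective is deterministic);
  the CI is a nonparametric bootstrap over observed trees. Topology
  frequencies are informative only for small taxon sets — with 17 taxa
  essentially every simulated tree is topologically unique — so γ should
  be estimated on the pruned subproblem around the hypothesized event,
  as the acceptance script does with four taxa.

## Discordance attribution

`clade_support` computes, for each rooted clade of a reference tree, the
fraction of (simulated or empirical) gene trees in which the clade is
recovered; denominators count only decisive trees (all clade members
present plus at least one outsider), so missing taxa shrink the
denominator rather than counting as non-support — the convention of
standard concordance summaries. The attribution rule is deliberately
simple: frequency strictly greater than 0.9 under the coalescent null is
labeled ILS-consistent; anything else is conflict beyond ILS
(hybridization, plastome capture). The threshold is strict because the
rule is stated as an inequality, and `attribute_discordance` exposes it
as a parameter. Gene concordance factors use unrooted bipartitions with
the four-block decisiveness rule; rooted-clade scoring is kept for
outgroup-rooted reference comparisons, and both modes are available
because published pipelines have mixed the two conventions.

## Locus screening

The bait-design triage operates on per-locus gene trees with ultrafast
bootstrap supports and on aligned reference/query sequence pairs:

1. collapse internal branches with support `< 70` (unlabeled branches
   conservatively count as support 0, configurable);
2. a locus is *unresolved* if nothing survives, *informative* if strictly
   more than four surviving nodes have support `>= 90` (counting on the
   collapsed tree — the only reading under which unresolved trees exist);
3. sequence divergence is the gap- and ambiguity-excluded mismatch
   proportion, *divergent* means `>= 0.15` inclusive;
4. selected loci are the informative-and-divergent intersection.

The inclusive/exclusive readings ("more than four", "≥15%") follow the
literal statements; they are configuration defaults
(`locus_filter_config`), not hard-coded constants, since the original
counts cannot be re-derived without the source genomes.

## Trait–environment models

`ppca` implements phylogenetically structured PCA: with Brownian
covariance $C$ from the tree, the ancestral mean is
$a = (1^\top C^{-1}1)^{-1} 1^\top C^{-1}X$ and the evolutionary
covariance $R = (X-1a)^\top C^{-1} (X-1a)/(n-1)$ is eigendecomposed;
scores are $(X-1a)V$. When $C = cI$ this reduces to ordinary PCA with
eigenvalues scaled by $1/c$. Traits are z-scored by default
(`standardize_traits`) so that axes are not dominated by measurement
units; a raw-units analysis is available by skipping standardization.

`fit_pmm` fits $y = X\beta + b + e$, $b \sim N(0, \sigma_b^2\tilde C)$,
$e \sim N(0, \sigma_e^2 I)$, with $\tilde C$ scaled to maximum diagonal
1 so the two variance components are comparable. Estimation is ML with
the variance ratio $h = \sigma_b^2/(\sigma_b^2+\sigma_e^2)$ profiled on
[0, 1] after an eigendecomposition of $\tilde C$, so every fit is exact
and fast. Points that were genuinely open and how they were fixed:

* **ML, not REML, for model comparison.** Backward elimination compares
  fixed-effect structures by AIC, which is only valid under ML. However,
  ML underestimates $\sigma_b^2$ at species-level sample sizes, making
  Wald intervals anticonservative, so the dispersion entering
  `confint.pmm_fit` is re-estimated by REML — the standard mixed-model
  remedy. Simulation at n = 17 with a planted elevation slope gives
  ~92% empirical coverage for nominal 95% intervals.
* **The species-iid ("NP") random effect is confounded with the
  residual** when there is one observation per species, so that model
  collapses to OLS with a single variance (k = p + 1 in AIC). This is
  stated rather than hidden.
* **Random-effect choice** uses the boundary likelihood-ratio test with
  the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture,
  $p = \tfrac12 P(\chi^2_1 \ge LR)$, which equals 0.5 exactly at
  LR = 0; the phylogenetic model is chosen iff $p < 0.5$. The permissive
  cutoff retains any phylogenetic structure present; note that with 17
  species the power to detect even pure-Brownian signal is only ~85–90%,
  which is precisely why such a permissive cutoff is sensible at this
  scale. The strong-signal checks in the test suite therefore use
  50-species trees, where selection of the phylogenetic model is
  near-certain.
* **Backward elimination** starts from all interactions of elevation,
  precipitation and temperature, removes the term whose removal most
  lowers AIC while respecting marginality, and stops when nothing
  improves. AIC is permissive: on pure noise each candidate term
  survives with probability $P(\chi^2_1 > 2) \approx 0.16$, so the
  intercept-only model is the modal but not the dominant choice. That is
  a property of the criterion, not a defect of the search — and it is
  the reason the pipeline pairs selection with k-fold cross-validation
  (`kfold_cv`, k = 3 or 4) to flag overfit models. CV predicts held-out
  species by the conditional Brownian expectation given the training
  species under the phylogenetic model, and by fixed effects alone under
  OLS.
* `r2_lik` is $1 - \exp(-\tfrac2n(\ell_{full}-\ell_{reduced}))$; the
  total $R^2$ reduces to the intercept-only OLS model. `by_adjust`
  implements the Benjamini–Yekutieli step-up with
  $c(m) = \sum_{k\le m} 1/k$ as a generalized routine (unit $c(m)$
  reproduces Benjamini–Hochberg exactly); tests cross-check both against
  `p.adjust`.

## Brownian ancestral states and centroid biogeography

`bm_ancestral` returns the GLS/kriging reconstruction: root state
$\hat\mu = (1^\top C^{-1}1)^{-1}1^\top C^{-1}x$ and node states
$\hat\mu + c_k^\top C^{-1}(x - \hat\mu)$, which coincide with the
maximum-likelihood states under Brownian motion (the two-tip case gives
inverse-branch-length weighting). Variances are kriging variances with
the estimated-mean correction, scaled by the ML rate. Geographic
centroids are arithmetic means of occurrence records (south/west
negative); latitude and longitude are reconstructed as two independent
univariate Brownian characters. No spherical correction is applied: the
taxa occupy a small, connected region far from the antimeridian, where
plain averaging avoids discontinuity and periodicity issues. Misplaced
or misidentified records are handled by an exclusion flag column, not by
species-specific rules; coordinate deduplication is a flag, default off.

## DEC range evolution

Ranges are subsets of $A$ areas; the observable state space has
$2^A - 1$ states (127 at $A = 7$) plus an internal null range reached
when a single-area range goes extinct. Anagenetic rates: gain of area
$b$ by range $r$ at $d\,|r|$ (all source areas equally weighted, no
distance matrix), loss of any held area at $e$. Cladogenesis enumerates
ordered daughter pairs — sympatric duplication for single-area parents,
subset sympatry and single-area vicariance for wider parents, plus jump
events with weight $j$ ($j = 0$ is plain DEC) — normalized to
probabilities within the parent state. The likelihood is Felsenstein
pruning with matrix exponentials (`Matrix::expm`, a general dense Padé
routine; eigendecomposition-based exponentials are avoided because DEC
generators need not be diagonalizable with real eigenvalues) and a flat
root prior over non-null states, the common default where the original
analysis did not state its root treatment. Habitat matrices are first
reduced by `reduce_areas`, which iteratively drops areas occupied by a
single species that also holds another retained area — such
autapomorphic habitats are unlikely to have been ancestral — while never
leaving a species rangeless.

`fit_dec` maximizes over $(d, e[, j])$ on the log scale from several
seeded starts; DEC+J at $j = 0$ reproduces DEC to machine precision, and
AIC uses k = 2 or 3. A known limitation shared with all DEC
implementations: $e$ is weakly identified from extant ranges and is
often driven to the boundary at modest tree sizes, while $d$ is
recovered reliably (the tests assert rank-recovery of $d$ across a
planted grid rather than tight calibration of $e$).

`dec_stochastic_map` samples full range histories conditional on the
data: node states from conditional likelihoods, cladogenetic events from
their posterior weights, and branch paths endpoint-conditioned by
rejection sampling with a uniformization fallback (so short branches
with incompatible endpoints cannot stall). Each anagenetic gain of area
$b$ from range $r$ contributes $1/|r|$ to every (source → $b$) cell —
the event sums to one and the rule is symmetric across sources, since
multi-area attribution is not otherwise defined — and cladogenetic jumps
are attributed the same way. The forward simulator (`gen_ranges`) uses
exactly the same generator and cladogenesis weights and logs every
dispersal, so mapping accuracy is tested against forward-simulated
truth: aggregated over 20 data sets in a moderate-dispersal regime
(15 species, 4 areas, d = 0.2, e = 0.02 — chosen so count cells are
well populated), mapped means fall within ±30% of the true counts.

## The synthetic-data generators

All inputs are generated, never downloaded. The scenario defaults mirror
the study system: 17 species, crown height 5.6, elevations clamped to
[0, 3900] m after Brownian simulation (clamping, not reflection —
boundary values are biologically meaningful for coastal-desert and
high-Andean species), a temperature lapse of ~5.5 °C/km with small local
noise, one reticulation at γ = 0.254, seven habitats, and target-capture
panels of 500 loci with planted support regimes and exact-count
divergences (mutating exactly round(target·L) sites keeps the realized
p-distance within 0.5/L ≤ 0.01 of target deterministically).
`fixture_deuterocohnia()` packages a stylized 17-tip tree with the six
published clades in their published backbone order (F, then E, then D
sister to the remainder) and mid-range published elevations; its branch
lengths and within-clade resolutions are synthetic stand-ins, which is
why every quantitative test uses planted-truth generators rather than
the fixture's particulars. Trait panels mix elevation-driven,
temperature-driven and purely phylogenetic traits, emulating the
published vegetative/floral split.

Each generator derives its own substream from the master seed
(`substream_seed`, fixed offsets per generator), so adding a generator
never perturbs another's draws and every output is byte-identical under
a fixed seed. Ground truth (slopes, centroids, event logs) travels as
attributes and can be written to JSON sidecars (`write_scenario`);
downstream recovery tests read truth only from there.

What the generators do *not* emulate: sequence evolution along trees
(the divergence screen is pairwise, so a two-taxon substitution process
suffices), gene-tree estimation error, spatial sampling bias in
occurrences, and correlated trait residuals. Passing tests therefore
demonstrate correctness of the algorithms under their stated models, not
robustness to those real-data complications.

## Problem sizes and determinism

The test suite uses full-size checks where the statistics demand it
(50 000 coalescent replicates per closed-form comparison; 500
mixed-model recovery fits; 100 γ-recovery repetitions; 200 exhaustive
concordance oracles; 20 stochastic-mapping data sets) and small
parameterized cases elsewhere; the whole suite runs in a few minutes on
one CPU. Every stochastic computation takes an explicit seed, and the
acceptance script threads a single `--seed` through all of them.
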