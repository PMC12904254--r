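---
title: "Inferring and exploring fitness landscapes of coevolving protein interfaces"
author: "coevoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and exploring fitness landscapes of coevolving protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevoscape)
```

# The experiment this package models

In a library-on-library ("synthetic coevolution") selection, two protein
partners are randomized simultaneously at a handful of surface positions
and selected for binding *to each other* over several rounds. Deep
sequencing of each round yields, per round, read counts of chain-A/chain-B
sequence pairs. The reference design randomizes five positions on one
Z-domain (chain A) and six on another (chain B) with the five hydrophobic
amino acids M, F, L, I, V encoded by the degenerate codon DTS — a
theoretical nucleotide diversity of $6^{11} \approx 3.63\times10^8$ and a
protein diversity of $5^{11}$:

```{r diversity}
sch <- LibraryScheme(chainAPositions = c(8, 11, 14, 15, 45),
                     chainBPositions = c(29, 30, 33, 43, 44, 47),
                     degenerateCodon = "DTS")
theoreticalDiversity(sch)
```

`coevoscape` implements the computational side of such an experiment:
enrichment filtering and sequence-similarity networks, a generative model
of the selection (the *selection probabilistic model*, SPM) whose fitted
parameters define a sequence-to-fitness function, epistasis
decomposition of that function, adaptive-walk simulation to map the
energy-well geometry of the landscape, seed-sequence identification, and
inter-chain contact classification for solved complex structures. A
synthetic-data generator reproduces the generative process end to end so
every stage can be validated against a known ground truth.

# The selection probabilistic model

## Generative view of a multi-round selection

Let $q_0$ be the sequence-pair distribution entering selection and
$c_r(x)$ the read counts in round $r$ with total $T_r$. Each round
multiplies the previous distribution by a selection factor and
renormalizes, and reads are a multinomial sample:

$$q_r(x) \;\propto\; q_{r-1}(x)\,e^{f_{r\theta}(x)}, \qquad
  c_r \sim \mathrm{Multinomial}(T_r,\; q_r).$$

The round-$r$ fitness $f_{r\theta}$ is the log selection factor; energy
is negative fitness. We parametrize $f_{r\theta}(x) = a_r f_\theta(x) +
b_r$ with $a_r \ge 0$ (softplus): a shared neural trunk $f_\theta$ —
four fully connected hidden layers of 100 ReLU units on a one-hot
encoding — scaled per round. This affine coupling is the minimal
structure under which a *global* fitness $f_\theta$ is well defined
alongside the per-round fitnesses; it is a modelling choice of this
package, since only the existence of both is specified by the protocol
the model follows.

Two consequences of this form are worth documenting:

* **Collapse of the likelihood.** Propagating $q_r$ forward and
  normalizing shows $q_r = \mathrm{softmax}(\log q_0 + A_r f_\theta)$
  with $A_r = \sum_{s\le r} a_s$: the per-round offsets $b_r$ and the
  normalizers cancel. Only the cumulative slopes are identified by the
  data.
* **Gauge freedom.** Adding a constant to $f_\theta$ leaves every
  $q_r$ unchanged (this invariance is tested). We fix the gauge by
  centring: the reported global fitness is zero-mean over the observed
  universe, and $b_r = -a_r\,\bar f$ makes each per-round fitness
  zero-mean too. Absolute fitness values are therefore not comparable
  across datasets; differences and ranks are.

$q_0$ is the pseudocount-smoothed (default 0.5) empirical round-0
distribution. Training maximizes the multinomial log-likelihood of
rounds $1..R$ with Adam (learning rate 0.001, weight decay $10^{-5}$,
dropout 0.1, at most 500 epochs), hyperparameter defaults that follow
the reference protocol for this model family. Because the softmax
couples every sequence in a round, gradients are computed full-batch
whenever the observed universe fits within the configured batch size
(10,000) — always the case at the problem sizes this package targets;
dropout is implemented as per-unit masks resampled each epoch and
shared across the batch, the natural variant for full-batch training.
Early stopping monitors the log-loss of a 10% held-out split of
final-round sequences (patience 20, relative tolerance $10^{-6}$);
these stopping constants are choices of this package. Inference is
deterministic and extrapolates to the full combinatorial space, which
the trajectory stage requires.

A two-sequence dataset makes the estimator auditable by hand: with
round-0 counts (500, 500) and round-1 counts (900, 100), the
maximum-likelihood round-1 fitness difference is the binomial log-odds
ratio $\ln 9 \approx 2.197$, which the fitted model reproduces to
within 0.05 (see the test suite and acceptance script).

## What the synthetic generator does and does not emulate

`sampleLandscape()` draws a ground truth with Gaussian additive effects
(scale 1 by default), Gaussian pairwise effects (scale 0.5) on a random
30% of position pairs, half of them inter-chain — a moderately epistatic
landscape in which additive structure dominates, consistent with what
selection experiments of this kind typically infer.
`simulateSelection()` then applies a logistic selection link
$s_r(x) = \mathrm{logit}^{-1}(\sigma_r(f^*(x) - o_r))$ — chosen because
a selection *probability* must lie in $[0,1]$; the offset defaults to
the mean universe fitness so selection bites in the middle of the
fitness range — and samples multinomial reads at the stated depth
(default rounds: 5; default depth: $10^5$).

The generator reproduces the sampling noise and round-to-round dynamics
of a real selection, but deliberately not sequencing error, PCR bias,
or cell-growth dynamics. Passing recovery tests on synthetic data
therefore demonstrates correctness of the inference given the model
family, not robustness to those artefacts. The benchmark scale used
throughout tests and the acceptance script is a 6-position, 5-letter
scheme (15,625 sequences, 5 rounds, depth $10^5$), where the fitted
model's global fitness achieves Spearman rank correlation above 0.9
with the truth across seeds; full 11-position schemes are supported but
enumeration-heavy stages then work on reduced or observed universes.

# Epistasis decomposition

`decomposeFitness()` performs a functional-ANOVA decomposition under
the uniform reference distribution over the alphabet (the orthogonal
contrast system that underlies the Walsh–Hadamard view of discrete
landscapes):

$$\beta_0 = \mathbb E[f], \quad
  \beta_i(a) = \mathbb E[f \mid x_i = a] - \beta_0, \quad
  \beta_{ij}(a,b) = \mathbb E[f \mid x_i = a, x_j = b] - \beta_i(a) -
  \beta_j(b) - \beta_0,$$

with Möbius subtraction continuing at order 3. Effect sizes are
zero-mean over every coordinate, the decomposition reconstructs $f$
exactly at full order, and a term's **importance** is the
max-minus-min of its effect sizes over letter configurations — the
maximal dynamic range attributable to those positions (a
partial-dependence-style importance for categorical variables, and the
convention used for all summaries here). The **REI** at a given order
is the mean importance per inter-chain term divided by the mean per
intra-chain term; it is reported as undefined (0/0) on additive
landscapes.

Conditional means are computed exhaustively up to $10^6$ enumerated
sequences and by Monte Carlo ($10^5$ uniform draws, seeded) beyond;
MC estimates converge to the exhaustive values at the usual
$1/\sqrt{n}$ rate (tested). A uniform reference is the default because
the importance should describe the landscape, not the library
composition; a frequency-weighted variant would answer a different
question and is intentionally not the default. External scorers (for
example structure-conditioned sequence models) plug in through
`epistasisFromScores()`, which demands full coverage of the enumerated
subspace rather than silently imputing gaps.

```{r xor}
schAB <- LibraryScheme(1, 2, alphabet = c("A", "B"))
xor <- function(s) as.numeric(substr(s, 1, 1) == substr(s, 2, 2))
epistasisTerms(decomposeFitness(xor, schAB, maxOrder = 2))
```

# Trajectories, wells, and their statistics

`simulateTrajectories()` runs greedy stochastic adaptive walks: from a
uniform-random start, repeatedly list all single-position substitutions
that *strictly* increase fitness, pick one uniformly, stop at a strict
local optimum. Equal-fitness moves are not improving moves — with a
continuous fitness ties have measure zero, but quantized external
scorers can produce them, and treating ties as moves would allow
non-terminating walks. The **accessibility** of a sequence is the
fraction of walks terminating there. The reference protocol simulates
$10^7$ walks; desk-scale analyses here use $10^4$–$10^5$, which the
protocol itself reports as sufficient for stable conclusions, and the
sub-sampling consistency of accessibility is tested. Walks are
vectorized over cohorts (default 200,000) so memory stays flat, and a
fixed seed gives bit-identical ensembles.

`findWells()` ranks terminals by accessibility (top 20 by default, per
the reference protocol) and attaches energies ($E = -f$) and relative
energies (zero at the strongest binder found). `wellDepth()` defines
the depth of a well as the minimal *cumulative* uphill energy needed to
reach any other top-well representative: on the single-substitution
move graph with edge weight $\max(0, E(v) - E(u))$, a Dijkstra
shortest path — "cumulative" rules out the max-single-step barrier
convention, which remains available (`barrier = "max"`) for
sensitivity analysis. Depth is $+\infty$ when only one well exists.

Statistical comparison of two landscape geometries follows the
bootstrap recipe: resample read counts (`bootstrapDatasets()`, totals
preserved), refit the SPM, re-simulate walks, recompute wells
(`bootstrapGeometry()`), then test with one-sided Mann–Whitney U
whether, e.g., the natural interface's top-well depth exceeds 3 times
the synthetic interface's deepest top-well depth and its top
accessibility exceeds 5 times the synthetic one
(`compareGeometries()`, factors 3 and 5 by default). The replicates
are treated as unpaired — the U test is inherently unpaired, and the
protocol does not state a pairing. Affinity measurements convert to
the same energy scale via $\Delta\Delta G = RT\ln(K_{D,2}/K_{D,1})$:

```{r kd}
energyGapFromKd(0.4e-6, 8.8e-6)   # synthetic-interface gap, kcal/mol
energyGapFromKd(2.4e-9, 6.7e-6)   # natural-interface gap
```

# Seed sequences and paths

A *seed* is a weak binder that funnels evolution into one well:
fitness inside a weak-binding band, **exclusivity** (fraction of
trajectories through it that end at the target well) at least 0.9,
**contribution** (fraction of the well's arrivals passing through it)
at least 0.01, and at least 3 substitutions from the well
representative — all reference-protocol thresholds. The band is
defined by the data, as the mean global fitness of final-round
sequences with read counts 5 and 20; on datasets where an anchor count
is absent the nearest observed count is used, so the rule remains
data-driven rather than hard-coded to any particular dataset's values.
The protocol conflates "most likely well" (most frequent terminal
among targets) with the exclusivity-maximizing well; `findSeeds()`
assigns by the former and flags candidates for which the two differ.

`extractPaths()` re-simulates a dedicated ensemble started at the seed
— exact for the seed's downstream behaviour and far cheaper than
archiving $10^7$ global paths — and tabulates the distinct
monotone-fitness paths to the target with multiplicities, folding the
largest set of least-visited paths whose collective weight stays below
15% into a single minor fraction.

# Enrichment and networks

`pairEnrichment()` scores every observed chain-A/chain-B pair with the
one-sided hypergeometric survival probability $P(X \ge k)$ given the
pair count $k$, marginal counts $n$ and $N$, and population size $M$
(exact, via R's `phyper`); `filterEnriched()` keeps pairs with
$p < 0.05$ and $k \ge 20$ — strictly below for the p-value, inclusive
for the count, exactly as the protocol states them, with no multiple-
testing correction by default (a BH option exists). Because published
summaries are ambiguous about whether "enriched sequences" counts
pairs or unique concatenated sequences, the summary attribute reports
both. `buildSSN()` joins concatenated sequences at Hamming distance
strictly below 3 (fixed-length position strings make insertions and
deletions meaningless, so edit distance reduces to Hamming distance);
`detectCommunities()` clusters by seeded greedy modularity (Louvain;
Leiden optional) and contracts communities into a community map whose
edge weights count inter-community edges; `pairingMatrix()`
cross-tabulates enriched pairs by community — the numbers behind a
chord diagram, which this package does not draw.

# Structure contacts

`interChainContacts()` lists heavy-atom pairs across two chains closer
than 4.0 Å (first model, altloc blank/A, no waters or ligands; the
3.8 Å residue-level convention is available via the cutoff argument),
and `classifyContacts()` labels each contact LL, LF or FF according to
whether the residues sit at randomized (library) or constant
(framework) positions, reporting the contact ratio LL/(LF$_A$+LF$_B$)
at atomic and residue level. Published average ratios for this system
(0.61 synthetic; 0.22 and 0.33 for two natural libraries) depend on
the deposited structures and are reference points, not quantities this
package can recompute without them.

# Numerical choices and limitations

* Sequence spaces are enumerated (indices in base-$|$alphabet$|$);
  walks, Dijkstra and exhaustive ANOVA work on the enumeration. The
  practical ceiling is a few million sequences; the full $5^{11}$ space
  is enumerable for scoring but the geometry stages are intended for
  reduced schemes.
* All stochastic entry points take an integer seed, restore the
  caller's RNG state, and derive per-stage/per-replicate seeds
  deterministically from a master seed (`runPipeline()`), so a rerun
  with the same configuration is bit-identical.
* The SPM's absolute fitness scale is gauge- and dataset-dependent; no
  attempt is made to reproduce published absolute fitness values, only
  relations among them.
* `fitSPM()` requires at least two rounds (selection is unidentifiable
  from one), warns on constant counts (near-flat fitness), and treats
  unobserved sequences as inference-time extrapolation only — they do
  not enter the training normalizer.
* Hypergeometric p-values, community detection, Dijkstra, Mann–Whitney
  tests and structure parsing are delegated to `stats`, `igraph` and
  `bio3d`; the inference machinery specific to this package (SPM,
  ANOVA decomposition, walks, geometry, seeds) is implemented here and
  cross-checked against independent oracles in the test suite.

# End-to-end example

```{r pipeline, eval = FALSE}
cfg <- pipelineConfig(
  scheme = LibraryScheme(1:3, 4:6, alphabet = c("F", "I", "L", "M", "V")),
  simulate = list(nRounds = 5, depth = 1e5),
  nTrajectories = 1e5, masterSeed = 1L)
res <- runPipeline(cfg, "coevo-run")
res$geometry
```

The run directory contains flat TSV/JSON stage outputs (counts,
enrichment table, SPM scores and serialized model, epistasis tables,
trajectory summary, wells and barriers, seeds) plus a manifest with
per-stage seeds and output hashes.
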