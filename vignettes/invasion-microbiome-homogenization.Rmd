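---
title: "Quantifying gut-microbiome shift and homogenization during invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gut-microbiome shift and homogenization during invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invashift)
```

## The question

When a species colonizes a new range, its gut microbiome can respond in
several qualitatively different ways: the microbiome of each individual can
become more or less diverse; the dissimilarity *between* individuals of the
same population can shrink (homogenization) or grow (differentiation); and,
when two related invaders co-occur, their microbiomes can converge or
diverge. `invashift` implements a complete analysis chain for distinguishing
these trajectories from amplicon (ASV) count tables of hosts sampled in
their native and invaded ranges — the motivating system being two sibling
herbivorous rabbitfishes that entered the Mediterranean through the Suez
Canal — together with a synthetic-data generator that plants each trajectory
so that every stage of the chain can be validated against ground truth.

## Diversity model: Hill numbers

All diversity quantities use the Hill-number framework, so taxonomic and
phylogenetic, presence-based and abundance-based indices live on one scale
(effective numbers). For a relative-abundance vector $p$:

$$ {}^qD = \Big(\sum_{i:\,p_i>0} p_i^q\Big)^{1/(1-q)}, \qquad
   {}^1D = \exp\Big(-\sum_i p_i \ln p_i\Big), $$

with $q = 0$ counting taxa and $q = 1$ weighting them by abundance. The
$q = 1$ case is always computed by its closed-form limit, never by a
numerical approach to $q \to 1$.

Phylogenetic diversity replaces taxa by tree branches: each branch $b$ with
length $L_b$ and descendant relative abundance $a_b$ is a "lineage" weighted
by $L_b/T$, where $T = \sum_b L_b a_b$ is the abundance-weighted mean depth.
On a star tree with equal branch lengths this reduces exactly to the
taxonomic formula, which is one of the package's invariant tests.

### Pairwise dissimilarity

For a pair of communities, gamma diversity is the Hill number of the
equal-weight pooled community, alpha is the corresponding equal-weight
two-community alpha, and $\beta = \gamma/\alpha \in [1, 2]$. The reported
dissimilarity is the Sørensen-type local overlap complement $1 - C_{qN}$
with $N = 2$: it equals the classic Sørensen dissimilarity at $q = 0$ and
$\ln\beta/\ln 2$ at $q = 1$. The framework offers several normalizations and
the source study does not name the one it used, so the Jaccard-type
$1 - U_{qN}$ is exposed as `variant = "jaccard"`; all defaults use the
Sørensen form because it reduces to the presence-absence Sørensen index that
"compositional dissimilarity" conventionally denotes. Pooling weights are
always $(1/2, 1/2)$ since inputs are relative abundances.

For the phylogenetic facet, the pair's tree is conceptually pruned to the
union support and $T$ recomputed per pair. Numerically no pruning is
needed: branches with zero pooled abundance carry no weight, and branches
with pooled abundance exactly 1 (the stem above the ancestor of the pair's
support) are excluded, which is algebraically identical to pruning on an
ultrametric tree. A fixed-$T$ mode (`fixed_T`) is available for users who
prefer a tree-wide normalization.

## Ordination and permutation tests

`permanova()` implements the McArdle–Anderson trace formulation directly on
the Gower-centered matrix $G$ of $-d^2/2$, with *sequential* (Type-I) sums
of squares via hat-matrix projections of the cumulative model, so the
default term order `region, season, region:season` tests the interaction
after its main effects. Permutation p-values use free relabelling with the
add-one convention $p = (1 + \#\{F^* \ge F\})/(1 + m)$, so $p$ is never 0;
for $n \le 9$ an exhaustive mode enumerates all $n!$ relabellings and
reports the exact p. The implementation is cross-checked in the test suite
against `vegan::adonis2` (agreement to $10^{-10}$ on sums of squares, F and
$R^2$) and, on univariate Euclidean data, against the classical one-way
ANOVA F.

`permdisp()` embeds the dissimilarity matrix by PCoA keeping
negative-eigenvalue axes, and computes each sample's distance to its group
center with Anderson's imaginary-axis correction
$\sqrt{\max(0, \Delta^2_{pos} - \Delta^2_{neg})}$. The default center is the
**centroid**; the reference implementation (`vegan::betadisper`) defaults to
the spatial median, and that option is provided (`center =
"spatial_median"`, fitted by a Weiszfeld-type iteration under the corrected
metric). The centroid default was chosen because group mean dispersions then
have a closed geometric meaning that the scaling tests exploit (a group
scaled by 2 around its centroid yields exactly a dispersion ratio of 2); the
tests verify equality with `betadisper(type = "centroid")`. The permutation
p permutes the distances-to-center across samples.

## Core microbiome: Poisson abundance–occupancy null

For feature $i$ with total count $N_i$ over $n$ samples, a neutral Poisson
model with per-sample rate $\lambda_i = N_i/n$ predicts expected occupancy

$$ E[O_i] = n\,(1 - e^{-\lambda_i}). $$

The default decision rule calls a feature core when its observed occupancy
is at or above this expectation (and at least `min_occupancy = 1`). The
underlying published algorithm's exact rule is not fully specified by its
description; "at or above expectation" is the minimal reading of comparing
the observed abundance–occurrence distribution with the stochastic Poisson
null, and a stochastic-envelope mode (`mode = "envelope"`, comparing $O_i$
with the lower $\alpha$-quantile of the simulated null occupancy) is
provided for sensitivity analysis. The envelope simulation uses the exact
equivalence "occupancy of $n$ Poisson($\lambda$) draws $\sim$
Binomial($n$, $1 - e^{-\lambda}$)". Because the null assumes comparable
sampling effort, rarefied or equal-depth input is recommended (documented,
not enforced).

Unequal group sizes are handled by the bootstrap: `bootstrap_core()` draws
`n_boot` hosts without replacement `B = 1000` times (the defaults mirror
the motivating study's 1000 iterations and per-species minima of 32 and 9
hosts), and the consensus core is the union over species × region groups of
features called core in more than 80% of iterations.

A caveat the tests make explicit: in very homogeneous groups (high Dirichlet
concentration) many moderately abundant taxa are consistently present and
therefore sit at or above the Poisson expectation, so the consensus over
*all* groups is intentionally inclusive. The planted-core recovery test
evaluates sensitivity and false-positive rate on a single native-range group
of 30 hosts, where the method's discrimination is meaningful.

## Differential abundance

Two routes are provided per taxonomic rank and for KO tables: one-way ANOVA
on centered log-ratio (CLR) transformed counts, and Kruskal–Wallis on
relative abundances with Benjamini–Hochberg adjustment across the features
of one rank. Zero handling for the CLR uses a pseudocount of 0.5 added to
all counts (the source analysis does not state its zero treatment;
0.5 is a common default and is configurable). The FDR family is all
features within one rank and one feature kind; both raw and adjusted
significance flags are always emitted because published summaries mix both
conventions. Features with zero variance are flagged degenerate with
$p = 1$ rather than erroring.

## Homogenization and trajectory classification

For a chosen context (within-species within-region, within-species
between-regions, between-species within-region) the package extracts all
relevant pairwise dissimilarities and summarizes the change from a reference
(native) region to a comparison region as

$$ \%\Delta = 100\,\frac{\bar d_{ref} - \bar d_{cmp}}{\bar d_{ref}}, $$

averaged (mean ± SD) across the index configuration set. The default set
crosses $q \in \{0, 1\}$ with taxonomic dissimilarity at Phylum, Family and
ASV rank plus phylogenetic dissimilarity at ASV rank — 8 configurations.
Phylogenetic dissimilarity at collapsed ranks is omitted by default because
it requires a rank-level tree, which cannot be derived from a taxonomy
table alone; a user who has one can pass it and extend the grid. The
per-configuration table is always emitted so any subset can be re-averaged.

Significance between two sets of pairwise values uses Kruskal–Wallis or
Wilcoxon rank tests, as in the motivating analysis. Pairwise
dissimilarities that share samples are not independent; the test output
carries this caveat and no correction is invented. For the same reason the
generator's null-scenario test checks the *sign balance* of dispersion
differences across replicates rather than the nominal size of the rank test,
which is anticonservative under this pseudoreplication.

The trajectory classifier turns these comparisons into labels per species
(homogenization / differentiation / no_change from the within-region
dispersion change; shifted / no_shift from between- vs within-region means)
and an interspecific label, with the modal verdict across configurations
reported when several are supplied. Ties resolve to `no_change`.

## SCFA functional groups

KO tables restricted to short-chain fatty-acid groups are analysed "like
taxonomic diversity": each group's subset table is **re-closed** to relative
abundance (each SCFA group is its own composition; re-closure after
subsetting is enforced and tested), then fed to the same Hill/PERMANOVA/
PERMDISP/homogenization machinery. Because the actual KO membership lists
are study-specific and not published, the default mapping is an explicitly
synthetic placeholder that slices the KO universe into groups of the
conventional cardinalities (formate 25, acetate 17, propionate 13, butyrate
17, valerate 14); real analyses should supply their own mapping via a TSV or
YAML file.

## The synthetic-data generator

`simulate_dataset()` draws, for each host, a composition from a
Dirichlet–multinomial model: group mean profile $\pi_g$ (log-normal
baseline, sd 1.5 on the log scale, giving realistic rank-abundance curves)
and concentration $\theta_g$, then counts from
Multinomial(depth, composition). The design choices:

* **Dispersion axis.** $\theta_g$ is the homogenization dial: higher
  $\theta$ means more similar hosts. Defaults
  ($\theta = 30, 80, 200$ for native, near-invaded, far-invaded) plant the
  increasing-homogenization gradient for both species. Microbiome fits of
  Dirichlet–multinomial concentrations commonly land in the tens-to-hundreds
  range, so these are realistic magnitudes.
* **Core block.** A planted core (10% of features sharing half the
  profile mass evenly) is modelled as consistent colonizers: core features
  form their own Dirichlet block with concentration multiplied by
  `core_evenness = 8`, keeping their occupancy near 1 in every group while
  non-core features carry the group's dispersion. Block weights come from
  the group profile, so the expected composition is exactly $\pi_g$.
* **Regional shifts.** 30% of non-core features receive a planted
  log-fold change (magnitude 1.5, random sign, scaling with distance along
  the region gradient), giving the differential-abundance and PERMANOVA
  stages something to detect. Seasons add a small log-fold effect (0.3) to
  10% of features so the `region:season` interaction is testable.
* **Sampling design.** Default group sizes (21 and 5 hosts per
  region × season for the two species) echo a design with many hosts of a
  common invader and few of a rarer one; sequencing depth is normal
  (mean 6000, sd 1500), so the default rarefaction depth of 2000 rarely
  drops samples.
* **Derived KO table.** A fixed sparse linear map (density 0.05, gamma
  weights) of the taxon counts, rounded. It stands for gene-content
  inference output structurally (non-negative, linear in the taxa) with no
  attempt to mimic real KEGG content.
* **Tree and taxonomy.** A pure-birth tree rescaled to unit height over
  the features, and random nested Phylum/Family labels with a skewed
  size distribution (a few dominant phyla and a tail of small ones, so
  presence-absence composition still varies at coarse ranks) and a 15%
  unassigned slice below phylum.

What the generator does **not** emulate: real sequences or chimeras,
taxonomy errors, spatial/site structure within regions, depth-composition
interactions, phylogenetic signal in the planted effects (shifted features
are random with respect to the tree), or realistic KO pathway structure.
Passing tests therefore demonstrate correctness of the estimators and tests
under a controlled model of dispersion, shift and core structure — not
robustness to every artefact of real amplicon data.

`expected_dispersion()` is the parameter-recovery oracle: a Monte-Carlo
estimate (with standard error) of the expected within-group $q = 1$
taxonomic dissimilarity implied by a scenario. The recovery tests plant
dispersion reductions of roughly 25%, 50% and 75% (invaded-range
$\theta = 52, 110, 380$ against native 30, calibrated once against the
oracle), simulate 20 replicate datasets of 30 hosts per region at depth
2000, and require the recovered percent homogenization to sit within ±10
percentage points of the oracle.

## Numerical choices and degenerate inputs

* Permutation p-values use the add-one floor and a fixed seed everywhere;
  sub-stream seeds are derived deterministically so pipeline stages can be
  re-run in isolation.
* Dissimilarities are clamped to $[0, 1]$ against floating-point drift;
  identical pairs return exactly 0.
* Rarefaction is a single multivariate-hypergeometric draw per sample
  (sampling without replacement); under-depth samples are dropped and
  listed, not padded.
* Aggregation keys "unassigned" labels on the full upstream lineage so
  distinct unassigned clades are not merged.
* All-zero samples, singleton groups, aliased model terms, features missing
  from taxonomy or tree, and empty KO intersections raise errors that name
  the offending ids or terms; zero-variance features in differential
  abundance are flagged rather than fatal.
* PCoA retains negative eigenvalues and reports them; coordinates are
  returned for positive axes, and PERMDISP consumes both sets.

## Problem sizes

The test suite and the acceptance script run on deliberately small
instances — 40–150 features, 4–30 hosts per group, depths of 2000–6000,
200–1000 bootstrap/permutation iterations — chosen so the whole suite
completes in a few minutes while keeping every Monte-Carlo comparison
inside its stated tolerance. All sizes are parameters; nothing in the
implementation depends on them.

## Known limitations

* The Poisson occupancy null treats counts as comparable across samples;
  with strongly unequal depths its expectation is biased (rarefy first).
* The consensus core is permissive in highly homogeneous groups (see
  above); interpret the union across regions accordingly.
* Rank tests on pairwise dissimilarities inherit pseudoreplication; their
  p-values are indicative, as in the motivating analysis.
* Phylogenetic dissimilarity at collapsed taxonomic ranks requires a
  user-supplied rank-level tree.
* The KO mapping shipped by default is synthetic; functional conclusions
  require a curated KO list.
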