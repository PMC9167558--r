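# invashift

Analysis of host gut-microbiome **shift and homogenization during
biological invasion**, from amplicon (16S ASV) count tables of hosts
sampled in their native and invaded ranges.

When an invasive species establishes in a new region its gut microbiome can
change along several axes at once: individual (alpha) diversity can rise or
fall, the dissimilarity *between* conspecific individuals can shrink
(**intraspecific homogenization**) or grow (differentiation), and the
microbiomes of two co-invading species can converge (**interspecific
homogenization**). `invashift` implements the full analysis chain needed to
distinguish these trajectories — motivated by the invasion of the
Mediterranean by two sibling herbivorous rabbitfishes — and ships a
synthetic-data generator that plants every trajectory so each stage can be
validated against ground truth.

## What it computes

* **Table handling** — TSV/BIOM ASV and KO tables, taxonomy, metadata,
  Newick trees; prevalence filtering (drop features present in ≤ 3
  samples), taxonomy-label exclusion (chloroplasts, mitochondria), seeded
  rarefaction (default depth 2000), closure to relative abundance, and
  aggregation to Phylum/Family/ASV rank.
* **Hill-number diversity** — alpha and pairwise beta, taxonomic and
  phylogenetic, any order `q ≥ 0` with `q = 0` (richness-like) and `q = 1`
  (entropy-like) as the working pair:
  `qD = (Σ p_i^q)^{1/(1−q)}`, `1D = exp(−Σ p_i ln p_i)`; phylogenetic
  variants weight tree branches by `L_b/T` with `T = Σ L_b a_b`. Pairwise
  dissimilarity is the Sørensen-type local overlap complement `1 − C_qN`
  (classic Sørensen at `q = 0`, `ln β / ln 2` at `q = 1`; Jaccard-type
  available).
* **Ordination & tests** — PCoA with negative-eigenvalue reporting;
  PERMANOVA (McArdle–Anderson trace form, sequential sums of squares,
  `region, season, region:season`), pairwise PERMANOVA with FDR, and
  PERMDISP with Anderson's negative-axis correction; exact enumeration for
  tiny designs; everything seeded.
* **Core microbiome** — the Poisson abundance–occupancy null
  `E[O_i] = n (1 − e^{−λ_i})`, `λ_i = N_i/n`: features whose observed
  occupancy meets the neutral expectation, made robust to unequal group
  sizes by a bootstrap (1000 draws of fixed size, consensus at > 80%)
  and unioned across species × region groups.
* **Differential abundance** — one-way ANOVA on centered log-ratio
  transformed counts and Kruskal–Wallis on relative abundances with
  Benjamini–Hochberg correction, per rank and for KO tables.
* **Homogenization** — within/between-species pairwise-dissimilarity sets,
  percent change `100 (d̄_ref − d̄_cmp)/d̄_ref` summarized mean ± SD across
  index configurations, rank tests, and a trajectory classifier
  (homogenization / differentiation / no_change per species, plus the
  interspecific verdict).
* **SCFA functional groups** — the same beta machinery applied to KO
  tables restricted to short-chain fatty-acid groups (formate, acetate,
  propionate, butyrate, valerate, all), re-closed per group.
* **Pipeline** — `run_pipeline()` drives all stages from one (YAML)
  config with a seed, writing TSV artifacts and a checksummed manifest.

## Worked example

```r
library(invashift)

scenario <- synthetic_scenario(
  n_features  = 120,
  n_per_group = c(S_rivulatus = 10, S_luridus = 6),
  regions     = c("RedSea", "Levantine", "Crete"),  # native first
  seed        = 42)
sim    <- simulate_dataset(scenario)
counts <- filter_features(sim$counts, sim$taxonomy, min_samples = 3)

# abundance-weighted phylogenetic dissimilarity between all hosts
d   <- hill_dissimilarity(counts, q = 1, facet = "phylogenetic",
                          tree = sim$tree)
riv  <- sim$meta$sample_id[sim$meta$host_species == "S_rivulatus"]
meta <- sim$meta[match(riv, sim$meta$sample_id), ]

permanova(d[riv, riv], meta,
          terms = c("region", "season", "region:season"),
          n_perm = 999, seed = 1)
#>            term Df SumOfSqs     R2     F     p
#> 1        region  2  0.02211 0.2867 11.72 0.001
#> 2        season  1  0.00183 0.0237  1.94 0.094
#> 3 region:season  2  0.00225 0.0292  1.19 0.278
#> 4      Residual 54  0.05093 0.6604    NA    NA
#> 5         Total 59  0.07713 1.0000    NA    NA

permdisp(d[riv, riv], meta$region, n_perm = 999, seed = 2)
#> PERMDISP (centroid): F = 125.8 on 2, 57 df; permutation p = 0.001 (999 perms)
#> group mean dispersions:
#>     Crete Levantine    RedSea
#>    0.0127    0.0237    0.0437

percent_homogenization(d, sim$meta, "intraspecific_within_region",
                       "S_rivulatus", "RedSea", "Crete")$mean_percent
#> [1] 71.02096

classify_trajectory(d, sim$meta, c("S_rivulatus", "S_luridus"),
                    "RedSea", "Crete")
#> Trajectory classification (alpha = 0.05 )
#>   S_rivulatus: homogenization
#>   S_luridus: homogenization
#>   interspecific: homogenization
#>   scenario: homogenization within and between species
```

Reading the output: the region factor explains ~29% of the variance in
microbiome structure (PERMANOVA `R²`), with an F-value six times that of
season; PERMDISP shows inter-individual dispersion dropping from the native
region (0.044) to the far invaded region (0.013) — a 71% homogenization —
and the trajectory classifier labels the planted scenario correctly:
homogenization both within and between species.

## Package layout

```
R/                      implementation (tables, simulate, hill, ordination,
                        core, diffabund, homogenization, scfa, pipeline)
tests/testthat/         unit, property and acceptance tests
scripts/acceptance.R    end-to-end reproduction script
vignettes/              methods vignette: models, assumptions, design choices
```
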