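# shared fixture builders; everything is generated in code at test time

tiny_counts <- function() {
  count_table(matrix(c(5, 2, 0,
                       0, 3, 7),
                     nrow = 3,
                     dimnames = list(c("s1", "s2", "s3"), c("f1", "f2"))))
}

random_counts <- function(n_samples, n_features, seed = 1, max_count = 50) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_features, lambda = max_count / 5),
                n_samples, n_features,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                sprintf("f%03d", seq_len(n_features))))
    m[1, 1] <- m[1, 1] + 1  # guard against an all-zero table
    count_table(m)
  })
}

toy_taxonomy <- function(feature_ids, phylum = NULL, family = NULL,
                         class = NULL) {
  n <- length(feature_ids)
  data.frame(feature_id = feature_ids,
             Domain = rep("Bacteria", n),
             Phylum = phylum %||% rep("PhylumA", n),
             Class = class %||% rep("unassigned", n),
             Order = rep("unassigned", n),
             Family = family %||% rep("FamA", n),
             Genus = rep("unassigned", n),
             Species = rep("unassigned", n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# star tree with unit branch lengths over the given labels
star_tree <- function(labels) {
  tr <- ape::stree(length(labels), type = "star")
  tr$tip.label <- labels
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# random relative-abundance vector (some structural zeros)
random_relabund <- function(k, zero_frac = 0.2) {
  x <- rgamma(k, shape = 0.8)
  x[runif(k) < zero_frac] <- 0
  if (sum(x) == 0) x[1] <- 1
  x / sum(x)
}

# metadata for a block of fish samples
fish_meta <- function(ids, species, region, season = "spring") {
  data.frame(sample_id = ids, compartment = "fish", host_species = species,
             region = region, season = season, site = "siteA",
             stringsAsFactors = FALSE)
}

# small two-species / two-region simulation used by several modules
small_sim <- function(seed = 7, n_features = 80, n1 = 6, n2 = 4, ...) {
  sc <- synthetic_scenario(n_features = n_features,
                           n_per_group = c(S_rivulatus = n1, S_luridus = n2),
                           seed = seed, ...)
  simulate_dataset(sc)
}

# classical one-way ANOVA F computed from first principles (independent of
# both stats::aov and the package), used as a permutation-test oracle
oneway_F_direct <- function(x, g) {
  g <- as.factor(g)
  n <- length(x)
  k <- nlevels(g)
  gm <- tapply(x, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (gm - mean(x))^2)
  ssw <- sum((x - gm[as.integer(g)])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}
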