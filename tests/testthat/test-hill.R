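test_that("taxonomic Hill numbers match their closed forms", {
  expect_identical(hill_alpha(c(0.5, 0.5), 0), 2)
  expect_equal(hill_alpha(c(0.5, 0.5), 1), 2)
  expect_equal(hill_alpha(c(0.8, 0.2), 1),
               exp(-0.8 * log(0.8) - 0.2 * log(0.2)))
  expect_equal(hill_alpha(c(0.8, 0.2), 2), 1 / (0.8^2 + 0.2^2))
  expect_error(hill_alpha(c(0.5, 0.4), 1), "sum to 1")
  expect_error(hill_alpha(c(0.5, 0.5), -1), "q must")
})

test_that("Hill alpha is non-increasing in q", {
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- random_relabund(12)
      vals <- vapply(c(0, 0.5, 1, 2, 4), function(q) hill_alpha(p, q),
                     numeric(1))
      expect_true(all(diff(vals) <= 1e-10))
    }
  })
})

test_that("phylogenetic Hill alpha reduces to taxonomic on star trees", {
  withr::with_seed(17, {
    for (i in 1:20) {
      k <- sample(3:10, 1)
      labs <- paste0("t", seq_len(k))
      p <- setNames(random_relabund(k, zero_frac = 0.3), labs)
      tr <- star_tree(labs)
      for (q in c(0, 1, 2)) {
        expect_equal(hill_phylo_alpha(p, tr, q), hill_alpha(p, q),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("phylogenetic Hill alpha matches hand branch enumeration", {
  # ((A:1,B:1):1,C:2); p = (0.5, 0.3, 0.2)
  # branches: A (L=1,a=.5), B (1,.3), AB (1,.8), C (2,.2); T = 2
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  p <- c(A = 0.5, B = 0.3, C = 0.2)
  Tq <- 0.5 + 0.3 + 0.8 + 2 * 0.2
  expect_equal(Tq, 2)
  expect_equal(hill_phylo_alpha(p, tr, 0), (1 + 1 + 1 + 2) / Tq)
  h1 <- exp(-((1 / Tq) * (0.5 * log(0.5) + 0.3 * log(0.3) + 0.8 * log(0.8)) +
                (2 / Tq) * 0.2 * log(0.2)))
  expect_equal(hill_phylo_alpha(p, tr, 1), h1)
  h2 <- ((1 / Tq) * (0.5^2 + 0.3^2 + 0.8^2) + (2 / Tq) * 0.2^2)^(1 / (1 - 2))
  expect_equal(hill_phylo_alpha(p, tr, 2), h2)
  # single taxon on any tree -> 1 lineage
  expect_equal(hill_phylo_alpha(c(A = 1, B = 0, C = 0), tr, 1), 1)
  expect_error(hill_phylo_alpha(c(A = 0.5, Z = 0.5), tr, 1), "Z")
})

test_that("pairwise beta hits the Sorensen / Jaccard set-theoretic cases", {
  # supports {A,B} vs {B,C}, equal abundances
  p1 <- c(A = 0.5, B = 0.5, C = 0)
  p2 <- c(A = 0, B = 0.5, C = 0.5)
  expect_equal(hill_beta_pair(p1, p2, 0), 0.5)                 # Sorensen
  expect_equal(hill_beta_pair(p1, p2, 0, variant = "jaccard"), 2 / 3)
  for (q in c(0, 0.5, 1, 2)) {
    expect_equal(hill_beta_pair(p1, p1, q), 0)
  }
  d1 <- c(A = 0.6, B = 0.4, C = 0, D = 0)
  d2 <- c(A = 0, B = 0, C = 0.3, D = 0.7)
  for (q in c(0, 1)) {
    expect_equal(hill_beta_pair(d1, d2, q), 1)
    expect_equal(hill_beta_pair(d1, d2, q, variant = "jaccard"), 1)
  }
  expect_error(hill_beta_pair(c(0.5, 0.5), c(0.2, 0.3, 0.5), 1), "feature space")
})

test_that("q = 1 is the continuous limit of the general-q formula", {
  withr::with_seed(23, {
    for (i in 1:10) {
      p1 <- random_relabund(15)
      p2 <- random_relabund(15)
      expect_lt(abs(hill_beta_pair(p1, p2, 0.999) -
                      hill_beta_pair(p1, p2, 1)), 1e-3)
      expect_lt(abs(hill_alpha(p1, 0.999) - hill_alpha(p1, 1)),
                1e-3 * hill_alpha(p1, 1))
    }
  })
})

test_that("dissimilarity matrices equal elementwise pair computation", {
  sim <- small_sim(seed = 5, n_features = 40, n1 = 3, n2 = 2)
  rel <- to_relative(sim$counts)[1:8, ]
  rel <- rel[, colSums(rel) > 0]
  rel <- rel / rowSums(rel)
  for (q in c(0, 1)) {
    D <- dissimilarity_matrix(rel, q)
    expect_true(isSymmetric(D))
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(unname(diag(D)), rep(0, nrow(D)))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(D[i, j], hill_beta_pair(rel[i, ], rel[j, ], q))
    }
  }
})

test_that("q = 0 taxonomic dissimilarity equals set-arithmetic Sorensen", {
  sim <- small_sim(seed = 13, n_features = 30, n1 = 3, n2 = 2)
  rel <- to_relative(sim$counts)[1:6, ]
  D <- dissimilarity_matrix(rel, 0)
  pres <- rel > 0
  for (i in 1:5) for (j in (i + 1):6) {
    a <- sum(pres[i, ] & pres[j, ])
    s1 <- sum(pres[i, ])
    s2 <- sum(pres[j, ])
    expect_equal(D[i, j], 1 - 2 * a / (s1 + s2))
  }
})

test_that("phylogenetic dissimilarity matrix is consistent and bounded", {
  sim <- small_sim(seed = 19, n_features = 30, n1 = 3, n2 = 2)
  rel <- to_relative(sim$counts)[1:6, ]
  for (q in c(0, 1)) {
    D <- dissimilarity_matrix(rel, q, facet = "phylogenetic", tree = sim$tree)
    expect_true(isSymmetric(D))
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D[1, 2],
                 hill_beta_pair(rel[1, ], rel[2, ], q,
                                facet = "phylogenetic", tree = sim$tree))
  }
  # identical rows -> zero dissimilarity, both facets
  rel2 <- rbind(rel[1, ], rel[1, ])
  rownames(rel2) <- c("a", "b")
  expect_equal(dissimilarity_matrix(rel2, 1)["a", "b"], 0)
  expect_equal(dissimilarity_matrix(rel2, 1, facet = "phylogenetic",
                                    tree = sim$tree)["a", "b"], 0)
})

test_that("phylogenetic beta responds to tree distance between supports", {
  # two disjoint singleton communities: dissimilarity must be 1 regardless
  # of how close the leaves are, but beta of overlapping pairs depends on
  # shared branch length: sister-leaf mixtures are less dissimilar than
  # distant-leaf mixtures
  tr <- ape::read.tree(text = "((A:1,B:1):3,(C:1,D:1):3);")
  pAB <- c(A = 0.5, B = 0.5, C = 0, D = 0)
  pAC <- c(A = 0.5, B = 0, C = 0.5, D = 0)
  pA <- c(A = 1, B = 0, C = 0, D = 0)
  pB <- c(A = 0, B = 1, C = 0, D = 0)
  d_sister <- hill_beta_pair(pA, pB, 1, "phylogenetic", tr)
  d_cross <- hill_beta_pair(pA, c(A = 0, B = 0, C = 1, D = 0), 1,
                            "phylogenetic", tr)
  expect_equal(d_sister, 1)
  expect_equal(d_cross, 1)
  d_mix <- hill_beta_pair(pAB, pAC, 1, "phylogenetic", tr)
  expect_gt(d_mix, 0)
  expect_lt(d_mix, 1)
})

test_that("hill_dissimilarity aggregates rank before computing", {
  sim <- small_sim(seed = 3, n_features = 40, n1 = 4, n2 = 3)
  d_phy <- hill_dissimilarity(sim$counts, q = 1, rank = "Phylum",
                              taxonomy = sim$taxonomy)
  agg <- aggregate_rank(sim$counts, sim$taxonomy, "Phylum")
  d_manual <- dissimilarity_matrix(to_relative(agg), 1)
  expect_equal(d_phy, d_manual)
  expect_error(hill_dissimilarity(sim$counts, q = 1, facet = "phylogenetic",
                                  rank = "Phylum", taxonomy = sim$taxonomy,
                                  tree = sim$tree), "rank-collapsed")
})

test_that("dissimilarity matrices survive a TSV round trip", {
  sim <- small_sim(seed = 3, n_features = 30, n1 = 3, n2 = 2)
  D <- hill_dissimilarity(sim$counts, q = 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_dissimilarity(D, tf)
  back <- read_dissimilarity(tf)
  expect_equal(back, D, tolerance = 1e-12)
})
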