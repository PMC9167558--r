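test_that("PCoA reproduces Euclidean configurations", {
  withr::with_seed(41, {
    X <- matrix(rnorm(10 * 2), 10, 2)
    rownames(X) <- paste0("s", 1:10)
    d <- as.matrix(dist(X))
    pc <- pcoa(d)
    rec <- as.matrix(dist(pc$points))
    expect_equal(rec, d, tolerance = 1e-8)
    expect_equal(ncol(pc$neg_points), 0L)
    # eigenvalue sum equals the trace of the centered matrix
    expect_equal(sum(pc$eig), pc$trace, tolerance = 1e-10)
  })
  dz <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  pz <- pcoa(dz)
  expect_true(all(abs(pz$eig) < 1e-12))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA pseudo-F equals classical ANOVA F on univariate data", {
  withr::with_seed(55, {
    for (i in 1:10) {
      g <- factor(rep(c("a", "b", "c"), times = c(5, 6, 4)))
      x <- rnorm(length(g)) + as.integer(g) * runif(1)
      d <- as.matrix(dist(x))
      rownames(d) <- colnames(d) <- paste0("s", seq_along(x))
      res <- permanova(d, data.frame(g = g), "g", n_perm = 19, seed = i)
      expect_equal(res$F[1], oneway_F_direct(x, g), tolerance = 1e-8)
    }
  })
})

test_that("PERMANOVA matches vegan::adonis2 on a two-factor model", {
  sim <- small_sim(seed = 7, n_features = 60, n1 = 6, n2 = 4)
  meta <- sim$meta
  sel <- meta$host_species == "S_rivulatus"
  d <- hill_dissimilarity(sim$counts, q = 1)[meta$sample_id[sel],
                                             meta$sample_id[sel]]
  mine <- permanova(d, meta[sel, ], c("region", "season", "region:season"),
                    n_perm = 49, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ region + season + region:season,
                        data = meta[sel, ], permutations = 19, by = "terms")
  expect_equal(mine$SumOfSqs[1:4], ref$SumOfSqs[1:4], tolerance = 1e-10)
  expect_equal(mine$F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(mine$R2[1:3], ref$R2[1:3], tolerance = 1e-10)
  # SS decomposition is exact
  expect_equal(sum(mine$SumOfSqs[1:4]), mine$SumOfSqs[5], tolerance = 1e-9)
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  withr::with_seed(77, {
    x <- rnorm(6)
    g <- factor(c("a", "a", "a", "b", "b", "b"))
    d <- as.matrix(dist(x))
    rownames(d) <- colnames(d) <- paste0("s", 1:6)
    res <- permanova(d, data.frame(g = g), "g", exhaustive = TRUE)
    # independent oracle: classical F over all 720 relabellings
    perms <- expand.grid(rep(list(1:6), 6))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
    F_obs <- oneway_F_direct(x, g)
    F_all <- apply(perms, 1, function(r) oneway_F_direct(x[r], g))
    expect_equal(res$p[1], mean(F_all >= F_obs - 1e-12))
    expect_equal(attr(res, "n_perm"), 720L)
  })
})

test_that("permutation p-values respect the add-one floor and the seed", {
  sim <- small_sim(seed = 9, n_features = 40, n1 = 5, n2 = 3)
  meta <- sim$meta
  sel <- meta$host_species == "S_rivulatus"
  d <- hill_dissimilarity(sim$counts, q = 1)[meta$sample_id[sel],
                                             meta$sample_id[sel]]
  r1 <- permanova(d, meta[sel, ], c("region", "season"), n_perm = 99, seed = 3)
  r2 <- permanova(d, meta[sel, ], c("region", "season"), n_perm = 99, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_true(all(r1$p[1:2] >= 1 / 100))
})

test_that("aliased terms are reported by name", {
  withr::with_seed(12, {
    d <- as.matrix(dist(rnorm(8)))
    rownames(d) <- colnames(d) <- paste0("s", 1:8)
    g <- factor(rep(c("a", "b"), each = 4))
    dup <- data.frame(g = g, h = g)  # h aliased with g
    expect_error(permanova(d, dup, c("g", "h"), n_perm = 9), "h")
  })
})

test_that("pairwise PERMANOVA reduces to one-way and enumerates level pairs", {
  sim <- small_sim(seed = 21, n_features = 50, n1 = 5, n2 = 3)
  meta <- sim$meta
  sel <- meta$host_species == "S_rivulatus"
  d <- hill_dissimilarity(sim$counts, q = 1)[meta$sample_id[sel],
                                             meta$sample_id[sel]]
  groups <- meta$region[sel]
  pw <- pairwise_permanova(d, groups, n_perm = 49, seed = 5)
  expect_equal(nrow(pw), 3L)  # C(3,2)
  two <- groups %in% c("RedSea", "Crete")
  one_way <- permanova(d[two, two], data.frame(group = groups[two]), "group",
                       n_perm = 49, seed = 1)
  expect_equal(pw$F[pw$group1 == "Crete" & pw$group2 == "RedSea"],
               one_way$F[1], tolerance = 1e-10)
  expect_error(pairwise_permanova(d, seq_along(groups)), "fewer than 2")
})

test_that("PERMDISP distances match direct coordinate computation", {
  withr::with_seed(61, {
    X <- matrix(rnorm(16 * 3), 16, 3)
    rownames(X) <- paste0("s", 1:16)
    g <- factor(rep(c("a", "b"), each = 8))
    d <- as.matrix(dist(X))
    pd <- permdisp(d, g, n_perm = 99, seed = 2)
    manual <- numeric(16)
    for (lev in levels(g)) {
      sel <- g == lev
      cen <- colMeans(X[sel, ])
      manual[sel] <- sqrt(rowSums(sweep(X[sel, ], 2, cen)^2))
    }
    expect_equal(unname(pd$distances), manual, tolerance = 1e-8)
    # against the reference implementation
    bd <- vegan::betadisper(as.dist(d), g, type = "centroid")
    expect_equal(unname(pd$distances), unname(bd$distances), tolerance = 1e-8)
  })
})

test_that("PERMDISP recovers a planted dispersion ratio of 2", {
  withr::with_seed(71, {
    A <- matrix(rnorm(20 * 2), 20, 2)
    B <- sweep(A, 2, colMeans(A)) * 2  # same shape, doubled spread
    B <- sweep(B, 2, c(10, 10), "+")   # move centroid away
    X <- rbind(A, B)
    rownames(X) <- paste0("s", 1:40)
    g <- factor(rep(c("a", "b"), each = 20))
    pd <- permdisp(as.matrix(dist(X)), g, n_perm = 199, seed = 3)
    expect_equal(unname(pd$group_means["b"] / pd$group_means["a"]), 2,
                 tolerance = 1e-8)
    expect_lt(pd$p_perm, 0.05)
  })
})

test_that("PERMDISP handles non-Euclidean matrices via Anderson's correction", {
  sim <- small_sim(seed = 33, n_features = 50, n1 = 6, n2 = 4)
  meta <- sim$meta
  sel <- meta$host_species == "S_rivulatus"
  d <- hill_dissimilarity(sim$counts, q = 1)[meta$sample_id[sel],
                                             meta$sample_id[sel]]
  g <- factor(meta$region[sel])
  pd <- permdisp(d, g, n_perm = 99, seed = 4)
  bd <- vegan::betadisper(as.dist(d), g, type = "centroid")
  expect_equal(unname(pd$distances), unname(bd$distances), tolerance = 1e-6)
  expect_error(permdisp(d[1:7, 1:7], factor(c(rep("a", 6), "b"))),
               "fewer than 2")
})

test_that("spatial-median PERMDISP runs and gives non-negative distances", {
  withr::with_seed(81, {
    X <- matrix(rnorm(12 * 2), 12, 2)
    rownames(X) <- paste0("s", 1:12)
    g <- factor(rep(c("a", "b"), each = 6))
    pd <- permdisp(as.matrix(dist(X)), g, n_perm = 49, seed = 1,
                   center = "spatial_median")
    expect_true(all(pd$distances >= 0))
    # spatial median minimizes the sum of distances at least as well as the
    # centroid does
    pc <- permdisp(as.matrix(dist(X)), g, n_perm = 49, seed = 1)
    expect_lte(sum(pd$distances), sum(pc$distances) + 1e-6)
  })
})
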