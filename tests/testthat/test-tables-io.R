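test_that("TSV count tables round-trip with ids and totals preserved", {
  tab <- tiny_counts()
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(sum(tab), 17)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, tf)
  back <- read_count_table(tf)
  expect_equal(unclass(back)[, ], unclass(tab)[, ])
  expect_identical(rownames(back), c("s1", "s2", "s3"))
})

test_that("malformed and empty tables are rejected with context", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\t3\toops"), tf)
  expect_error(read_count_table(tf), "s1.*f2")
  writeLines("sample_id\tf1", tf)
  expect_error(read_count_table(tf), "empty|malformed")
  m <- matrix(-1, 1, 1, dimnames = list("s1", "f1"))
  expect_error(count_table(m), "negative")
  m2 <- matrix(1.5, 1, 1, dimnames = list("s1", "f1"))
  expect_error(count_table(m2), "non-integer")
})

test_that("BIOM and TSV encodings of the same matrix read identically", {
  skip_if_not_installed("biomformat")
  tab <- random_counts(4, 6, seed = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  biom <- withr::local_tempfile(fileext = ".biom")
  write_count_table(tab, tsv)
  biomformat::write_biom(biomformat::make_biom(t(unclass(tab)[, ])), biom)
  a <- read_count_table(tsv, "tsv")
  b <- read_count_table(biom, "biom")
  expect_equal(unclass(a)[, ], unclass(b)[rownames(a), colnames(a)])
})

test_that("prevalence filter removes features in min_samples samples or fewer", {
  m <- matrix(0, 5, 3, dimnames = list(paste0("s", 1:5), c("in3", "in4", "in5")))
  m[1:3, 1] <- 1  # occupancy 3 -> removed at min_samples = 3
  m[1:4, 2] <- 1  # occupancy 4 -> retained
  m[, 3] <- 2
  tab <- count_table(m)
  tax <- toy_taxonomy(colnames(m))
  out <- filter_features(tab, tax, min_samples = 3)
  expect_identical(colnames(out), c("in4", "in5"))
  expect_identical(attr(out, "removed_features"), "in3")
})

test_that("taxonomy-based exclusion removes chloroplast-like features", {
  tab <- random_counts(4, 3, seed = 5)
  tax <- toy_taxonomy(colnames(tab),
                      class = c("Chloroplast", "unassigned", "unassigned"))
  out <- filter_features(tab, tax, min_samples = 0)
  expect_false("f001" %in% colnames(out))
  expect_true(all(c("f002", "f003") %in% colnames(out)))
  # missing taxonomy entries are reported by id
  expect_error(filter_features(tab, tax[-1, ], min_samples = 0), "f001")
})

test_that("filtering is idempotent", {
  tab <- random_counts(6, 10, seed = 11)
  tax <- toy_taxonomy(colnames(tab))
  once <- filter_features(tab, tax, min_samples = 2)
  twice <- filter_features(once, tax, min_samples = 2)
  expect_equal(unclass(once)[, ], unclass(twice)[, ])
})

test_that("rarefaction conserves depth, drops shallow samples, is seeded", {
  m <- matrix(c(3000, 900, 700, 600), 2, 2, byrow = TRUE,
              dimnames = list(c("deep", "shallow"), c("f1", "f2")))
  tab <- count_table(m)
  r <- rarefy(tab, depth = 2000, seed = 4)
  expect_equal(unname(rowSums(r)), 2000)
  expect_identical(attr(r, "dropped_samples"), "shallow")
  r2 <- rarefy(tab, depth = 2000, seed = 4)
  expect_identical(unclass(r)[, ], unclass(r2)[, ])
  r3 <- rarefy(tab, depth = 2000, seed = 5)
  expect_false(identical(unclass(r)[, ], unclass(r3)[, ]))
  expect_error(rarefy(tab, depth = 0), "depth")
})

test_that("rarefied counts are hypergeometric draws with the right mean", {
  tab <- count_table(matrix(c(30, 70), 1, 2,
                            dimnames = list("s1", c("a", "b"))))
  draws <- vapply(seq_len(2000), function(i) {
    unclass(rarefy(tab, depth = 10, seed = i))[1, "a"]
  }, numeric(1))
  # E[count] = depth * 30/100 = 3; MC SE ~ 0.031
  expect_lt(abs(mean(draws) - 3), 0.15)
})

test_that("relative abundance closes rows to 1 and rejects empty samples", {
  expect_equal(unname(to_relative(count_table(matrix(c(2, 2), 1, 2,
    dimnames = list("s", c("a", "b")))))[1, ]), c(0.5, 0.5))
  expect_equal(unname(to_relative(count_table(matrix(c(10, 0), 1, 2,
    dimnames = list("s", c("a", "b")))))[1, ]), c(1, 0))
  tab <- random_counts(5, 8, seed = 2)
  expect_equal(unname(rowSums(to_relative(tab))), rep(1, 5))
  m <- matrix(c(1, 0, 2, 0), 2, 2, dimnames = list(c("ok", "empty"),
                                                   c("a", "b")))
  expect_error(to_relative(count_table(m)), "empty")
})

test_that("rank aggregation sums family members and conserves totals", {
  m <- matrix(c(3, 1, 4, 2, 5, 6), 2, 3,
              dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
  tab <- count_table(m)
  tax <- toy_taxonomy(colnames(m),
                      family = c("Rikenellaceae", "Rikenellaceae", "Other"))
  agg <- aggregate_rank(tab, tax, "Family")
  expect_equal(unclass(agg)["s1", "Rikenellaceae"], 3 + 4)
  expect_identical(aggregate_rank(tab, tax, "ASV"), tab)
  # conservation across random tables and ranks
  tab2 <- random_counts(5, 12, seed = 9)
  tax2 <- toy_taxonomy(colnames(tab2),
                       phylum = sample(c("P1", "P2", "P3"), 12, replace = TRUE),
                       family = sample(c("Fa", "Fb", "unassigned"), 12,
                                       replace = TRUE))
  for (rk in c("Phylum", "Family")) {
    expect_equal(rowSums(aggregate_rank(tab2, tax2, rk)), rowSums(tab2))
  }
})

test_that("unassigned labels are pooled per upstream lineage, not merged", {
  m <- matrix(1, 1, 2, dimnames = list("s1", c("f1", "f2")))
  tax <- toy_taxonomy(c("f1", "f2"), phylum = c("P1", "P2"),
                      family = c("unassigned", "unassigned"))
  agg <- aggregate_rank(count_table(m), tax, "Family")
  expect_equal(ncol(agg), 2L)  # two distinct unassigned lineages
})

test_that("metadata validation enforces compartments and host species", {
  meta <- fish_meta(c("s1", "s2"), "S_rivulatus", "RedSea")
  expect_silent(validate_sample_metadata(meta))
  bad <- meta
  bad$compartment[1] <- "reef"
  expect_error(validate_sample_metadata(bad), "compartment")
  bad2 <- meta
  bad2$host_species[1] <- NA
  expect_error(validate_sample_metadata(bad2), "host_species")
  tab <- random_counts(3, 2, seed = 1)
  expect_error(validate_sample_metadata(meta, tab), "missing")
})

test_that("trees are validated for labels, lengths and ultrametricity", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  expect_s3_class(read_feature_tree(tf), "phylo")
  writeLines("((A:1,B:1):1,C:5);", tf)
  expect_warning(read_feature_tree(tf), "ultrametric")
})
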