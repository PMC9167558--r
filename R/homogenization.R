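# Within- and between-group pairwise dissimilarity, percent homogenization
# across Hill index configurations, and classification of the invasion
# trajectory of each species (more/less variable, shifted or not, converging
# with the co-invader or not).

#' Extract a set of pairwise dissimilarities for one comparison context
#'
#' Three contexts are supported:
#' `"intraspecific_within_region"` (all unordered pairs of conspecific hosts
#' within one region), `"intraspecific_between_regions"` (all cross pairs of
#' conspecific hosts between two regions) and
#' `"interspecific_within_region"` (all cross pairs of hosts of two species
#' within one region).
#'
#' @param d Dissimilarity matrix over samples.
#' @param meta Sample metadata.
#' @param context One of the three contexts above.
#' @param species Character vector: one species for intraspecific contexts,
#'   two for the interspecific context.
#' @param regions Character vector: one region for within-region contexts,
#'   two for the between-regions context.
#' @return List of class `pairwise_set`: `values` (dissimilarities), `pairs`
#'   (sample-id pairs), `context`, `species`, `regions`.
#' @export
pairwise_sets <- function(d, meta,
                          context = c("intraspecific_within_region",
                                      "intraspecific_between_regions",
                                      "interspecific_within_region"),
                          species, regions) {
  context <- match.arg(context)
  d <- check_distmatrix(d)
  meta <- validate_sample_metadata(meta)
  meta <- meta[match(rownames(d), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stopf("metadata does not cover all samples in d")
  fish <- meta$compartment == "fish" & !is.na(meta$host_species)
  pick <- function(sp, rg) {
    meta$sample_id[fish & meta$host_species == sp & meta$region == rg]
  }
  if (context == "intraspecific_within_region") {
    if (length(species) != 1L || length(regions) != 1L) {
      stopf("context '%s' needs one species and one region", context)
    }
    ids <- pick(species, regions)
    if (length(ids) < 2L) stopf("fewer than 2 samples for %s in %s",
                                species, regions)
    pr <- utils::combn(ids, 2L)
    a <- pr[1L, ]
    b <- pr[2L, ]
  } else if (context == "intraspecific_between_regions") {
    if (length(species) != 1L || length(regions) != 2L) {
      stopf("context '%s' needs one species and two regions", context)
    }
    ids1 <- pick(species, regions[1L])
    ids2 <- pick(species, regions[2L])
    if (length(ids1) == 0L || length(ids2) == 0L) {
      stopf("empty selection for %s in %s", species,
            paste(regions, collapse = "/"))
    }
    g <- expand.grid(a = ids1, b = ids2, stringsAsFactors = FALSE)
    a <- g$a
    b <- g$b
  } else {
    if (length(species) != 2L || length(regions) != 1L) {
      stopf("context '%s' needs two species and one region", context)
    }
    ids1 <- pick(species[1L], regions)
    ids2 <- pick(species[2L], regions)
    if (length(ids1) == 0L || length(ids2) == 0L) {
      stopf("empty selection for %s in %s", paste(species, collapse = "/"),
            regions)
    }
    g <- expand.grid(a = ids1, b = ids2, stringsAsFactors = FALSE)
    a <- g$a
    b <- g$b
  }
  structure(list(values = d[cbind(a, b)],
                 pairs = data.frame(a = a, b = b, stringsAsFactors = FALSE),
                 context = context, species = species, regions = regions),
            class = "pairwise_set")
}

# mean dissimilarity of the relevant context in one region
context_mean <- function(d, meta, context, species, region) {
  mean(pairwise_sets(d, meta, context, species, region)$values)
}

#' Percent homogenization between a reference and a comparison region
#'
#' For every index configuration, computes the mean pairwise dissimilarity of
#' the chosen context in the reference (by convention native) region and in
#' the comparison region, and the percent change
#' `100 * (mean_ref - mean_cmp) / mean_ref`. Positive values indicate
#' homogenization (lower dissimilarity in the comparison region), negative
#' values differentiation. The summary across configurations is an unweighted
#' mean and standard deviation.
#'
#' @param dms Named list of dissimilarity matrices (one per configuration),
#'   e.g. from [dissimilarity_set()]; a single matrix is also accepted.
#' @param meta Sample metadata.
#' @param context `"intraspecific_within_region"` or
#'   `"interspecific_within_region"`.
#' @param species One species (intraspecific) or two (interspecific).
#' @param reference_region,comparison_region Region labels; the reference is
#'   the baseline of the percent change.
#' @return List with `per_config` (data frame of means and percent change),
#'   `mean_percent`, `sd_percent`.
#' @export
percent_homogenization <- function(dms, meta,
                                   context = c("intraspecific_within_region",
                                               "interspecific_within_region"),
                                   species, reference_region,
                                   comparison_region) {
  context <- match.arg(context)
  if (is.matrix(dms)) dms <- list(index = dms)
  if (is.null(names(dms))) names(dms) <- paste0("config", seq_along(dms))
  rows <- lapply(names(dms), function(nm) {
    m_ref <- context_mean(dms[[nm]], meta, context, species, reference_region)
    m_cmp <- context_mean(dms[[nm]], meta, context, species, comparison_region)
    pct <- if (m_ref <= 0) NA_real_ else 100 * (m_ref - m_cmp) / m_ref
    data.frame(config = nm, mean_reference = m_ref, mean_comparison = m_cmp,
               percent_change = pct, undefined = m_ref <= 0,
               stringsAsFactors = FALSE)
  })
  per_config <- do.call(rbind, rows)
  if (any(per_config$undefined)) {
    warnf("reference mean dissimilarity is zero for config(s): %s",
          paste(per_config$config[per_config$undefined], collapse = ", "))
  }
  list(per_config = per_config,
       mean_percent = mean(per_config$percent_change, na.rm = TRUE),
       sd_percent = stats::sd(per_config$percent_change, na.rm = TRUE))
}

#' Rank test between two sets of pairwise dissimilarities
#'
#' Kruskal-Wallis or Wilcoxon rank-sum test on the two collections of
#' pairwise values. Pairwise dissimilarities sharing samples are not
#' independent; the returned object carries this caveat and no correction is
#' applied.
#'
#' @param set_a,set_b `pairwise_set` objects or numeric vectors.
#' @param test `"kruskal"` or `"wilcoxon"`.
#' @return List with `statistic`, `p`, `test`, `n`, `note`.
#' @export
dissimilarity_tests <- function(set_a, set_b, test = c("kruskal", "wilcoxon")) {
  test <- match.arg(test)
  va <- if (inherits(set_a, "pairwise_set")) set_a$values else as.numeric(set_a)
  vb <- if (inherits(set_b, "pairwise_set")) set_b$values else as.numeric(set_b)
  if (length(va) == 0L || length(vb) == 0L) stopf("empty dissimilarity set")
  degenerate <- length(unique(c(va, vb))) == 1L
  if (degenerate) {
    return(list(statistic = NA_real_, p = 1, test = test,
                n = c(length(va), length(vb)), degenerate = TRUE,
                note = "all values tied; test degenerate"))
  }
  if (test == "kruskal") {
    ht <- stats::kruskal.test(list(va, vb))
  } else {
    ht <- stats::wilcox.test(va, vb, exact = FALSE)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, test = test,
       n = c(length(va), length(vb)), degenerate = FALSE,
       note = "pairwise dissimilarities share samples and are not independent")
}

verdict_from <- function(delta, p, alpha) {
  if (is.na(p) || p >= alpha) "no_change"
  else if (delta > 0) "homogenization"
  else "differentiation"
}

#' Classify the invasion trajectory of the microbiome
#'
#' For each species, compares within-region pairwise dissimilarity between
#' the native and the invaded region (variability verdict: homogenization if
#' significantly lower in the invaded range, differentiation if higher), and
#' compares between-region to within-native dissimilarity (shift verdict).
#' Interspecific convergence is assessed from the cross-species dissimilarity
#' in the two regions where both species occur. With several index
#' configurations, each is classified separately and the modal verdict is
#' reported.
#'
#' @param dms Named list of dissimilarity matrices (or a single matrix).
#' @param meta Sample metadata.
#' @param species Character vector of the two species.
#' @param native_region,invaded_region Region labels to contrast.
#' @param alpha Significance level for the verdicts (default 0.05).
#' @param test Rank test for the comparisons (default `"kruskal"`).
#' @return List of class `trajectory`: per-species verdicts, `interspecific`
#'   verdict, `scenario` string, and the per-config detail table.
#' @export
classify_trajectory <- function(dms, meta, species, native_region,
                                invaded_region, alpha = 0.05,
                                test = "kruskal") {
  if (length(species) != 2L) stopf("exactly two species expected")
  if (is.matrix(dms)) dms <- list(index = dms)
  if (is.null(names(dms))) names(dms) <- paste0("config", seq_along(dms))
  detail <- list()
  for (nm in names(dms)) {
    d <- dms[[nm]]
    for (sp in species) {
      wn <- pairwise_sets(d, meta, "intraspecific_within_region", sp,
                          native_region)
      wi <- pairwise_sets(d, meta, "intraspecific_within_region", sp,
                          invaded_region)
      bt <- pairwise_sets(d, meta, "intraspecific_between_regions", sp,
                          c(native_region, invaded_region))
      tv <- dissimilarity_tests(wn, wi, test)
      ts <- dissimilarity_tests(bt, wn, test)
      detail[[length(detail) + 1L]] <- data.frame(
        config = nm, scope = sp,
        delta = mean(wn$values) - mean(wi$values),
        p_variability = tv$p,
        variability = verdict_from(mean(wn$values) - mean(wi$values), tv$p,
                                   alpha),
        shift = if (!is.na(ts$p) && ts$p < alpha &&
                    mean(bt$values) > mean(wn$values)) "shifted" else "no_shift",
        stringsAsFactors = FALSE)
    }
    in_n <- pairwise_sets(d, meta, "interspecific_within_region", species,
                          native_region)
    in_i <- pairwise_sets(d, meta, "interspecific_within_region", species,
                          invaded_region)
    ti <- dissimilarity_tests(in_n, in_i, test)
    detail[[length(detail) + 1L]] <- data.frame(
      config = nm, scope = "interspecific",
      delta = mean(in_n$values) - mean(in_i$values),
      p_variability = ti$p,
      variability = verdict_from(mean(in_n$values) - mean(in_i$values), ti$p,
                                 alpha),
      shift = NA_character_, stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, detail)
  modal <- function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    if (length(tb) > 1L && tb[1L] == tb[2L]) "no_change" else names(tb)[1L]
  }
  sp_verdict <- vapply(species, function(sp) {
    modal(detail$variability[detail$scope == sp])
  }, character(1))
  inter <- modal(detail$variability[detail$scope == "interspecific"])
  scenario <- if (all(sp_verdict == "homogenization") &&
                  inter == "homogenization") {
    "homogenization within and between species"
  } else if (all(sp_verdict == "differentiation")) {
    "differentiation within species"
  } else if (all(sp_verdict == "no_change") && inter == "no_change") {
    "no change"
  } else {
    "mixed trajectories"
  }
  structure(list(species_verdicts = sp_verdict, interspecific = inter,
                 scenario = scenario, detail = detail, alpha = alpha),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory classification (alpha =", x$alpha, ")\n")
  for (sp in names(x$species_verdicts)) {
    cat(sprintf("  %s: %s\n", sp, x$species_verdicts[[sp]]))
  }
  cat(sprintf("  interspecific: %s\n  scenario: %s\n",
              x$interspecific, x$scenario))
  invisible(x)
}

#' Full homogenization report
#'
#' Percent-change summaries for each species between the native region and
#' every invaded region, plus the interspecific summary, with rank tests,
#' across a set of index configurations.
#'
#' @param dms Named list of dissimilarity matrices.
#' @param meta Sample metadata.
#' @param species Two species labels.
#' @param native_region Native (reference) region.
#' @param invaded_regions Character vector of invaded regions.
#' @param test Rank test for significance.
#' @param alpha Significance level.
#' @return List with `intraspecific` and `interspecific` result tables and
#'   the `trajectory` classification against the first invaded region.
#' @export
homogenization_report <- function(dms, meta, species, native_region,
                                  invaded_regions, test = "kruskal",
                                  alpha = 0.05) {
  if (is.matrix(dms)) dms <- list(index = dms)
  intra <- list()
  for (sp in species) {
    for (rg in invaded_regions) {
      ph <- percent_homogenization(dms, meta, "intraspecific_within_region",
                                   sp, native_region, rg)
      tt <- dissimilarity_tests(
        pairwise_sets(dms[[1L]], meta, "intraspecific_within_region", sp,
                      native_region),
        pairwise_sets(dms[[1L]], meta, "intraspecific_within_region", sp, rg),
        test)
      intra[[length(intra) + 1L]] <- data.frame(
        species = sp, reference = native_region, comparison = rg,
        mean_percent = ph$mean_percent, sd_percent = ph$sd_percent,
        statistic = tt$statistic, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  inter <- list()
  for (rg in invaded_regions) {
    ph <- percent_homogenization(dms, meta, "interspecific_within_region",
                                 species, native_region, rg)
    tt <- dissimilarity_tests(
      pairwise_sets(dms[[1L]], meta, "interspecific_within_region", species,
                    native_region),
      pairwise_sets(dms[[1L]], meta, "interspecific_within_region", species,
                    rg),
      test)
    inter[[length(inter) + 1L]] <- data.frame(
      reference = native_region, comparison = rg,
      mean_percent = ph$mean_percent, sd_percent = ph$sd_percent,
      statistic = tt$statistic, p = tt$p, stringsAsFactors = FALSE)
  }
  list(intraspecific = do.call(rbind, intra),
       interspecific = do.call(rbind, inter),
       trajectory = classify_trajectory(dms, meta, species, native_region,
                                        invaded_regions[1L], alpha, test))
}
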