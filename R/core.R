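# Core-microbiome identification from a Poisson abundance-occupancy null.
# For feature i with total count N_i over n samples, a neutral Poisson model
# with rate lambda_i = N_i / n predicts an expected occupancy
# E[O_i] = n * (1 - exp(-lambda_i)). Features observed at or above that
# expectation are occupying more hosts than their abundance alone predicts
# and are called core; a bootstrap over host subsets of fixed size makes the
# call robust to unequal group sizes.

#' Abundance-occupancy statistics per feature
#'
#' For every feature: observed occupancy (samples with count > 0), total
#' count, the per-sample Poisson rate `lambda = N_total / n` and the expected
#' occupancy under the Poisson null, `n * (1 - exp(-lambda))`. Counts should
#' be comparable across samples (equal-depth or rarefied input recommended;
#' not enforced).
#'
#' @param table A [count_table()] with at least 2 samples.
#' @return Data frame with columns `feature_id`, `o_obs`, `n_total`, `n`,
#'   `lambda`, `o_exp`.
#' @export
occupancy_stats <- function(table) {
  m <- if (inherits(table, "count_table")) as_matrix(table) else as.matrix(table)
  if (nrow(m) < 2L) stopf("need at least 2 samples")
  n <- nrow(m)
  n_total <- colSums(m)
  lambda <- n_total / n
  data.frame(
    feature_id = colnames(m),
    o_obs = colSums(m > 0),
    n_total = n_total,
    n = n,
    lambda = lambda,
    o_exp = n * (1 - exp(-lambda)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Call core features against the Poisson null
#'
#' Under `mode = "at_expectation"` a feature is core when its observed
#' occupancy is at or above the Poisson expectation. Under
#' `mode = "envelope"` the observed occupancy is compared with the lower
#' `alpha`-quantile of the simulated null occupancy distribution (the
#' occupancy of `n` independent Poisson(lambda) draws, simulated via its
#' exact Binomial(n, 1 - exp(-lambda)) equivalent). Both modes additionally
#' require `o_obs >= min_occupancy`.
#'
#' @param records Data frame from [occupancy_stats()].
#' @param mode `"at_expectation"` (default) or `"envelope"`.
#' @param alpha Lower quantile for the envelope mode.
#' @param min_occupancy Minimum observed occupancy (default 1; an unobserved
#'   feature can never be core).
#' @param n_sim Null simulations per feature for the envelope mode.
#' @param seed Integer seed for the envelope simulations.
#' @return Character vector of core feature ids.
#' @export
call_core <- function(records, mode = c("at_expectation", "envelope"),
                      alpha = 0.05, min_occupancy = 1, n_sim = 1000,
                      seed = NULL) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (mode == "at_expectation") {
    is_core <- records$o_obs >= records$o_exp
  } else {
    prob <- 1 - exp(-records$lambda)
    lower <- with_seed(seed, vapply(seq_len(nrow(records)), function(i) {
      stats::quantile(stats::rbinom(n_sim, records$n[i], prob[i]),
                      probs = alpha, names = FALSE, type = 1)
    }, numeric(1)))
    is_core <- records$o_obs >= lower
  }
  is_core <- is_core & records$o_obs >= min_occupancy
  records$feature_id[is_core]
}

#' Bootstrap consensus core for one species x region group
#'
#' Draws `n_boot` hosts without replacement from the group `B` times, calls
#' core features on each draw, and reports the fraction of draws in which
#' each feature was called core.
#'
#' @param table A [count_table()] of fish samples.
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @param species,region Group selectors matched against `host_species` and
#'   `region`.
#' @param n_boot Hosts drawn per iteration; must not exceed the group size.
#' @param B Bootstrap iterations (default 1000).
#' @param threshold Consensus frequency threshold (default 0.8).
#' @param seed Integer seed.
#' @param mode,min_occupancy Passed to [call_core()].
#' @return Data frame with columns `species`, `region`, `feature_id`,
#'   `frequency`, `is_core` (frequency > threshold); attributes `B`,
#'   `n_boot`, `threshold`.
#' @export
bootstrap_core <- function(table, meta, species, region, n_boot, B = 1000,
                           threshold = 0.8, seed = NULL,
                           mode = "at_expectation", min_occupancy = 1) {
  if (B < 1) stopf("B must be >= 1")
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  meta <- align_metadata(meta, table)
  sel <- meta$compartment == "fish" &
    !is.na(meta$host_species) & meta$host_species == species &
    meta$region == region
  ids <- meta$sample_id[sel]
  if (length(ids) < n_boot) {
    stopf("group %s/%s has %d samples, fewer than n_boot = %d",
          species, region, length(ids), n_boot)
  }
  m <- as_matrix(table)[ids, , drop = FALSE]
  # sort rows so frequencies do not depend on incoming sample order
  m <- m[order(rownames(m)), , drop = FALSE]
  hits <- stats::setNames(numeric(ncol(m)), colnames(m))
  with_seed(seed, {
    for (b in seq_len(B)) {
      sub <- m[sample.int(nrow(m), n_boot), , drop = FALSE]
      core <- call_core(occupancy_stats(sub), mode = mode,
                        min_occupancy = min_occupancy)
      hits[core] <- hits[core] + 1
    }
  })
  out <- data.frame(species = species, region = region,
                    feature_id = names(hits), frequency = unname(hits) / B,
                    stringsAsFactors = FALSE)
  out$is_core <- out$frequency > threshold
  attr(out, "B") <- B
  attr(out, "n_boot") <- n_boot
  attr(out, "threshold") <- threshold
  out
}

#' Consensus core across species x region groups
#'
#' The consensus core is the union, over all groups, of features whose
#' bootstrap frequency exceeds the threshold in at least one group.
#'
#' @param entries List of data frames from [bootstrap_core()].
#' @param threshold Optional override of the per-entry thresholds.
#' @return List with `consensus` (character vector of feature ids) and
#'   `frequencies` (row-bound entries).
#' @export
consensus_union <- function(entries, threshold = NULL) {
  if (length(entries) == 0L) stopf("need at least one bootstrap entry")
  if (is.data.frame(entries)) entries <- list(entries)
  freq <- do.call(rbind, lapply(entries, function(e) {
    thr <- threshold %||% attr(e, "threshold") %||% 0.8
    e$is_core <- e$frequency > thr
    e
  }))
  list(consensus = sort(unique(freq$feature_id[freq$is_core])),
       frequencies = freq)
}

#' Per-sample proportion of reads in the core microbiome
#'
#' @param table A [count_table()].
#' @param consensus Character vector of core feature ids (must be a subset of
#'   the table's features).
#' @return Named numeric vector in `[0, 1]`, one entry per sample.
#' @export
core_proportion <- function(table, consensus) {
  m <- if (inherits(table, "count_table")) as_matrix(table) else as.matrix(table)
  extra <- setdiff(consensus, colnames(m))
  if (length(extra) > 0L) {
    stopf("consensus features absent from table: %s",
          paste(extra, collapse = ", "))
  }
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stopf("sample(s) with zero total count: %s",
          paste(rownames(m)[totals <= 0], collapse = ", "))
  }
  rowSums(m[, colnames(m) %in% consensus, drop = FALSE]) / totals
}
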