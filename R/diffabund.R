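# Per-feature between-group tests: one-way ANOVA on centered log-ratio
# transformed counts (compositional scale) and Kruskal-Wallis on relative
# abundances with Benjamini-Hochberg correction across features.

#' Centered log-ratio transform
#'
#' `clr(x)_i = log((x_i + pseudocount) / g)` per sample, where `g` is the
#' geometric mean of the pseudocount-shifted row. Every transformed row sums
#' to zero.
#'
#' @param table A [count_table()] or numeric matrix (samples x features).
#' @param pseudocount Positive shift added to all counts before taking logs
#'   (default 0.5).
#' @return Matrix of CLR values with the input dimnames.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  m <- if (inherits(table, "count_table")) as_matrix(table) else as.matrix(table)
  lx <- log(m + pseudocount)
  lx - rowMeans(lx)
}

prepare_groups <- function(groups, n) {
  groups <- droplevels(as.factor(groups))
  if (length(groups) != n) stopf("groups length does not match samples")
  if (nlevels(groups) < 2L) stopf("need at least 2 group levels")
  small <- names(which(table(groups) < 2))
  if (length(small) > 0L) {
    stopf("group level(s) with fewer than 2 samples: %s",
          paste(small, collapse = ", "))
  }
  groups
}

group_means <- function(m, groups) {
  gm <- apply(m, 2L, function(v) tapply(v, groups, mean))
  t(gm)
}

#' Per-feature one-way ANOVA on CLR values
#'
#' Classical one-way ANOVA F per feature. Features with zero variance across
#' all samples are degenerate: they get `p = 1` and a `degenerate` flag
#' rather than an error.
#'
#' @param clr Matrix from [clr_transform()] (samples x features).
#' @param groups Factor of group membership, aligned with rows.
#' @param alpha Significance level for the `sig_raw`/`sig_fdr` flags.
#' @return Data frame with `feature_id`, `statistic` (F), `p`, `q` (BH across
#'   features), `sig_raw`, `sig_fdr`, `degenerate`, and per-group CLR means.
#' @export
anova_per_feature <- function(clr, groups, alpha = 0.05) {
  m <- as.matrix(clr)
  groups <- prepare_groups(groups, nrow(m))
  stat <- p <- rep(NA_real_, ncol(m))
  degen <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (stats::var(v) < 1e-14) {
      degen[j] <- TRUE
      p[j] <- 1
      next
    }
    fit <- summary(stats::aov(v ~ groups))[[1L]]
    stat[j] <- fit[["F value"]][1L]
    p[j] <- fit[["Pr(>F)"]][1L]
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature_id = colnames(m), statistic = stat, p = p, q = q,
                    sig_raw = !is.na(p) & p < alpha,
                    sig_fdr = !is.na(q) & q < alpha,
                    degenerate = degen, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(group_means(m, groups)))
}

#' Per-feature Kruskal-Wallis tests with FDR correction
#'
#' Kruskal-Wallis H (with tie correction, via [stats::kruskal.test()]) per
#' feature on relative abundances, Benjamini-Hochberg adjustment across the
#' features of the table, and significance flags on both raw and adjusted
#' p-values.
#'
#' @param table Relative-abundance matrix (or [count_table()]; values are
#'   used as given).
#' @param groups Factor of group membership.
#' @param alpha Significance level (default 0.05).
#' @return Data frame as in [anova_per_feature()] with per-group mean
#'   abundances.
#' @export
kruskal_per_feature <- function(table, groups, alpha = 0.05) {
  m <- if (inherits(table, "count_table")) as_matrix(table) else as.matrix(table)
  groups <- prepare_groups(groups, nrow(m))
  stat <- p <- rep(NA_real_, ncol(m))
  degen <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (length(unique(v)) == 1L) {
      degen[j] <- TRUE
      p[j] <- 1
      next
    }
    kt <- stats::kruskal.test(v, groups)
    stat[j] <- unname(kt$statistic)
    p[j] <- kt$p.value
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature_id = colnames(m), statistic = stat, p = p, q = q,
                    sig_raw = !is.na(p) & p < alpha,
                    sig_fdr = !is.na(q) & q < alpha,
                    degenerate = degen, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(group_means(m, groups)))
}

#' Summarize significant features across ranks
#'
#' @param results Named list of result data frames (one per taxonomic rank,
#'   from [anova_per_feature()] or [kruskal_per_feature()]).
#' @param which Count significance on raw (`"raw"`) or FDR-adjusted
#'   (`"fdr"`) p-values.
#' @return Data frame with `rank`, `n_significant`, `n_tested`, `fraction`.
#' @export
significance_summary <- function(results, which = c("raw", "fdr")) {
  which <- match.arg(which)
  if (is.data.frame(results)) results <- list(all = results)
  flag <- paste0("sig_", which)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(rank = nm, n_significant = sum(r[[flag]]),
               n_tested = nrow(r),
               fraction = if (nrow(r) > 0) sum(r[[flag]]) / nrow(r) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
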