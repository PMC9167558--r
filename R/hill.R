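# Hill-number alpha diversity and pairwise beta dissimilarity, taxonomic and
# phylogenetic. Order q tunes the weight of abundance: q = 0 counts taxa or
# lineages (presence-absence), q = 1 weights them by relative abundance
# (exponential of Shannon entropy). Phylogenetic variants follow the
# branch-decomposition formulation: every branch is a "lineage" with length
# L_b and descendant relative abundance a_b, normalized by the mean tree
# depth T = sum(L_b * a_b).

check_relabund <- function(p, what = "p") {
  if (any(p < 0)) stopf("%s has negative entries", what)
  if (abs(sum(p) - 1) > 1e-8) {
    stopf("%s must sum to 1 (got %.10f); use to_relative() first", what, sum(p))
  }
  invisible(p)
}

# Hill number of a weighted abundance assemblage: sum_b w_b * a_b^q, with the
# q = 1 limit taken in closed form. Taxonomic diversity is the special case
# w = 1; phylogenetic diversity uses w = L/T over branches.
hill_weighted <- function(a, w, q) {
  keep <- a > 0
  a <- a[keep]
  w <- w[keep]
  if (length(a) == 0L) return(0)
  if (q == 1) {
    exp(-sum(w * a * log(a)))
  } else {
    sum(w * a^q)^(1 / (1 - q))
  }
}

#' Hill-number alpha diversity of one community
#'
#' Effective number of taxa of order `q`: richness at `q = 0`, the exponential
#' of Shannon entropy at `q = 1`, and `(sum p_i^q)^(1/(1-q))` otherwise.
#'
#' @param p Relative-abundance vector summing to 1.
#' @param q Diversity order, finite and >= 0.
#' @return Effective number of taxa.
#' @examples
#' hill_alpha(c(0.5, 0.5), q = 0)  # 2
#' hill_alpha(c(0.8, 0.2), q = 1)  # exp(Shannon)
#' @export
hill_alpha <- function(p, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0) {
    stopf("q must be a single finite number >= 0")
  }
  check_relabund(p)
  hill_weighted(p, rep(1, length(p)), q)
}

# Per-branch descendant abundances for every sample at once.
# P: samples x tips relative-abundance matrix (colnames in tree$tip.label).
# Returns list(lengths, A) with A: edges x samples.
branch_abundances <- function(tree, P) {
  miss <- setdiff(colnames(P), tree$tip.label)
  if (length(miss) > 0L) {
    stopf("features missing from tree: %s", paste(miss, collapse = ", "))
  }
  tree <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ns <- nrow(P)
  acc <- matrix(0, ntip + nnode, ns)
  idx <- match(tree$tip.label, colnames(P))
  has <- !is.na(idx)
  acc[seq_len(ntip)[has], ] <- t(P[, idx[has], drop = FALSE])
  edge <- tree$edge
  A <- matrix(0, nrow(edge), ns)
  for (i in seq_len(nrow(edge))) {
    child <- edge[i, 2L]
    A[i, ] <- acc[child, ]
    acc[edge[i, 1L], ] <- acc[edge[i, 1L], ] + acc[child, ]
  }
  rownames(A) <- NULL
  list(lengths = tree$edge.length, A = A)
}

#' Phylogenetic Hill-number alpha diversity
#'
#' Effective number of lineages of order `q` for one community on a rooted
#' tree: branches are weighted by `L_b / T` where `T = sum(L_b a_b)` is the
#' abundance-weighted mean depth. On a star tree with unit branches this
#' equals [hill_alpha()].
#'
#' @param p Named relative-abundance vector; names must be tree leaf labels.
#' @param tree A rooted `phylo` object with branch lengths.
#' @param q Diversity order.
#' @return Effective number of lineages.
#' @export
hill_phylo_alpha <- function(p, tree, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0) {
    stopf("q must be a single finite number >= 0")
  }
  check_relabund(p)
  if (is.null(names(p))) stopf("p must be named by tree leaf labels")
  ba <- branch_abundances(tree, matrix(p, nrow = 1L,
                                       dimnames = list("s", names(p))))
  a <- ba$A[, 1L]
  L <- ba$lengths
  Tbar <- sum(L * a)
  if (Tbar <= 0) stopf("mean tree depth is zero; empty community?")
  hill_weighted(a, L / Tbar, q)
}

# beta (gamma/alpha, in [1, N]) -> local overlap dissimilarity 1 - C_qN or
# 1 - U_qN for N = 2. Sorensen-type 1 - C_qN reduces to classic Sorensen at
# q = 0 and to log(beta)/log(2) at q = 1; Jaccard-type 1 - U_qN reduces to
# classic Jaccard at q = 0.
beta_to_dissim <- function(beta, q, variant = c("sorensen", "jaccard"), N = 2) {
  variant <- match.arg(variant)
  beta <- pmin(pmax(beta, 1), N)
  if (q == 1) {
    d <- log(beta) / log(N)
  } else {
    expo <- if (variant == "sorensen") q - 1 else 1 - q
    d <- 1 - ((1 / beta)^expo - (1 / N)^expo) / (1 - (1 / N)^expo)
  }
  pmin(pmax(d, 0), 1)
}

# gamma and alpha Hill numbers of a pair of weighted assemblages under equal
# pooling weights (1/2, 1/2); returns beta = gamma / alpha in [1, 2].
pair_beta_weighted <- function(a1, a2, w, q) {
  abar <- (a1 + a2) / 2
  gamma <- hill_weighted(abar, w, q)
  if (q == 1) {
    h <- function(a) {
      keep <- a > 0
      sum(w[keep] * (a[keep] / 2) * log(a[keep] / 2))
    }
    alpha <- exp(-(h(a1) + h(a2))) / 2
  } else {
    s <- function(a) {
      keep <- a > 0
      sum(w[keep] * (a[keep] / 2)^q)
    }
    alpha <- (s(a1) + s(a2))^(1 / (1 - q)) / 2
  }
  gamma / alpha
}

#' Pairwise Hill-number dissimilarity between two communities
#'
#' Computes gamma diversity of the equal-weight pooled pair, the corresponding
#' alpha, their ratio beta in `[1, 2]`, and maps beta to a dissimilarity in
#' `[0, 1]` through the two-community local overlap. The default
#' Sorensen-type measure equals the classic Sorensen dissimilarity at
#' `q = 0` and `log(beta)/log(2)` at `q = 1`; the Jaccard-type alternative is
#' available via `variant`. For the phylogenetic facet the tree is implicitly
#' pruned to the union support of the pair (branches without descendant
#' abundance, and the stem above the pair's ancestor, carry no weight) and the
#' mean depth `T` is recomputed from the pooled pair unless `fixed_T` is
#' given.
#'
#' @param p1,p2 Relative-abundance vectors on the same feature space (equal
#'   length; names, when present, must match).
#' @param q Diversity order.
#' @param facet `"taxonomic"` or `"phylogenetic"`.
#' @param tree Required for the phylogenetic facet.
#' @param variant `"sorensen"` (default) or `"jaccard"`.
#' @param fixed_T Optional fixed mean depth for the phylogenetic facet; by
#'   default `T` is recomputed per pair from the pooled assemblage.
#' @return Dissimilarity in `[0, 1]`; 0 for identical inputs, 1 for disjoint
#'   supports.
#' @export
hill_beta_pair <- function(p1, p2, q, facet = c("taxonomic", "phylogenetic"),
                           tree = NULL, variant = c("sorensen", "jaccard"),
                           fixed_T = NULL) {
  facet <- match.arg(facet)
  variant <- match.arg(variant)
  if (length(p1) != length(p2)) stopf("p1 and p2 have different feature spaces")
  if (!is.null(names(p1)) && !is.null(names(p2)) &&
      !identical(names(p1), names(p2))) {
    stopf("p1 and p2 have mismatched feature names")
  }
  check_relabund(p1, "p1")
  check_relabund(p2, "p2")
  if (facet == "taxonomic") {
    beta <- pair_beta_weighted(p1, p2, rep(1, length(p1)), q)
  } else {
    if (is.null(tree)) stopf("facet='phylogenetic' requires a tree")
    if (is.null(names(p1))) stopf("p must be named by tree leaf labels")
    P <- rbind(p1, p2)
    colnames(P) <- names(p1)
    ba <- branch_abundances(tree, P)
    beta <- phylo_pair_beta(ba$A[, 1L], ba$A[, 2L], ba$lengths, q, fixed_T)
  }
  beta_to_dissim(beta, q, variant)
}

# beta for one pair from per-branch abundances; drops stem branches whose
# pooled abundance is 1 (ancestors of the whole pair support), which is
# exactly what pruning to the union support does on an ultrametric tree.
phylo_pair_beta <- function(a1, a2, L, q, fixed_T = NULL) {
  abar <- (a1 + a2) / 2
  keep <- abar > 0 & abar < 1 - 1e-12
  if (!any(keep)) return(1)
  Tbar <- fixed_T %||% sum(L[keep] * abar[keep])
  if (Tbar <= 0) return(1)
  w <- L[keep] / Tbar
  pair_beta_weighted(a1[keep], a2[keep], w, q)
}

#' All-pairs Hill dissimilarity matrix
#'
#' @param rel Samples x features relative-abundance matrix (rows sum to 1),
#'   e.g. from [to_relative()].
#' @param q Diversity order.
#' @param facet `"taxonomic"` or `"phylogenetic"`.
#' @param tree Required for the phylogenetic facet.
#' @param variant Passed to [hill_beta_pair()].
#' @return Symmetric matrix with zero diagonal and entries in `[0, 1]`,
#'   dimnames = sample ids.
#' @export
dissimilarity_matrix <- function(rel, q, facet = c("taxonomic", "phylogenetic"),
                                 tree = NULL,
                                 variant = c("sorensen", "jaccard")) {
  facet <- match.arg(facet)
  variant <- match.arg(variant)
  rel <- as.matrix(rel)
  n <- nrow(rel)
  if (n < 2L) stopf("need at least 2 samples")
  bad <- which(abs(rowSums(rel) - 1) > 1e-8)
  if (length(bad) > 0L) {
    stopf("rows not summing to 1: %s",
          paste(rownames(rel)[bad], collapse = ", "))
  }
  D <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  if (facet == "taxonomic") {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        beta <- pair_beta_weighted(rel[i, ], rel[j, ], rep(1, ncol(rel)), q)
        D[i, j] <- D[j, i] <- beta_to_dissim(beta, q, variant)
      }
    }
  } else {
    if (is.null(tree)) stopf("facet='phylogenetic' requires a tree")
    ba <- branch_abundances(tree, rel)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        beta <- phylo_pair_beta(ba$A[, i], ba$A[, j], ba$lengths, q)
        D[i, j] <- D[j, i] <- beta_to_dissim(beta, q, variant)
      }
    }
  }
  D
}

#' Hill dissimilarity at a taxonomic rank
#'
#' Convenience wrapper: aggregates a count table to the requested rank,
#' closes rows to relative abundance and computes the all-pairs dissimilarity
#' matrix. The phylogenetic facet requires `rank = "ASV"` unless a tree whose
#' leaves are rank labels is supplied.
#'
#' @param table A [count_table()].
#' @param q,facet,tree,variant Passed on to [dissimilarity_matrix()].
#' @param rank `"ASV"`, `"Phylum"`, `"Family"`, ... (needs `taxonomy` unless
#'   `"ASV"`).
#' @param taxonomy Taxonomy table for rank aggregation.
#' @return Dissimilarity matrix.
#' @export
hill_dissimilarity <- function(table, q, facet = c("taxonomic", "phylogenetic"),
                               rank = "ASV", taxonomy = NULL, tree = NULL,
                               variant = c("sorensen", "jaccard")) {
  facet <- match.arg(facet)
  if (rank != "ASV") {
    if (is.null(taxonomy)) stopf("rank aggregation requires a taxonomy table")
    table <- aggregate_rank(table, taxonomy, rank)
    if (facet == "phylogenetic" &&
        !all(colnames(table) %in% (tree$tip.label %||% character()))) {
      stopf("phylogenetic facet at rank '%s' requires a rank-collapsed tree whose leaves are rank labels", rank)
    }
  }
  dissimilarity_matrix(to_relative(table), q, facet, tree, variant)
}

#' Default Hill index configurations
#'
#' The configuration grid used for multi-index summaries: q in {0, 1} crossed
#' with taxonomic dissimilarity at Phylum, Family and ASV rank plus
#' phylogenetic dissimilarity at ASV rank (phylogenetic dissimilarity at
#' collapsed ranks would require a rank-level tree and is omitted by
#' default).
#'
#' @param q Diversity orders to include.
#' @param ranks Taxonomic ranks for the taxonomic facet.
#' @param include_phylo Include phylogenetic facet at ASV rank.
#' @return Data frame with columns `config`, `q`, `facet`, `rank`.
#' @export
default_hill_configs <- function(q = c(0, 1),
                                 ranks = c("Phylum", "Family", "ASV"),
                                 include_phylo = TRUE) {
  cfg <- expand.grid(q = q, rank = ranks, facet = "taxonomic",
                     stringsAsFactors = FALSE)
  if (include_phylo) {
    cfg <- rbind(cfg, expand.grid(q = q, rank = "ASV", facet = "phylogenetic",
                                  stringsAsFactors = FALSE))
  }
  cfg$config <- sprintf("%s_q%g_%s", substr(cfg$facet, 1, 4), cfg$q, cfg$rank)
  cfg[, c("config", "q", "facet", "rank")]
}

#' Dissimilarity matrices for a set of Hill configurations
#'
#' @param table A [count_table()].
#' @param configs Data frame as returned by [default_hill_configs()].
#' @param taxonomy,tree Inputs forwarded per configuration.
#' @param variant Beta-dissimilarity variant.
#' @return Named list of dissimilarity matrices, one per configuration.
#' @export
dissimilarity_set <- function(table, configs = default_hill_configs(),
                              taxonomy = NULL, tree = NULL,
                              variant = "sorensen") {
  out <- vector("list", nrow(configs))
  names(out) <- configs$config
  for (k in seq_len(nrow(configs))) {
    out[[k]] <- hill_dissimilarity(table, q = configs$q[k],
                                   facet = configs$facet[k],
                                   rank = configs$rank[k],
                                   taxonomy = taxonomy, tree = tree,
                                   variant = variant)
  }
  out
}

#' Write / read a dissimilarity matrix as square TSV
#'
#' @param d Symmetric matrix with sample ids as dimnames.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_dissimilarity <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
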