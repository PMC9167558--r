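# PCoA, PERMANOVA (sequential sums of squares from the Gower-centered
# matrix, McArdle-Anderson trace formulation), pairwise PERMANOVA and
# PERMDISP, all operating directly on a dissimilarity matrix.

check_distmatrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stopf("expected a square dissimilarity matrix")
  }
  if (max(abs(d - t(d))) > 1e-12) stopf("dissimilarity matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("dissimilarity matrix diagonal must be zero")
  if (any(d < 0)) stopf("negative dissimilarities")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  d
}

# Gower-centered inner-product matrix G = C (-d^2/2) C
gower_center <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(d)
  rc <- rowMeans(A)
  G <- A - matrix(rc, n, n) - matrix(rc, n, n, byrow = TRUE) + mean(A)
  (G + t(G)) / 2
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centered matrix of `-d^2/2`. Negative
#' eigenvalues (from non-Euclidean dissimilarities) are retained and their
#' axes reported separately; for a Euclidean-embeddable matrix the inter-point
#' distances in the positive-axis space reproduce `d`.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @return List with `points` (coordinates on positive axes), `neg_points`
#'   (coordinates on negative axes, real-valued magnitudes), `eig` (all
#'   eigenvalues, decreasing), and `trace`.
#' @export
pcoa <- function(d) {
  d <- check_distmatrix(d)
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values), 1e-300) * 1e-9
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  npts <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), length(neg))
  rownames(pts) <- rownames(npts) <- rownames(d)
  if (length(pos)) colnames(pts) <- paste0("Axis", seq_along(pos))
  if (length(neg)) colnames(npts) <- paste0("NegAxis", seq_along(neg))
  list(points = pts, neg_points = npts, eig = e$values, trace = sum(diag(G)))
}

# build the ordered list of cumulative hat matrices for a sequential
# (Type-I) decomposition; terms evaluated in the order given
permanova_design <- function(data, terms) {
  f <- stats::terms(stats::reformulate(terms), keep.order = TRUE)
  mf <- stats::model.frame(f, data = data)
  for (j in seq_along(mf)) if (is.character(mf[[j]])) mf[[j]] <- factor(mf[[j]])
  for (j in seq_along(mf)) {
    if (is.factor(mf[[j]]) && nlevels(droplevels(mf[[j]])) < 2L) {
      stopf("factor '%s' has fewer than 2 levels among these samples",
            colnames(mf)[j])
    }
    if (is.factor(mf[[j]])) mf[[j]] <- droplevels(mf[[j]])
  }
  X <- stats::model.matrix(f, mf)
  assign <- attr(X, "assign")
  labels <- attr(f, "term.labels")
  n <- nrow(X)
  hats <- vector("list", length(labels) + 1L)
  ranks <- integer(length(labels) + 1L)
  for (k in 0:length(labels)) {
    Xk <- X[, assign <= k, drop = FALSE]
    qr_k <- qr(Xk)
    Q <- qr.Q(qr_k)[, seq_len(qr_k$rank), drop = FALSE]
    hats[[k + 1L]] <- tcrossprod(Q)
    ranks[k + 1L] <- qr_k$rank
  }
  df <- diff(ranks)
  aliased <- labels[df == 0L]
  if (length(aliased) > 0L) {
    stopf("aliased/confounded term(s): %s", paste(aliased, collapse = ", "))
  }
  list(hats = hats, df = df, labels = labels, rank_full = ranks[length(ranks)],
       n = n)
}

# sequential SS and per-term pseudo-F for one (possibly permuted) G
permanova_stats <- function(G, design) {
  traces <- vapply(design$hats, function(H) sum(H * G), numeric(1))
  ss <- diff(traces)
  ss_total <- sum(diag(G))
  ss_resid <- ss_total - traces[length(traces)]
  df_resid <- design$n - design$rank_full
  F_val <- (ss / design$df) / (ss_resid / df_resid)
  list(ss = ss, ss_resid = ss_resid, ss_total = ss_total,
       df_resid = df_resid, F = F_val)
}

# all permutations of 1..n as a matrix (n! rows); used for exhaustive tests
all_permutations <- function(n) {
  if (n > 9L) stopf("exhaustive enumeration limited to n <= 9")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq.int(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' PERMANOVA from a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance in the McArdle-Anderson
#' trace formulation: the Gower-centered matrix `G` of `-d^2/2` is partitioned
#' by sequential (Type-I) hat-matrix projections of the cumulative model, so
#' interaction terms such as `region:season` are tested after their main
#' effects. The pseudo-F of each term uses the residual mean square of the
#' full model. P-values come from free permutation of sample labels, with the
#' observed statistic included: `p = (1 + #[F* >= F]) / (1 + n_perm)`.
#'
#' @param d Dissimilarity matrix or `dist` object.
#' @param data Data frame of sample covariates, rows aligned with `d` (matched
#'   by `sample_id` column or rownames when present, otherwise by position).
#' @param terms Character vector of model terms in testing order, e.g.
#'   `c("region", "season", "region:season")`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for reproducible permutations.
#' @param exhaustive If `TRUE`, enumerate all `n!` permutations (n <= 9) and
#'   report the exact permutation p-value.
#' @return Data frame with one row per term plus `Residual` and `Total`:
#'   columns `Df`, `SumOfSqs`, `R2`, `F`, `p`. The number of permutations is
#'   in attribute `n_perm`.
#' @export
permanova <- function(d, data, terms, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  d <- check_distmatrix(d)
  n <- nrow(d)
  data <- as.data.frame(data)
  if ("sample_id" %in% colnames(data) && !is.null(rownames(d))) {
    idx <- match(rownames(d), data$sample_id)
    if (!anyNA(idx)) data <- data[idx, , drop = FALSE]
  }
  if (nrow(data) != n) stopf("covariate rows (%d) do not match samples (%d)",
                             nrow(data), n)
  if (!exhaustive && n_perm < 1) stopf("n_perm must be >= 1")
  design <- permanova_design(data, terms)
  G <- gower_center(d)
  obs <- permanova_stats(G, design)

  if (exhaustive) {
    perms <- all_permutations(n)
    count <- numeric(length(terms))
    for (r in seq_len(nrow(perms))) {
      Fp <- permanova_stats(G[perms[r, ], perms[r, ]], design)$F
      count <- count + (Fp >= obs$F - 1e-12)
    }
    pval <- count / nrow(perms)
    n_perm_used <- nrow(perms)
  } else {
    count <- numeric(length(terms))
    with_seed(seed, {
      for (r in seq_len(n_perm)) {
        pi <- sample.int(n)
        Fp <- permanova_stats(G[pi, pi], design)$F
        count <- count + (Fp >= obs$F - 1e-12)
      }
    })
    pval <- (1 + count) / (1 + n_perm)
    n_perm_used <- n_perm
  }

  out <- data.frame(
    term = c(design$labels, "Residual", "Total"),
    Df = c(design$df, obs$df_resid, n - 1L),
    SumOfSqs = c(obs$ss, obs$ss_resid, obs$ss_total),
    R2 = c(obs$ss, obs$ss_resid, obs$ss_total) / obs$ss_total,
    F = c(obs$F, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm_used
  attr(out, "seed") <- seed
  class(out) <- c("permanova", "data.frame")
  out
}

#' Pairwise PERMANOVA between factor levels
#'
#' One-way PERMANOVA restricted to each pair of levels of a grouping factor,
#' with optional false-discovery-rate adjustment across pairs.
#'
#' @param d Dissimilarity matrix.
#' @param groups Factor (or character) of group membership, aligned with `d`.
#' @param n_perm,seed Passed to [permanova()].
#' @param p_adjust `"fdr"` (Benjamini-Hochberg across pairs) or `"none"`.
#' @return Data frame with one row per level pair.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL,
                               p_adjust = c("fdr", "none")) {
  p_adjust <- match.arg(p_adjust)
  d <- check_distmatrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stopf("groups length does not match d")
  lev <- levels(droplevels(groups))
  if (length(lev) < 2L) stopf("need at least 2 group levels")
  small <- lev[table(groups)[lev] < 2]
  if (length(small) > 0L) {
    stopf("level(s) with fewer than 2 samples: %s", paste(small, collapse = ", "))
  }
  pairs <- utils::combn(lev, 2L)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    sel <- groups %in% pairs[, k]
    sub <- d[sel, sel, drop = FALSE]
    res <- permanova(sub, data.frame(group = droplevels(groups[sel])),
                     terms = "group", n_perm = n_perm,
                     seed = derive_seed(seed, k))
    rows[[k]] <- data.frame(group1 = pairs[1L, k], group2 = pairs[2L, k],
                            Df = res$Df[1L], SumOfSqs = res$SumOfSqs[1L],
                            R2 = res$R2[1L], F = res$F[1L], p = res$p[1L],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (p_adjust == "fdr") stats::p.adjust(out$p, "BH") else out$p
  out
}

# group centers and corrected distances in PCoA space (positive and negative
# axes); Anderson's correction subtracts the squared distance on the
# imaginary (negative-eigenvalue) axes
dispersion_distances <- function(pc, groups, center = "centroid") {
  lev <- levels(groups)
  dist_to <- function(X, c_) {
    if (ncol(X) == 0L) return(numeric(nrow(X)))
    rowSums(sweep(X, 2L, c_)^2)
  }
  dists <- numeric(length(groups))
  for (g in lev) {
    sel <- groups == g
    Xp <- pc$points[sel, , drop = FALSE]
    Xn <- pc$neg_points[sel, , drop = FALSE]
    if (center == "centroid") {
      cp <- colMeans(Xp)
      cn <- colMeans(Xn)
    } else {
      med <- spatial_median(Xp, Xn)
      cp <- med$cp
      cn <- med$cn
    }
    dists[sel] <- sqrt(pmax(0, dist_to(Xp, cp) - dist_to(Xn, cn)))
  }
  dists
}

# Weiszfeld-type iteration for the spatial median under the corrected
# (real minus imaginary) squared distance
spatial_median <- function(Xp, Xn, max_iter = 100, tol = 1e-8) {
  cp <- colMeans(Xp)
  cn <- if (ncol(Xn) > 0L) colMeans(Xn) else numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- rowSums(sweep(Xp, 2L, cp)^2)
    if (ncol(Xn) > 0L) d2 <- d2 - rowSums(sweep(Xn, 2L, cn)^2)
    dd <- sqrt(pmax(d2, 1e-12))
    w <- 1 / dd
    cp_new <- colSums(Xp * w) / sum(w)
    cn_new <- if (ncol(Xn) > 0L) colSums(Xn * w) / sum(w) else numeric(0)
    delta <- sum(abs(cp_new - cp)) + sum(abs(cn_new - cn))
    cp <- cp_new
    cn <- cn_new
    if (delta < tol) break
  }
  list(cp = cp, cn = cn)
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Embeds the dissimilarity matrix by PCoA (keeping negative-eigenvalue axes),
#' computes each sample's distance to its group center with the imaginary-axis
#' correction `sqrt(max(0, d2_pos - d2_neg))`, and tests equality of group
#' mean dispersions with the one-way ANOVA F on those distances. The
#' permutation p-value permutes the distances-to-center across samples.
#'
#' @param d Dissimilarity matrix.
#' @param groups Factor of group membership aligned with `d`; every group
#'   needs at least 2 samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param center `"centroid"` (default) or `"spatial_median"`.
#' @return List of class `permdisp`: `distances` (per sample), `group_means`,
#'   `F`, `df`, `p_perm`, `p_param`.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = NULL,
                     center = c("centroid", "spatial_median")) {
  center <- match.arg(center)
  d <- check_distmatrix(d)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(d)) stopf("groups length does not match d")
  singleton <- names(which(table(groups) < 2))
  if (length(singleton) > 0L) {
    stopf("group(s) with fewer than 2 samples: %s",
          paste(singleton, collapse = ", "))
  }
  pc <- pcoa(d)
  z <- dispersion_distances(pc, groups, center)
  names(z) <- rownames(d)
  fit <- stats::aov(z ~ groups)
  tab <- summary(fit)[[1L]]
  F_obs <- tab[["F value"]][1L]
  df <- c(tab[["Df"]][1L], tab[["Df"]][2L])
  p_param <- tab[["Pr(>F)"]][1L]
  # permutation loop: one-way F recomputed from group sums (equivalent to the
  # aov fit above, but cheap enough for thousands of permutations)
  gi <- as.integer(groups)
  sizes <- tabulate(gi)
  n <- length(z)
  k <- length(sizes)
  sst <- sum(z^2) - sum(z)^2 / n
  oneway_F <- function(v) {
    gs <- vapply(seq_len(k), function(g) sum(v[gi == g]), numeric(1))
    ssb <- sum(gs^2 / sizes) - sum(v)^2 / n
    (ssb / (k - 1)) / ((sst - ssb) / (n - k))
  }
  count <- 0L
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      if (oneway_F(z[sample.int(n)]) >= F_obs - 1e-12) count <- count + 1L
    }
  })
  structure(list(
    distances = z,
    group_means = tapply(z, groups, mean),
    F = F_obs, df = df,
    p_perm = (1 + count) / (1 + n_perm),
    p_param = p_param,
    center = center, n_perm = n_perm
  ), class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP (%s): F = %.4g on %d, %d df; permutation p = %.4g (%d perms)\n",
              x$center, x$F, x$df[1L], x$df[2L], x$p_perm, x$n_perm))
  cat("group mean dispersions:\n")
  print(round(x$group_means, 4))
  invisible(x)
}
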