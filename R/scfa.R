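# Beta-diversity machinery applied to KEGG Orthology tables restricted to
# short-chain fatty acid (SCFA) functional groups. KO abundances within a
# group are treated like taxonomic units: the subset table is re-closed to
# relative abundance and fed to the Hill dissimilarity, PERMANOVA and
# PERMDISP machinery.

# group name -> number of KOs in the default (synthetic) mapping, matching
# the cardinalities commonly reported for SCFA with 1-5 carbon atoms
SCFA_CARDINALITIES <- c(formate = 25L, acetate = 17L, propionate = 13L,
                        butyrate = 17L, valerate = 14L)

#' Build an SCFA group mapping
#'
#' An `scfa_groups` object maps each SCFA group name to a set of KO ids, plus
#' an `"all"` group equal to the union. Real KO lists are study-specific;
#' [default_scfa_groups()] builds a synthetic placeholder mapping by slicing
#' the supplied KO universe into groups of the conventional cardinalities
#' (formate 25, acetate 17, propionate 13, butyrate 17, valerate 14) -- users
#' analysing real data should supply their own mapping via [scfa_groups()] or
#' [read_scfa_groups()].
#'
#' @param groups Named list: group name -> character vector of KO ids.
#' @return List of class `scfa_groups` (with `"all"` appended).
#' @export
scfa_groups <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    stopf("groups must be a named list of KO id vectors")
  }
  groups <- groups[names(groups) != "all"]
  if (any(lengths(groups) == 0L)) {
    stopf("empty KO set for group(s): %s",
          paste(names(groups)[lengths(groups) == 0L], collapse = ", "))
  }
  groups$all <- sort(unique(unlist(groups, use.names = FALSE)))
  structure(groups, class = "scfa_groups")
}

#' @rdname scfa_groups
#' @param ko_ids KO id universe to slice into placeholder groups.
#' @export
default_scfa_groups <- function(ko_ids) {
  need <- sum(SCFA_CARDINALITIES)
  if (length(ko_ids) < need) {
    stopf("need at least %d KO ids for the default grouping, got %d",
          need, length(ko_ids))
  }
  off <- 0L
  out <- list()
  for (nm in names(SCFA_CARDINALITIES)) {
    k <- SCFA_CARDINALITIES[[nm]]
    out[[nm]] <- ko_ids[off + seq_len(k)]
    off <- off + k
  }
  scfa_groups(out)
}

#' @rdname scfa_groups
#' @param path TSV with columns `group` and `ko` (one row per pair), or a
#'   YAML file mapping group names to KO id lists.
#' @export
read_scfa_groups <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    return(scfa_groups(lapply(raw, as.character)))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("group", "ko") %in% colnames(df))) {
    stopf("SCFA TSV needs columns 'group' and 'ko'")
  }
  scfa_groups(split(df$ko, df$group))
}

#' Restrict a KO table to one SCFA group
#'
#' @param ko_table A [count_table()] with `feature_kind = "KO"`.
#' @param groups An `scfa_groups` object.
#' @param group Group name (one of the group names or `"all"`).
#' @return Subset [count_table()]; KO ids of the group absent from the table
#'   are listed in attribute `missing_kos`.
#' @export
subset_kos <- function(ko_table, groups, group) {
  if (!inherits(groups, "scfa_groups")) stopf("groups must be an scfa_groups object")
  if (!group %in% names(groups)) {
    stopf("unknown SCFA group '%s' (have: %s)", group,
          paste(names(groups), collapse = ", "))
  }
  ids <- groups[[group]]
  present <- intersect(colnames(ko_table), ids)
  if (length(present) == 0L) {
    stopf("no KO of group '%s' present in the table", group)
  }
  out <- rebuild_table(as_matrix(ko_table)[, present, drop = FALSE], ko_table)
  attr(out, "missing_kos") <- setdiff(ids, present)
  out
}

#' Beta-diversity analysis of SCFA functional groups
#'
#' For every SCFA group: restrict the KO table to the group, re-close to
#' relative abundance, compute Hill dissimilarity for each order `q`, then
#' run PERMANOVA (terms `region`, `season`, `region:season` by default),
#' PERMDISP on the region factor, and the percent homogenization between a
#' reference (native) and a comparison region.
#'
#' @param ko_table KO [count_table()].
#' @param meta Sample metadata aligned with the table (typically one host
#'   species at a time).
#' @param groups An `scfa_groups` object.
#' @param q Diversity orders (default `c(0, 1)`).
#' @param terms PERMANOVA terms.
#' @param n_perm Permutations for PERMANOVA/PERMDISP.
#' @param seed Integer seed.
#' @param reference_region,comparison_region Regions for the percent
#'   homogenization (optional; skipped when `NULL`).
#' @return Data frame with one row per (group, q): PERMANOVA region/season
#'   statistics, PERMDISP F and p, and percent homogenization. The full
#'   result objects are in attribute `details`.
#' @export
scfa_beta_analysis <- function(ko_table, meta, groups, q = c(0, 1),
                               terms = c("region", "season", "region:season"),
                               n_perm = 199, seed = NULL,
                               reference_region = NULL,
                               comparison_region = NULL) {
  meta <- align_metadata(meta, ko_table)
  rows <- list()
  details <- list()
  k <- 0L
  for (grp in names(groups)) {
    sub <- subset_kos(ko_table, groups, grp)
    rel <- to_relative(sub)
    for (qq in q) {
      k <- k + 1L
      d <- dissimilarity_matrix(rel, q = qq, facet = "taxonomic")
      pmv <- permanova(d, meta, terms = terms, n_perm = n_perm,
                       seed = derive_seed(seed, k))
      pdp <- permdisp(d, meta$region, n_perm = n_perm,
                      seed = derive_seed(seed, 1000L + k))
      pct <- NA_real_
      if (!is.null(reference_region) && !is.null(comparison_region)) {
        sp <- unique(meta$host_species[meta$compartment == "fish"])
        if (length(sp) == 1L) {
          ph <- percent_homogenization(d, meta, "intraspecific_within_region",
                                       sp, reference_region, comparison_region)
          pct <- ph$mean_percent
        }
      }
      i_region <- match("region", pmv$term)
      i_season <- match("season", pmv$term)
      rows[[k]] <- data.frame(
        group = grp, q = qq,
        R2_region = pmv$R2[i_region], F_region = pmv$F[i_region],
        p_region = pmv$p[i_region],
        R2_season = pmv$R2[i_season], F_season = pmv$F[i_season],
        p_season = pmv$p[i_season],
        F_ratio = pmv$F[i_region] / pmv$F[i_season],
        permdisp_F = pdp$F, permdisp_p = pdp$p_perm,
        percent_homogenization = pct,
        stringsAsFactors = FALSE)
      details[[paste(grp, qq, sep = "_q")]] <- list(permanova = pmv,
                                                    permdisp = pdp)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}
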