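#' @keywords internal
"_PACKAGE"

# Canonical rank names, outermost first.  Taxonomy tables must carry exactly
# these columns (plus feature_id); aggregation and label-based filtering key
# on them.
RANKS <- c("Domain", "Phylum", "Class", "Order", "Family", "Genus", "Species")

VALID_COMPARTMENTS <- c("fish", "water", "sediment", "algae", "seagrass", "turf")

#' Construct and validate a count table
#'
#' A count table is a samples x features matrix of non-negative integers with
#' unique sample ids as row names and unique feature ids as column names.
#' Features are either amplicon sequence variants (`"ASV"`) or KEGG Orthology
#' gene families (`"KO"`).
#'
#' @param counts Numeric matrix, samples in rows, features in columns, with
#'   dimnames set. Values must be non-negative and integer-valued.
#' @param feature_kind Either `"ASV"` or `"KO"`.
#' @return The validated matrix with class `count_table` and a `feature_kind`
#'   attribute.
#' @examples
#' m <- matrix(c(5, 2, 0, 0, 3, 7), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("f1", "f2")))
#' count_table(m)
#' @export
count_table <- function(counts, feature_kind = c("ASV", "KO")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("`counts` must be a numeric matrix (samples x features)")
  }
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stopf("count table is empty (%d samples x %d features)",
          nrow(counts), ncol(counts))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("count table needs sample ids (rownames) and feature ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) {
    stopf("duplicated sample ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stopf("duplicated feature ids: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  }
  bad <- which(is.na(counts) | counts < 0 | !is_wholenumber(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("non-integer or negative counts, e.g. sample '%s', feature '%s'",
          rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]])
  }
  counts <- round(counts)
  structure(counts, feature_kind = feature_kind,
            class = c("count_table", class(matrix())))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d %s features, total %s reads\n",
              nrow(x), ncol(x), attr(x, "feature_kind"),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

feature_kind <- function(table) attr(table, "feature_kind") %||% "ASV"

# strip class/attributes down to a plain numeric matrix
as_matrix <- function(table) {
  m <- unclass(table)
  attr(m, "feature_kind") <- NULL
  attr(m, "dropped_samples") <- NULL
  m
}

rebuild_table <- function(m, template) {
  count_table(m, feature_kind = feature_kind(template))
}

#' Read a count table from TSV or BIOM
#'
#' The TSV layout has sample ids in the first column and feature ids in the
#' header row. BIOM files (JSON or HDF5, as supported by the biomformat
#' package) store features x samples and are transposed on read.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @param feature_kind Passed to [count_table()].
#' @return A [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             feature_kind = c("ASV", "KO")) {
  format <- match.arg(format)
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L) {
      stopf("empty or malformed count table: %s", path)
    }
    ids <- as.character(df[[1L]])
    raw <- df[, -1L, drop = FALSE]
    m <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(ids, colnames(raw)))
    for (j in seq_len(ncol(raw))) {
      v <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(is.na(v) & !is.na(raw[[j]]))
      if (length(bad) > 0L) {
        stopf("non-numeric count at row '%s', column '%s' in %s",
              ids[bad[1L]], colnames(raw)[j], path)
      }
      m[, j] <- v
    }
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- t(methods::as(biomformat::biom_data(b), "matrix"))
    storage.mode(m) <- "double"
  }
  count_table(m, feature_kind = feature_kind)
}

#' Write a count table as TSV
#'
#' @param table A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), as_matrix(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or validate sample metadata
#'
#' Metadata is a data frame with one row per sample, columns `sample_id`,
#' `compartment`, `host_species`, `region`, `season`, `site`. Compartments are
#' restricted to fish, water, sediment, algae, seagrass and turf; fish samples
#' must carry a `host_species`.
#'
#' @param path TSV file with the columns above.
#' @return A data frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta Data frame of sample metadata.
#' @param table Optional [count_table()]; when given, every sample in the
#'   table must have exactly one metadata row.
#' @export
validate_sample_metadata <- function(meta, table = NULL) {
  need <- c("sample_id", "compartment", "region", "season")
  miss <- setdiff(need, colnames(meta))
  if (length(miss) > 0L) {
    stopf("metadata is missing columns: %s", paste(miss, collapse = ", "))
  }
  if (!"host_species" %in% colnames(meta)) meta$host_species <- NA_character_
  if (!"site" %in% colnames(meta)) meta$site <- NA_character_
  if (anyDuplicated(meta$sample_id)) {
    stopf("duplicated sample_id in metadata: %s",
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                collapse = ", "))
  }
  bad <- setdiff(unique(meta$compartment), VALID_COMPARTMENTS)
  if (length(bad) > 0L) {
    stopf("unknown compartment(s): %s", paste(bad, collapse = ", "))
  }
  fish <- meta$compartment == "fish"
  if (any(fish & (is.na(meta$host_species) | meta$host_species == ""))) {
    stopf("fish samples without host_species: %s",
          paste(meta$sample_id[fish & (is.na(meta$host_species) |
                                         meta$host_species == "")],
                collapse = ", "))
  }
  if (!is.null(table)) {
    miss <- setdiff(rownames(table), meta$sample_id)
    if (length(miss) > 0L) {
      stopf("samples missing from metadata: %s", paste(miss, collapse = ", "))
    }
  }
  meta
}

# align metadata rows to the samples of a table, in table order
align_metadata <- function(meta, table) {
  meta <- validate_sample_metadata(meta, table)
  meta[match(rownames(table), meta$sample_id), , drop = FALSE]
}

#' Read a taxonomy table
#'
#' A taxonomy table maps each feature id to labels for the seven canonical
#' ranks (Domain through Species); unassigned labels are written
#' `"unassigned"`.
#'
#' @param path TSV with columns `feature_id`, `Domain`, `Phylum`, `Class`,
#'   `Order`, `Family`, `Genus`, `Species`.
#' @return A data frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tax <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  validate_taxonomy(tax)
}

#' @rdname read_taxonomy
#' @param tax Data frame to validate.
#' @export
validate_taxonomy <- function(tax) {
  miss <- setdiff(c("feature_id", RANKS), colnames(tax))
  if (length(miss) > 0L) {
    stopf("taxonomy is missing columns: %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tax$feature_id)) {
    stopf("duplicated feature_id in taxonomy")
  }
  for (r in RANKS) {
    tax[[r]] <- ifelse(is.na(tax[[r]]) | tax[[r]] == "", "unassigned", tax[[r]])
  }
  tax[, c("feature_id", RANKS)]
}

#' Read a rooted phylogeny over features
#'
#' Reads a Newick tree, checks that it is rooted with unique leaf labels and
#' finite non-negative branch lengths, and warns when it is not ultrametric
#' within tolerance (phylogenetic Hill numbers assume branch lengths in
#' time-like units after ultrametricization).
#'
#' @param path Newick file.
#' @param tol Relative tolerance on tip-depth spread for the ultrametricity
#'   check.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_feature_tree <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tree <- ape::read.tree(path)
  validate_feature_tree(tree, tol = tol)
}

#' @rdname read_feature_tree
#' @param tree A `phylo` object.
#' @export
validate_feature_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stopf("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stopf("duplicated leaf labels in tree")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0)) {
    stopf("tree must have finite non-negative branch lengths")
  }
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (diff(range(depths)) > tol * max(max(depths), 1)) {
    warnf("tree is not ultrametric (tip depth spread %.3g); phylogenetic Hill numbers assume an ultrametric tree",
          diff(range(depths)))
  }
  tree
}

#' Remove rare and excluded features
#'
#' Drops features observed in `min_samples` samples or fewer, and features
#' whose taxonomy matches any excluded label at any rank (by default
#' chloroplast and mitochondrial sequences). Feature order is preserved and
#' the operation is idempotent.
#'
#' @param table A [count_table()].
#' @param taxonomy Taxonomy data frame covering every feature; may be `NULL`
#'   when `exclude_labels` is empty.
#' @param min_samples Features present (count > 0) in this many samples or
#'   fewer are removed. Default 3.
#' @param exclude_labels Character vector of rank labels; a feature carrying
#'   any of them at any rank is removed.
#' @return Filtered [count_table()]; removed feature ids are in attribute
#'   `removed_features`.
#' @export
filter_features <- function(table, taxonomy = NULL, min_samples = 3,
                            exclude_labels = c("Chloroplast", "Mitochondria")) {
  if (min_samples < 0) stopf("min_samples must be >= 0")
  m <- as_matrix(table)
  keep <- colSums(m > 0) > min_samples
  if (length(exclude_labels) > 0L) {
    if (is.null(taxonomy)) {
      stopf("taxonomy is required when exclude_labels is non-empty")
    }
    taxonomy <- validate_taxonomy(taxonomy)
    miss <- setdiff(colnames(m), taxonomy$feature_id)
    if (length(miss) > 0L) {
      stopf("features missing from taxonomy: %s", paste(miss, collapse = ", "))
    }
    lab <- as.matrix(taxonomy[match(colnames(m), taxonomy$feature_id), RANKS])
    excluded <- rowSums(matrix(lab %in% exclude_labels, nrow = nrow(lab))) > 0
    keep <- keep & !excluded
  }
  if (!any(keep)) stopf("no features left after filtering")
  out <- rebuild_table(m[, keep, drop = FALSE], table)
  attr(out, "removed_features") <- colnames(m)[!keep]
  out
}

#' Rarefy samples to equal depth
#'
#' Subsamples each sample without replacement (multivariate hypergeometric
#' draw) to exactly `depth` reads. Samples with fewer than `depth` total reads
#' are dropped and listed in the `dropped_samples` attribute.
#'
#' @param table A [count_table()].
#' @param depth Target depth per sample (default 2000).
#' @param seed Integer seed; the same seed reproduces the same subsample.
#' @return Rarefied [count_table()] with attribute `dropped_samples`.
#' @export
rarefy <- function(table, depth = 2000, seed = NULL) {
  if (depth < 1) stopf("rarefaction depth must be >= 1")
  m <- as_matrix(table)
  totals <- rowSums(m)
  dropped <- rownames(m)[totals < depth]
  m <- m[totals >= depth, , drop = FALSE]
  if (nrow(m) == 0L) stopf("no sample reaches depth %d", depth)
  rar <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    # rrarefy flags tables without singleton counts as suspicious; counts
    # are already validated as integers here
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- rebuild_table(rar, table)
  attr(out, "dropped_samples") <- dropped
  out
}

#' Close counts to relative abundances
#'
#' @param table A [count_table()] (or plain matrix) with positive row sums.
#' @return Matrix of proportions; every row sums to 1.
#' @export
to_relative <- function(table) {
  m <- if (inherits(table, "count_table")) as_matrix(table) else as.matrix(table)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stopf("sample(s) with zero total count: %s",
          paste(rownames(m)[totals <= 0], collapse = ", "))
  }
  sweep(m, 1L, totals, "/")
}

#' Aggregate features to a taxonomic rank
#'
#' Sums counts of features sharing the same label at the requested rank.
#' `rank = "ASV"` returns the table unchanged. Features labelled
#' `"unassigned"` at the target rank are pooled per distinct upstream lineage
#' (so unassigned families from different phyla stay apart). Per-sample totals
#' are conserved exactly.
#'
#' @param table A [count_table()].
#' @param taxonomy Taxonomy covering every feature.
#' @param rank `"ASV"` or one of the seven rank names.
#' @return Aggregated [count_table()].
#' @export
aggregate_rank <- function(table, taxonomy, rank = c("ASV", RANKS)) {
  rank <- match.arg(rank)
  if (rank == "ASV") return(table)
  taxonomy <- validate_taxonomy(taxonomy)
  m <- as_matrix(table)
  miss <- setdiff(colnames(m), taxonomy$feature_id)
  if (length(miss) > 0L) {
    stopf("features missing from taxonomy: %s", paste(miss, collapse = ", "))
  }
  idx <- match(colnames(m), taxonomy$feature_id)
  upto <- RANKS[seq_len(match(rank, RANKS))]
  lab <- taxonomy[[rank]][idx]
  path <- apply(taxonomy[idx, upto, drop = FALSE], 1L,
                paste, collapse = "|")
  key <- ifelse(lab == "unassigned", paste0("unassigned|", path), lab)
  agg <- t(rowsum(t(m), group = key, reorder = FALSE))
  rebuild_table(agg, table)
}
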