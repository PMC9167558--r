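# End-to-end orchestration: simulate or ingest tables, clean and (optionally)
# rarefy, compute Hill dissimilarity matrices, bootstrap the consensus core,
# run PERMANOVA / PERMDISP, differential abundance, the homogenization
# report and the SCFA functional analysis, writing versioned artifacts plus
# a manifest with checksums. Every stochastic stage draws its seed from a
# sub-stream of the master seed so stages are individually reproducible.

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_pipeline()]'s
#'   config list (see that help page).
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  yaml::read_yaml(path)
}

pipeline_defaults <- function(config) {
  defaults <- list(
    rarefy_depth = 2000,
    apply_rarefaction = FALSE,
    filter_min_samples = 3,
    exclude_labels = c("Chloroplast", "Mitochondria"),
    core_B = 1000,
    core_threshold = 0.8,
    core_n_boot = NULL,
    n_perm = 999,
    permanova_terms = c("region", "season", "region:season"),
    native_region = NULL,
    seed = 1L,
    run_scfa = TRUE,
    hill_configs = NULL
  )
  utils::modifyList(defaults, config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation from a scenario or
#' reading from paths), feature filtering, optional rarefaction, Hill
#' dissimilarity matrices for the configured index set, bootstrap consensus
#' core, PERMANOVA and PERMDISP per species, Kruskal-Wallis differential
#' abundance per rank, the homogenization report, and the SCFA functional
#' analysis. All artifacts are written under `out_dir` and listed, with MD5
#' checksums, in `manifest.json`; re-running with the same config reproduces
#' identical artifacts.
#'
#' @param config List (or path to a YAML file) with entries: either
#'   `scenario` (arguments to [synthetic_scenario()]) or `paths` (named
#'   `counts`, `metadata`, `taxonomy`, `tree`, `ko`); `out_dir`; optional
#'   `apply_rarefaction`, `rarefy_depth` (default 2000),
#'   `filter_min_samples` (default 3), `core_B` (default 1000),
#'   `core_threshold` (default 0.8), `core_n_boot` (named per species),
#'   `n_perm` (default 999), `permanova_terms`, `native_region`, `seed`,
#'   `run_scfa`.
#' @return Manifest list (also written as JSON), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- pipeline_defaults(config)
  if (is.null(cfg$out_dir)) stopf("config needs an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  artifacts <- character(0)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # --- acquire data -------------------------------------------------------
  dat <- run_stage("input", {
    if (!is.null(cfg$scenario)) {
      sc_args <- cfg$scenario
      if (is.null(sc_args$seed)) sc_args$seed <- derive_seed(seed, 10L)
      scenario <- do.call(synthetic_scenario, sc_args)
      sim <- simulate_dataset(scenario)
      say("simulated %d samples x %d features (seed %d)",
          nrow(sim$counts), ncol(sim$counts), scenario$seed)
      sim
    } else if (!is.null(cfg$paths)) {
      p <- cfg$paths
      list(counts = read_count_table(p$counts),
           meta = read_sample_metadata(p$metadata),
           taxonomy = read_taxonomy(p$taxonomy),
           tree = if (!is.null(p$tree)) read_feature_tree(p$tree) else NULL,
           ko_table = if (!is.null(p$ko))
             read_count_table(p$ko, feature_kind = "KO") else NULL,
           truth = NULL)
    } else {
      stopf("config needs either a 'scenario' or 'paths'")
    }
  })

  configs <- run_stage("config", {
    if (is.null(cfg$hill_configs)) {
      default_hill_configs(include_phylo = !is.null(dat$tree))
    } else {
      as.data.frame(cfg$hill_configs)
    }
  })
  if (any(configs$facet == "phylogenetic") && is.null(dat$tree)) {
    stopf("pipeline stage 'config' failed: phylogenetic facet requested but no tree supplied")
  }

  # --- clean --------------------------------------------------------------
  counts <- run_stage("filter", {
    out <- filter_features(dat$counts, dat$taxonomy,
                           min_samples = cfg$filter_min_samples,
                           exclude_labels = cfg$exclude_labels)
    say("filter: %d -> %d features", ncol(dat$counts), ncol(out))
    out
  })
  if (isTRUE(cfg$apply_rarefaction)) {
    counts <- run_stage("rarefy", {
      out <- rarefy(counts, depth = cfg$rarefy_depth,
                    seed = derive_seed(seed, 20L))
      dropped <- attr(out, "dropped_samples")
      say("rarefied to %d (%d sample(s) dropped)", cfg$rarefy_depth,
          length(dropped))
      out
    })
  }
  meta <- align_metadata(dat$meta, counts)
  write_count_table(counts, file.path(cfg$out_dir, "counts_clean.tsv"))
  artifacts <- c(artifacts, "counts_clean.tsv")

  # --- dissimilarity matrices --------------------------------------------
  dms <- run_stage("diversity", {
    out <- dissimilarity_set(counts, configs, taxonomy = dat$taxonomy,
                             tree = dat$tree)
    for (nm in names(out)) {
      write_dissimilarity(out[[nm]], file.path(cfg$out_dir,
                                               paste0("dissim_", nm, ".tsv")))
    }
    artifacts <- c(artifacts, paste0("dissim_", names(out), ".tsv"))
    say("computed %d dissimilarity matrices", length(out))
    out
  })

  species <- sort(unique(meta$host_species[meta$compartment == "fish"]))
  regions <- unique(meta$region)
  native <- cfg$native_region %||% regions[1L]

  # --- core microbiome ----------------------------------------------------
  core <- run_stage("core", {
    entries <- list()
    k <- 0L
    for (sp in species) {
      sizes <- table(meta$region[meta$host_species == sp &
                                   meta$compartment == "fish"])
      n_boot <- cfg$core_n_boot[[sp]] %||% max(2L, min(sizes))
      for (rg in names(sizes)) {
        k <- k + 1L
        entries[[k]] <- bootstrap_core(counts, meta, sp, rg,
                                       n_boot = n_boot, B = cfg$core_B,
                                       threshold = cfg$core_threshold,
                                       seed = derive_seed(seed, 30L + k))
      }
    }
    cons <- consensus_union(entries)
    utils::write.table(cons$frequencies,
                       file.path(cfg$out_dir, "core_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "core_frequencies.tsv")
    say("consensus core: %d features", length(cons$consensus))
    cons
  })

  # --- multivariate tests -------------------------------------------------
  tests <- run_stage("permanova", {
    rows <- list()
    for (sp in species) {
      sel <- meta$host_species == sp & meta$compartment == "fish"
      for (nm in names(dms)) {
        d <- dms[[nm]][meta$sample_id[sel], meta$sample_id[sel]]
        pmv <- permanova(d, meta[sel, , drop = FALSE],
                         terms = cfg$permanova_terms, n_perm = cfg$n_perm,
                         seed = derive_seed(seed, 50L))
        pmv$species <- sp
        pmv$config <- nm
        rows[[paste(sp, nm)]] <- as.data.frame(pmv)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(cfg$out_dir, "permanova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "permanova.tsv")
    tab
  })

  # --- differential abundance --------------------------------------------
  run_stage("differential_abundance", {
    for (sp in species) {
      sel <- meta$host_species == sp & meta$compartment == "fish"
      sub <- rebuild_table(as_matrix(counts)[meta$sample_id[sel], ,
                                             drop = FALSE], counts)
      res <- list()
      for (rk in c("Phylum", "Family", "ASV")) {
        agg <- aggregate_rank(sub, dat$taxonomy, rk)
        res[[rk]] <- kruskal_per_feature(to_relative(agg),
                                         meta$region[sel])
      }
      summ <- significance_summary(res, which = "raw")
      utils::write.table(summ,
                         file.path(cfg$out_dir,
                                   paste0("diffabund_summary_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts <- c(artifacts, paste0("diffabund_summary_", sp, ".tsv"))
    }
    NULL
  })

  # --- homogenization -----------------------------------------------------
  homog <- run_stage("homogenization", {
    inv <- setdiff(regions, native)
    rep <- homogenization_report(dms, meta, species[1:2], native, inv)
    utils::write.table(rep$intraspecific,
                       file.path(cfg$out_dir, "homogenization_intra.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rep$interspecific,
                       file.path(cfg$out_dir, "homogenization_inter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "homogenization_intra.tsv",
                    "homogenization_inter.tsv")
    say("trajectory: %s", rep$trajectory$scenario)
    rep
  })

  # --- SCFA functional ----------------------------------------------------
  if (isTRUE(cfg$run_scfa) && !is.null(dat$ko_table)) {
    run_stage("scfa", {
      grp <- default_scfa_groups(colnames(dat$ko_table))
      sp <- species[1L]
      sel <- meta$host_species == sp & meta$compartment == "fish"
      ko_sub <- rebuild_table(as_matrix(dat$ko_table)[meta$sample_id[sel], ,
                                                      drop = FALSE],
                              dat$ko_table)
      res <- scfa_beta_analysis(ko_sub, meta[sel, , drop = FALSE], grp,
                                n_perm = min(cfg$n_perm, 199),
                                seed = derive_seed(seed, 70L),
                                reference_region = native,
                                comparison_region = setdiff(regions,
                                                            native)[1L])
      utils::write.table(res, file.path(cfg$out_dir, "scfa_beta.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts <- c(artifacts, "scfa_beta.tsv")
      NULL
    })
  }

  # --- manifest -----------------------------------------------------------
  paths <- file.path(cfg$out_dir, artifacts)
  manifest <- list(
    seed = seed,
    native_region = native,
    species = species,
    trajectory = homog$trajectory$scenario,
    consensus_core_size = length(core$consensus),
    artifacts = data.frame(file = artifacts,
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE),
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
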