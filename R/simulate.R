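# Dirichlet-multinomial community simulator with planted structure: a
# log-normal baseline rank-abundance profile shared across groups, a set of
# evenly-spread core features, region-specific log-fold abundance shifts, a
# small seasonal effect, and group-specific Dirichlet concentration theta
# controlling inter-individual dispersion (higher theta = more homogeneous
# hosts). Every downstream stage of the pipeline can be validated against the
# planted ground truth.

#' Define a synthetic multi-region, multi-species scenario
#'
#' Defaults emulate a two-species Lessepsian invasion design: both species
#' sampled in their native region and two invaded regions, in two seasons,
#' with inter-individual dispersion decreasing (theta increasing) along the
#' invasion gradient, i.e. planted microbiome homogenization.
#'
#' @param n_features Number of ASVs (default 150).
#' @param species Species labels (first is used as-is in group tables).
#' @param regions Region labels; the first is the native region.
#' @param seasons Season labels.
#' @param n_per_group Named integer vector of samples per species, per
#'   region x season cell (defaults: 21 for the first species, 5 for the
#'   second, echoing a design with many hosts of a common invader and few of
#'   a rarer one).
#' @param baseline_logsd Log-normal sd of the baseline abundance profile.
#' @param dispersion_theta Named vector region -> Dirichlet concentration;
#'   may also be named `"species|region"` for species-specific values.
#' @param core_fraction Fraction of features planted as core (default 0.1).
#' @param core_mass Total relative abundance shared evenly by core features
#'   in every group profile (default 0.5).
#' @param core_evenness Concentration multiplier for the core block (default
#'   8): core taxa are modelled as consistent colonizers, drawn from their
#'   own Dirichlet with concentration `theta * core_evenness`, so their
#'   occupancy stays near 1 while non-core taxa keep the group's
#'   inter-individual dispersion.
#' @param shift_fraction Fraction of non-core features receiving a planted
#'   abundance shift in invaded regions.
#' @param shift_logfold Log-fold magnitude of the planted regional shifts.
#' @param season_logfold Log-fold magnitude of the seasonal effect (applied
#'   to a random 10% of features in the second season).
#' @param depth_mean,depth_sd Sequencing depth model (normal, truncated at
#'   100).
#' @param n_kos Number of KEGG Orthology features in the derived KO table.
#' @param ko_density Fraction of non-zero entries in the feature x KO
#'   incidence map.
#' @param seed Integer seed controlling every random element.
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_features = 150,
                               species = c("S_rivulatus", "S_luridus"),
                               regions = c("RedSea", "Levantine", "Crete"),
                               seasons = c("spring", "autumn"),
                               n_per_group = NULL,
                               baseline_logsd = 1.5,
                               dispersion_theta = c(RedSea = 30,
                                                    Levantine = 80,
                                                    Crete = 200),
                               core_fraction = 0.1,
                               core_mass = 0.5,
                               core_evenness = 8,
                               shift_fraction = 0.3,
                               shift_logfold = 1.5,
                               season_logfold = 0.3,
                               depth_mean = 6000,
                               depth_sd = 1500,
                               n_kos = 120,
                               ko_density = 0.05,
                               seed = 1L) {
  if (is.null(n_per_group)) {
    n_per_group <- stats::setNames(c(21L, rep(5L, length(species) - 1L)),
                                   species)
  }
  n_per_group <- unlist(n_per_group)  # accept YAML-style lists
  if (is.null(names(n_per_group)) && length(n_per_group) == length(species)) {
    names(n_per_group) <- species
  }
  dispersion_theta <- unlist(dispersion_theta)
  if (any(n_per_group < 2L)) stopf("all group sizes must be >= 2")
  if (core_fraction < 0 || core_fraction > 1) {
    stopf("core_fraction must be in [0, 1]")
  }
  if (any(dispersion_theta <= 0)) stopf("dispersion theta must be > 0")
  structure(list(
    n_features = n_features, species = species, regions = regions,
    seasons = seasons, n_per_group = n_per_group,
    baseline_logsd = baseline_logsd, dispersion_theta = dispersion_theta,
    core_fraction = core_fraction, core_mass = core_mass,
    core_evenness = core_evenness,
    shift_fraction = shift_fraction, shift_logfold = shift_logfold,
    season_logfold = season_logfold, depth_mean = depth_mean,
    depth_sd = depth_sd, n_kos = n_kos, ko_density = ko_density,
    seed = as.integer(seed)
  ), class = "synthetic_scenario")
}

theta_for <- function(scenario, species, region) {
  th <- scenario$dispersion_theta
  key <- paste(species, region, sep = "|")
  if (key %in% names(th)) return(unname(th[[key]]))
  if (region %in% names(th)) return(unname(th[[region]]))
  stopf("no dispersion theta defined for %s / %s", species, region)
}

# deterministic structural elements shared by simulate_dataset() and
# expected_dispersion(): baseline profile, core set, shifts, group profiles
scenario_structure <- function(scenario) {
  with_seed(scenario$seed, {
    F <- scenario$n_features
    ids <- sprintf("ASV%04d", seq_len(F))
    n_core <- round(scenario$core_fraction * F)
    core <- if (n_core > 0) sample(ids, n_core) else character(0)
    base <- stats::rlnorm(F, meanlog = 0, sdlog = scenario$baseline_logsd)
    names(base) <- ids
    noncore <- setdiff(ids, core)
    # core features share core_mass evenly; non-core keep the log-normal
    # shape on the remaining mass
    prof <- base
    if (n_core > 0) {
      prof[core] <- scenario$core_mass / n_core
      prof[noncore] <- base[noncore] / sum(base[noncore]) *
        (1 - scenario$core_mass)
    } else {
      prof <- base / sum(base)
    }
    n_shift <- round(scenario$shift_fraction * length(noncore))
    shifted <- if (n_shift > 0) sample(noncore, n_shift) else character(0)
    shift_sign <- stats::setNames(sample(c(-1, 1), n_shift, replace = TRUE),
                                  shifted)
    season_feats <- sample(ids, max(1, round(0.1 * F)))
    profiles <- list()
    for (sp in scenario$species) {
      for (rg in scenario$regions) {
        for (se in scenario$seasons) {
          p <- prof
          if (rg != scenario$regions[1L] && n_shift > 0) {
            grad <- match(rg, scenario$regions) - 1L  # stronger further out
            p[shifted] <- p[shifted] *
              exp(shift_sign * scenario$shift_logfold * grad /
                    max(1L, length(scenario$regions) - 1L))
          }
          if (se != scenario$seasons[1L]) {
            p[season_feats] <- p[season_feats] * exp(scenario$season_logfold)
          }
          profiles[[paste(sp, rg, se, sep = "|")]] <- p / sum(p)
        }
      }
    }
    list(feature_ids = ids, core = sort(core), shifted = shifted,
         shift_sign = shift_sign, season_features = season_feats,
         profiles = profiles)
  })
}

rdirichlet_one <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) {  # numerically degenerate draw; fall back to argmax mass
    x <- as.numeric(seq_along(alpha) == which.max(alpha))
  }
  x / sum(x)
}

# one host's composition: core taxa form their own high-concentration
# Dirichlet block (consistent colonizers), non-core taxa carry the group's
# dispersion theta; block weights come from the group mean profile so
# E[composition] = pi_g
draw_composition <- function(pi_g, core_ids, theta, core_evenness) {
  is_core <- names(pi_g) %in% core_ids
  if (!any(is_core)) return(rdirichlet_one(theta * pi_g))
  w_core <- sum(pi_g[is_core])
  comp <- numeric(length(pi_g))
  names(comp) <- names(pi_g)
  comp[is_core] <- w_core *
    rdirichlet_one(theta * core_evenness * pi_g[is_core] / w_core)
  comp[!is_core] <- (1 - w_core) *
    rdirichlet_one(theta * pi_g[!is_core] / (1 - w_core))
  comp
}

draw_depth <- function(n, scenario) {
  pmax(100L, as.integer(round(stats::rnorm(n, scenario$depth_mean,
                                           scenario$depth_sd))))
}

#' Simulate a full multi-region, multi-species dataset
#'
#' Per sample, a composition is drawn from
#' `Dirichlet(theta_g * pi_g)` where `pi_g` is the group mean profile
#' (baseline with planted core boost, regional shifts and season effect),
#' then counts from `Multinomial(depth, composition)`. The feature tree is a
#' pure-birth (Yule) tree rescaled to unit height; the taxonomy nests random
#' family labels within random phylum labels; the KO table is a fixed linear
#' map of the taxon counts (rounded), emulating gene-content inference
#' without any claim of mimicking real KEGG content.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `counts` ([count_table()]), `meta` (data frame),
#'   `taxonomy`, `tree` (`phylo`), `ko_table` ([count_table()]), and `truth`
#'   (list: `core`, `shifted`, `shift_sign`, `theta`, `dispersion_change`).
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  st <- scenario_structure(scenario)
  F <- scenario$n_features
  ids <- st$feature_ids

  groups <- expand.grid(species = scenario$species, region = scenario$regions,
                        season = scenario$seasons, stringsAsFactors = FALSE)
  counts <- NULL
  meta_rows <- list()
  with_seed(derive_seed(scenario$seed, 1L), {
    for (g in seq_len(nrow(groups))) {
      sp <- groups$species[g]; rg <- groups$region[g]; se <- groups$season[g]
      ng <- unname(scenario$n_per_group[[sp]])
      pi_g <- st$profiles[[paste(sp, rg, se, sep = "|")]]
      theta <- theta_for(scenario, sp, rg)
      depths <- draw_depth(ng, scenario)
      block <- matrix(0L, ng, F)
      for (i in seq_len(ng)) {
        comp <- draw_composition(pi_g, st$core, theta, scenario$core_evenness)
        block[i, ] <- as.integer(stats::rmultinom(1L, depths[i], comp))
      }
      spi <- match(sp, scenario$species)
      rownames(block) <- sprintf("sp%d_%s_%s_%02d", spi, rg, se, seq_len(ng))
      counts <- rbind(counts, block)
      meta_rows[[g]] <- data.frame(
        sample_id = rownames(block), compartment = "fish", host_species = sp,
        region = rg, season = se,
        site = paste0(rg, "_site", sample.int(3L, ng, replace = TRUE)),
        stringsAsFactors = FALSE)
    }
  })
  colnames(counts) <- ids
  meta <- do.call(rbind, meta_rows)

  tree <- with_seed(derive_seed(scenario$seed, 2L), {
    tr <- ape::rphylo(F, birth = 1, death = 0)
    tr$tip.label <- sample(ids)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr
  })

  taxonomy <- with_seed(derive_seed(scenario$seed, 3L), {
    # skewed phylum sizes: a few dominant phyla plus a tail of small ones,
    # so presence-absence composition still varies at coarse ranks
    n_phyla <- 10L
    phyla <- sprintf("Phylum%02d", seq_len(n_phyla))
    ph <- sample(phyla, F, replace = TRUE,
                 prob = rev(seq_len(n_phyla))^3)
    fam <- paste0(sub("Phylum", "Fam", ph), "_",
                  sample.int(4L, F, replace = TRUE))
    # leave a slice of features unassigned below phylum
    unass <- stats::runif(F) < 0.15
    fam[unass] <- "unassigned"
    data.frame(feature_id = ids, Domain = "Bacteria", Phylum = ph,
               Class = "unassigned", Order = "unassigned", Family = fam,
               Genus = "unassigned", Species = "unassigned",
               stringsAsFactors = FALSE)
  })

  ko <- with_seed(derive_seed(scenario$seed, 4L), {
    ko_ids <- sprintf("K%05d", seq_len(scenario$n_kos))
    map <- matrix(0, F, scenario$n_kos, dimnames = list(ids, ko_ids))
    nz <- stats::runif(length(map)) < scenario$ko_density
    map[nz] <- stats::rgamma(sum(nz), shape = 2, rate = 2)
    # every KO gets at least one contributing taxon
    empty <- which(colSums(map) == 0)
    for (j in empty) map[sample.int(F, 1L), j] <- stats::rgamma(1, 2, 2)
    list(map = map, table = round(counts %*% map))
  })

  truth <- list(core = st$core, shifted = st$shifted,
                shift_sign = st$shift_sign,
                theta = stats::setNames(
                  vapply(scenario$regions,
                         function(r) theta_for(scenario, scenario$species[1L], r),
                         numeric(1)),
                  scenario$regions),
                ko_map = ko$map)

  list(counts = count_table(counts, "ASV"), meta = meta, taxonomy = taxonomy,
       tree = tree, ko_table = count_table(ko$table, "KO"), truth = truth)
}

#' Monte-Carlo expected within-group dispersion
#'
#' Estimates the expected mean pairwise abundance-weighted (q = 1) taxonomic
#' dissimilarity between two hosts of one (species, region) group, by
#' repeatedly simulating host pairs from the scenario's
#' Dirichlet-multinomial model. Serves as the parameter-recovery oracle for
#' the homogenization analysis.
#'
#' @param scenario A [synthetic_scenario()].
#' @param species,region Group selectors.
#' @param n_rep Number of simulated pairs (default 200).
#' @param seed Seed for the Monte-Carlo draws (defaults to a sub-stream of
#'   the scenario seed).
#' @return List with `mean`, `se` (Monte-Carlo standard error), `n_rep`.
#' @export
expected_dispersion <- function(scenario, species, region, n_rep = 200,
                                seed = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!region %in% scenario$regions) stopf("unknown region '%s'", region)
  if (!species %in% scenario$species) stopf("unknown species '%s'", species)
  st <- scenario_structure(scenario)
  theta <- theta_for(scenario, species, region)
  seed <- seed %||% derive_seed(scenario$seed, 97L)
  vals <- with_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      se <- scenario$seasons[1L + (r %% length(scenario$seasons))]
      pi_g <- st$profiles[[paste(species, region, se, sep = "|")]]
      depths <- draw_depth(2L, scenario)
      p1 <- as.numeric(stats::rmultinom(
        1L, depths[1L],
        draw_composition(pi_g, st$core, theta, scenario$core_evenness)))
      p2 <- as.numeric(stats::rmultinom(
        1L, depths[2L],
        draw_composition(pi_g, st$core, theta, scenario$core_evenness)))
      hill_beta_pair(p1 / sum(p1), p2 / sum(p2), q = 1)
    }, numeric(1))
  })
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(n_rep), n_rep = n_rep)
}

#' Write all artifacts of a simulated dataset to disk
#'
#' Writes the count table, metadata, taxonomy (TSV), tree (Newick) and KO
#' table in the formats understood by the readers of this package.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    tree = file.path(dir, "tree.nwk"),
    ko = file.path(dir, "ko_counts.tsv")
  )
  write_count_table(sim$counts, paths[["counts"]])
  utils::write.table(sim$meta, paths[["metadata"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$taxonomy, paths[["taxonomy"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, paths[["tree"]])
  write_count_table(sim$ko_table, paths[["ko"]])
  invisible(paths)
}
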