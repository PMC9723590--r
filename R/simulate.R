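# Synthetic community generator.
#
# Emulates the study design the package targets: a small host clade (three
# families of unevenly sampled species), a microbial phylogeny whose deep
# clades can carry diet-associated effects while shallow structure tracks
# the host phylogeny, per-species and per-individual noise, and multinomial
# read sampling at uneven depth. Controls can be spiked with a known
# contaminant ASV set to exercise the QC filters.

#' Configuration for the synthetic community generator
#'
#' Defaults mirror the sampling design of a 15-species, 3-family host
#' clade with 1-30 fecal samples per species and read depths of at least
#' 2000.
#'
#' @param n_species Number of host species.
#' @param family_sizes Integer partition of the species into family clades.
#' @param samples_per_species Samples collected per species (recycled if
#'   scalar). The default is the uneven per-species sampling of a field
#'   study (1 to 30 samples per species, 160 in total).
#' @param n_asvs Number of (non-contaminant) ASVs.
#' @param read_depth_range Per-sample sequencing depth is drawn uniformly
#'   from this range (default 2000-10000 reads).
#' @param sigma_phy Brownian-motion rate of the host-structured per-ASV
#'   effects (variance accrued over the unit-depth host tree); 0 switches
#'   phylosymbiosis off.
#' @param beta_diet Effect size of the diet trait on deep-clade ASVs;
#'   0 switches the diet effect off.
#' @param tau_deep Relative depth (0-1) of the cut defining "deep"
#'   microbial clades: lineages crossing this depth with at least two
#'   descendant tips form diet-responsive clades.
#' @param lambda_diet Pagel's lambda of the simulated diet trait (how
#'   phylogenetically structured diet itself is).
#' @param sigma_noise Per-(species, ASV) log-abundance noise sd.
#' @param sigma_individual Per-(sample, ASV) log-abundance noise sd.
#' @param n_controls Number of PCR negative-control samples.
#' @param n_contaminants Number of contaminant ASVs spiked into controls
#'   (and, at trace counts, into true samples).
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical datasets.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 15,
                              family_sizes = c(5, 7, 3),
                              samples_per_species = c(11, 1, 30, 9, 6, 16, 18,
                                                      12, 7, 17, 3, 4, 6, 13, 7),
                              n_asvs = 150,
                              read_depth_range = c(2000, 10000),
                              sigma_phy = 9,
                              beta_diet = 1,
                              tau_deep = 0.3,
                              lambda_diet = 0.7,
                              sigma_noise = 0.25,
                              sigma_individual = 0.5,
                              n_controls = 10,
                              n_contaminants = 10,
                              seed = 1) {
  cfg <- list(n_species = as.integer(n_species),
              family_sizes = as.integer(family_sizes),
              samples_per_species = as.integer(rep_len(samples_per_species, n_species)),
              n_asvs = as.integer(n_asvs),
              read_depth_range = as.integer(read_depth_range),
              sigma_phy = sigma_phy, beta_diet = beta_diet,
              tau_deep = tau_deep, lambda_diet = lambda_diet,
              sigma_noise = sigma_noise, sigma_individual = sigma_individual,
              n_controls = as.integer(n_controls),
              n_contaminants = as.integer(n_contaminants),
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_species < 3) stop("need at least 3 species", call. = FALSE)
  if (sum(cfg$family_sizes) != cfg$n_species || any(cfg$family_sizes < 1)) {
    stop("`family_sizes` must be a positive partition of `n_species`", call. = FALSE)
  }
  if (any(cfg$samples_per_species < 1)) stop("samples_per_species must be >= 1", call. = FALSE)
  if (cfg$n_asvs < 10) stop("need at least 10 ASVs", call. = FALSE)
  if (cfg$read_depth_range[1] < 1 || diff(cfg$read_depth_range) < 0) {
    stop("invalid read_depth_range", call. = FALSE)
  }
  for (v in c("sigma_phy", "beta_diet", "sigma_noise", "sigma_individual")) {
    if (cfg[[v]] < 0) stop("`", v, "` must be >= 0", call. = FALSE)
  }
  if (cfg$tau_deep < 0 || cfg$tau_deep > 1) stop("`tau_deep` must be in [0, 1]", call. = FALSE)
  if (cfg$lambda_diet < 0 || cfg$lambda_diet > 1) stop("`lambda_diet` must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Simulate a pure-birth (Yule) tree rescaled to unit depth
#'
#' @param n_tips Number of tips (>= 3 unless `labels` are supplied).
#' @param seed Optional integer seed.
#' @param labels Optional tip labels (default `t1`, `t2`, ...).
#' @return An ultrametric [ape::phylo] tree with root-to-tip depth 1.
#' @export
simulate_yule_tree <- function(n_tips, seed = NULL, labels = NULL) {
  if (n_tips < 3) stop("need at least 3 tips", call. = FALSE)
  if (!is.null(seed)) set.seed(derive_seed(seed, "yule"))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_tips)
    tree$tip.label <- labels
  }
  tree
}

# Yule subtree whose tips sit exactly `depth` below its root node; the
# returned Newick fragment carries no stem. Single tips have no internal
# structure, which the caller absorbs into the stem.
yule_subtree_newick <- function(labels, depth) {
  k <- length(labels)
  if (k == 1) return(list(newick = labels, internal_depth = 0))
  if (k == 2) {
    return(list(newick = sprintf("(%s:%g,%s:%g)", labels[1], depth,
                                 labels[2], depth),
                internal_depth = depth))
  }
  tr <- ape::rphylo(k, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * depth
  tr$tip.label <- labels
  list(newick = sub(";$", "", ape::write.tree(tr)), internal_depth = depth)
}

# Host tree with the family partition expressed as monophyletic clades
# hanging off a fixed backbone; unit root-to-tip depth. The first two
# families are sisters (splitting at depth 0.25), remaining families attach
# at the root; every family crown sits at depth 0.5.
simulate_host_tree <- function(cfg) {
  species <- sprintf("species_%02d", seq_len(cfg$n_species))
  fams <- split(species, rep(seq_along(cfg$family_sizes), cfg$family_sizes))
  sub_depth <- 0.5
  subs <- lapply(fams, yule_subtree_newick, depth = sub_depth)
  # stem from the attach point down to each family crown (absorbing the
  # missing internal depth of singleton families)
  stem <- function(i, attach_depth) {
    attach_depth_to_crown <- sub_depth - attach_depth
    sprintf("%s:%g", subs[[i]]$newick,
            attach_depth_to_crown + (sub_depth - subs[[i]]$internal_depth))
  }
  if (length(subs) == 2) {
    nwk <- sprintf("(%s,%s);", stem(1, 0), stem(2, 0))
  } else {
    inner <- sprintf("(%s,%s):0.25", stem(1, 0.25), stem(2, 0.25))
    rest <- vapply(seq_along(subs)[-(1:2)], stem, character(1), attach_depth = 0)
    nwk <- sprintf("(%s,%s);", inner, paste(rest, collapse = ","))
  }
  list(tree = read_newick(text = nwk), families = fams)
}

#' Simulate a Brownian-motion trait on a tree
#'
#' One multivariate-normal draw with covariance `rate * V(lambda)`, where
#' `V` is the shared-branch-length covariance of the tree and `lambda`
#' scales its off-diagonal entries.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param rate Brownian rate (variance per unit branch length); 0 gives a
#'   constant trait.
#' @param lambda Phylogenetic structure in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A named numeric vector over the tips.
#' @export
simulate_bm_trait <- function(tree, rate, lambda = 1, seed = NULL) {
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("`lambda` must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(derive_seed(seed, "bm_trait"))
  n <- length(tree$tip.label)
  if (rate == 0) return(stats::setNames(rep(0, n), tree$tip.label))
  drop(bm_matrix(tree, rate, 1, lambda))[tree$tip.label]
}

# n_draws independent BM traits as an n_tips x n_draws matrix.
bm_matrix <- function(tree, rate, n_draws, lambda = 1) {
  v <- lambda_transform(ape::vcv(tree), lambda)
  l <- chol(rate * v + diag(1e-10, nrow(v)))
  z <- matrix(stats::rnorm(nrow(v) * n_draws), nrow(v), n_draws)
  out <- crossprod(l, z)
  rownames(out) <- rownames(v)
  out
}

#' Deep-clade membership of microbial tree tips
#'
#' Cuts the tree at relative depth `tau_deep`; each lineage crossing the
#' cut defines a clade of descendant tips. Clades with at least two tips
#' are "deep" (they originated before the cut and had already diversified);
#' their tips share a clade id. Singleton lineages get `NA`.
#'
#' @param tree An ultrametric [ape::phylo] tree.
#' @param tau_deep Relative depth of the cut in `[0, 1]`.
#' @return Integer vector of clade ids (NA for tips outside deep clades),
#'   named by tip.
#' @export
deep_clade_groups <- function(tree, tau_deep) {
  depths <- ape::node.depth.edgelength(tree)
  cut <- tau_deep * max(depths)
  ntip <- length(tree$tip.label)
  et <- edge_tip_incidence(tree)
  crossing <- which(depths[tree$edge[, 1]] < cut - 1e-12 &
                      depths[tree$edge[, 2]] >= cut - 1e-12)
  group <- rep(NA_integer_, ntip)
  gid <- 0L
  for (e in crossing) {
    tips <- which(et$inc[e, ])
    if (length(tips) >= 2) {
      gid <- gid + 1L
      group[tips] <- gid
    }
  }
  stats::setNames(group, tree$tip.label)
}

#' Simulate a full synthetic dataset
#'
#' Generates the host tree (family clades on a fixed backbone), a Yule
#' microbial tree, a phylogenetically structured diet trait, an unstructured
#' habitat trait, per-ASV log-abundance effects, and multinomial reads:
#'
#' * each ASV carries a Brownian host-structured effect (rate `sigma_phy`)
#'   evolving on the host tree — the phylosymbiosis signal;
#' * ASVs in microbial clades older than `tau_deep` additionally receive
#'   `beta_diet * diet(species) * u(clade)`, a clade-shared diet loading —
#'   the "diet acts on ancient clades" signal;
#' * species- and individual-level Gaussian noise is added, relative
#'   abundances are the softmax over ASVs, and reads are multinomial at a
#'   uniform random depth within `read_depth_range`;
#' * optional PCR negative controls consisting of a known contaminant ASV
#'   set, traces of which are also spiked into the true samples.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `synthetic_dataset` with `host_tree`,
#'   `microbial_tree`, `table` (all samples incl. controls), `meta`,
#'   `traits` (six diet proportions + habitat, per species), `latent`
#'   (diet score, clade loadings, deep-clade map) and `config`.
#' @export
simulate_community <- function(cfg = simulation_config()) {
  validate_config(cfg)
  set.seed(cfg$seed)
  host <- simulate_host_tree(cfg)
  species <- host$tree$tip.label
  n_sp <- cfg$n_species

  # genus assignment: blocks of <= 2 species within each family
  genus <- character(n_sp); names(genus) <- species
  g <- 0L
  for (fam in host$families) {
    blocks <- split(fam, ceiling(seq_along(fam) / 2))
    for (b in blocks) { g <- g + 1L; genus[b] <- sprintf("genus_%02d", g) }
  }
  family <- rep(sprintf("family_%d", seq_along(host$families)),
                lengths(host$families))
  names(family) <- unlist(host$families)
  family <- family[species]

  # traits: phylogenetically structured diet, unstructured habitat
  diet_raw <- simulate_bm_trait(host$tree, rate = 1, lambda = cfg$lambda_diet)
  diet <- drop(scale(diet_raw)); names(diet) <- species
  habitat <- stats::setNames(stats::rnorm(n_sp), species)
  items <- c("fruit", "leaves", "insects", "bamboo", "gum", "flowers")
  item_base <- c(1.5, 1.0, 0.5, -2.0, -1.5, -0.5)
  item_load <- c(0.2, -1.2, 1.2, -0.3, 0.4, 0.1)   # diet axis ~ insects vs leaves
  diet_props <- t(vapply(species, function(s) {
    softmax(item_base + item_load * diet[s] + stats::rnorm(6, 0, 0.3))
  }, numeric(6)))
  colnames(diet_props) <- items
  traits <- cbind(diet_props, habitat = habitat)

  # microbial tree and per-ASV effects
  asv_ids <- sprintf("asv_%04d", seq_len(cfg$n_asvs))
  mic <- simulate_yule_tree(cfg$n_asvs, labels = asv_ids)
  base <- stats::rnorm(cfg$n_asvs)
  g_phy <- if (cfg$sigma_phy > 0) {
    t(bm_matrix(host$tree, cfg$sigma_phy, cfg$n_asvs))[, species, drop = FALSE]
  } else {
    matrix(0, cfg$n_asvs, n_sp, dimnames = list(NULL, species))
  }
  deep <- deep_clade_groups(mic, cfg$tau_deep)
  u <- rep(0, cfg$n_asvs)
  if (any(!is.na(deep))) {
    per_clade <- stats::rnorm(max(deep, na.rm = TRUE))
    u[!is.na(deep)] <- per_clade[deep[!is.na(deep)]]
  }

  # species-level expected log abundances
  eta_sp <- sapply(species, function(s) {
    base + g_phy[, s] + cfg$beta_diet * diet[s] * u +
      stats::rnorm(cfg$n_asvs, 0, cfg$sigma_noise)
  })

  # individual samples
  n_samples <- sum(cfg$samples_per_species)
  counts <- matrix(0L, n_samples, cfg$n_asvs)
  sample_ids <- character(n_samples)
  sample_sp <- character(n_samples)
  row <- 0L
  for (si in seq_len(n_sp)) {
    s <- species[si]
    for (k in seq_len(cfg$samples_per_species[si])) {
      row <- row + 1L
      sample_ids[row] <- sprintf("%s_s%02d", s, k)
      sample_sp[row] <- s
      eta <- eta_sp[, s] + stats::rnorm(cfg$n_asvs, 0, cfg$sigma_individual)
      depth <- sample(cfg$read_depth_range[1]:cfg$read_depth_range[2], 1)
      counts[row, ] <- stats::rmultinom(1, depth, softmax(eta))[, 1]
    }
  }
  dimnames(counts) <- list(sample_ids, asv_ids)

  # contaminant spike + PCR negative controls
  meta_controls <- NULL
  if (cfg$n_controls > 0 && cfg$n_contaminants > 0) {
    contam_ids <- sprintf("contam_%02d", seq_len(cfg$n_contaminants))
    trace <- matrix(stats::rpois(n_samples * cfg$n_contaminants, 3),
                    n_samples, cfg$n_contaminants,
                    dimnames = list(sample_ids, contam_ids))
    counts <- cbind(counts, trace)
    ctrl_ids <- sprintf("control_%02d", seq_len(cfg$n_controls))
    ctrl <- matrix(0L, cfg$n_controls, ncol(counts),
                   dimnames = list(ctrl_ids, colnames(counts)))
    for (i in seq_len(cfg$n_controls)) {
      ctrl[i, contam_ids] <- stats::rmultinom(
        1, sample(300:1500, 1), softmax(stats::rnorm(cfg$n_contaminants)))[, 1]
    }
    counts <- rbind(counts, ctrl)
    meta_controls <- data.frame(sample_id = ctrl_ids, host_species = "",
                                host_genus = "", host_family = "",
                                site = "lab", is_control = TRUE)
  }

  site <- ifelse(habitat > 0, "east_rainforest", "west_dryforest")
  meta <- data.frame(sample_id = sample_ids,
                     host_species = sample_sp,
                     host_genus = unname(genus[sample_sp]),
                     host_family = unname(family[sample_sp]),
                     site = unname(site[sample_sp]),
                     is_control = FALSE)
  if (!is.null(meta_controls)) meta <- rbind(meta, meta_controls)

  structure(list(host_tree = host$tree,
                 microbial_tree = mic,
                 table = asv_table(counts),
                 meta = sample_info(meta),
                 traits = traits,
                 latent = list(diet = diet, habitat = habitat,
                               clade_loading = u, deep_clades = deep),
                 config = cfg),
            class = "synthetic_dataset")
}

#' Write / read a synthetic dataset as a plain-text bundle
#'
#' The bundle is the package's standard input format: the count table and
#' metadata as TSV, the two trees as Newick, the trait table as TSV and the
#' generating configuration as YAML.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asv_table(ds$table, file.path(dir, "asv_table.tsv"))
  write_sample_info(ds$meta, file.path(dir, "metadata.tsv"))
  write_newick(ds$host_tree, file.path(dir, "host_tree.nwk"))
  write_newick(ds$microbial_tree, file.path(dir, "microbial_tree.nwk"))
  tr <- data.frame(species = rownames(ds$traits), ds$traits, check.names = FALSE)
  utils::write.table(tr, file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(unclass(ds$config), file.path(dir, "config.yml"))
  }
  invisible(dir)
}

#' @rdname write_synthetic_bundle
#' @export
read_synthetic_bundle <- function(dir) {
  tr <- utils::read.delim(file.path(dir, "traits.tsv"), check.names = FALSE)
  traits <- as.matrix(tr[, -1, drop = FALSE])
  rownames(traits) <- tr[[1]]
  cfg <- NULL
  if (file.exists(file.path(dir, "config.yml")) &&
      requireNamespace("yaml", quietly = TRUE)) {
    cfg <- do.call(simulation_config, yaml::read_yaml(file.path(dir, "config.yml")))
  }
  structure(list(host_tree = read_newick(file.path(dir, "host_tree.nwk")),
                 microbial_tree = read_newick(file.path(dir, "microbial_tree.nwk")),
                 table = read_asv_table(file.path(dir, "asv_table.tsv")),
                 meta = read_sample_info(file.path(dir, "metadata.tsv")),
                 traits = traits,
                 latent = NULL,
                 config = cfg),
            class = "synthetic_dataset")
}
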