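# End-to-end orchestration: QC -> rarefaction -> diversity -> species-level
# aggregation -> dendrogram congruence + Mantel grid -> ordination,
# phylogenetic signal, and trait regressions.

#' Pipeline configuration
#'
#' @param rarefaction_depth Reads per sample after rarefaction (default 2000).
#' @param metrics Beta-diversity metrics to run (default all four).
#' @param include_faith_pd Also compute Faith's PD and test it downstream.
#' @param n_random_pick Number of random-pick replicate datasets (default 10).
#' @param n_null_trees Null size of the Robinson-Foulds randomization test
#'   (default 10000).
#' @param mantel_permutations,adonis_permutations,signal_permutations
#'   Permutation counts for the Mantel, PERMANOVA/PERMDISP and Blomberg's K
#'   tests (defaults 999, 999, 999).
#' @param k_axes Principal coordinates retained for signal tests (default 5).
#' @param species_aggregation `"re_rarefy"` (default: rarefy the
#'   mean-ceiling species table back to the common depth) or
#'   `"renormalize"` (leave the ceiling counts; metrics use relative
#'   abundance / presence).
#' @param seed Master seed; all stage seeds are derived from it by stable
#'   labeled hashing, so any stage can be replayed independently.
#' @return A list of class `run_config`.
#' @export
run_config <- function(rarefaction_depth = 2000,
                       metrics = c("bray_curtis", "jaccard",
                                   "unweighted_unifrac", "weighted_unifrac"),
                       include_faith_pd = TRUE,
                       n_random_pick = 10,
                       n_null_trees = 10000,
                       mantel_permutations = 999,
                       adonis_permutations = 999,
                       signal_permutations = 999,
                       k_axes = 5,
                       species_aggregation = c("re_rarefy", "renormalize"),
                       seed = 1) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  species_aggregation <- match.arg(species_aggregation)
  for (nm in c("rarefaction_depth", "n_random_pick", "n_null_trees",
               "mantel_permutations", "adonis_permutations",
               "signal_permutations", "k_axes")) {
    assert_scalar_count(get(nm), nm)
  }
  structure(list(rarefaction_depth = as.integer(rarefaction_depth),
                 metrics = metrics,
                 include_faith_pd = isTRUE(include_faith_pd),
                 n_random_pick = as.integer(n_random_pick),
                 n_null_trees = as.integer(n_null_trees),
                 mantel_permutations = as.integer(mantel_permutations),
                 adonis_permutations = as.integer(adonis_permutations),
                 signal_permutations = as.integer(signal_permutations),
                 k_axes = as.integer(k_axes),
                 species_aggregation = species_aggregation,
                 seed = as.integer(seed)),
            class = "run_config")
}

beta_distance <- function(metric, table, tree) {
  switch(metric,
         bray_curtis = bray_curtis(table),
         jaccard = jaccard(table),
         unweighted_unifrac = unweighted_unifrac(table, tree),
         weighted_unifrac = weighted_unifrac(table, tree),
         stop("unknown metric: ", metric, call. = FALSE))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full phylosymbiosis analysis
#'
#' Executes, on an input bundle (count table, metadata, microbial and host
#' trees, traits):
#' control-ASV removal, minimum-depth filtering and rarefaction; sample- and
#' species-level beta diversity for each requested metric; Faith's PD;
#' species-level datasets by mean-ceiling averaging and `n_random_pick`
#' random picks; per dataset and metric a UPGMA dendrogram, the
#' Robinson-Foulds randomization test against the host tree, and a Mantel
#' test against host patristic distances; principal coordinates of the
#' species-average distances with Blomberg's K and Pagel's lambda per axis
#' (and for Faith's PD); PGLS of each metric's PCo1 on diet and habitat
#' PC1 scores with their interaction; and sample-level PERMANOVA
#' (`Diet_PC1 * Habitat_PC1 + family/genus/species`, sequential SS) with
#' PERMDISP homogeneity checks per taxonomic level.
#'
#' @param input A `synthetic_dataset` (from [simulate_community()] or
#'   [read_synthetic_bundle()]), or any list with elements `table`, `meta`,
#'   `host_tree`, `microbial_tree`, `traits`.
#' @param cfg A [run_config()].
#' @param outdir Optional directory; if given, every result family is
#'   written as a TSV plus a run log of the seeds consumed.
#' @return A list of class `phylosym_report` with data frames
#'   `rf_results`, `mantel_results`, `signal_results`, `pgls_results`,
#'   `permanova_results`, `permdisp_results`, `alpha`, `summary` (the
#'   species-average congruence table: metric, RF, RF p, Mantel r,
#'   Mantel p), plus `datasets`, `distances` and `seeds`.
#' @export
run_phylosymbiosis <- function(input, cfg = run_config(), outdir = NULL) {
  seeds <- list()
  take_seed <- function(label) {
    s <- derive_seed(cfg$seed, label)
    seeds[[label]] <<- s
    s
  }

  # ---- QC and rarefaction ------------------------------------------------
  meta <- sample_info(as.data.frame(input$meta))
  tab <- input$table
  if (any(meta$is_control)) {
    tab <- stage("remove_control_asvs", remove_control_asvs(tab, meta))
  }
  tab <- stage("filter_min_depth", filter_min_depth(tab, cfg$rarefaction_depth))
  tab <- stage("rarefy", rarefy(tab, cfg$rarefaction_depth, take_seed("rarefy")))
  meta <- meta[match(rownames(tab), meta$sample_id), , drop = FALSE]

  # ---- host tree restricted to observed species --------------------------
  species <- sort(unique(meta$host_species))
  host <- stage("prune_host_tree", prune_and_rename(input$host_tree, species))
  host_pat <- patristic_distances(host)

  # ---- species-level datasets -------------------------------------------
  sp_avg <- stage("mean_ceiling", mean_ceiling(tab, meta))
  if (cfg$species_aggregation == "re_rarefy") {
    sp_avg <- rarefy(sp_avg, cfg$rarefaction_depth, take_seed("re_rarefy"))
  }
  picks <- stage("random_pick",
                 random_pick(tab, meta, cfg$n_random_pick, take_seed("random_pick")))
  datasets <- c(list(species_average = sp_avg),
                stats::setNames(picks, sprintf("random_pick_%02d",
                                               seq_along(picks))))

  # ---- congruence grid: RF + Mantel per dataset x metric -----------------
  rf_rows <- list(); mantel_rows <- list(); dist_cache <- list()
  for (ds_name in names(datasets)) {
    for (metric in cfg$metrics) {
      d <- stage(paste0("beta:", metric, ":", ds_name),
                 beta_distance(metric, datasets[[ds_name]], input$microbial_tree))
      dist_cache[[paste(ds_name, metric, sep = ":")]] <- d
      dend <- stage("upgma", upgma(d))
      rf <- rf_randomization_test(host, dend, cfg$n_null_trees,
                                  take_seed(paste("rf", ds_name, metric)))
      mt <- mantel_test(d, host_pat, cfg$mantel_permutations,
                        take_seed(paste("mantel", ds_name, metric)))
      rf_rows[[length(rf_rows) + 1]] <-
        data.frame(dataset = ds_name, metric = metric, rf = rf$observed_rf,
                   null_mean = mean(rf$null_rf), p_value = rf$p_value)
      mantel_rows[[length(mantel_rows) + 1]] <-
        data.frame(dataset = ds_name, metric = metric, r = mt$r,
                   p_value = mt$p_value)
    }
  }
  rf_results <- do.call(rbind, rf_rows)
  mantel_results <- do.call(rbind, mantel_rows)

  # ---- alpha diversity ---------------------------------------------------
  alpha <- NULL
  if (cfg$include_faith_pd) {
    pd_samples <- stage("faith_pd", faith_pd(tab, input$microbial_tree))
    pd_species <- faith_pd(sp_avg, input$microbial_tree)
    alpha <- list(samples = pd_samples, species = pd_species)
  }

  # ---- ordination + phylogenetic signal (species-average dataset) --------
  signal_rows <- list()
  ord <- list()
  for (metric in cfg$metrics) {
    d <- dist_cache[[paste("species_average", metric, sep = ":")]]
    pc <- stage("pcoa", pcoa(d, cfg$k_axes))
    ord[[metric]] <- pc
    for (ax in seq_len(ncol(pc$coordinates))) {
      x <- stats::setNames(pc$coordinates[, ax], pc$labels)
      k <- blomberg_k(host, x, cfg$signal_permutations,
                      take_seed(paste("K", metric, ax)))
      l <- pagel_lambda(host, x)
      signal_rows[[length(signal_rows) + 1]] <- data.frame(
        response = metric, axis = paste0("PCo", ax),
        blomberg_k = k$estimate, k_p = k$p_value,
        pagel_lambda = l$estimate, lambda_p = l$p_value)
    }
  }
  if (cfg$include_faith_pd) {
    k <- blomberg_k(host, alpha$species, cfg$signal_permutations,
                    take_seed("K faith_pd"))
    l <- pagel_lambda(host, alpha$species)
    signal_rows[[length(signal_rows) + 1]] <- data.frame(
      response = "faith_pd", axis = "PD",
      blomberg_k = k$estimate, k_p = k$p_value,
      pagel_lambda = l$estimate, lambda_p = l$p_value)
  }
  signal_results <- do.call(rbind, signal_rows)

  # ---- trait PCs ---------------------------------------------------------
  traits <- as.matrix(input$traits)
  diet_cols <- setdiff(colnames(traits), "habitat")
  diet_pc1 <- trait_pca(traits[, diet_cols, drop = FALSE])$scores[, 1]
  habitat_pc1 <- if (sum(colnames(traits) == "habitat") == 1) {
    drop(scale(traits[, "habitat"]))           # single habitat variable
  } else {
    trait_pca(traits[, colnames(traits) == "habitat", drop = FALSE],
              scale = TRUE)$scores[, 1]
  }
  names(habitat_pc1) <- rownames(traits)
  trait_pc <- cbind(Diet_PC1 = diet_pc1[species], Habitat_PC1 = habitat_pc1[species])
  rownames(trait_pc) <- species

  # ---- PGLS per metric (species-average PCo1) + Faith's PD ---------------
  pgls_rows <- list()
  pgls_response <- lapply(cfg$metrics, function(metric) {
    pc <- ord[[metric]]
    stats::setNames(pc$coordinates[, 1], pc$labels)
  })
  names(pgls_response) <- cfg$metrics
  if (cfg$include_faith_pd) pgls_response$faith_pd <- alpha$species
  for (resp in names(pgls_response)) {
    fit <- stage(paste0("pgls:", resp),
                 pgls(host, pgls_response[[resp]], trait_pc, interaction = TRUE))
    cf <- fit$coefficients
    getp <- function(term) cf$p_value[match(term, cf$term)]
    pgls_rows[[length(pgls_rows) + 1]] <- data.frame(
      response = resp,
      diet_p = getp("Diet_PC1"), habitat_p = getp("Habitat_PC1"),
      interaction_p = getp("Diet_PC1:Habitat_PC1"),
      model_p = fit$model_p, aic = fit$aic)
  }
  pgls_results <- do.call(rbind, pgls_rows)

  # ---- sample-level PERMANOVA + PERMDISP ---------------------------------
  design <- data.frame(sample_id = meta$sample_id,
                       host_species = meta$host_species,
                       host_genus = meta$host_genus,
                       host_family = meta$host_family,
                       Diet_PC1 = unname(diet_pc1[meta$host_species]),
                       Habitat_PC1 = unname(habitat_pc1[meta$host_species]))
  adonis_formula <- "Diet_PC1 * Habitat_PC1 + host_family / host_genus / host_species"
  permanova_rows <- list(); permdisp_rows <- list()
  for (metric in cfg$metrics) {
    d <- stage(paste0("beta_samples:", metric),
               beta_distance(metric, tab, input$microbial_tree))
    pa <- permanova(d, design, adonis_formula, cfg$adonis_permutations,
                    take_seed(paste("adonis", metric)))
    permanova_rows[[length(permanova_rows) + 1]] <-
      cbind(metric = metric, pa$table)
    for (lvl in c("host_family", "host_genus", "host_species")) {
      groups <- stats::setNames(meta[[lvl]], meta$sample_id)
      pd_fit <- permdisp(d, groups, cfg$adonis_permutations,
                         take_seed(paste("permdisp", metric, lvl)))
      permdisp_rows[[length(permdisp_rows) + 1]] <- data.frame(
        metric = metric, grouping = lvl, f_statistic = pd_fit$f_statistic,
        p_value = pd_fit$p_value)
    }
  }
  permanova_results <- do.call(rbind, permanova_rows)
  permdisp_results <- do.call(rbind, permdisp_rows)

  # ---- species-average summary (congruence table) ------------------------
  sa_rf <- rf_results[rf_results$dataset == "species_average", ]
  sa_mt <- mantel_results[mantel_results$dataset == "species_average", ]
  summary_tab <- data.frame(distance_matrix = sa_rf$metric,
                            rf = sa_rf$rf, rf_p = sa_rf$p_value,
                            mantel_r = sa_mt$r[match(sa_rf$metric, sa_mt$metric)],
                            mantel_p = sa_mt$p_value[match(sa_rf$metric, sa_mt$metric)])

  report <- structure(list(rf_results = rf_results,
                           mantel_results = mantel_results,
                           signal_results = signal_results,
                           pgls_results = pgls_results,
                           permanova_results = permanova_results,
                           permdisp_results = permdisp_results,
                           alpha = alpha,
                           summary = summary_tab,
                           datasets = datasets,
                           distances = dist_cache,
                           trait_pc = trait_pc,
                           n_samples_retained = nrow(tab),
                           seeds = seeds,
                           config = cfg),
                      class = "phylosym_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8", na = "NA")
  }
  wt(report$rf_results, "rf_results.tsv")
  wt(report$mantel_results, "mantel_results.tsv")
  wt(report$signal_results, "signal_results.tsv")
  wt(report$pgls_results, "pgls_results.tsv")
  wt(report$permanova_results, "permanova_results.tsv")
  wt(report$permdisp_results, "permdisp_results.tsv")
  wt(report$summary, "summary.tsv")
  if (!is.null(report$alpha)) {
    wt(data.frame(sample_id = names(report$alpha$samples),
                  faith_pd = unname(report$alpha$samples)), "alpha_faith_pd.tsv")
  }
  log <- c(sprintf("phylosym run, master seed %d", report$config$seed),
           sprintf("samples retained after QC/rarefaction: %d",
                   report$n_samples_retained),
           "stage seeds:",
           sprintf("  %s: %d", names(report$seeds), unlist(report$seeds)))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.phylosym_report <- function(x, ...) {
  cat("Phylosymbiosis analysis report\n")
  cat(sprintf("  samples retained: %d; datasets: %d; metrics: %s\n",
              x$n_samples_retained, length(x$datasets),
              paste(x$config$metrics, collapse = ", ")))
  cat("  species-average congruence:\n")
  print(x$summary, digits = 3)
  invisible(x)
}
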