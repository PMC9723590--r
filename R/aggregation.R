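# Species-level aggregation: reduce the sample-level dataset to one
# community per host species, so that the community table matches the tips
# of the host phylogeny.

# sample id -> species lookup restricted to the table's (non-control) rows
species_of_samples <- function(m, meta) {
  meta <- sample_info(as.data.frame(meta))
  meta <- meta[!meta$is_control, , drop = FALSE]
  unmapped <- setdiff(rownames(m), meta$sample_id)
  if (length(unmapped)) {
    stop("sample(s) missing from metadata: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(meta$host_species, meta$sample_id)[rownames(m)]
}

#' Species-average community by the mean-ceiling rule
#'
#' For each host species, the per-ASV counts are averaged across that
#' species' samples and rounded up: `entry(species, asv) =
#' ceiling(mean(count))`. The ceiling keeps every ASV observed in any
#' sample of a species present in its average community.
#'
#' @param table An [asv_table()] of sample-level counts.
#' @param meta A `sample_info` data frame mapping samples to species.
#' @return An [asv_table()] with one row per host species.
#' @export
mean_ceiling <- function(table, meta) {
  m <- as_counts(table)
  sp <- species_of_samples(m, meta)
  meta_sp <- unique(sample_info(as.data.frame(meta))$host_species[
    !sample_info(as.data.frame(meta))$is_control])
  absent <- setdiff(meta_sp, sp)
  if (length(absent)) {
    warning("species with zero samples excluded: ", paste(absent, collapse = ", "))
  }
  sums <- rowsum(m, group = sp)
  n_per <- as.vector(table(sp)[rownames(sums)])
  out <- ceiling(sums / n_per)
  asv_table(out[sort(rownames(out)), , drop = FALSE])
}

#' Random-pick replicate species communities
#'
#' Builds `n_replicates` species-level tables, each formed by picking one
#' sample per species at random. Species with at least `n_replicates`
#' samples contribute a distinct sample to every replicate (picking without
#' replacement); species with fewer samples have each sample reused either
#' `floor(n/s)` or `ceiling(n/s)` times, with the assignment to replicates
#' randomized.
#'
#' @inheritParams mean_ceiling
#' @param n_replicates Number of replicate tables (default 10).
#' @param seed Integer seed; fixed seed gives identical replicate lists.
#' @return A list of `n_replicates` [asv_table()]s with species as rows.
#'   The picked sample ids are attached to each table as attribute
#'   `"picked"` (named by species).
#' @export
random_pick <- function(table, meta, n_replicates = 10, seed = 1) {
  assert_scalar_count(n_replicates, "n_replicates")
  m <- as_counts(table)
  sp <- species_of_samples(m, meta)
  species <- sort(unique(sp))
  set.seed(derive_seed(seed, "random_pick"))
  assignment <- lapply(stats::setNames(species, species), function(s) {
    ids <- rownames(m)[sp == s]
    k <- length(ids)
    if (k >= n_replicates) {
      ids[sample.int(k, n_replicates)]
    } else {
      # balanced recycling: each sample used floor(n/k) or ceiling(n/k) times
      ids[sample(rep_len(seq_len(k), n_replicates))]
    }
  })
  lapply(seq_len(n_replicates), function(r) {
    picked <- vapply(assignment, `[`, character(1), r)
    out <- m[picked, , drop = FALSE]
    rownames(out) <- species
    res <- asv_table(out)
    attr(res, "picked") <- picked
    res
  })
}
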