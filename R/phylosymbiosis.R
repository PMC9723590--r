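# Dendrogram congruence and distance-correlation machinery: UPGMA,
# normalized Robinson-Foulds with a randomized-topology null, and Mantel
# tests of microbiome distance against host patristic distance.

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering; the resulting dendrogram is
#' rooted and ultrametric, with each merge placed at half the
#' average-linkage distance (so cophenetic distances reproduce the linkage
#' distances). Labels are processed in lexicographic order so tied merges
#' resolve identically across platforms.
#'
#' @param dm A [distance_matrix()] with at least two labels.
#' @return A rooted ultrametric [ape::phylo] dendrogram.
#' @export
upgma <- function(dm) {
  m <- as_dm(dm)
  if (nrow(m) < 2) stop("need at least 2 labels", call. = FALSE)
  ord <- order(rownames(m))
  m <- m[ord, ord]
  ape::as.phylo(stats::hclust(stats::as.dist(m), method = "average"))
}

# Canonical non-trivial unrooted bipartitions of a tree, keyed as strings.
# Each split is represented by the side not containing the reference tip
# (the lexicographically smallest label), so rooted and unrooted encodings
# of the same split collide.
tree_bipartitions <- function(tree) {
  labels <- sort(tree$tip.label)
  ref <- labels[1]
  n <- length(labels)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (ref %in% side) side <- setdiff(labels, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      keys <- c(keys, paste(side, collapse = "\r"))
    }
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the non-trivial (unrooted) bipartitions present in exactly one of
#' the two trees. The normalized form divides by the total number of
#' non-trivial bipartitions across both trees, giving a value in
#' \[0, 1\] (0 = identical topology, 1 = no shared splits); for two fully
#' resolved trees on n tips this denominator is `2(n - 3)`, and the
#' definition extends to multifurcating dendrograms from tied merges.
#'
#' @param t1,t2 [ape::phylo] trees on identical tip sets.
#' @param normalized Return the normalized distance (default) or the raw
#'   split count.
#' @return A single number.
#' @export
robinson_foulds <- function(t1, t2, normalized = TRUE) {
  diff_tips <- union(setdiff(t1$tip.label, t2$tip.label),
                     setdiff(t2$tip.label, t1$tip.label))
  if (length(diff_tips)) {
    stop("tip sets differ: ", paste(diff_tips, collapse = ", "), call. = FALSE)
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (!normalized) return(rf)
  denom <- length(b1) + length(b2)
  if (denom == 0) 0 else rf / denom
}

#' Random bifurcating topology on a label set
#'
#' Draws a random binary topology (successive random joins, as in
#' [ape::rtree()]) with the labels assigned in uniformly random order and
#' unit branch lengths. This is the null model for the Robinson-Foulds
#' randomization test.
#'
#' @param labels Character vector of at least 3 tip labels.
#' @param seed Optional integer seed.
#' @return An [ape::phylo] tree.
#' @export
random_topology <- function(labels, seed = NULL) {
  if (length(labels) < 3) stop("need at least 3 labels", call. = FALSE)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (!is.null(seed)) set.seed(derive_seed(seed, "random_topology"))
  tree <- ape::rtree(length(labels), tip.label = sample(labels))
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Robinson-Foulds randomization test of topological congruence
#'
#' Compares the observed normalized RF distance between the host phylogeny
#' and a microbiome dendrogram to the distances obtained when the
#' dendrogram is replaced by `n_null` random topologies on the same tips.
#' Low observed RF relative to the null indicates phylosymbiosis. The
#' p-value uses the add-one rule
#' `p = (1 + #{null RF <= observed}) / (1 + n_null)`, so the smallest
#' attainable p at 10,000 null trees is below 1e-4.
#'
#' @param host Host phylogeny ([ape::phylo]).
#' @param gm_dendrogram Microbiome dendrogram on the same tip set.
#' @param n_null Number of random topologies (default 10000).
#' @param seed Integer seed.
#' @return A list of class `rf_test` with elements `observed_rf`,
#'   `null_rf`, `p_value`, `n_null`.
#' @export
rf_randomization_test <- function(host, gm_dendrogram, n_null = 10000, seed = 1) {
  assert_scalar_count(n_null, "n_null")
  observed <- robinson_foulds(host, gm_dendrogram, normalized = TRUE)
  labels <- host$tip.label
  set.seed(derive_seed(seed, "rf_null"))
  null_rf <- vapply(seq_len(n_null), function(i) {
    robinson_foulds(host, random_topology(labels), normalized = TRUE)
  }, numeric(1))
  p <- (1 + sum(null_rf <= observed)) / (1 + n_null)
  structure(list(observed_rf = observed, null_rf = null_rf,
                 p_value = p, n_null = n_null),
            class = "rf_test")
}

#' @export
print.rf_test <- function(x, ...) {
  cat(sprintf("RF randomization test: observed nRF = %.3f, null mean = %.3f, p = %.4g (n_null = %d)\n",
              x$observed_rf, mean(x$null_rf), x$p_value, x$n_null))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle distances, with significance
#' from joint row/column permutations of one matrix (one-tailed, greater:
#' phylosymbiosis predicts a positive correlation between host phylogenetic
#' and microbiome distance). Wraps [vegan::mantel()].
#'
#' @param dm1,dm2 [distance_matrix()] objects on the same label set (order
#'   may differ; matrices are aligned internally).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A list of class `mantel_result` with `r`, `p_value`,
#'   `n_permutations`, `method`.
#' @export
mantel_test <- function(dm1, dm2, n_permutations = 999, seed = 1) {
  assert_scalar_count(n_permutations, "n_permutations")
  ms <- align_dms(dm1, dm2)
  if (nrow(ms[[1]]) < 4) stop("need at least 4 objects", call. = FALSE)
  set.seed(derive_seed(seed, "mantel"))
  fit <- vegan::mantel(stats::as.dist(ms[[1]]), stats::as.dist(ms[[2]]),
                       method = "pearson", permutations = n_permutations)
  structure(list(r = unname(fit$statistic), p_value = unname(fit$signif),
                 n_permutations = n_permutations, method = "pearson"),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %d permutations): r = %.3f, p = %.4g\n",
              x$method, x$n_permutations, x$r, x$p_value))
  invisible(x)
}
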