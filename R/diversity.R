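# Alpha and beta diversity.
#
# The phylogenetic metrics (UniFrac, Faith's PD) share one primitive: the
# edge-by-tip incidence of the microbial tree. Edge i "covers" tip t when t
# descends from the child node of edge i; the mass of a community under an
# edge is then a single matrix product away.

# Edge-by-tip incidence for a rooted tree. Returns a list with the edge
# lengths and a logical E x Ntip matrix (TRUE where the tip descends from
# the edge's child node).
edge_tip_incidence <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; phylogenetic diversity undefined", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode_total <- ntip + tree$Nnode
  inc_nodes <- matrix(FALSE, nnode_total, ntip)
  inc_nodes[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]; child <- po$edge[k, 2]
    inc_nodes[parent, ] <- inc_nodes[parent, ] | inc_nodes[child, ]
  }
  list(lengths = tree$edge.length,
       inc = inc_nodes[tree$edge[, 2], , drop = FALSE],
       tips = tree$tip.label)
}

# Map table columns onto tree tips: samples x tips abundance matrix.
# ASVs with non-zero counts must all be tree tips; tree tips absent from
# the table get zero abundance.
table_on_tips <- function(m, tree) {
  present <- colnames(m)[colSums(m) > 0]
  missing_tips <- setdiff(present, tree$tip.label)
  if (length(missing_tips)) {
    stop("ASV(s) not found in tree: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  out <- matrix(0, nrow(m), length(tree$tip.label),
                dimnames = list(rownames(m), tree$tip.label))
  shared <- intersect(colnames(m), tree$tip.label)
  out[, shared] <- m[, shared]
  out
}

check_no_empty <- function(m) {
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty)) {
    stop("sample(s) with zero total count have undefined distances: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = 1 - 2 * sum_j min(x_j, y_j) / (sum_j x_j + sum_j y_j)`,
#' an abundance-weighted dissimilarity that treats all ASVs as unrelated
#' ("star phylogeny" metric).
#'
#' @param table An [asv_table()] with at least two samples.
#' @return A [distance_matrix()] over the samples, values in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  m <- check_no_empty(as_counts(table))
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  distance_matrix(vegan::vegdist(m, method = "bray"))
}

#' Jaccard distance (presence/absence)
#'
#' `d(x, y) = 1 - |supp(x) n supp(y)| / |supp(x) u supp(y)|` on the sets of
#' ASVs present in each sample.
#'
#' @inheritParams bray_curtis
#' @return A [distance_matrix()], values in \[0, 1\].
#' @export
jaccard <- function(table) {
  m <- check_no_empty(as_counts(table))
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  distance_matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
}

# Shared pairwise machinery for both UniFrac variants.
unifrac_engine <- function(table, tree, weighted, normalized) {
  m <- check_no_empty(as_counts(table))
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  a <- table_on_tips(m, tree)
  et <- edge_tip_incidence(tree)
  inc <- et$inc * 1
  n <- nrow(a)
  d <- matrix(0, n, n, dimnames = list(rownames(a), rownames(a)))
  if (weighted) {
    rel <- a / rowSums(a)
    p <- inc %*% t(rel)                      # edges x samples: mass under edge
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(et$lengths * abs(p[, i] - p[, j]))
      if (normalized) {
        den <- sum(et$lengths * (p[, i] + p[, j]))
        d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
      } else {
        d[i, j] <- d[j, i] <- num
      }
    }
  } else {
    pres <- (inc %*% t(a > 0)) > 0           # edges x samples: any tip present
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      either <- pres[, i] | pres[, j]
      unique_len <- sum(et$lengths[xor(pres[, i], pres[, j])])
      total_len <- sum(et$lengths[either])
      d[i, j] <- d[j, i] <- if (total_len > 0) unique_len / total_len else 0
    }
  }
  distance_matrix(d)
}

#' Unweighted UniFrac distance
#'
#' Fraction of branch length on the microbial tree that leads to tips
#' present in exactly one of the two communities, out of the branch length
#' leading to tips present in either. Presence/absence only; deep branches
#' carry more weight than in star-phylogeny metrics.
#'
#' @param table An [asv_table()]; every ASV with a non-zero count must be a
#'   tip of `tree`.
#' @param tree Rooted microbial phylogeny ([ape::phylo]) with branch lengths.
#' @return A [distance_matrix()], values in \[0, 1\].
#' @export
unweighted_unifrac <- function(table, tree) {
  unifrac_engine(table, tree, weighted = FALSE, normalized = FALSE)
}

#' Weighted UniFrac distance
#'
#' `d(A, B) = sum_i b_i * |p_i^A - p_i^B|` over branches `i` with length
#' `b_i`, where `p_i^X` is the fraction of community X's reads descending
#' from branch `i`. The default is the unnormalized sum; with
#' `normalized = TRUE` the sum is divided by `sum_i b_i (p_i^A + p_i^B)`,
#' bounding it to \[0, 1\].
#'
#' @inheritParams unweighted_unifrac
#' @param normalized Divide by the maximal attainable value for the pair.
#' @return A [distance_matrix()].
#' @export
weighted_unifrac <- function(table, tree, normalized = FALSE) {
  unifrac_engine(table, tree, weighted = TRUE, normalized = normalized)
}

#' Faith's phylogenetic diversity
#'
#' Per sample, the sum of branch lengths of the minimal subtree connecting
#' the root and all tips present in the sample. With
#' `include_root = FALSE`, the path between the root and the most recent
#' common ancestor of the present tips is excluded.
#'
#' @inheritParams unweighted_unifrac
#' @param include_root Include the stem path up to the tree root (default).
#' @return A named numeric vector of PD values (summed branch length).
#' @export
faith_pd <- function(table, tree, include_root = TRUE) {
  m <- as_counts(table)
  a <- table_on_tips(m, tree)
  et <- edge_tip_incidence(tree)
  pres <- (et$inc %*% t(a > 0)) > 0          # edges x samples
  pd <- colSums(pres * et$lengths)
  names(pd) <- rownames(a)
  empty <- rowSums(a) == 0
  if (any(empty)) {
    warning("empty sample(s) assigned PD = 0: ",
            paste(names(pd)[empty], collapse = ", "))
    pd[empty] <- 0
  }
  if (!include_root) {
    depths <- ape::node.depth.edgelength(tree)
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    for (s in which(!empty)) {
      tips <- which(a[s, ] > 0)
      mrca <- if (length(tips) > 1) ape::getMRCA(tree, tips) else root
      if (length(tips) == 1) {
        pd[s] <- 0
      } else if (mrca != root) {
        pd[s] <- pd[s] - depths[mrca]
      }
    }
  }
  pd
}
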