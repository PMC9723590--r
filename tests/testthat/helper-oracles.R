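# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths: branch sets are found by walking
# root-to-tip paths edge by edge, linkage by a naive O(n^3) loop, and
# PERMANOVA sums of squares by direct group summation.

# --- tree path enumeration (independent of edge_tip_incidence) -----------

# For each tip, the set of edge indices on its root-to-tip path.
oracle_tip_paths <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  lapply(seq_len(ntip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
}

# Tips descending from each edge, via path membership.
oracle_edge_tips <- function(tree) {
  paths <- oracle_tip_paths(tree)
  lapply(seq_len(nrow(tree$edge)), function(e) {
    which(vapply(paths, function(p) e %in% p, logical(1)))
  })
}

# --- beta diversity oracles ----------------------------------------------

oracle_bray <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

oracle_jaccard <- function(x, y) {
  a <- which(x > 0); b <- which(y > 0)
  1 - length(intersect(a, b)) / length(union(a, b))
}

# Enumerate every branch, classify it as shared/unique between the two
# communities, and sum. `xa`, `xb` are count vectors named by tree tips.
oracle_unifrac <- function(xa, xb, tree, weighted = FALSE, normalized = FALSE) {
  edge_tips <- oracle_edge_tips(tree)
  len <- tree$edge.length
  xa <- xa[tree$tip.label]; xb <- xb[tree$tip.label]
  if (weighted) {
    pa <- xa / sum(xa); pb <- xb / sum(xb)
    num <- den <- 0
    for (e in seq_along(edge_tips)) {
      ma <- sum(pa[edge_tips[[e]]]); mb <- sum(pb[edge_tips[[e]]])
      num <- num + len[e] * abs(ma - mb)
      den <- den + len[e] * (ma + mb)
    }
    if (normalized) num / den else num
  } else {
    uniq <- tot <- 0
    for (e in seq_along(edge_tips)) {
      ina <- any(xa[edge_tips[[e]]] > 0); inb <- any(xb[edge_tips[[e]]] > 0)
      if (ina || inb) tot <- tot + len[e]
      if (xor(ina, inb)) uniq <- uniq + len[e]
    }
    if (tot == 0) 0 else uniq / tot
  }
}

oracle_faith_pd <- function(x, tree) {
  edge_tips <- oracle_edge_tips(tree)
  x <- x[tree$tip.label]
  sum(tree$edge.length[vapply(edge_tips, function(t) any(x[t] > 0), logical(1))])
}

# --- naive average-linkage clustering (cophenetic matrix) -----------------

oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  heights <- matrix(0, n, n, dimnames = list(labels, labels))
  active <- rep(TRUE, length(clusters))
  cd <- function(c1, c2) mean(d[c1, c2, drop = FALSE])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(Inf, NA, NA)
    for (i in idx) for (j in idx) if (i < j) {
      v <- cd(clusters[[i]], clusters[[j]])
      if (v < best[1] - 1e-12) best <- c(v, i, j)
    }
    i <- best[2]; j <- best[3]
    heights[clusters[[i]], clusters[[j]]] <- best[1]
    heights[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active[j] <- FALSE
  }
  heights
}

# --- exhaustive bipartitions (path-based, unrooted, non-trivial) ----------

oracle_bipartitions <- function(tree) {
  labels <- sort(tree$tip.label)
  ref <- labels[1]
  n <- length(labels)
  edge_tips <- oracle_edge_tips(tree)
  keys <- vapply(edge_tips, function(tips) {
    side <- sort(tree$tip.label[tips])
    if (ref %in% side) side <- setdiff(labels, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(side, collapse = "\r")
  }, character(1))
  unique(keys[!is.na(keys)])
}

oracle_rf <- function(t1, t2, normalized = TRUE) {
  b1 <- oracle_bipartitions(t1); b2 <- oracle_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (!normalized) return(rf)
  if (length(b1) + length(b2) == 0) 0 else rf / (length(b1) + length(b2))
}

# --- classical one-factor PERMANOVA pseudo-F by direct group sums ---------

oracle_permanova_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    dg <- d[i, i, drop = FALSE]
    ss_within <- ss_within + sum(dg[lower.tri(dg)]^2) / length(i)
  }
  a <- length(unique(groups))
  ss_a <- ss_total - ss_within
  (ss_a / (a - 1)) / (ss_within / (n - a))
}

# --- random fixtures ------------------------------------------------------

random_count_table <- function(n_samples, n_asvs, max_count = 50,
                               asv_ids = sprintf("t%d", seq_len(n_asvs))) {
  m <- matrix(rpois(n_samples * n_asvs, max_count / 5), n_samples, n_asvs,
              dimnames = list(sprintf("s%d", seq_len(n_samples)), asv_ids))
  # ensure no all-zero rows
  for (i in which(rowSums(m) == 0)) m[i, sample(n_asvs, 1)] <- 1L
  m
}

random_bl_tree <- function(n) {
  tr <- ape::rtree(n, tip.label = sprintf("t%d", seq_len(n)))
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  tr
}

toy_meta <- function(samples, species, controls = character(0)) {
  sample_info(data.frame(
    sample_id = c(samples, controls),
    host_species = c(species, rep("", length(controls))),
    host_genus = c(paste0("g_", species), rep("", length(controls))),
    host_family = c(rep("famA", length(samples)), rep("", length(controls))),
    site = "site1",
    is_control = c(rep(FALSE, length(samples)), rep(TRUE, length(controls)))))
}
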