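# Distance-based multivariate tests at the sample level: PERMANOVA
# (adonis) with sequential sums of squares, and the PERMDISP
# homogeneity-of-dispersions check that guards its interpretation.

#' PERMANOVA (adonis) on a distance matrix
#'
#' Sequential (additive, type-I) decomposition of the Gower-centered
#' inner-product matrix by the terms of `formula`, with pseudo-F statistics
#' tested by free permutation of sample labels. The usual formula
#' operators apply: `A*B` expands to `A + B + A:B`, nesting `A/B/C` to
#' `A + A:B + A:B:C`. Terms whose factor has a single level are dropped
#' with a warning. Wraps [vegan::adonis2()] with `by = "terms"`.
#'
#' @param dm A [distance_matrix()] over the samples.
#' @param design Data frame of per-sample factors and covariates; rownames
#'   (or a `sample_id` column) must match the distance-matrix labels.
#' @param formula Right-hand side, as formula or string, e.g.
#'   `~ Diet_PC1 * Habitat_PC1 + host_family / host_genus / host_species`.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A list of class `permanova_result` with a tidy `table`
#'   (term, df, ss, r2, pseudo_f, p_value; includes Residual and Total
#'   rows) and `n_permutations`.
#' @export
permanova <- function(dm, design, formula, n_permutations = 999, seed = 1) {
  assert_scalar_count(n_permutations, "n_permutations")
  m <- as_dm(dm)
  design <- as.data.frame(design)
  if (!is.null(design$sample_id)) rownames(design) <- design$sample_id
  missing_s <- setdiff(rownames(m), rownames(design))
  if (length(missing_s)) {
    stop("design missing sample(s): ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  design <- design[rownames(m), , drop = FALSE]
  rhs <- if (inherits(formula, "formula")) {
    paste(deparse(formula[[length(formula)]]), collapse = " ")
  } else {
    sub("^~", "", as.character(formula))
  }
  # drop variables that cannot contribute (single-level factors)
  vars <- intersect(all.vars(stats::as.formula(paste("~", rhs))), names(design))
  for (v in vars) {
    if (!is.numeric(design[[v]]) && length(unique(design[[v]])) < 2) {
      warning("term '", v, "' has a single level and was dropped")
      rhs <- gsub(sprintf("(^|[^[:alnum:]._])%s([^[:alnum:]._]|$)", v), "\\1 1 \\2", rhs)
    }
  }
  d <- stats::as.dist(m)   # adonis2 evaluates the response in this frame
  f <- stats::as.formula(paste("d ~", rhs), env = environment())
  set.seed(derive_seed(seed, "permanova"))
  fit <- vegan::adonis2(f, data = design, permutations = n_permutations,
                        by = "terms")
  tab <- as.data.frame(fit)
  out <- data.frame(term = rownames(tab), df = tab$Df, ss = tab$SumOfSqs,
                    r2 = tab$R2, pseudo_f = tab$F, p_value = tab[["Pr(>F)"]],
                    row.names = NULL)
  structure(list(table = out, n_permutations = n_permutations),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations)\n", x$n_permutations))
  print(x$table, digits = 4)
  invisible(x)
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the distance matrix by principal coordinates (retaining
#' imaginary-axis contributions as squared-distance subtractions), computes
#' each sample's distance to its group centroid, and tests equality of
#' mean dispersion across groups with a permutation F-test. A significant
#' PERMANOVA together with a significant PERMDISP can reflect dispersion
#' differences rather than centroid shifts. Wraps [vegan::betadisper()] +
#' [vegan::permutest()].
#'
#' @param dm A [distance_matrix()].
#' @param groups Per-sample group labels (named by sample, or in
#'   distance-matrix order). At least two groups with two members each.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A list of class `permdisp_result` with `groups`,
#'   `distances` (per-sample distance to group centroid), `f_statistic`,
#'   `p_value`, `n_permutations`.
#' @export
permdisp <- function(dm, groups, n_permutations = 999, seed = 1) {
  assert_scalar_count(n_permutations, "n_permutations")
  m <- as_dm(dm)
  if (!is.null(names(groups))) {
    missing_s <- setdiff(rownames(m), names(groups))
    if (length(missing_s)) stop("groups missing sample(s): ",
                                paste(missing_s, collapse = ", "), call. = FALSE)
    groups <- groups[rownames(m)]
  } else if (length(groups) != nrow(m)) {
    stop("`groups` must be named or match the number of samples", call. = FALSE)
  }
  groups <- factor(groups)
  sizes <- table(groups)
  # singleton groups are tolerated (they contribute zero dispersion), but
  # the F test needs at least two groups with within-group spread
  if (sum(sizes >= 2) < 2) {
    stop("need >= 2 groups with >= 2 members", call. = FALSE)
  }
  fit <- vegan::betadisper(stats::as.dist(m), groups, type = "centroid")
  set.seed(derive_seed(seed, "permdisp"))
  pt <- vegan::permutest(fit, permutations = n_permutations)
  structure(list(groups = groups,
                 distances = stats::setNames(fit$distances, rownames(m)),
                 f_statistic = pt$tab$F[1], p_value = pt$tab[["Pr(>F)"]][1],
                 n_permutations = n_permutations),
            class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat(sprintf("PERMDISP (%d permutations): F = %.3f, p = %.4g\n",
              x$n_permutations, x$f_statistic, x$p_value))
  invisible(x)
}
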