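# Ordination: classical principal coordinates analysis on a distance
# matrix and ordinary PCA on a trait table.

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns coordinates
#' scaled by the square roots of the positive eigenvalues. Negative
#' eigenvalues (non-Euclidean input, common for Bray-Curtis) are reported
#' but excluded from the coordinates and from the proportions of variance
#' explained; no Cailliez/Lingoes correction is applied.
#'
#' @param dm A [distance_matrix()].
#' @param k Number of axes to return (default 5). Truncated with a warning
#'   if it exceeds the number of positive eigenvalues.
#' @return A list of class `pcoa_result` with `labels`, `coordinates`
#'   (n x k, columns `PCo1`, ...), `eigenvalues` (all, descending) and
#'   `proportion_explained` (over positive eigenvalues, for the retained
#'   axes).
#' @export
pcoa <- function(dm, k = 5) {
  m <- as_dm(dm)
  n <- nrow(m)
  assert_scalar_count(k, "k")
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% (m^2) %*% j
  g <- (g + t(g)) / 2
  ee <- eigen(g, symmetric = TRUE)
  tol <- max(abs(ee$values)) * 1e-10
  pos <- which(ee$values > tol)
  if (k > length(pos)) {
    warning(sprintf("only %d positive eigenvalue(s); k truncated from %d",
                    length(pos), k))
    k <- length(pos)
  }
  keep <- pos[seq_len(k)]
  coords <- ee$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ee$values[keep]), nrow = k)
  dimnames(coords) <- list(rownames(m), paste0("PCo", seq_len(k)))
  structure(list(labels = rownames(m),
                 coordinates = coords,
                 eigenvalues = ee$values,
                 proportion_explained = ee$values[keep] / sum(ee$values[pos])),
            class = "pcoa_result")
}

#' Principal component analysis of a trait table
#'
#' Column-centered (optionally unit-variance standardized) PCA of
#' per-species traits, e.g. the six food-item proportions of a diet table
#' or environmental suitability values. PC1 scores are the usual univariate
#' trait summaries (`Diet_PC1`, `Habitat_PC1`) fed to downstream
#' phylogenetic regressions.
#'
#' @param traits Numeric matrix or data frame, species in rows, traits in
#'   columns (>= 2 traits, >= 3 species).
#' @param scale Standardize columns to unit variance (default FALSE:
#'   centering only).
#' @return A list of class `trait_pca` with `scores`, `loadings` and
#'   `proportion_explained` (one value per PC, summing to 1).
#' @export
trait_pca <- function(traits, scale = FALSE) {
  x <- as.matrix(traits)
  if (ncol(x) < 2 || nrow(x) < 3) stop("need >= 2 traits and >= 3 species", call. = FALSE)
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance trait column(s) with scale = TRUE: ",
           paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  structure(list(scores = fit$x,
                 loadings = fit$rotation,
                 proportion_explained = fit$sdev^2 / sum(fit$sdev^2)),
            class = "trait_pca")
}
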