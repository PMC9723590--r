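# Phylogenetic signal statistics for a univariate species trait (e.g. a
# principal-coordinate score of microbiome beta diversity, or Faith's PD).

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be named by species", call. = FALSE)
  missing_sp <- setdiff(tree$tip.label, names(trait))
  if (length(missing_sp)) {
    stop("trait missing for tip(s): ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  trait[tree$tip.label]
}

#' Blomberg's K with a tip-permutation test
#'
#' K is the ratio of the observed mean squared trait deviation (from the
#' phylogenetically estimated mean) to the GLS mean square under the
#' Brownian-motion covariance of the tree, scaled by its Brownian
#' expectation: K = 1 under Brownian motion, K > 1 when close relatives
#' resemble each other more than Brownian motion predicts. Significance is
#' one-tailed (greater) from random permutations of trait values across
#' tips, with the observed value included in the reference set (add-one
#' rule). Computation is delegated to [phytools::phylosig()].
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param trait Named numeric vector (one value per tip); must vary.
#' @param n_permutations Number of tip permutations (default 1000).
#' @param seed Integer seed.
#' @return A list of class `signal_result` with `statistic_name`,
#'   `estimate`, `p_value`, `n_permutations`.
#' @export
blomberg_k <- function(tree, trait, n_permutations = 1000, seed = 1) {
  assert_scalar_count(n_permutations, "n_permutations")
  x <- align_trait(tree, trait)
  if (stats::sd(x) == 0) stop("trait has zero variance", call. = FALSE)
  set.seed(derive_seed(seed, "blomberg_k"))
  # phylosig() includes the observed K as the first element of sim.K, so
  # nsim = n_permutations + 1 yields p = (1 + #{K_perm >= K_obs}) / (1 + n).
  fit <- phytools::phylosig(tree, x, method = "K", test = TRUE,
                            nsim = n_permutations + 1)
  structure(list(statistic_name = "blomberg_k",
                 estimate = unname(fit$K), p_value = unname(fit$P),
                 n_permutations = n_permutations),
            class = "signal_result")
}

#' Pagel's lambda by maximum likelihood
#'
#' Lambda scales the off-diagonal (shared-history) entries of the
#' Brownian-motion covariance: 0 means the trait is independent of the
#' phylogeny, 1 means pure Brownian motion. The estimate maximizes the
#' Gaussian likelihood jointly with the Brownian rate and root state over
#' `[0, lambda_max]`; the p-value is a likelihood-ratio test against
#' lambda = 0 (chi-squared, 1 df). Computation is delegated to
#' [phytools::phylosig()].
#'
#' @inheritParams blomberg_k
#' @return A list of class `signal_result` with `statistic_name`,
#'   `estimate`, `p_value`, `lr_statistic`, `log_likelihood`.
#' @export
pagel_lambda <- function(tree, trait) {
  x <- align_trait(tree, trait)
  if (stats::sd(x) == 0) stop("trait has zero variance", call. = FALSE)
  if (tree$Nnode <= 1) {
    stop("star phylogeny: lambda is unidentifiable (likelihood flat in lambda)",
         call. = FALSE)
  }
  fit <- phytools::phylosig(tree, x, method = "lambda", test = TRUE)
  structure(list(statistic_name = "pagel_lambda",
                 estimate = unname(fit$lambda), p_value = unname(fit$P),
                 lr_statistic = unname(2 * (fit$logL - fit$logL0)),
                 log_likelihood = unname(fit$logL)),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.3f, p = %.4g\n", x$statistic_name, x$estimate, x$p_value))
  invisible(x)
}
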