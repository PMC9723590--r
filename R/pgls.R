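# Phylogenetic generalized least squares: linear regression of a species
# trait with residual covariance proportional to the (lambda-transformed)
# Brownian-motion covariance of the host tree.

# Pagel-lambda transform of a BM covariance matrix (off-diagonals scaled).
lambda_transform <- function(v, lambda) {
  out <- v * lambda
  diag(out) <- diag(v)
  out
}

# Gaussian log-likelihood of a GLS fit with ML variance.
gls_loglik <- function(resid, v) {
  n <- length(resid)
  l <- chol(v)
  z <- backsolve(l, resid, transpose = TRUE)
  rss <- sum(z^2)
  s2 <- rss / n
  -n / 2 * log(2 * pi) - n / 2 * log(s2) - sum(log(diag(l))) - n / 2
}

# Core GLS solve: returns coefficients, their covariance scale, RSS on the
# whitened scale, and the whitened design for downstream F tests.
gls_fit <- function(y, x, v) {
  l <- chol(v)
  yw <- backsolve(l, y, transpose = TRUE)
  xw <- backsolve(l, x, transpose = TRUE)
  qrx <- qr(xw)
  if (qrx$rank < ncol(xw)) {
    bad <- colnames(xw)[qrx$pivot[(qrx$rank + 1):ncol(xw)]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qrx, yw)
  resid_w <- yw - xw %*% beta
  rss <- sum(resid_w^2)
  # (X' V^-1 X)^-1, unscrambling the QR pivot
  ri <- chol2inv(qr.R(qrx))
  xtx_inv <- matrix(0, ncol(xw), ncol(xw))
  xtx_inv[qrx$pivot, qrx$pivot] <- ri
  list(beta = beta, rss = rss, xtx_inv = xtx_inv, yw = yw, xw = xw)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `response ~ predictors` with residual covariance
#' `sigma^2 * V(lambda)`, where `V` is the Brownian-motion covariance
#' implied by the tree (shared branch length from the root) and `lambda`
#' scales its off-diagonal entries. With `lambda = 0` the fit reduces to
#' ordinary least squares; the default `lambda = 1` is the pure
#' Brownian-motion fit. `lambda = "ML"` profiles the likelihood over
#' `[0, 1]`.
#'
#' Coefficient p-values are two-sided t-tests on `n - p - 1` residual
#' degrees of freedom; the overall model p-value is an F-test of the full
#' model against the intercept-only model on the whitened scale.
#' `AIC = -2 logLik + 2 (p + 2)` counts the `p` slopes, the intercept and
#' the residual variance.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param response Named numeric vector (one value per tip).
#' @param predictors Named numeric matrix/data frame of per-species
#'   predictors (rownames = species).
#' @param interaction Add pairwise products of the predictor columns.
#' @param lambda Either a fixed value in `[0, 1]` (default 1) or `"ML"`.
#' @return A list of class `pgls_result` with `coefficients` (a data frame
#'   with estimate, std. error, t, p per term), `model_p`, `model_f`,
#'   `aic`, `log_likelihood`, `lambda_used`, `df_residual`, `n`.
#' @export
pgls <- function(tree, response, predictors, interaction = FALSE, lambda = 1) {
  y <- align_trait(tree, response)
  px <- as.matrix(predictors)
  if (is.null(rownames(px))) stop("predictors must have species rownames", call. = FALSE)
  missing_sp <- setdiff(tree$tip.label, rownames(px))
  if (length(missing_sp)) {
    stop("predictors missing for tip(s): ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  px <- px[tree$tip.label, , drop = FALSE]
  if (isTRUE(interaction) && ncol(px) >= 2) {
    combs <- utils::combn(colnames(px), 2)
    inter <- sapply(seq_len(ncol(combs)), function(i) px[, combs[1, i]] * px[, combs[2, i]])
    colnames(inter) <- apply(combs, 2, paste, collapse = ":")
    px <- cbind(px, inter)
  }
  n <- length(y)
  p <- ncol(px)
  if (n <= p + 2) stop("too few species for the number of predictors", call. = FALSE)
  x <- cbind("(Intercept)" = 1, px)
  v0 <- ape::vcv(tree)[tree$tip.label, tree$tip.label]

  fit_at <- function(lam) {
    v <- lambda_transform(v0, lam)
    f <- gls_fit(y, x, v)
    f$loglik <- gls_loglik(drop(y - x %*% f$beta), v)
    f$v <- v
    f
  }

  if (identical(lambda, "ML")) {
    opt <- stats::optimize(function(l) fit_at(l)$loglik, c(0, 1), maximum = TRUE)
    # compare against the boundary values, optimize() can miss an endpoint
    cand <- c(0, opt$maximum, 1)
    lls <- vapply(cand, function(l) fit_at(l)$loglik, numeric(1))
    lambda_used <- cand[which.max(lls)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("`lambda` must be in [0, 1] or \"ML\"", call. = FALSE)
    }
    lambda_used <- lambda
  }
  fit <- fit_at(lambda_used)
  df_res <- n - p - 1
  s2 <- fit$rss / df_res
  se <- sqrt(diag(fit$xtx_inv) * s2)
  tval <- drop(fit$beta) / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  coefs <- data.frame(term = colnames(x), estimate = drop(fit$beta),
                      std_error = se, t_value = tval, p_value = pval,
                      row.names = NULL)
  # overall F test vs intercept-only on the whitened scale
  null_fit <- gls_fit(y, x[, 1, drop = FALSE], fit$v)
  if (fit$rss < .Machine$double.eps * null_fit$rss) {
    warning("residual sum of squares is (numerically) zero; exact fit")
    model_f <- Inf; model_p <- 0
  } else {
    model_f <- ((null_fit$rss - fit$rss) / p) / (fit$rss / df_res)
    model_p <- stats::pf(model_f, p, df_res, lower.tail = FALSE)
  }
  aic <- -2 * fit$loglik + 2 * (p + 2)
  structure(list(coefficients = coefs, model_p = model_p, model_f = model_f,
                 aic = aic, log_likelihood = fit$loglik,
                 lambda_used = lambda_used, df_residual = df_res, n = n),
            class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf("PGLS (lambda = %.3f, n = %d): model F = %.3f, p = %.4g, AIC = %.2f\n",
              x$lambda_used, x$n, x$model_f, x$model_p, x$aic))
  print(x$coefficients, digits = 4)
  invisible(x)
}
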