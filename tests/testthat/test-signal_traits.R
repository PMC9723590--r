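# Ordination, phylogenetic signal, PGLS, PERMANOVA and PERMDISP.

test_that("PCoA recovers Euclidean configurations exactly", {
  pts <- rbind(p1 = c(0, 0), p2 = c(3, 0), p3 = c(0, 4))
  d <- distance_matrix(as.matrix(dist(pts)))
  res <- suppressWarnings(pcoa(d, 2))
  expect_equal(as.matrix(dist(res$coordinates)), unclass(d),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))
  expect_equal(sum(res$proportion_explained), 1, tolerance = 1e-9)
  # coordinate columns are orthogonal
  cp <- crossprod(res$coordinates)
  expect_equal(cp[1, 2], 0, tolerance = 1e-9)
})

test_that("identical objects get identical coordinates", {
  d <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  res <- suppressWarnings(pcoa(distance_matrix(d), 2))
  expect_equal(res$coordinates["a", ], res$coordinates["b", ], tolerance = 1e-9)
})

test_that("non-Euclidean distances yield reported negative eigenvalues", {
  # violates the four-point condition strongly enough to go non-Euclidean
  d <- matrix(c(0, 2, 2, 1.1,
                2, 0, 2, 1.1,
                2, 2, 0, 1.1,
                1.1, 1.1, 1.1, 0), 4)
  d <- d^2  # squared distances exaggerate the violation
  dimnames(d) <- list(letters[1:4], letters[1:4])
  res <- suppressWarnings(pcoa(distance_matrix(d), 3))
  expect_true(min(res$eigenvalues) < -1e-8)
  expect_true(all(res$proportion_explained >= 0))
  # k beyond the positive spectrum truncates with a warning
  expect_warning(pcoa(distance_matrix(d), 4), "truncated")
})

test_that("PCoA matches classical scaling from cmdscale", {
  set.seed(14)
  d <- as.matrix(dist(matrix(rnorm(24), 8)))
  dimnames(d) <- list(sprintf("s%d", 1:8), sprintf("s%d", 1:8))
  res <- pcoa(distance_matrix(d), 3)
  ref <- cmdscale(as.dist(d), k = 3, eig = TRUE)
  expect_equal(abs(res$coordinates), abs(ref$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(res$eigenvalues[1:3], ref$eig[1:3], tolerance = 1e-8)
})

test_that("Blomberg's K is 1 on a star tree and affine invariant", {
  star <- read_newick(text = paste0("(", paste0("t", 1:12, ":1", collapse = ","), ");"))
  set.seed(15)
  x <- setNames(rnorm(12), paste0("t", 1:12))
  k <- blomberg_k(star, x, n_permutations = 50, seed = 1)
  expect_equal(k$estimate, 1, tolerance = 1e-8)
  tr <- simulate_yule_tree(16, seed = 2)
  y <- setNames(rnorm(16), tr$tip.label)
  k1 <- blomberg_k(tr, y, n_permutations = 50, seed = 1)
  k2 <- blomberg_k(tr, 10 * y - 3, n_permutations = 50, seed = 1)
  expect_equal(k1$estimate, k2$estimate, tolerance = 1e-10)
  expect_error(blomberg_k(tr, setNames(rep(1, 16), tr$tip.label)), "variance")
})

test_that("Pagel's lambda is affine invariant and flags star trees", {
  tr <- simulate_yule_tree(24, seed = 4)
  x <- simulate_bm_trait(tr, rate = 1, seed = 5)
  l1 <- pagel_lambda(tr, x)
  l2 <- pagel_lambda(tr, -2 * x + 7)
  expect_equal(l1$estimate, l2$estimate, tolerance = 1e-6)
  expect_true(l1$estimate >= 0 && l1$estimate <= 1.001)
  star <- read_newick(text = paste0("(", paste0("t", 1:8, ":1", collapse = ","), ");"))
  expect_error(pagel_lambda(star, setNames(rnorm(8), paste0("t", 1:8))),
               "unidentifiable")
})

test_that("PGLS on a star tree equals ordinary least squares", {
  star <- read_newick(text = paste0("(", paste0("t", 1:20, ":1", collapse = ","), ");"))
  set.seed(16)
  x1 <- rnorm(20); x2 <- rnorm(20)
  y <- 1.5 * x1 - 0.5 * x2 + rnorm(20)
  names(y) <- paste0("t", 1:20)
  px <- cbind(x1 = x1, x2 = x2); rownames(px) <- names(y)
  fit <- pgls(star, y, px)
  ref <- summary(lm(y ~ x1 + x2))
  expect_equal(fit$coefficients$estimate, unname(ref$coefficients[, 1]),
               tolerance = 1e-9)
  expect_equal(fit$coefficients$std_error, unname(ref$coefficients[, 2]),
               tolerance = 1e-9)
  expect_equal(fit$coefficients$p_value, unname(ref$coefficients[, 4]),
               tolerance = 1e-9)
  expect_equal(fit$model_p, unname(pf(ref$fstatistic[1], ref$fstatistic[2],
                                      ref$fstatistic[3], lower.tail = FALSE)),
               tolerance = 1e-9)
})

test_that("PGLS under Brownian covariance matches nlme::gls", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule_tree(20, seed = 17)
  set.seed(18)
  x <- simulate_bm_trait(tr, 1)
  y <- 0.8 * x + simulate_bm_trait(tr, 0.5)
  px <- cbind(x = x)
  fit <- pgls(tr, y, px, lambda = 1)
  df <- data.frame(y = y, x = x, sp = names(y))
  ref <- nlme::gls(y ~ x, data = df, method = "ML",
                   correlation = ape::corBrownian(1, tr, form = ~sp))
  rs <- summary(ref)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$std_error, unname(rs$tTable[, 2]),
               tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-5)
})

test_that("PGLS flags exact fits and singular designs", {
  tr <- simulate_yule_tree(10, seed = 19)
  y <- simulate_bm_trait(tr, 1, seed = 20)
  px <- cbind(self = y)
  expect_warning(fit <- pgls(tr, y, px), "exact fit|zero")
  expect_equal(fit$coefficients$estimate[2], 1, tolerance = 1e-8)
  px2 <- cbind(a = y, b = 2 * y)
  expect_error(pgls(tr, y + rnorm(10), px2), "collinear")
})

test_that("single-factor PERMANOVA equals the direct group-sum pseudo-F", {
  set.seed(22)
  for (rep in 1:5) {
    n <- 12
    g <- rep(c("u", "v", "w"), each = 4)
    d <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    dimnames(d) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
    design <- data.frame(sample_id = rownames(d), g = g)
    res <- permanova(distance_matrix(d), design, "g", n_permutations = 49, seed = 1)
    f_direct <- oracle_permanova_f(d, g)
    expect_equal(res$table$pseudo_f[res$table$term == "g"], f_direct,
                 tolerance = 1e-10)
    # decomposition identity
    r2 <- res$table$r2
    expect_equal(sum(r2[res$table$term %in% c("g", "Residual")]), 1,
                 tolerance = 1e-9)
  }
})

test_that("well-separated clouds reach the minimal permutation p", {
  set.seed(23)
  pts <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:20), sprintf("s%d", 1:20))
  design <- data.frame(sample_id = rownames(d), g = rep(c("a", "b"), each = 10))
  res <- permanova(distance_matrix(d), design, "g", n_permutations = 999, seed = 2)
  expect_equal(res$table$p_value[1], 0.001)
})

test_that("PERMANOVA drops single-level terms with a warning", {
  set.seed(24)
  d <- as.matrix(dist(matrix(rnorm(16), 8)))
  dimnames(d) <- list(sprintf("s%d", 1:8), sprintf("s%d", 1:8))
  design <- data.frame(sample_id = rownames(d),
                       g = rep(c("a", "b"), 4), only = "one")
  expect_warning(res <- permanova(distance_matrix(d), design, "only + g",
                                  n_permutations = 49, seed = 1),
                 "single level")
  expect_true("g" %in% res$table$term)
  expect_false("only" %in% res$table$term)
})

test_that("PERMDISP measures distances to centroids and detects inflation", {
  set.seed(25)
  pts <- rbind(matrix(rnorm(40, sd = 1), 20), matrix(rnorm(40, sd = 4), 20))
  d <- as.matrix(dist(pts))
  labs <- sprintf("s%d", 1:40)
  dimnames(d) <- list(labs, labs)
  groups <- setNames(rep(c("tight", "wide"), each = 20), labs)
  res <- permdisp(distance_matrix(d), groups, n_permutations = 199, seed = 1)
  expect_true(all(res$distances >= 0))
  expect_lt(res$p_value, 0.05)
  expect_error(permdisp(distance_matrix(d), setNames(c("x", rep("y", 39)), labs)),
               ">= 2")
})

test_that("trait PCA proportions behave and scaling is honored", {
  set.seed(26)
  x <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("sp%d", 1:10), c("a", "b", "c")))
  res <- trait_pca(x)
  expect_equal(sum(res$proportion_explained), 1, tolerance = 1e-12)
  # two perfectly correlated traits: PC1 carries everything under scaling
  y <- cbind(a = x[, 1], b = 3 * x[, 1] + 2)
  res2 <- trait_pca(y, scale = TRUE)
  expect_equal(res2$proportion_explained[1], 1, tolerance = 1e-12)
  y2 <- cbind(a = x[, 1], const = rep(1, 10))
  expect_error(trait_pca(y2, scale = TRUE), "const")
})
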