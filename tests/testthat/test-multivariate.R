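# PCA and OPLS-DA engines: eigendecomposition oracle, defining
# constraints, VIP normalization, S-plot formulas, cross-validation.

test_that("PCA loadings equal covariance eigenvectors up to sign", {
  set.seed(14)
  for (rep in 1:3) {
    x <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, letters[1:4]))
    fit <- fit_pca(x, n_components = 4)
    ev <- eigen(cov(x))$vectors
    for (k in 1:4) {
      expect_equal(abs(unname(fit$loadings[, k])), abs(ev[, k]),
                   tolerance = 1e-8)
    }
    # scores are centered data on loadings; their covariance is diagonal
    sc_cov <- cov(fit$scores)
    expect_equal(sc_cov, diag(diag(sc_cov)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # variance fractions are non-increasing and sum to 1 over all components
    expect_true(all(diff(fit$explained) <= 1e-12))
    expect_equal(fit$r2x, 1, tolerance = 1e-12)
  }
})

test_that("collinear data loads on a single component", {
  t <- seq(-2, 2, length.out = 9)
  x <- cbind(a = 3 * t, b = -1.5 * t)
  fit <- fit_pca(x, 1)
  expect_equal(fit$explained[1], 1, tolerance = 1e-12)
  expect_error(fit_pca(matrix(1, 5, 3), 1), "constant")
  expect_error(fit_pca(matrix(rnorm(12), 4, 3), 4), "n_components")
})

test_that("OPLS-DA separates separable clusters and honours its constraints", {
  set.seed(15)
  n <- 12
  y <- rep(c("case", "ctrl"), each = n / 2)
  x <- matrix(rnorm(n * 6, 0, 0.3), n, 6)
  x[y == "case", 1:2] <- x[y == "case", 1:2] + 3
  colnames(x) <- sprintf("F%d", 1:6)
  fit <- fit_oplsda(x, y, n_orth = 1, positive_class = "case")
  expect_true(all(fit$t[y == "case"] > 0))
  expect_true(all(fit$t[y == "ctrl"] < 0))
  expect_gt(fit$r2y, 0.8)
  # orthogonal scores are exactly uncorrelated with the response
  yv <- ifelse(y == "case", 1, -1)
  for (o in seq_len(fit$n_orth)) {
    expect_lt(abs(cor(fit$t_orth[, o], yv)), 1e-8)
  }
  # prediction reproduces training classes
  pred <- predict(fit, x)
  expect_identical(pred$class, y)
})

test_that("data with no Y-orthogonal structure yields a negligible orthogonal component", {
  set.seed(16)
  y <- rep(c("a", "b"), each = 6)
  beta <- rnorm(5)
  x <- outer(ifelse(y == "a", 1, -1), beta) + matrix(rnorm(60, 0, 1e-3), 12, 5)
  colnames(x) <- sprintf("F%d", 1:5)
  fit <- fit_oplsda(x, y, n_orth = 1)
  if (fit$n_orth > 0) {
    expect_lt(var(fit$t_orth[, 1]), 1e-3 * var(fit$t))
  } else {
    succeed("orthogonal extraction stopped for lack of structure")
  }
})

test_that("with no orthogonal components the predictive weight is the PLS1 solution", {
  set.seed(17)
  x <- matrix(rnorm(48), 8, 6, dimnames = list(NULL, sprintf("F%d", 1:6)))
  y <- rep(c("a", "b"), 4)
  fit <- fit_oplsda(x, y, n_orth = 0, positive_class = "a")
  # textbook one-component PLS1 weight: X_c' y_c, normalized
  yv <- ifelse(y == "a", 1, -1)
  yc <- yv - mean(yv)
  xc <- scale(x, center = TRUE, scale = FALSE)
  w_ref <- drop(crossprod(xc, yc))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(abs(sum(fit$w * w_ref)), 1, tolerance = 1e-10)
  expect_equal(unname(fit$t), drop(xc %*% (fit$w)), tolerance = 1e-10)
})

test_that("adding orthogonal components never decreases R2Y and R2X stays in [0,1]", {
  set.seed(18)
  x <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, sprintf("F%d", 1:8)))
  y <- rep(c("a", "b"), each = 10)
  x[y == "a", 1] <- x[y == "a", 1] + 1.5
  r2y <- vapply(0:3, function(k) fit_oplsda(x, y, n_orth = k)$r2y, numeric(1))
  expect_true(all(diff(r2y) >= -1e-10))
  fit <- fit_oplsda(x, y, n_orth = 2)
  expect_gte(fit$r2x, 0)
  expect_lte(fit$r2x, 1)
  expect_error(fit_oplsda(x, rep("a", 20)), "two classes")
})

test_that("squared VIP sums to the feature count and concentrates on informative features", {
  set.seed(19)
  x <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, sprintf("F%d", 1:8)))
  y <- rep(c("a", "b"), each = 10)
  x[y == "a", 3] <- x[y == "a", 3] + 2
  for (k in 0:2) {
    fit <- fit_oplsda(x, y, n_orth = k)
    expect_equal(sum(fit$vip^2), 8, tolerance = 1e-8)
  }
  # a single informative feature among pure noise approaches VIP = sqrt(p)
  x2 <- matrix(rnorm(40 * 8, 0, 1), 40, 8, dimnames = list(NULL, sprintf("F%d", 1:8)))
  y2 <- rep(c("a", "b"), each = 20)
  x2[, 1] <- ifelse(y2 == "a", 1, -1) * 3 + rnorm(40, 0, 0.05)
  fit2 <- fit_oplsda(x2, y2, n_orth = 0)
  expect_gt(fit2$vip[["F1"]], 0.85 * sqrt(8))
  expect_true(all(fit2$vip[-1] < 1))
})

test_that("S-plot coordinates equal direct covariance and correlation formulas", {
  set.seed(20)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("F1", "F2", "F3")))
  y <- rep(c("a", "b"), 5)
  x[, 1] <- ifelse(y == "a", 1.5, -1.5) + rnorm(10, 0, 0.2)
  fit <- fit_oplsda(x, y, n_orth = 0, positive_class = "a")
  sp <- s_plot(fit, x)
  for (j in 1:3) {
    expect_equal(sp$p[j], cov(fit$t, x[, j]), tolerance = 1e-12)
    expect_equal(sp$pcorr[j], cor(fit$t, x[, j]), tolerance = 1e-12)
  }
  expect_true(all(abs(sp$pcorr) <= 1))
  # a feature equal to the score itself has pcorr exactly 1
  x2 <- cbind(x, Ft = fit$t)
  sp2 <- s_plot(fit, x2)
  expect_equal(sp2$pcorr[sp2$feature_id == "Ft"], 1, tolerance = 1e-12)
  expect_error(s_plot(fit, cbind(x, Fc = rep(1, 10))), "constant")
})

test_that("cross-validated PRESS equals an explicit leave-fold-out loop", {
  set.seed(22)
  x <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, sprintf("F%d", 1:4)))
  y <- rep(c("a", "b"), 3)
  x[y == "a", 1] <- x[y == "a", 1] + 2
  folds <- c(1, 1, 2, 2, 3, 3)
  got <- cross_validate("oplsda", x, y, folds = folds, n_orth = 0)
  yv <- ifelse(y == "a", 1, -1)
  press <- 0; ss <- 0
  for (f in 1:3) {
    tr <- folds != f
    fit <- fit_oplsda(x[tr, , drop = FALSE], y[tr], n_orth = 0,
                      positive_class = "a")
    yh <- predict(fit, x[!tr, , drop = FALSE])$y_hat
    press <- press + sum((yv[!tr] - yh)^2)
    ss <- ss + sum((yv[!tr] - mean(yv[tr]))^2)
  }
  expect_equal(got$press, press, tolerance = 1e-10)
  expect_equal(got$q2, 1 - press / ss, tolerance = 1e-10)
})

test_that("Q2 behaves at the noise and noiseless limits", {
  set.seed(23)
  # pure-noise response: Q2 at or below ~0 on average
  q2_null <- vapply(1:8, function(s) {
    x <- matrix(rnorm(16 * 6), 16, 6, dimnames = list(NULL, sprintf("F%d", 1:6)))
    y <- rep(c("a", "b"), each = 8)
    cross_validate("oplsda", x, y, k_folds = 4, seed = s)$q2
  }, numeric(1))
  expect_lt(mean(q2_null), 0.1)
  # strongly predictable response: Q2 near 1
  x <- matrix(rnorm(20 * 6, 0, 0.1), 20, 6, dimnames = list(NULL, sprintf("F%d", 1:6)))
  y <- rep(c("a", "b"), each = 10)
  x[y == "a", 1:3] <- x[y == "a", 1:3] + 4
  q2_perfect <- cross_validate("oplsda", x, y, k_folds = 5, seed = 1)$q2
  expect_gt(q2_perfect, 0.9)
  # PCA Q2: strong low-rank structure is predictive
  z <- tcrossprod(rnorm(20), rnorm(6)) + matrix(rnorm(120, 0, 0.05), 20, 6)
  colnames(z) <- sprintf("F%d", 1:6)
  expect_gt(cross_validate("pca", z, k_folds = 5, seed = 1, n_components = 1)$q2, 0.8)
  # determinism given the seed
  a <- cross_validate("pca", z, k_folds = 5, seed = 9, n_components = 1)
  b <- cross_validate("pca", z, k_folds = 5, seed = 9, n_components = 1)
  expect_identical(a, b)
})

test_that("orthogonal component count selection stops when Q2 stalls", {
  set.seed(24)
  x <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, sprintf("F%d", 1:6)))
  y <- rep(c("a", "b"), each = 10)
  x[y == "a", 1] <- x[y == "a", 1] + 2
  pick <- choose_n_orth(x, y, max_orth = 2, seed = 3)
  expect_true(pick$n_orth %in% 0:2)
  expect_type(pick$q2, "double")
})
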