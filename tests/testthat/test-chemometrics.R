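test_that("autoscaling centers, scales and is idempotent", {
  X <- cbind(a = c(1, 3), b = c(10, 30))
  sc <- autoscale(X)
  expect_equal(unname(sc$values[, "a"]), c(-1, 1) / sqrt(2))
  expect_equal(colMeans(sc$values), c(a = 0, b = 0))
  expect_equal(apply(sc$values, 2, stats::sd), c(a = 1, b = 1))
  # idempotence
  again <- autoscale(sc$values)
  expect_equal(again$values, sc$values, tolerance = 1e-12)
  # constant column left at zero with a warning
  expect_warning(cc <- autoscale(cbind(a = c(1, 2, 3), b = c(4, 4, 4))),
                 "constant")
  expect_equal(unname(cc$values[, "b"]), c(0, 0, 0))
  expect_error(autoscale(matrix(1, 1, 2)), "2 rows")
})

test_that("training scaling parameters transfer to new data", {
  withr::with_seed(8, X <- matrix(rnorm(40), 10, 4))
  sc <- autoscale(X)
  expect_equal(apply_scaling(sc, X), sc$values, ignore_attr = TRUE)
  expect_error(apply_scaling(sc, X[, 1:3]), "mismatch")
})

test_that("PCA matches its closed forms and fixes component signs", {
  # two perfectly correlated variables: PC1 explains all variance,
  # loading proportional to (1,1)/sqrt(2)
  withr::with_seed(21, z <- rnorm(30))
  sc <- autoscale(cbind(z, z))
  pc <- suppressWarnings(pca(sc, 2))
  expect_equal(pc$explained[1], 1)
  expect_equal(abs(unname(pc$loadings[, 1])), rep(1 / sqrt(2), 2))
  expect_true(all(pc$loadings[, 1] > 0))  # sign convention

  # isotropic data: roughly equal split
  withr::with_seed(22, Y <- matrix(rnorm(4000), 2000, 2))
  pc2 <- pca(autoscale(Y), 2)
  expect_equal(pc2$explained, c(0.5, 0.5), tolerance = 0.05)
  expect_true(all(diff(pc2$explained) <= 0))

  # score covariance is diagonal; loadings orthonormal; fractions sum to 1
  withr::with_seed(23, W <- matrix(rnorm(200), 20, 10))
  pc3 <- pca(autoscale(W), 10)
  offdiag <- stats::cov(pc3$scores); diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 1e-8)
  expect_equal(crossprod(pc3$loadings), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(pc3$explained), 1)
})

test_that("PCA agrees with prcomp up to component sign", {
  withr::with_seed(31, X <- matrix(rnorm(150), 30, 5))
  sc <- autoscale(X)
  ours <- pca(sc, 5)
  ref <- stats::prcomp(sc$values, center = FALSE, scale. = FALSE)
  for (j in 1:5) {
    expect_equal(abs(unname(ours$loadings[, j])), abs(unname(ref$rotation[, j])),
                 tolerance = 1e-8)
  }
  expect_equal(ours$explained, ref$sdev^2 / sum(ref$sdev^2), tolerance = 1e-10)
})

test_that("confidence ellipses scale with the chi-square quantile", {
  withr::with_seed(41, {
    th <- runif(200, 0, 2 * pi)
    ring <- cbind(3 * cos(th), 3 * sin(th))
  })
  e <- confidence_ellipse(ring, level = 0.95)
  expect_equal(unname(e$center), c(0, 0), tolerance = 0.35)
  expect_equal(e$chisq_quantile, stats::qchisq(0.95, 2))
  expect_equal(e$chisq_quantile, 5.991, tolerance = 1e-3)
  # doubling the scores doubles the axes (shape scales by 4)
  e2 <- confidence_ellipse(2 * ring, level = 0.95)
  expect_equal(e2$shape, 4 * e$shape, tolerance = 1e-9)
  # membership: Mahalanobis rule
  inside <- ellipse_contains(e, rbind(c(0, 0), c(50, 50)))
  expect_equal(inside, c(TRUE, FALSE))
  path <- ellipse_path(e, 50)
  expect_equal(dim(path), c(50L, 2L))
  # boundary points sit exactly at the quantile
  d2 <- stats::mahalanobis(path, e$center, e$cov)
  expect_equal(d2, rep(e$chisq_quantile, 50), tolerance = 1e-8)

  expect_error(confidence_ellipse(ring[1:2, ]), ">= 3 samples")
  expect_error(confidence_ellipse(cbind(1:9, 2 * (1:9))), "degenerate")
})

test_that("PLS-DA separates separable clouds and is deterministic", {
  cl <- separable_clouds()
  m <- fit_plsda(cl$X, cl$labels, n_lv = 1)
  pr <- predict(m, cl$X)
  expect_equal(pr$labels, cl$labels)  # zero training misclassification
  # duplicated point predicts identically
  pr2 <- predict(m, cl$X[c(1, 1), ])
  expect_equal(pr2$scores[1, ], pr2$scores[2, ])
  expect_error(predict(m, cl$X[, 1, drop = FALSE]), "mismatch")
  expect_error(fit_plsda(cl$X, rep("one", nrow(cl$X))), "2 classes")
})

test_that("successive PLS scores are orthogonal and weights find the signal", {
  withr::with_seed(51, {
    X <- matrix(rnorm(300), 60, 5)
    y <- as.numeric(X[, 3] > 0)
  })
  sc <- autoscale(X)
  fit <- voccheese:::pls1_nipals(sc$values, y, ncomp = 4)
  G <- crossprod(fit$Tm)
  diag(G) <- 0
  expect_lt(max(abs(G)), 1e-8)
  # single informative column dominates the first weight vector
  expect_equal(which.max(abs(fit$W[, 1])), 3L)
  expect_gt(abs(fit$W[3, 1]), 0.9)
})

test_that("PLS with full rank reproduces ordinary least squares", {
  withr::with_seed(52, {
    X <- matrix(rnorm(120), 24, 5)
    y <- as.numeric(X[, 1] - X[, 2] + rnorm(24, 0, 0.2) > 0)
  })
  sc <- autoscale(X)
  fit <- voccheese:::pls1_nipals(sc$values, y, ncomp = 5)
  pls_pred <- voccheese:::pls1_predict_cum(fit, sc$values)[, fit$ncomp]
  ols <- stats::lm.fit(cbind(1, sc$values), y)
  expect_equal(pls_pred, drop(cbind(1, sc$values) %*% ols$coefficients),
               tolerance = 1e-8)
})

test_that("null labels give near-zero training R2Y with one latent variable", {
  withr::with_seed(53, {
    X <- matrix(rnorm(400 * 5), 400, 5)
    y <- rep(c(0, 1), 200)
  })
  sc <- autoscale(X)
  fit <- voccheese:::pls1_nipals(sc$values, y, ncomp = 1)
  yhat <- voccheese:::pls1_predict_cum(fit, sc$values)[, 1]
  r2y <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_lt(r2y, 0.05)
})

test_that("PLS1 predictions and VIP agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(61, {
    X <- matrix(rnorm(180), 30, 6)
    colnames(X) <- paste0("v", 1:6)
    y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(30, 0, 0.3) > 0)
  })
  sc <- autoscale(X)
  fit <- voccheese:::pls1_nipals(sc$values, y, ncomp = 2)
  ours <- voccheese:::pls1_predict_cum(fit, sc$values)[, 2]
  ref <- mixOmics::pls(X, y, ncomp = 2, mode = "regression", scale = TRUE)
  theirs <- predict(ref, X)$predict[, , 2]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
  vref <- mixOmics::vip(mixOmics::plsda(X, factor(y), ncomp = 2))[, 2]
  expect_equal(unname(vip_scores(fit)), unname(vref), tolerance = 1e-10)
})

test_that("VIP satisfies its normalization and symmetry properties", {
  # identical copies of one signal: all VIP = 1
  withr::with_seed(71, z <- rnorm(40))
  X <- cbind(z, z, z, z) + matrix(rnorm(160, 0, 1e-8), 40, 4)
  y <- as.numeric(z > 0)
  fit <- voccheese:::pls1_nipals(autoscale(X)$values, y, ncomp = 1)
  expect_equal(unname(vip_scores(fit)), rep(1, 4), tolerance = 1e-3)

  # one informative variable among p: its VIP approaches sqrt(p) while the
  # pure-noise variables (whose sample correlation with y is O(1/sqrt(n)))
  # stay small
  withr::with_seed(72, {
    p <- 8
    W <- matrix(rnorm(500 * p), 500, p)
    yy <- W[, 5] * 2
  })
  fit2 <- voccheese:::pls1_nipals(autoscale(W)$values, yy, ncomp = 1)
  v2 <- vip_scores(fit2)
  expect_equal(v2[5], sqrt(p), tolerance = 0.02)
  expect_true(all(v2[-5] < 0.5))

  # normalization identity on random fits
  withr::with_seed(73, {
    for (i in 1:10) {
      n <- sample(15:40, 1); p <- sample(4:12, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      fit <- voccheese:::pls1_nipals(voccheese:::autoscale_quiet(X)$values, y,
                                     ncomp = sample(1:3, 1))
      expect_equal(sum(vip_scores(fit)^2), p, tolerance = 1e-6)
    }
  })
})

test_that("marker selection applies an inclusive cutoff sorted by VIP", {
  v <- c(a = 1.5, b = 1.2, c = 0.9)
  expect_equal(names(select_markers(v, 1.2)), c("a", "b"))
  expect_equal(length(select_markers(v, 2)), 0L)
  expect_error(select_markers(v, -1))
})

test_that("VIP selection recovers planted markers from default synthetic data", {
  tab <- generate_voc_table(study_config("camembert", seed = 19))
  X <- voc_matrix(tab)
  m <- fit_plsda(X, dose_class_labels(tab$dose_kgy), n_lv = 3)
  sel <- select_markers(vip_max(m), cutoff = 1.2)
  truth <- attr(tab, "discriminant")
  expect_gte(mean(truth %in% names(sel)), 0.8)
})

test_that("maximum VIP of a binary model equals its positive-class VIP", {
  cl <- separable_clouds(n = 12, gap = 4, seed = 9)
  m <- fit_plsda(cl$X, cl$labels, n_lv = 2)
  expect_equal(unname(vip_max(m)),
               unname(pmax(vip_scores(m, class = "pos"),
                           vip_scores(m, class = "neg"))))
})
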