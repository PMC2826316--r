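test_that("scaling modes produce the documented columns", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(0, 0, 0))
  p <- suppressMessages(scale_matrix(X, scaling_spec("pareto")))
  expect_equal(p$dropped, "c")
  expect_equal(unname(p$X[, "a"]), c(-1, 0, 1))  # sd 1 so pareto = UV here
  uv <- suppressMessages(scale_matrix(X, scaling_spec("unit_variance")))
  expect_equal(unname(uv$X[, "b"]), c(-1, 0, 1))  # sd 2
  expect_equal(colMeans(p$X), c(a = 0, b = 0))
  expect_error(scale_matrix(cbind(c(1, 1), c(2, 2)), scaling_spec("pareto")),
               "zero variance")
})

test_that("PCA matches the truncated SVD and orders components by variance", {
  # rank-1 matrix: first component explains everything
  X1 <- outer(c(1, 2, 3, 4), c(1, -1, 2))
  X1 <- sweep(X1, 2, colMeans(X1))
  p1 <- suppressWarnings(fit_pca(X1, 1))
  expect_equal(p1$r2x[1], 1, tolerance = 1e-12)
  withr::with_seed(4, X <- scale(matrix(rnorm(60), 10, 6)))
  p <- fit_pca(X, 3)
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-10)
  expect_true(all(diff(p$r2x) <= 1e-12))
  recon <- p$scores %*% t(p$loadings)
  sv <- svd(X)
  recon_svd <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  expect_equal(sum((X - recon)^2), sum((X - recon_svd)^2), tolerance = 1e-8)
  expect_warning(fit_pca(X1, 3), "truncated")
})

test_that("PLS recovers perfect predictors and ignores orthogonal responses", {
  # orthogonal design matrix: one component recovers an axis response
  # exactly, and loadings recover the axes up to sign
  withr::with_seed(12, X <- qr.Q(qr(matrix(rnorm(80), 16, 5))) * 4)
  y <- X[, 3]
  f <- fit_pls(X, y, 1)
  expect_equal(f$r2y[1], 1, tolerance = 1e-10)
  expect_equal(abs(f$W[3, 1]), 1, tolerance = 1e-8)
  # response orthogonal to every column
  q <- qr.Q(qr(cbind(X, rnorm(16))))[, 6]
  y_orth <- q - mean(q)
  y_orth <- y_orth - X %*% solve(crossprod(X), crossprod(X, y_orth))
  f0 <- fit_pls(X, as.numeric(y_orth), 1)
  expect_lt(f0$r2y[1], 1e-8)
  expect_error(fit_pls(X, rep(1, 16), 1), "constant")
})

test_that("PLS scores are orthogonal and R2Y is non-decreasing", {
  dat <- random_xy(20, 6, seed = 31)
  sc <- scale_matrix(dat$X, scaling_spec("unit_variance"))
  f <- fit_pls(sc$X, dat$y - mean(dat$y), 4)
  G <- crossprod(f$T)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  expect_true(all(diff(f$r2y_cum) >= -1e-12))
})

test_that("one-component PLS1 equals the closed-form projection regression", {
  dat <- random_xy(15, 4, seed = 77)
  sc <- scale_matrix(dat$X, scaling_spec("unit_variance"))
  yc <- dat$y - mean(dat$y)
  f <- fit_pls(sc$X, yc, 1)
  w <- crossprod(sc$X, yc); w <- w / sqrt(sum(w^2))
  t <- sc$X %*% w
  pred_closed <- t %*% (crossprod(t, yc) / sum(t^2))
  expect_equal(as.numeric(predict(f, sc$X)), as.numeric(pred_closed),
               tolerance = 1e-10)
})

test_that("PLS1 predictions are invariant to orthogonal rotation of X", {
  dat <- random_xy(18, 5, seed = 41)
  withr::with_seed(42, R <- qr.Q(qr(matrix(rnorm(25), 5, 5))))
  sc <- scale_matrix(dat$X, scaling_spec("none"))
  yc <- dat$y - mean(dat$y)
  p1 <- predict(fit_pls(sc$X, yc, 1), sc$X)
  Xr <- dat$X %*% R
  sc2 <- scale_matrix(Xr, scaling_spec("none"))
  p2 <- predict(fit_pls(sc2$X, yc, 1), sc2$X)
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-9)
})

test_that("Q2 equals the brute-force segment-refit oracle", {
  for (s in 1:5) {
    dat <- random_xy(21, 5, seed = 100 + s)
    got <- q2_cv(dat$X, dat$y, n_components = 2,
                 x_scaling = scaling_spec("pareto"))
    want <- oracle_q2(dat$X, dat$y, 2)
    expect_equal(got$q2, want$q2, tolerance = 1e-9)
    expect_equal(got$q2_cum, want$q2_cum, tolerance = 1e-9)
  }
})

test_that("Q2 reaches 1 on noise-free linear data and <= 0 under the null", {
  dat <- random_xy(28, 4, seed = 9, noise = 0)
  expect_gte(q2_cv(dat$X, dat$y, 4,
                   x_scaling = scaling_spec("unit_variance"))$q2_cum, 0.999)
  nulls <- vapply(1:30, function(s) {
    withr::with_seed(300 + s, {
      X <- matrix(rnorm(28 * 6), 28, 6)
      y <- rnorm(28)
    })
    q2_cv(X, y, 1)$q2_cum
  }, numeric(1))
  expect_lt(mean(nulls), 0)
})

test_that("Q2 on a hand-checkable single-feature dataset matches the oracle", {
  X <- matrix(c(1, 2, 3, 4, 5, 6, 7), 7, 1)
  y <- c(1.1, 1.9, 3.2, 3.9, 5.1, 5.8, 7.2)
  got <- q2_cv(X, y, 1, n_segments = 7, x_scaling = scaling_spec("none"))
  want <- oracle_q2(X, y, 1, nseg = 7, mode = "none")
  expect_equal(got$q2_cum, want$q2_cum, tolerance = 1e-12)
  expect_gt(got$q2_cum, 0.9)
  expect_error(q2_cv(X[1:5, , drop = FALSE], y[1:5], 1, n_segments = 7),
               "fewer samples")
})

test_that("Q2 never exceeds R2Y on the training data and both are scale-invariant", {
  for (s in 1:5) {
    dat <- random_xy(21, 6, seed = 500 + s)
    sc <- scale_matrix(dat$X, scaling_spec("pareto"))
    f <- fit_pls(sc$X, dat$y - mean(dat$y), 2)
    cv <- q2_cv(dat$X, dat$y, 2)
    expect_lt(cv$q2_cum, f$r2y_cum[2] + 1e-9)
    cv_scaled <- q2_cv(dat$X, dat$y * 7.5, 2)
    expect_equal(cv$q2_cum, cv_scaled$q2_cum, tolerance = 1e-9)
  }
})

test_that("permutation validation separates real structure from noise", {
  dat <- random_xy(28, 6, seed = 13, noise = 0.2)
  v <- permutation_validate(dat$X, dat$y, 1, n_permutations = 25, seed = 2)
  expect_equal(nrow(v$permuted), 25)
  expect_true(all(v$real_Q2 > v$permuted$Q2))
  # pure-noise X: the real Q2 is not separated from the permuted ones
  withr::with_seed(77, {
    Xn <- matrix(rnorm(28 * 6), 28, 6); yn <- rnorm(28)
  })
  v0 <- permutation_validate(Xn, yn, 1, n_permutations = 25, seed = 2)
  expect_gt(mean(v0$permuted$Q2 >= v0$real_Q2), 0)
  # determinism
  v1 <- permutation_validate(dat$X, dat$y, 1, n_permutations = 1, seed = 99)
  v2 <- permutation_validate(dat$X, dat$y, 1, n_permutations = 1, seed = 99)
  expect_identical(v1$permuted, v2$permuted)
})

test_that("left-out prediction recovers noise-free responses and fixed folds", {
  dat <- random_xy(24, 3, seed = 21, noise = 0)
  lo <- predict_left_out(dat$X, dat$y, n_components = 3, n_folds = 4,
                         n_repeats = 2, seed = 5,
                         x_scaling = scaling_spec("unit_variance"))
  expect_equal(lo$predictions$y_pred, lo$predictions$y_true, tolerance = 1e-6)
  lo2 <- predict_left_out(dat$X, dat$y, n_components = 3, n_folds = 4,
                          n_repeats = 2, seed = 5,
                          x_scaling = scaling_spec("unit_variance"))
  expect_identical(lo$predictions$fold, lo2$predictions$fold)
  # permuted response: per-group prediction means stay near the grand mean
  d <- make_design(3, doses = c(0, 50, 500, 1000), days = 1)
  withr::with_seed(6, {
    X <- matrix(rnorm(12 * 10), 12, 10)
    yp <- sample(d$dose)
  })
  lp <- predict_left_out(X, yp, 1, n_folds = 3, n_repeats = 5, seed = 8)
  spread <- diff(range(lp$summary$mean_pred))
  expect_lt(spread, diff(range(d$dose)))
})

test_that("component selection stops when per-component Q2 drops", {
  dat <- random_xy(35, 5, seed = 61, noise = 0.1)
  k <- select_components(dat$X, dat$y, max_components = 4,
                         x_scaling = scaling_spec("unit_variance"))
  expect_gte(k, 1)
  expect_lte(k, 4)
  withr::with_seed(62, {
    Xn <- matrix(rnorm(35 * 5), 35, 5); yn <- rnorm(35)
  })
  expect_equal(select_components(Xn, yn, max_components = 4), 1L)
})
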