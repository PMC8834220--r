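test_that("SIMPLS collapses to the simple regression slope at p = 1", {
  set.seed(10)
  x <- matrix(rnorm(30)); y <- 2 * x[, 1] + rnorm(30, 0, 0.1)
  fit <- fit_simpls(x, y, 1)
  expect_equal(unname(fit$coef), cov(x[, 1], y) / var(x[, 1]),
               tolerance = 1e-12)
})

test_that("SIMPLS at full rank equals OLS and recovers noiseless truth", {
  set.seed(11)
  X <- matrix(rnorm(100), 20, 5)
  y <- drop(X %*% c(1, -2, 0, 3, 0.5)) + rnorm(20, 0, 0.3)
  fit <- fit_simpls(X, y, 5)
  ols <- lm.fit(cbind(1, X), y)
  expect_lt(max(abs(fit$fitted - ols$fitted.values)), 1e-8)
  # orthogonal scores and the beta reproduction identity
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_equal(fit$fitted,
               drop(fit$y_mean + sweep(X, 2, fit$x_mean) %*% fit$coef),
               tolerance = 1e-10)
  # exact recovery when y is exactly linear in a 2-dim X subspace
  y2 <- drop(X %*% c(1, 1, 0, 0, 0))
  fit2 <- fit_simpls(X, y2, 5)
  expect_lt(sqrt(mean(fit2$residuals^2)), 1e-10)
})

test_that("SIMPLS fitted values agree with an independent NIPALS PLS1", {
  set.seed(12)
  for (rep in 1:5) {
    X <- matrix(rnorm(25 * 8), 25, 8)
    y <- drop(X %*% rnorm(8)) + rnorm(25, 0, 0.5)
    for (A in c(1, 3, 5)) {
      expect_lt(max(abs(fit_simpls(X, y, A)$fitted -
                          nipals_pls1(X, y, A)$fitted)), 1e-8)
    }
  }
})

test_that("prediction honors the centering identities", {
  set.seed(13)
  X <- matrix(rnorm(36), 12, 3); y <- rnorm(12)
  fit <- fit_simpls(X, y, 2)
  expect_equal(predict(fit, X), fit$fitted, tolerance = 1e-12)
  expect_equal(unname(predict(fit, matrix(fit$x_mean, 1))), fit$y_mean,
               tolerance = 1e-12)
  expect_error(predict(fit, X[, 1:2]), "columns")
})

test_that("LOO cross-validation equals the naive refit loop exactly", {
  set.seed(14)
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- drop(X %*% c(1, 0, -1)) + rnorm(8, 0, 0.2)
  cv <- loo_cv(X, y, 2)
  for (a in 1:2) {
    naive <- sapply(1:8, function(i) {
      predict(fit_simpls(X[-i, ], y[-i], a), X[i, , drop = FALSE], ncomp = a)
    })
    expect_equal(unname(cv$predictions[, a]), unname(naive),
                 tolerance = 1e-12)
  }
  expect_equal(cv$rmsecv$rmsecv,
               sqrt(colMeans((cv$predictions - y)^2)), ignore_attr = TRUE)
})

test_that("duplicated rows make LOO optimistic (leakage sanity check)", {
  set.seed(15)
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- drop(X %*% c(2, -1, 0, 0)) + rnorm(10, 0, 0.05)
  Xd <- rbind(X, X); yd <- c(y, y)
  cv <- loo_cv(Xd, yd, 4)
  expect_lt(min(cv$rmsecv$rmsecv), 0.1)
})

test_that("an uninformative X keeps selected component counts small", {
  set.seed(16)
  sel <- replicate(30, {
    X <- matrix(rnorm(20 * 10), 20, 10)
    y <- rnorm(20)
    loo_cv(X, y, 8)$ncomp
  })
  expect_lte(median(sel), 3)
})

test_that("delete-one jack-knife SEs match a brute-force loop", {
  set.seed(17)
  X <- matrix(rnorm(24), 8, 3); colnames(X) <- c("a", "b", "c")
  y <- drop(X %*% c(1, 0, -2)) + rnorm(8, 0, 0.3)
  jk <- jackknife_beta(X, y, 2)
  B <- sapply(1:8, function(i) fit_simpls(X[-i, ], y[-i], 2)$coef)
  se <- sqrt(7 / 8 * rowSums((B - rowMeans(B))^2))
  expect_equal(jk$se, unname(se), tolerance = 1e-12)
  full <- fit_simpls(X, y, 2)
  expect_equal(jk$p.value,
               unname(2 * pt(-abs(full$coef / se), df = 7)),
               tolerance = 1e-12)
  expect_true(all(jk$conf.low <= jk$estimate & jk$estimate <= jk$conf.high))
})

test_that("jack-knife p-values are invariant to rescaling the response", {
  set.seed(18)
  X <- matrix(rnorm(60), 15, 4)
  y <- drop(X %*% c(3, 0, 0, -1)) + rnorm(15, 0, 0.4)
  jk1 <- jackknife_beta(X, y, 3)
  jk2 <- jackknife_beta(X, 100 * y + 7, 3)
  expect_equal(jk1$p.value, jk2$p.value, tolerance = 1e-8)
})

test_that("jack-knife finds a strong planted coefficient and not noise", {
  set.seed(19)
  hits <- replicate(20, {
    X <- matrix(rnorm(30 * 6), 30, 6)
    y <- 2 * X[, 1] + rnorm(30, 0, 0.05)
    jk <- jackknife_beta(X, y, 3)
    jk$p.value[1] < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate inputs raise the documented errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_simpls(X, rep(1, 10), 1), "zero variance")
  expect_warning(fit_simpls(X, rnorm(10), 5), "reduced")
  expect_error(jackknife_beta(X, rnorm(10), 1, n_segments = 1), "between")
  expect_error(loo_cv(X[1:2, ], rnorm(2), 1), "at least 3")
})
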