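test_that("PCA explains rank-1 data with one component and reconstructs at full rank", {
  set.seed(20)
  u <- rnorm(12); v <- rnorm(5)
  X1 <- outer(u, v)
  p1 <- pca_fit(X1, k = 3)
  expect_equal(p1$explained[1], 1, tolerance = 1e-10)

  X <- matrix(rnorm(60), 12, 5)
  full <- pca_fit(X)
  expect_equal(sum(full$all_explained), 1, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(full$loadings) - diag(ncol(full$loadings)))),
            1e-8)
  rec <- sweep(full$scores %*% t(full$loadings), 2, full$center, "+")
  expect_lt(max(abs(rec - X)), 1e-8)
  expect_error(pca_fit(X, k = 10), "<=")
})

test_that("Mahalanobis distance matches hand algebra and whitened norms", {
  # 4 points at the corners of a square: every D^2 is 1.5 by hand
  # (deviations (+-1, +-1), covariance diag(4/3))
  sq <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  mh <- mahalanobis_flag(sq, alpha = 0.05)
  expect_equal(mh$d2, rep(1.5, 4), tolerance = 1e-12)

  set.seed(21)
  Z <- matrix(rnorm(400), 200, 2)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  W <- Z %*% solve(chol(cov(Z)))          # exactly whitened
  mh2 <- mahalanobis_flag(W)
  expect_equal(mh2$d2, rowSums(scale(W, scale = FALSE)^2), tolerance = 1e-8)

  # invariance under an invertible affine map of score space
  A <- matrix(c(2, 1, 0, 3), 2)
  mh3 <- mahalanobis_flag(Z %*% A + 5)
  expect_equal(mh3$d2, mahalanobis_flag(Z)$d2, tolerance = 1e-8)
})

test_that("a planted 10-SD point is the one sample flagged", {
  set.seed(22)
  sc <- matrix(rnorm(200), 100, 2)
  sc[37, ] <- c(10 * sd(sc[, 1]), 0)
  mh <- mahalanobis_flag(sc, alpha = 0.025)
  expect_true(mh$flag[37])
  expect_equal(which(mh$flag), 37)
})

test_that("PLS score/orthogonal distances obey the structural identities", {
  set.seed(23)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(30, 0.2)
  A <- 3
  fit <- fit_simpls(X, y, A)
  d <- pls_distances(fit, X)
  n <- nrow(X)
  expect_equal(mean(d$h), A * (n - 1) / n, tolerance = 1e-10)
  # center row: h = 0, q = 0
  d0 <- pls_distances(fit, matrix(fit$x_mean, 1))
  expect_equal(d0$h, 0, tolerance = 1e-12)
  expect_equal(d0$q, 0, tolerance = 1e-12)
  # reconstructed rows lie exactly in the model plane: q = 0
  rec <- sweep(fit$scores %*% t(fit$P), 2, fit$x_mean, "+")
  expect_lt(max(pls_distances(fit, rec)$q), 1e-16 * max(d$q) + 1e-12)
})

test_that("data-driven limits recover chi-square scale and dof by Monte Carlo", {
  set.seed(24)
  u <- 2 * rchisq(10000, 4) / 4            # u0 = 2, N = 4
  cl <- critical_limits(tibble::tibble(h = u), approach = "data_driven",
                        alpha = 0.05)
  expect_lte(abs(cl$limits$N - 4), 1)
  expect_equal(cl$limits$u0, 2, tolerance = 0.1)
  clr <- critical_limits(tibble::tibble(h = u), approach = "robust",
                         alpha = 0.05)
  expect_lte(abs(clr$limits$N - 4), 1)
  expect_equal(clr$limits$u0, 2, tolerance = 0.1)
})

test_that("robust limits resist contamination that classical limits absorb", {
  set.seed(25)
  caught_rob <- numeric(100); caught_cls <- numeric(100)
  for (r in 1:100) {
    u <- rchisq(200, 5)
    bad <- sample(200, 40)
    u[bad] <- u[bad] * 50
    dd <- tibble::tibble(h = u)
    rob <- critical_limits(dd, "robust", alpha = 0.05)
    cls <- critical_limits(dd, "data_driven", alpha = 0.05)
    caught_rob[r] <- mean(rob$flags$flag[bad])
    caught_cls[r] <- mean(cls$flags$flag[bad])
  }
  expect_gte(mean(caught_rob), 0.95)
  expect_gt(mean(caught_rob), mean(caught_cls))

  # a single extreme point moves robust limits < 5 %, classical > 5 %
  set.seed(26)
  u <- rchisq(100, 5)
  u2 <- c(u[-1], 500)
  lim <- function(x, ap) critical_limits(tibble::tibble(h = x), ap)$limits$limit
  expect_lt(abs(lim(u2, "robust") - lim(u, "robust")) / lim(u, "robust"), 0.05)
  expect_gt(abs(lim(u2, "data_driven") - lim(u, "data_driven")) /
              lim(u, "data_driven"), 0.05)
})

test_that("degenerate distance sets raise errors", {
  expect_error(critical_limits(tibble::tibble(h = rep(2, 20)), "robust"),
               "variance")
  u <- c(rep(2, 18), 2.1, 1.9)             # variance > 0 but IQR = 0
  expect_error(critical_limits(tibble::tibble(h = u), "robust"), "IQR")
  expect_error(critical_limits(tibble::tibble(h = rchisq(20, 3)),
                               alpha = 1.5), "alpha")
})
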