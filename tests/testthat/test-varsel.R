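test_that("MC-UVE ranks a planted predictor top and excludes noise by construction", {
  set.seed(30)
  top <- replicate(10, {
    X <- matrix(rnorm(40 * 51), 40, 51)
    y <- 3 * X[, 5] + rnorm(40, 0, 0.3)
    sel <- mcuve(X, y, ncomp = 2, n_runs = 60, seed = sample.int(1e6, 1))
    which.max(abs(sel$stability)) == 5
  })
  expect_gte(mean(top), 0.9)

  set.seed(31)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- 3 * X[, 1] + rnorm(40, 0, 0.2)
  sel <- mcuve(X, y, ncomp = 2, n_runs = 60, seed = 99)
  expect_true(sel$selected[1])
  # reproducible from (data, params, seed)
  sel2 <- mcuve(X, y, ncomp = 2, n_runs = 60, seed = 99)
  expect_identical(sel$stability, sel2$stability)
  expect_error(mcuve(X, y, 2, n_runs = 10), ">= 50")
  expect_error(mcuve(X, y, 2, n_runs = 60, sample_fraction = 1.2), "0, 1")
})

test_that("permuting the response destroys the planted ranking", {
  set.seed(32)
  X <- matrix(rnorm(40 * 51), 40, 51)
  y <- 3 * X[, 5] + rnorm(40, 0, 0.3)
  ranks <- replicate(15, {
    yp <- sample(y)
    s <- mcuve(X, yp, ncomp = 2, n_runs = 50, seed = sample.int(1e6, 1))
    rank(-abs(s$stability))[5]
  })
  expect_gt(median(ranks), 10)
})

test_that("MC-UVE stability is equivariant to rescaling a column at full rank", {
  # PLS coefficients are scale-equivariant only when every latent dimension
  # is used (the OLS limit); stability, a mean/SD ratio, is then invariant
  set.seed(33)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- 2 * X[, 3] + rnorm(40, 0, 0.2)
  s1 <- suppressWarnings(mcuve(X, y, ncomp = 6, n_runs = 60, n_noise = 2, seed = 7))
  X2 <- X; X2[, 3] <- X2[, 3] * 10
  s2 <- suppressWarnings(mcuve(X2, y, ncomp = 6, n_runs = 60, n_noise = 2, seed = 7))
  expect_equal(s1$stability[3], s2$stability[3], tolerance = 1e-4)
})

test_that("beta selection keeps significant coefficient peaks and valleys", {
  set.seed(34)
  n <- 60; p <- 31
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0(seq(4000, by = 8, length.out = p))
  y <- 2 * X[, 10] - 2 * X[, 20] + rnorm(n, 0, 0.2)
  hits <- replicate(20, {
    idx <- sample(n)
    fit <- fit_simpls(X[idx, ], y[idx], 4)
    jk <- jackknife_beta(X[idx, ], y[idx], 4)
    sel <- selected_indices(beta_select(jk, fit))
    all(c(10, 20) %in% sel)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("beta selection errors when nothing is significant", {
  set.seed(35)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- rnorm(30)
  fit <- fit_simpls(X, y, 2)
  jk <- jackknife_beta(X, y, 2)
  jk$p.value[] <- 1
  expect_error(beta_select(jk, fit), "relax")
})

test_that("selection on the synthetic study is a pinned, shrinking set", {
  fx <- tiny_study(seed = 6)
  avg <- average_replicates(fx$spectra, "berry_id")
  sp <- fit_pretreatment(avg, c("snv", "mean_center"))$spectra
  X <- spectra_matrix(sp)
  y <- fx$berries$TSS[match(avg$sample_id, fx$berries$berry_id)]
  fit <- fit_simpls(X, y, 4)
  jk <- jackknife_beta(X, y, 4)
  sel <- beta_select(jk, fit)
  idx <- selected_indices(sel)
  expect_gt(length(idx), 0)
  expect_lt(length(idx), ncol(X))
  expect_identical(idx, sort(idx))
  # regression pin: identical inputs give the identical selection
  sel2 <- beta_select(jackknife_beta(X, y, 4), fit_simpls(X, y, 4))
  expect_identical(selected_indices(sel2), idx)
})

test_that("augmentation appends exactly one final column", {
  X <- matrix(rnorm(50 * 165), 50, 165)
  out <- augment_predictors(X, rnorm(50), name = "diameter")
  expect_equal(ncol(out), 166)
  expect_equal(colnames(out)[166], "diameter")
  expect_error(augment_predictors(X, rnorm(10)), "one value per sample")
  # degenerate constant extra column is rejected downstream by min-max
  out2 <- augment_predictors(X, rep(1, 50))
  expect_error(fit_apply_scaler(out2, mode = "minmax"), "diameter")
})
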