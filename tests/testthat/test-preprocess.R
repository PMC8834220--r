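make_row_spectra <- function(rows, grid = NULL) {
  m <- do.call(rbind, rows)
  grid <- grid %||% seq(8 * ncol(m), 8, by = -8)
  spectra_tbl(paste0("s", seq_len(nrow(m))), m, grid)
}

test_that("SNV centers and scales each spectrum and is affine-invariant", {
  sp <- make_row_spectra(list(c(1, 2, 3)))
  expect_equal(unname(spectra_matrix(snv(sp))[1, ]), c(-1, 0, 1))
  # fixed point
  z <- c(-1, 0, 1)
  expect_equal(unname(spectra_matrix(snv(make_row_spectra(list(z))))[1, ]), z)
  # affine invariance
  set.seed(1)
  x <- rnorm(50)
  two <- make_row_spectra(list(x, 1.7 * x + 0.3))
  out <- spectra_matrix(snv(two))
  expect_equal(unname(out[1, ]), unname(out[2, ]), tolerance = 1e-8)
  expect_error(snv(make_row_spectra(list(rep(2, 5)))), "s1")
})

test_that("MSC removes affine distortions of the reference exactly", {
  set.seed(2)
  ref <- abs(rnorm(40)) + 1
  sp <- make_row_spectra(list(ref, 2 * ref + 5, 0.5 * ref - 1))
  out <- msc(sp, reference = ref)
  m <- spectra_matrix(out$spectra)
  for (i in 1:3) expect_equal(unname(m[i, ]), unname(ref), tolerance = 1e-10)
  # refit oracle: OLS of corrected rows on the reference gives slope 1, int 0
  default <- msc(sp)
  mm <- spectra_matrix(default$spectra)
  ref2 <- default$transform$reference
  for (i in 1:3) {
    cf <- coef(lm(mm[i, ] ~ ref2))
    expect_equal(unname(cf), c(0, 1), tolerance = 1e-10)
  }
  expect_error(msc(sp, reference = rep(1, 40)), "zero variance")
})

test_that("Savitzky-Golay reproduces polynomials and scales derivatives by spacing", {
  grid <- seq(8000, 4008, by = -8)          # 500 points, 8 cm^-1 spacing
  q <- 3 + 0.002 * grid + 1e-6 * grid^2     # quadratic in wavenumber
  sp <- spectra_tbl("q", matrix(q, 1), grid)
  sm <- spectra_matrix(savgol(sp, window = 11, polyorder = 2, deriv = 0))
  expect_equal(unname(sm[1, ]), unname(q), tolerance = 1e-8)
  # derivative of a line is its slope, per cm^-1, despite the descending grid
  lin <- spectra_tbl("l", matrix(5 - 0.01 * grid, 1), grid)
  d1 <- spectra_matrix(savgol(lin, window = 15, polyorder = 2, deriv = 1))
  expect_equal(unname(d1[1, ]), rep(-0.01, length(grid)), tolerance = 1e-10)
  expect_error(savgol(sp, window = 10), "odd")
  expect_error(savgol(sp, window = 11, polyorder = 11), "<")
  expect_error(savgol(sp, window = 11, polyorder = 2, deriv = 3), "<=")
})

test_that("Savitzky-Golay interior points equal the windowed LSQ oracle", {
  set.seed(3)
  grid <- seq(6000, 5208, by = -8)          # 100 points
  x <- as.numeric(arima.sim(list(ar = 0.9), 100)) + 5
  sp <- spectra_tbl("r", matrix(x, 1), grid)
  for (prm in list(c(11, 2, 0), c(15, 3, 1), c(17, 4, 2))) {
    sm <- spectra_matrix(savgol(sp, prm[1], prm[2], prm[3]))
    for (i in c(20, 50, 80)) {
      expect_equal(sm[1, i], sg_point_oracle(x, i, prm[1], prm[2], prm[3],
                                             h = -8),
                   tolerance = 1e-10)
    }
  }
})

test_that("scalers learn constants on the training split only", {
  tr <- cbind(a = c(2, 4, 6), b = c(1, 2, 4))
  te <- cbind(a = c(0, 8), b = c(2, 2))
  mm <- fit_apply_scaler(tr, te, mode = "minmax")
  expect_equal(unname(mm$train[, "a"]), c(0, 0.5, 1))
  expect_equal(range(mm$train), c(0, 1))
  # value below the train minimum maps below 0 with train constants
  expect_lt(mm$applied[1, "a"], 0)
  expect_gt(mm$applied[2, "a"], 1)
  mc <- fit_apply_scaler(tr, te, mode = "mean_center")
  expect_equal(max(abs(colMeans(mc$train))), 0, tolerance = 1e-12)
  expect_equal(unname(mc$applied[1, ]), c(0 - 4, 2 - 7 / 3))
  expect_error(fit_apply_scaler(cbind(k = c(1, 1)), mode = "minmax"), "k")
})

test_that("chain order matters and fitted chains re-apply without re-estimation", {
  set.seed(4)
  m <- matrix(abs(rnorm(60)) + 1, 4, 15)
  sp <- spectra_tbl(paste0("s", 1:4), m, seq(120, 8, by = -8))
  a <- fit_pretreatment(sp, c("snv", "mean_center"))$spectra
  b <- fit_pretreatment(sp, c("mean_center", "snv"))$spectra
  expect_gt(max(abs(spectra_matrix(a) - spectra_matrix(b))), 1e-6)

  fit <- fit_pretreatment(sp[1:3, ], c("msc", "mean_center"))
  # applying to the training rows reproduces the fitted training output
  expect_equal(spectra_matrix(apply_pretreatment(fit, sp[1:3, ])),
               spectra_matrix(fit$spectra), tolerance = 1e-12)
  # constants frozen: a new row does not shift them (training output fixed)
  out4 <- apply_pretreatment(fit, sp)
  expect_equal(spectra_matrix(out4)[1:3, ], spectra_matrix(fit$spectra),
               tolerance = 1e-12)
  expect_equal(pretreatment_label(c("snv", "mean_center")), "snv+mean_center")
})
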