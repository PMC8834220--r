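test_that("study at the default design yields 270 berries and 810 face spectra", {
  out <- generate_study(study_design(seed = 5))
  expect_equal(nrow(out$berries), 3 * 3 * 30)
  expect_equal(nrow(out$spectra), 270 * 3)
  expect_equal(length(spectra_grid(out$spectra)), 1001)
  expect_equal(range(spectra_grid(out$spectra)), c(4000, 12000))
  # descending instrument convention, 8 cm^-1 spacing
  expect_equal(unique(diff(spectra_grid(out$spectra))), -8)
})

test_that("texture identities hold exactly, for hand values and every generated record", {
  expect_equal(texture_identities(10, 2, 0.5), tibble::tibble(BG = 5, BCh = 10))
  expect_equal(texture_identities(0, 3, 0.3)$BG, 0)
  expect_equal(texture_identities(0, 3, 0.3)$BCh, 0)
  expect_error(texture_identities(1, 1, 1.2), "BCo")
  expect_error(texture_identities(-1, 1, 0.5))

  b <- tiny_study(seed = 9)$berries
  expect_identical(b$BG, b$BH * b$BCo)
  expect_identical(b$BCh, b$BH * b$BCo * b$BS)
  expect_true(all(b$BCo > 0 & b$BCo < 1))
  expect_true(all(b$diameter > 0))
  expect_true(all(b$TSS > 0))
  expect_true(all(b$weight > 0))
})

test_that("zero noise collapses faces onto the pure mixture spectrum", {
  zero <- noise_model(0, 0, 0, 0, 0, 0)
  des <- study_design(n_blocks = 1, n_bags_per_block = 1,
                      n_berries_per_bag = 3, n_faces = 3, seed = 2)
  out <- generate_study(des, noise = zero, grid = instrument_grid(by = 80))
  m <- spectra_matrix(out$spectra)
  for (b in unique(out$spectra$berry_id)) {
    faces <- m[out$spectra$berry_id == b, , drop = FALSE]
    expect_equal(max(apply(faces, 2, function(v) diff(range(v)))), 0)
    # averaging therefore reproduces the (shared) pure spectrum exactly
    expect_identical(colMeans(faces), faces[1, ])
  }
})

test_that("a fixed seed reproduces the study byte-for-byte; seeds differ", {
  a <- generate_study(study_design(n_blocks = 1, n_bags_per_block = 1,
                                   n_berries_per_bag = 4, seed = 7),
                      grid = instrument_grid(by = 160))
  b <- generate_study(study_design(n_blocks = 1, n_bags_per_block = 1,
                                   n_berries_per_bag = 4, seed = 7),
                      grid = instrument_grid(by = 160))
  c <- generate_study(study_design(n_blocks = 1, n_bags_per_block = 1,
                                   n_berries_per_bag = 4, seed = 8),
                      grid = instrument_grid(by = 160))
  expect_identical(a, b)
  expect_false(identical(a$spectra, c$spectra))

  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_spectra(a$spectra, fa); write_spectra(b$spectra, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("absorbance is linear in concentration (Beer-Lambert mixing)", {
  grid <- instrument_grid(by = 40)
  bands <- tibble::tibble(component = "sugars", center = 8333,
                          width = 150, amplitude = 0.4)
  s1 <- mixture_spectrum(grid, bands, c(sugars = 1))
  s2 <- mixture_spectrum(grid, bands, c(sugars = 2))
  expect_equal(s2, 2 * s1)
  expect_equal(max(s1), 0.4 * max(exp(-0.5 * ((grid - 8333) / 150)^2)))
  # two components superpose additively
  two <- dplyr::bind_rows(bands,
    tibble::tibble(component = "water", center = 5128, width = 180,
                   amplitude = 1.2))
  s12 <- mixture_spectrum(grid, two, c(sugars = 1, water = 0.5))
  sw <- mixture_spectrum(grid,
    two[two$component == "water", ], c(water = 0.5))
  expect_equal(s12, s1 + sw)
})

test_that("invalid designs and band libraries are rejected", {
  expect_error(study_design(n_blocks = 0), "positive")
  expect_error(study_design(density_classes = tibble::tibble(
    label = "a", density = 1, weight = 0.5)), "sum to 1")
  bad_bands <- tibble::tibble(component = "water", center = 200,
                              width = 50, amplitude = 1)
  expect_error(generate_study(study_design(), bands = bad_bands,
                              grid = instrument_grid(by = 80)),
               "outside the grid")
  expect_error(noise_model(multiplicative_sd = -1))
})
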