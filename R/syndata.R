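#' Study design for a synthetic berry population
#'
#' Describes the sampling layout of a table-grape NIR study: blocks in the
#' vineyard, bags per block, berries analyzed per bag, replicate spectra per
#' berry (berry "faces"), and the densimetric classes berries are drawn from.
#' The default reproduces a 3 blocks x 3 bags x 30 berries design with 3
#' spectra per berry, i.e. 270 berries and 810 face-level spectra.
#'
#' @param n_blocks,n_bags_per_block,n_berries_per_bag,n_faces positive counts.
#' @param density_classes data frame with columns `label`, `density` (g/mL)
#'   and `weight` (mixing proportions summing to 1). Densimetric flotation
#'   sorting is emulated only as this latent class label.
#' @param seed integer seed; a fixed seed makes [generate_study()] output
#'   byte-identical.
#' @return a `study_design` list.
#' @export
study_design <- function(n_blocks = 3, n_bags_per_block = 3,
                         n_berries_per_bag = 30, n_faces = 3,
                         density_classes = default_density_classes(),
                         seed = 1L) {
  counts <- c(n_blocks = n_blocks, n_bags_per_block = n_bags_per_block,
              n_berries_per_bag = n_berries_per_bag, n_faces = n_faces)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("design counts must be positive integers")
  }
  density_classes <- tibble::as_tibble(density_classes)
  stopifnot(all(c("label", "density", "weight") %in% names(density_classes)))
  if (abs(sum(density_classes$weight) - 1) > 1e-12) {
    abort("density class mixing weights must sum to 1")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 n_bags_per_block = as.integer(n_bags_per_block),
                 n_berries_per_bag = as.integer(n_berries_per_bag),
                 n_faces = as.integer(n_faces),
                 density_classes = density_classes,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @rdname study_design
#' @export
default_density_classes <- function() {
  tibble::tibble(label = c("low", "mid", "high"),
                 density = c(1.02, 1.04, 1.06),
                 weight = c(1, 1, 1) / 3)
}

#' The FT-NIR instrument wavenumber grid
#'
#' 12,000 to 4,000 cm^-1 at 8 cm^-1 spacing (descending, the instrument
#' convention), 1001 points.
#'
#' @param from,to,by grid end points and spacing in cm^-1.
#' @return numeric vector of wavenumbers, descending.
#' @export
instrument_grid <- function(from = 12000, to = 4000, by = 8) {
  seq(from, to, by = -abs(by))
}

#' Absorption band library for the synthetic spectra
#'
#' Gaussian bands (center, width, amplitude) per chemical component. The
#' default centers are the classic NIR assignments for water, sugars,
#' organic acids and pectins in grape berries: O-H overtones near 10,526,
#' 6896, 6849 and 5128 cm^-1 (water), sugar-related C-H/O-H bands near 8333,
#' 5917, 5714, 4424 and 4344 cm^-1, organic-acid/sugar O-H second overtones
#' near 10,101 cm^-1, and broad pectin-associated bands in the combination
#' region.
#'
#' @return tibble with columns `component`, `center` (cm^-1), `width`
#'   (cm^-1), `amplitude`.
#' @export
band_library <- function() {
  tibble::tribble(
    ~component,      ~center, ~width, ~amplitude,
    "water",          10526,    260,     0.30,
    "water",           6896,    220,     1.00,
    "water",           6849,    220,     0.80,
    "water",           5128,    180,     1.20,
    "sugars",          8333,    150,     0.40,
    "sugars",          5917,    120,     0.30,
    "sugars",          5714,    120,     0.30,
    "sugars",          4424,    100,     0.35,
    "sugars",          4344,     90,     0.30,
    "organic_acids",  10101,    130,     0.15,
    "organic_acids",   4424,    110,     0.10,
    "pectins",         4700,    150,     0.20,
    "pectins",         5180,    140,     0.15
  )
}

#' Noise model for synthetic face-level spectra
#'
#' Intact berries are inhomogeneous samples; replicate scans of different
#' berry faces differ by scatter and presentation effects. Each face-level
#' spectrum is the berry's pure mixture spectrum distorted by a
#' multiplicative gain, an additive offset, a linear baseline, white noise,
#' and a per-face perturbation of the component concentrations; an optional
#' additive offset shared by all berries of a block emulates a field/batch
#' effect.
#'
#' @param multiplicative_sd SD of the per-face multiplicative scatter gain.
#' @param offset_sd SD of the per-face additive offset (absorbance units).
#' @param baseline_slope_sd SD of a per-face linear baseline (absorbance
#'   units across the full grid span).
#' @param white_sd SD of iid white noise per grid point.
#' @param face_sd SD of the per-face relative perturbation of component
#'   concentrations (berry-face inhomogeneity).
#' @param block_offset_sd SD of the per-block additive offset; set larger to
#'   exercise design-discrimination checks, 0 to switch the block effect off.
#' @return a `noise_model` list.
#' @export
noise_model <- function(multiplicative_sd = 0.05, offset_sd = 0.02,
                        baseline_slope_sd = 0.01, white_sd = 0.003,
                        face_sd = 0.01, block_offset_sd = 0.004) {
  vals <- c(multiplicative_sd, offset_sd, baseline_slope_sd, white_sd,
            face_sd, block_offset_sd)
  if (any(vals < 0) || any(!is.finite(vals))) {
    abort("all noise SDs must be finite and >= 0")
  }
  structure(list(multiplicative_sd = multiplicative_sd, offset_sd = offset_sd,
                 baseline_slope_sd = baseline_slope_sd, white_sd = white_sd,
                 face_sd = face_sd, block_offset_sd = block_offset_sd),
            class = "noise_model")
}

#' Latent link between berry density/diameter and reference values
#'
#' The generator's biological model. A berry's latent density (g/mL, set by
#' its densimetric class) and equatorial diameter (mm) determine the
#' reference values:
#' \itemize{
#'   \item TSS (degrees Brix) is linear in density plus Gaussian noise —
#'     soluble solids are what densimetric flotation measures.
#'   \item hardness BH (N) and springiness BS (mm) decrease with ripeness
#'     through a saturating logistic in density, with a diameter term;
#'     springiness additionally has a diameter-by-ripeness interaction, so
#'     these links are smoothly nonlinear and a nonlinear regressor has
#'     headroom over a linear one.
#'   \item cohesiveness BCo is nearly decoupled from the spectra-visible
#'     latents: mean 0.24, SD 0.03 — its small variability is itself a
#'     property of the population.
#'   \item gumminess and chewiness are the TPA identities BG = BH x BCo and
#'     BCh = BH x BCo x BS, applied exactly.
#' }
#' Component concentrations follow: sugars track TSS, water opposes sugars,
#' organic acids decline with ripeness, pectins track hardness; a mild
#' diameter-dependent path-length gain scales the whole pure spectrum.
#'
#' All coefficients are configurable; defaults bracket plausible
#' table-grape ranges (TSS ~ 12-21 Brix, BH ~ 4-14 N, BS ~ 1-2 mm).
#'
#' @param ... named overrides of the default coefficients (see
#'   `formals(link_spec)` for names and defaults).
#' @return a `link_spec` list.
#' @export
link_spec <- function(...) {
  defaults <- list(
    density_sd = 0.008,          # within-class latent density spread
    diameter_mean = 18, diameter_sd = 1.2, diameter_density_slope = 20,
    tss_intercept = 10, tss_density_slope = 170, tss_sd = 0.5,
    bh_base = 4, bh_amp = 9, bh_mid = 1.04, bh_scale = 0.012,
    bh_diameter_slope = 0.25, bh_sd = 0.35,
    bs_base = 1.0, bs_amp = 0.8, bs_mid = 1.04, bs_scale = 0.010,
    bs_diameter_slope = 0.05, bs_interaction = 0.04, bs_sd = 0.05,
    bco_mean = 0.24, bco_sd = 0.03,
    conc_sugar_per_brix = 1 / 16,
    conc_water_base = 1.15, conc_water_sugar_slope = -0.10,
    conc_acid_base = 0.8, conc_acid_density_slope = -8, conc_acid_sd = 0.05,
    conc_pectin_per_newton = 1 / 9, conc_pectin_sd = 0.02,
    pathlength_per_mm = 0.03
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown link coefficients: ", paste(unknown, collapse = ", ")))
  }
  defaults[names(dots)] <- dots
  structure(defaults, class = "link_spec")
}

#' TPA texture identities
#'
#' Gumminess and chewiness are not measured independently in texture profile
#' analysis; they are derived from hardness (BH, N), cohesiveness (BCo,
#' dimensionless in (0,1)) and springiness (BS, mm): BG = BH x BCo (N) and
#' BCh = BH x BCo x BS (mJ).
#'
#' @param BH hardness in N, >= 0.
#' @param BS springiness in mm, >= 0.
#' @param BCo cohesiveness, strictly inside (0, 1).
#' @return tibble with columns `BG` and `BCh`.
#' @examples
#' texture_identities(BH = 10, BS = 2, BCo = 0.5)  # BG 5, BCh 10
#' @export
texture_identities <- function(BH, BS, BCo) {
  if (!all(is.finite(BH), is.finite(BS), is.finite(BCo))) {
    abort("texture inputs must be finite")
  }
  if (any(BH < 0) || any(BS < 0)) {
    abort("BH and BS must be >= 0")
  }
  if (any(BCo <= 0) || any(BCo >= 1)) {
    abort("cohesiveness BCo must lie strictly inside (0, 1)")
  }
  tibble::tibble(BG = BH * BCo, BCh = BH * BCo * BS)
}

#' Pure Beer-Lambert mixture spectrum
#'
#' Sum over components of concentration times the component's Gaussian band
#' profile, evaluated on the grid. This is the noise-free spectrum the
#' generator distorts; absorbance is linear in every concentration.
#'
#' @param grid wavenumber grid (cm^-1).
#' @param bands band library tibble (component, center, width, amplitude).
#' @param concentrations named numeric vector, one entry per component in
#'   `bands`.
#' @return numeric vector of absorbances on `grid`.
#' @export
mixture_spectrum <- function(grid, bands, concentrations) {
  prof <- gaussian_bands(grid, bands)
  comps <- rownames(prof)
  if (!all(comps %in% names(concentrations))) {
    abort("`concentrations` must name every component in `bands`")
  }
  drop(concentrations[comps] %*% prof)
}

gaussian_bands <- function(grid, bands) {
  # component pure-profile matrix: components x grid points
  comps <- unique(bands$component)
  prof <- matrix(0, length(comps), length(grid),
                 dimnames = list(comps, NULL))
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    prof[b$component, ] <- prof[b$component, ] +
      b$amplitude * exp(-0.5 * ((grid - b$center) / b$width)^2)
  }
  prof
}

#' Generate a synthetic berry study
#'
#' Draws a full berry population under a [study_design()], computes the
#' reference values through the [link_spec()] latent model, and synthesizes
#' face-level NIR spectra as Beer-Lambert mixtures of the [band_library()]
#' component profiles distorted by the [noise_model()]. With an all-zero
#' noise model the faces of a berry are identical and equal the berry's pure
#' mixture spectrum.
#'
#' @param design a [study_design()].
#' @param bands a band library tibble.
#' @param noise a [noise_model()].
#' @param link a [link_spec()].
#' @param grid wavenumber grid; defaults to the 1001-point instrument grid.
#' @return list with elements `spectra` (face-level spectra tibble with
#'   metadata `berry_id`, `block`, `bag`, `face`) and `berries` (reference
#'   tibble: design labels, weight, diameter, TSS, BH, BS, BCo, BG, BCh).
#' @examples
#' tiny <- study_design(n_blocks = 1, n_bags_per_block = 1,
#'                      n_berries_per_bag = 4, n_faces = 2, seed = 7)
#' out <- generate_study(tiny, grid = instrument_grid(by = 80))
#' nrow(out$berries); nrow(out$spectra)
#' @export
generate_study <- function(design = study_design(), bands = band_library(),
                           noise = noise_model(), link = link_spec(),
                           grid = instrument_grid()) {
  stopifnot(inherits(design, "study_design"))
  check_grid(grid)
  rng <- range(grid)
  if (any(bands$center < rng[1] | bands$center > rng[2])) {
    bad <- bands$center[bands$center < rng[1] | bands$center > rng[2]][1]
    abort(paste0("band center ", bad, " cm^-1 lies outside the grid range"))
  }
  if (any(bands$width <= 0)) abort("band widths must be > 0")

  set.seed(design$seed)
  n_berries <- design$n_blocks * design$n_bags_per_block *
    design$n_berries_per_bag

  lay <- tidyr::expand_grid(block = seq_len(design$n_blocks),
                            bag = seq_len(design$n_bags_per_block),
                            berry = seq_len(design$n_berries_per_bag))
  cls_idx <- sample.int(nrow(design$density_classes), n_berries,
                        replace = TRUE, prob = design$density_classes$weight)
  cls <- design$density_classes[cls_idx, ]

  density <- rnorm(n_berries, cls$density, link$density_sd)
  diameter <- rnorm(n_berries, link$diameter_mean, link$diameter_sd) +
    link$diameter_density_slope * (density - mean(design$density_classes$density))
  diameter <- pmax(diameter, 8)
  # volume of a sphere of that diameter (mm -> cm), times latent density
  weight <- density * (4 / 3) * pi * (diameter / 20)^3

  TSS <- link$tss_intercept + link$tss_density_slope * (density - 1) +
    rnorm(n_berries, 0, link$tss_sd)
  TSS <- pmax(TSS, 0.5)
  ripeness_h <- stats::plogis(-(density - link$bh_mid) / link$bh_scale)
  ripeness_s <- stats::plogis(-(density - link$bs_mid) / link$bs_scale)
  BH <- link$bh_base + link$bh_amp * ripeness_h +
    link$bh_diameter_slope * (diameter - link$diameter_mean) +
    rnorm(n_berries, 0, link$bh_sd)
  BH <- pmax(BH, 0.1)
  BS <- link$bs_base + link$bs_amp * ripeness_s +
    link$bs_diameter_slope * (diameter - link$diameter_mean) +
    link$bs_interaction * (diameter - link$diameter_mean) * ripeness_s +
    rnorm(n_berries, 0, link$bs_sd)
  BS <- pmax(BS, 0.05)
  BCo <- pmin(pmax(rnorm(n_berries, link$bco_mean, link$bco_sd), 0.02), 0.98)
  tex <- texture_identities(BH, BS, BCo)

  berry_id <- sprintf("B%d_G%d_N%02d", lay$block, lay$bag, lay$berry)
  berries <- tibble::tibble(
    berry_id = berry_id, block = lay$block, bag = lay$bag,
    density_class = cls$label, density = density, weight = weight,
    diameter = diameter, TSS = TSS, BH = BH, BS = BS, BCo = BCo,
    BG = tex$BG, BCh = tex$BCh)

  # component concentrations per berry
  c_sugar <- link$conc_sugar_per_brix * TSS
  c_water <- link$conc_water_base + link$conc_water_sugar_slope * c_sugar
  c_acid <- pmax(link$conc_acid_base +
                   link$conc_acid_density_slope * (density - 1.04) +
                   rnorm(n_berries, 0, link$conc_acid_sd), 0)
  c_pectin <- pmax(link$conc_pectin_per_newton * BH +
                     rnorm(n_berries, 0, link$conc_pectin_sd), 0)
  prof <- gaussian_bands(grid, bands)
  conc <- cbind(water = c_water, sugars = c_sugar,
                organic_acids = c_acid, pectins = c_pectin)
  conc <- conc[, rownames(prof), drop = FALSE]
  gain_diam <- 1 + link$pathlength_per_mm * (diameter - link$diameter_mean)
  pure <- (conc %*% prof) * gain_diam

  block_offsets <- rnorm(design$n_blocks, 0, noise$block_offset_sd)
  ramp <- seq(-0.5, 0.5, length.out = length(grid))

  nf <- design$n_faces
  n_spec <- n_berries * nf
  face_of <- rep(seq_len(nf), times = n_berries)
  berry_of <- rep(seq_len(n_berries), each = nf)

  spec <- matrix(0, n_spec, length(grid))
  for (k in seq_len(n_spec)) {
    i <- berry_of[k]
    conc_face <- conc[i, ] * (1 + rnorm(ncol(conc), 0, noise$face_sd))
    pure_face <- as.vector(conc_face %*% prof) * gain_diam[i]
    gain <- 1 + rnorm(1, 0, noise$multiplicative_sd)
    offset <- rnorm(1, 0, noise$offset_sd)
    slope <- rnorm(1, 0, noise$baseline_slope_sd)
    white <- rnorm(length(grid), 0, noise$white_sd)
    spec[k, ] <- pure_face * gain + offset + slope * ramp + white +
      block_offsets[berries$block[i]]
  }
  # guard the zero-noise conservation contract exactly
  zero_noise <- all(unlist(noise[c("multiplicative_sd", "offset_sd",
                                   "baseline_slope_sd", "white_sd",
                                   "face_sd", "block_offset_sd")]) == 0)
  if (zero_noise) {
    spec <- pure[berry_of, , drop = FALSE]
  }

  ids <- paste0(berries$berry_id[berry_of], "_F", face_of)
  meta <- tibble::tibble(berry_id = berries$berry_id[berry_of],
                         block = berries$block[berry_of],
                         bag = berries$bag[berry_of],
                         face = face_of)
  list(spectra = spectra_tbl(ids, spec, grid, meta = meta),
       berries = berries)
}
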