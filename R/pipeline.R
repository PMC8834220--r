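#' Rank candidate pre-treatments and flag design discrimination
#'
#' Applies each candidate pre-treatment chain, runs a PCA and records the
#' cumulative variance explained by the first two components. Chains whose
#' first two score dimensions separate the samples by experimental-design
#' block (mean silhouette of the block labels above
#' `silhouette_threshold`) are flagged and excluded from the ranking: a
#' pre-treatment that mostly discriminates the field layout would let the
#' design, not the berry chemistry, drive the calibration.
#'
#' @param raw spectra tibble (replicate-averaged), with a block label
#'   metadata column.
#' @param candidates list of pre-treatment chains (see
#'   [fit_pretreatment()]); names are used as labels when present.
#' @param block_col metadata column holding the design label.
#' @param silhouette_threshold flagging threshold on the mean silhouette.
#' @return tibble ranked by cumulative variance among unflagged chains:
#'   `pretreatment`, `cumvar2`, `silhouette`, `flagged`, `rank`.
#' @export
select_pretreatment <- function(raw, candidates, block_col = "block",
                                silhouette_threshold = 0.25) {
  if (length(candidates) == 0) abort("no candidate pre-treatments")
  if (!block_col %in% names(raw)) {
    abort(paste0("design label column `", block_col, "` not found"))
  }
  labels <- as.character(raw[[block_col]])
  rows <- purrr::map_dfr(seq_along(candidates), function(i) {
    steps <- candidates[[i]]
    lab <- names(candidates)[i] %||% ""
    if (!nzchar(lab)) lab <- pretreatment_label(steps)
    sp <- fit_pretreatment(raw, steps)$spectra
    pca <- pca_fit(spectra_matrix(sp), k = 2)
    sil <- if (length(unique(labels)) > 1) {
      mean_silhouette(pca$scores, labels)
    } else 0
    tibble::tibble(pretreatment = lab,
                   cumvar2 = pca$cumulative[2],
                   silhouette = sil,
                   flagged = sil > silhouette_threshold)
  })
  if (all(rows$flagged)) {
    abort(paste0("every candidate discriminates the design blocks; ",
                 "silhouettes: ",
                 paste(signif(rows$silhouette, 3), collapse = ", ")))
  }
  rows <- dplyr::arrange(rows, .data$flagged, dplyr::desc(.data$cumvar2))
  rows$rank <- ifelse(rows$flagged, NA_integer_, seq_len(nrow(rows)) -
                        cumsum(rows$flagged))
  rows$rank[!rows$flagged] <- seq_len(sum(!rows$flagged))
  rows
}

mean_silhouette <- function(scores, labels) {
  D <- as.matrix(stats::dist(scores))
  labs <- unique(labels)
  s <- vapply(seq_len(nrow(D)), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(labs, labels[i]), function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_calibration()] with the pinned defaults:
#' SNV + mean centering (mean centering alone for hardness), one-shot
#' outlier removal at Mahalanobis alpha 0.025 and robust-limit outlier alpha 0.01,
#' Kennard-Stone 80/20 split on min-max normalized data, beta-coefficient
#' wavelength selection at p < 0.05 with the peak/valley magnitude rule,
#' LOO-CV SIMPLS up to `ncomp_max` components, and the [ann_spec()]
#' network. Diameter augmentation defaults to on for the size-driven
#' texture responses (BS, BCh) and off for TSS, BH and BCo.
#'
#' @param response one of `"TSS"`, `"BH"`, `"BS"`, `"BCo"`, `"BCh"`.
#' @param pretreatment pre-treatment chain; NULL picks the per-response
#'   default.
#' @param augment append the equatorial diameter as a predictor? NULL picks
#'   the per-response default.
#' @param selection `"beta"`, `"mcuve"` or `"none"`.
#' @param split_fraction Kennard-Stone training fraction.
#' @param ncomp_max LOO-CV component ceiling.
#' @param p_threshold,magnitude_rule passed to [beta_select()].
#' @param mcuve_runs,mcuve_fraction passed to [mcuve()].
#' @param ann_epochs,ann_l1 network training length and L1 penalty.
#' @param outlier_ncomp PLS components of the residual-distance screen.
#' @param alpha_mahalanobis,alpha_limits,var_target outlier screen levels.
#' @param scaler_fit `"train"` (default; min-max constants from training
#'   rows only) or `"all"`.
#' @param models model set to fit.
#' @param seed master seed for all stochastic stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(response = "TSS", pretreatment = NULL,
                            augment = NULL,
                            selection = c("beta", "mcuve", "none"),
                            split_fraction = 0.8, ncomp_max = 10,
                            p_threshold = 0.05,
                            magnitude_rule = "extrema",
                            mcuve_runs = 500, mcuve_fraction = 0.8,
                            ann_epochs = 1000, ann_l1 = 1e-4,
                            outlier_ncomp = 5, alpha_mahalanobis = 0.025,
                            alpha_limits = 0.01, var_target = 0.95,
                            scaler_fit = c("train", "all"),
                            models = c("pls_full", "pls_selected", "ann"),
                            seed = 1L) {
  selection <- match.arg(selection)
  scaler_fit <- match.arg(scaler_fit)
  response <- match.arg(response, c("TSS", "BH", "BS", "BCo", "BCh"))
  if (is.null(pretreatment)) {
    pretreatment <- if (response == "BH") "mean_center"
                    else c("snv", "mean_center")
  }
  if (is.null(augment)) augment <- response %in% c("BS", "BCh")
  structure(list(response = response, pretreatment = pretreatment,
                 augment = augment, selection = selection,
                 split_fraction = split_fraction, ncomp_max = ncomp_max,
                 p_threshold = p_threshold, magnitude_rule = magnitude_rule,
                 mcuve_runs = mcuve_runs, mcuve_fraction = mcuve_fraction,
                 ann_epochs = ann_epochs, ann_l1 = ann_l1,
                 outlier_ncomp = outlier_ncomp,
                 alpha_mahalanobis = alpha_mahalanobis,
                 alpha_limits = alpha_limits, var_target = var_target,
                 scaler_fit = scaler_fit, models = models,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full calibration workflow for one response
#'
#' Stages, in order: replicate averaging; pre-treatment (the configured
#' chain); outlier screening on the pre-treated spectra (PCA/Mahalanobis
#' plus robust PLS residual limits) and one-shot removal; Kennard-Stone
#' split on min-max normalized spectra; then per model set: full-spectrum
#' SIMPLS with LOO-CV component selection, jack-knife beta wavelength
#' selection with a reduced SIMPLS refit, and the feed-forward network on
#' the selected (optionally diameter-augmented, min-max scaled) predictors.
#' Modeling constants — pre-treatment constants, min-max ranges, selection,
#' component counts — are learned on training rows only; the final model's
#' data-driven critical limits are reported for reference.
#'
#' @param spectra face-level or averaged spectra tibble with `berry_id`
#'   metadata.
#' @param berries reference tibble with `berry_id`, the response column and
#'   `diameter`.
#' @param config a [pipeline_config()].
#' @return a `nir_run` report: `$metrics` (model x evaluation set tibble),
#'   `$counts`, `$outliers`, `$selection`, `$split`, fitted model objects
#'   and the resolved config.
#' @export
run_calibration <- function(spectra, berries, config = pipeline_config()) {
  response <- config$response
  if (!response %in% names(berries)) {
    abort(paste0("response `", response, "` not found in berry table"))
  }
  set.seed(config$seed)

  # --- averaging --------------------------------------------------------
  n_raw <- nrow(spectra)
  if ("berry_id" %in% names(spectra) &&
      anyDuplicated(spectra$berry_id) > 0) {
    avg <- average_replicates(spectra, "berry_id")
  } else {
    avg <- spectra
    if (!"berry_id" %in% names(avg)) avg$berry_id <- avg$sample_id
    avg$sample_id <- avg$berry_id
  }
  ord <- match(avg$sample_id, berries$berry_id)
  if (anyNA(ord)) abort("averaged spectra contain berries missing from the reference table")
  ref <- berries[ord, ]
  y_all <- ref[[response]]

  # --- pre-treatment (screening pass on all samples) --------------------
  pt_all <- fit_pretreatment(avg, config$pretreatment)

  # --- outlier screens, one-shot removal --------------------------------
  screen <- screen_outliers(pt_all$spectra, y_all,
                            ncomp = config$outlier_ncomp,
                            alpha_mahalanobis = config$alpha_mahalanobis,
                            alpha_limits = config$alpha_limits,
                            var_target = config$var_target)
  keep <- !screen$flag
  avg_kept <- avg[keep, , drop = FALSE]
  ref_kept <- ref[keep, , drop = FALSE]
  y_kept <- y_all[keep]

  # --- Kennard-Stone split on min-max normalized pre-treated spectra ----
  pt_kept <- fit_pretreatment(avg_kept, config$pretreatment)
  m_kept <- spectra_matrix(pt_kept$spectra)
  varying <- apply(m_kept, 2, function(v) max(v) > min(v))
  mm_all <- fit_apply_scaler(m_kept[, varying, drop = FALSE],
                             mode = "minmax")$train
  split <- kennard_stone(mm_all, fraction = config$split_fraction)

  # --- train-only pre-treatment for modeling ----------------------------
  pt_fit <- fit_pretreatment(avg_kept[split$train, , drop = FALSE],
                             config$pretreatment)
  Xtr <- spectra_matrix(pt_fit$spectra)
  Xte <- spectra_matrix(apply_pretreatment(pt_fit,
                                           avg_kept[split$test, , drop = FALSE]))
  ytr <- y_kept[split$train]; yte <- y_kept[split$test]
  dtr <- ref_kept$diameter[split$train]; dte <- ref_kept$diameter[split$test]

  metrics <- list(); fits <- list(); selection <- NULL
  a_cap <- min(config$ncomp_max, nrow(Xtr) - 2, ncol(Xtr))

  # --- full-spectrum PLS ------------------------------------------------
  cv_full <- loo_cv(Xtr, ytr, a_cap)
  fit_full <- fit_simpls(Xtr, ytr, cv_full$ncomp)
  if ("pls_full" %in% config$models) {
    metrics$pls_full <- dplyr::bind_rows(
      dplyr::mutate(fit_metrics(ytr, cv_full$loo_pred, "train_cv"),
                    model = "pls_full", ncomp = cv_full$ncomp),
      dplyr::mutate(fit_metrics(yte, predict(fit_full, Xte), "external"),
                    model = "pls_full", ncomp = cv_full$ncomp))
    fits$pls_full <- fit_full
  }

  # --- wavelength selection --------------------------------------------
  selection_error <- NULL
  if (config$selection == "beta") {
    jk <- jackknife_beta(Xtr, ytr, cv_full$ncomp)
    selection <- tryCatch(
      beta_select(jk, fit_full, p_threshold = config$p_threshold,
                  magnitude_rule = config$magnitude_rule),
      error = function(e) {
        # no reduced model can be built (nothing significant); continue
        # with the full spectrum so the remaining models still run
        warn(conditionMessage(e))
        NULL
      })
    if (is.null(selection)) selection_error <- "no significant predictors"
  } else if (config$selection == "mcuve") {
    selection <- mcuve(Xtr, ytr, cv_full$ncomp, n_runs = config$mcuve_runs,
                       sample_fraction = config$mcuve_fraction,
                       seed = config$seed)
  }
  sel_idx <- if (is.null(selection)) seq_len(ncol(Xtr))
             else selected_indices(selection)

  # --- reduced PLS ------------------------------------------------------
  if ("pls_selected" %in% config$models && !is.null(selection)) {
    Xtr_s <- Xtr[, sel_idx, drop = FALSE]
    Xte_s <- Xte[, sel_idx, drop = FALSE]
    a_sel <- min(a_cap, length(sel_idx))
    cv_sel <- loo_cv(Xtr_s, ytr, a_sel)
    fit_sel <- fit_simpls(Xtr_s, ytr, cv_sel$ncomp)
    metrics$pls_selected <- dplyr::bind_rows(
      dplyr::mutate(fit_metrics(ytr, cv_sel$loo_pred, "train_cv"),
                    model = "pls_selected", ncomp = cv_sel$ncomp),
      dplyr::mutate(fit_metrics(yte, predict(fit_sel, Xte_s), "external"),
                    model = "pls_selected", ncomp = cv_sel$ncomp))
    fits$pls_selected <- fit_sel
  }

  # --- ANN --------------------------------------------------------------
  if ("ann" %in% config$models) {
    Xtr_a <- Xtr[, sel_idx, drop = FALSE]
    Xte_a <- Xte[, sel_idx, drop = FALSE]
    if (config$augment) {
      Xtr_a <- augment_predictors(Xtr_a, dtr)
      Xte_a <- augment_predictors(Xte_a, dte)
    }
    keep_cols <- apply(Xtr_a, 2, function(v) max(v) > min(v))
    Xtr_a <- Xtr_a[, keep_cols, drop = FALSE]
    Xte_a <- Xte_a[, keep_cols, drop = FALSE]
    mm_fit_rows <- if (config$scaler_fit == "all") rbind(Xtr_a, Xte_a)
                   else Xtr_a
    sc <- fit_apply_scaler(mm_fit_rows, mode = "minmax")$transform
    Xtr_n <- apply_scaler(Xtr_a, sc); Xte_n <- apply_scaler(Xte_a, sc)
    spec <- ann_spec(ncol(Xtr_n), l1_lambda = config$ann_l1,
                     epochs = config$ann_epochs, seed = config$seed)
    net <- build_ann(spec)
    net <- train_ann(net, add_plus_one(Xtr_n, spec), ytr)
    val_pred <- predict(net, add_plus_one(Xtr_n, spec)[net$split$val, ,
                                                       drop = FALSE])
    metrics$ann <- dplyr::bind_rows(
      dplyr::mutate(fit_metrics(ytr[net$split$val], val_pred, "train_cv"),
                    model = "ann", ncomp = NA_integer_),
      dplyr::mutate(fit_metrics(yte, predict(net, add_plus_one(Xte_n, spec)),
                                "external"),
                    model = "ann", ncomp = NA_integer_))
    fits$ann <- net
  }

  # reference data-driven limits on the final full model
  dd_limits <- critical_limits(pls_distances(fit_full, Xtr),
                               approach = "data_driven",
                               alpha = config$alpha_limits)

  metrics_tbl <- dplyr::relocate(dplyr::bind_rows(metrics),
                                 "model", "set", "ncomp")
  counts <- tibble::tibble(stage = c("raw_spectra", "after_averaging",
                                     "after_outlier_removal",
                                     "train", "test"),
                           n = c(n_raw, nrow(avg), sum(keep),
                                 length(split$train), length(split$test)))
  structure(list(response = response,
                 pretreatment = pretreatment_label(config$pretreatment),
                 metrics = metrics_tbl, counts = counts,
                 outliers = screen,
                 removed = screen$sample_id[screen$flag],
                 selection = selection, n_selected = length(sel_idx),
                 selection_error = selection_error,
                 split = split, fits = fits, dd_limits = dd_limits,
                 config = config),
            class = "nir_run")
}

#' @export
print.nir_run <- function(x, ...) {
  cat("Calibration run for ", x$response, " (", x$pretreatment, ")\n",
      sep = "")
  cat("samples: ", paste(x$counts$n, collapse = " -> "),
      " (", paste(x$counts$stage, collapse = " -> "), ")\n", sep = "")
  cat("selected predictors: ", x$n_selected, "\n", sep = "")
  print(as.data.frame(
    dplyr::select(x$metrics, "model", "set", "ncomp", "r.squared",
                  "rmse", "bias", "rpd")), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Generate a study fixture
#'
#' Two canned problem sizes of the synthetic study: `"tiny"` (2 blocks x 2
#' bags x 6 berries, 2 faces, 101-point grid) for fast end-to-end tests,
#' and `"full_scale"` (3 x 3 x 30 berries, 3 faces, 1001-point grid). When
#' `dir` is given, the spectra and reference tables are written as CSV and
#' the design/noise/seed as a YAML config next to them.
#'
#' @param profile `"tiny"` or `"full_scale"`.
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return list with `spectra`, `berries`, `design`, `noise`, and `paths`
#'   (when written).
#' @export
make_fixture <- function(profile = c("tiny", "full_scale"), seed = 1L,
                         dir = NULL) {
  profile <- match.arg(profile)
  if (profile == "tiny") {
    design <- study_design(n_blocks = 2, n_bags_per_block = 2,
                           n_berries_per_bag = 6, n_faces = 2, seed = seed)
    grid <- instrument_grid(by = 80)
  } else {
    design <- study_design(seed = seed)
    grid <- instrument_grid()
  }
  noise <- noise_model()
  out <- generate_study(design, noise = noise, grid = grid)
  out$design <- design
  out$noise <- noise
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p_spec <- file.path(dir, "spectra.csv")
    p_ref <- file.path(dir, "berries.csv")
    p_cfg <- file.path(dir, "study.yaml")
    write_spectra(out$spectra, p_spec)
    readr::write_csv(out$berries, p_ref, progress = FALSE)
    yaml::write_yaml(list(
      profile = profile, seed = seed,
      design = list(n_blocks = design$n_blocks,
                    n_bags_per_block = design$n_bags_per_block,
                    n_berries_per_bag = design$n_berries_per_bag,
                    n_faces = design$n_faces,
                    density_classes = as.list(design$density_classes)),
      noise = unclass(noise),
      grid = list(from = max(grid), to = min(grid),
                  by = abs(diff(grid)[1]))), p_cfg, precision = 15)
    out$paths <- c(spectra = p_spec, berries = p_ref, config = p_cfg)
  }
  out
}

#' Regenerate a study from a fixture YAML config
#'
#' @param path YAML file written by [make_fixture()].
#' @return as [generate_study()].
#' @export
study_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  design <- study_design(
    n_blocks = cfg$design$n_blocks,
    n_bags_per_block = cfg$design$n_bags_per_block,
    n_berries_per_bag = cfg$design$n_berries_per_bag,
    n_faces = cfg$design$n_faces,
    density_classes = tibble::as_tibble(cfg$design$density_classes),
    seed = cfg$seed)
  noise <- do.call(noise_model, cfg$noise)
  grid <- instrument_grid(cfg$grid$from, cfg$grid$to, cfg$grid$by)
  generate_study(design, noise = noise, grid = grid)
}
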