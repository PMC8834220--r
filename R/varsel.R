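#' Monte Carlo uninformative variable elimination
#'
#' Fits many PLS models on random subsamples of the calibration rows and
#' scores every predictor by the stability of its regression coefficient,
#' s_j = mean_r(b_j) / sd_r(b_j). Predictors whose coefficients are large
#' but unstable across subsamples score low and are eliminated. The cutoff
#' follows the classical noise-augmentation rule: artificial noise columns
#' of negligible amplitude are appended before the runs and the cutoff is a
#' high quantile (default 99th) of their |s|; only real predictors whose
#' |s| exceeds it are selected.
#'
#' @param X predictor matrix (n x p).
#' @param y response vector.
#' @param ncomp PLS components per subsample fit.
#' @param n_runs number of Monte Carlo fits (>= 50; default 500).
#' @param sample_fraction fraction of rows per fit, in (0, 1); default 0.8.
#' @param cutoff_quantile quantile of |s| over the noise block used as the
#'   cutoff; default 0.99.
#' @param n_noise number of appended artificial noise columns (default p).
#' @param seed integer seed for the subsampling.
#' @return a `selection_result` tibble: `index`, `term`, `stability`,
#'   `selected`; attributes `method = "mcuve"`, `cutoff`, `params`.
#' @export
mcuve <- function(X, y, ncomp, n_runs = 500, sample_fraction = 0.8,
                  cutoff_quantile = 0.99, n_noise = ncol(X), seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n_runs < 50) abort("`n_runs` must be >= 50")
  if (sample_fraction <= 0 || sample_fraction >= 1) {
    abort("`sample_fraction` must be in (0, 1)")
  }
  set.seed(seed)
  noise_amp <- 1e-10 * max(mean(abs(X)), .Machine$double.eps)
  Xa <- cbind(X, matrix(rnorm(n * n_noise, 0, noise_amp), n, n_noise))
  m_sub <- max(2, round(sample_fraction * n))
  B <- matrix(0, ncol(Xa), n_runs)
  for (r in seq_len(n_runs)) {
    idx <- sample.int(n, m_sub)
    B[, r] <- fit_simpls(Xa[idx, , drop = FALSE], y[idx], ncomp)$coef
  }
  mu <- rowMeans(B)
  sdv <- apply(B, 1, sd)
  stab <- mu / sdv
  if (any(sdv == 0)) {
    warn("zero coefficient variance for some columns; stability set to Inf")
    stab[sdv == 0] <- sign(mu[sdv == 0]) * Inf
  }
  s_real <- stab[seq_len(p)]
  s_noise <- stab[p + seq_len(n_noise)]
  cutoff <- quantile(abs(s_noise), cutoff_quantile, names = FALSE)
  sel <- which(abs(s_real) > cutoff | is.infinite(s_real))
  out <- tibble::tibble(index = seq_len(p),
                        term = colnames(X) %||% paste0("x", seq_len(p)),
                        stability = s_real,
                        selected = seq_len(p) %in% sel)
  attr(out, "method") <- "mcuve"
  attr(out, "cutoff") <- cutoff
  attr(out, "params") <- list(ncomp = ncomp, n_runs = n_runs,
                              sample_fraction = sample_fraction,
                              cutoff_quantile = cutoff_quantile,
                              n_noise = n_noise, seed = seed)
  class(out) <- c("selection_result", class(out))
  out
}

plateau_extrema <- function(b) {
  # strict local extrema of a curve; plateaus keep their leftmost index
  r <- rle(b)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- cumsum(c(1, r$lengths[-k]))
  keep <- vapply(2:(k - 1), function(j) {
    (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1]) ||
      (r$values[j] < r$values[j - 1] && r$values[j] < r$values[j + 1])
  }, logical(1))
  starts[2:(k - 1)][keep]
}

#' Wavelength selection by significant high \eqn{\beta} coefficients
#'
#' Keeps predictors whose jack-knife p-value is below `p_threshold` and
#' whose coefficient magnitude satisfies the magnitude rule: by default the
#' predictor must sit on a peak or valley of the coefficient curve (a
#' strict local extremum over the wavenumber grid, plateaus keeping the
#' leftmost index); alternatively the top quantile of |beta| among the
#' significant predictors.
#'
#' @param jk a [jackknife_beta()] result.
#' @param model the `nir_pls` model the jack-knife was computed on.
#' @param p_threshold significance threshold (default 0.05).
#' @param magnitude_rule `"extrema"` or `"quantile"`.
#' @param beta_quantile quantile of |beta| for the `"quantile"` rule.
#' @return a `selection_result` tibble (columns `index`, `term`,
#'   `estimate`, `p.value`, `selected`).
#' @export
beta_select <- function(jk, model, p_threshold = 0.05,
                        magnitude_rule = c("extrema", "quantile"),
                        beta_quantile = 0.75) {
  magnitude_rule <- match.arg(magnitude_rule)
  beta <- model$coef
  p <- length(beta)
  stopifnot(nrow(jk) == p)
  signif_idx <- which(jk$p.value < p_threshold)
  if (magnitude_rule == "extrema") {
    mag_idx <- plateau_extrema(as.numeric(beta))
  } else {
    thr <- quantile(abs(beta[signif_idx]), beta_quantile, names = FALSE)
    mag_idx <- which(abs(beta) >= thr)
  }
  sel <- intersect(signif_idx, mag_idx)
  if (length(sel) == 0) {
    abort(paste0("no predictor is both significant (p < ", p_threshold,
                 ") and on a coefficient peak/valley; relax the thresholds"))
  }
  sel <- sort(sel)
  out <- tibble::tibble(index = seq_len(p),
                        term = jk$term,
                        estimate = unname(beta),
                        p.value = jk$p.value,
                        selected = seq_len(p) %in% sel)
  attr(out, "method") <- "beta"
  attr(out, "params") <- list(p_threshold = p_threshold,
                              magnitude_rule = magnitude_rule,
                              beta_quantile = beta_quantile)
  class(out) <- c("selection_result", class(out))
  out
}

#' @rdname beta_select
#' @param selection a `selection_result`.
#' @export
selected_indices <- function(selection) {
  selection$index[selection$selected]
}

#' Append an external predictor column
#'
#' Texture parameters depend strongly on berry size, so the equatorial
#' diameter (trivially measured with a caliper) is appended to the selected
#' wavenumbers as a final predictor column. The appended column never takes
#' part in wavelength selection and is always last.
#'
#' @param X predictor matrix after wavelength selection.
#' @param extra numeric vector, one value per row of `X`.
#' @param name column name for the appended predictor.
#' @return matrix with `ncol(X) + 1` columns.
#' @export
augment_predictors <- function(X, extra, name = "diameter") {
  X <- as.matrix(X)
  if (length(extra) != nrow(X)) {
    abort("`extra` must have one value per sample")
  }
  out <- cbind(X, extra)
  colnames(out)[ncol(out)] <- name
  out
}
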