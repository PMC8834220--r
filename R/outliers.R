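#' Principal component analysis of pre-treated spectra
#'
#' SVD-based PCA with internal column centering. Loading signs are fixed so
#' the largest-magnitude element of each loading vector is positive, making
#' the decomposition deterministic.
#'
#' @param X numeric matrix (samples x variables).
#' @param k number of components, at most `min(n - 1, p)`.
#' @return a `nir_pca` list: `loadings` (p x k, orthonormal), `scores`
#'   (n x k), `explained` (variance fractions), `cumulative`, `center`,
#'   `sdev`.
#' @export
pca_fit <- function(X, k = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1, p)
  k <- k %||% kmax
  if (k > kmax) abort(paste0("k must be <= min(n - 1, p) = ", kmax))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(loadings = loadings, scores = scores,
                 explained = ev[seq_len(k)],
                 cumulative = cumsum(ev)[seq_len(k)],
                 all_explained = ev, center = ctr,
                 sdev = sv$d[seq_len(k)] / sqrt(max(n - 1, 1))),
            class = "nir_pca")
}

#' Mahalanobis-distance screening on PCA scores
#'
#' Squared Mahalanobis distances of the score rows from their mean, flagged
#' against the chi-square quantile with `k` degrees of freedom: a sample is
#' flagged when D^2 exceeds `qchisq(1 - alpha, k)`.
#'
#' @param scores numeric matrix (n x k) of PCA scores.
#' @param alpha flagging level (default 0.025).
#' @return tibble: `sample`, `d2`, `limit`, `flag`.
#' @export
mahalanobis_flag <- function(scores, alpha = 0.025) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (k >= n) abort("need more samples than score dimensions")
  S <- stats::cov(scores)
  ok <- tryCatch({solve(S); TRUE}, error = function(e) FALSE)
  if (!ok) abort("singular score covariance; use fewer components")
  d2 <- stats::mahalanobis(scores, colMeans(scores), S)
  lim <- qchisq(1 - alpha, df = k)
  tibble::tibble(sample = rownames(scores) %||% as.character(seq_len(n)),
                 d2 = as.numeric(d2), limit = lim, flag = d2 > lim)
}

#' Score and orthogonal distances of samples to a PLS model
#'
#' The score distance h measures leverage within the model plane: the sum
#' over components of the squared score normalized by that component's
#' training score variance. The orthogonal distance q is the squared norm
#' of the X-residual after projecting onto the loading space. For the
#' orthonormal training scores of SIMPLS the training mean of h is
#' A (n - 1) / n.
#'
#' @param model a fitted [fit_simpls()] model.
#' @param X matrix of samples to measure (default: reconstructed training
#'   rows are used when omitted is not supported; pass the training X).
#' @return tibble: `sample`, `h`, `q`.
#' @export
pls_distances <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p) abort("column mismatch with the model")
  Xc <- sweep(X, 2, model$x_mean)
  # scores of new rows in the SIMPLS basis: T_new = Xc R
  Tn <- Xc %*% model$R
  var_a <- colSums(model$scores^2) / (model$n - 1)
  h <- drop((Tn^2) %*% (1 / var_a))
  resid <- Xc - Tn %*% t(model$P)
  q <- rowSums(resid^2)
  tibble::tibble(sample = rownames(X) %||% as.character(seq_len(nrow(X))),
                 h = h, q = q)
}

chisq_dof_robust <- function(m, r, n_max = 200) {
  # match IQR/median of u0 * chi2_N / N to the observed ratio
  ratio <- r / m
  cand <- seq_len(n_max)
  theo <- (qchisq(0.75, cand) - qchisq(0.25, cand)) / qchisq(0.5, cand)
  cand[which.min(abs(theo - ratio))]
}

#' Chi-square critical limits for model distances
#'
#' Each distance (score or orthogonal) is modeled as u0 * chi2_N / N. The
#' data-driven approach estimates u0 and N from moments (u0 = mean,
#' N = round(2 mean^2 / var)); the robust approach replaces them with the
#' median and inter-quartile range: N is matched so the theoretical
#' IQR/median ratio of a scaled chi-square equals the observed one, and
#' u0 = median * N / qchisq(0.5, N). The limit at level `alpha` is
#' u0 * qchisq(1 - alpha, N) / N; a sample is an outlier when either its h
#' or its q exceeds the respective limit.
#'
#' @param distances tibble from [pls_distances()] (columns `h` and `q`), or
#'   any tibble of nonnegative distance columns.
#' @param approach `"robust"` (median/IQR) or `"data_driven"` (moments).
#' @param alpha flagging level (default 0.05).
#' @return a `critical_limits` list: per-distance tibble `limits`
#'   (distance, u0, N, limit), per-sample tibble `flags` (sample, h, q,
#'   flag_h, flag_q, flag).
#' @export
critical_limits <- function(distances,
                            approach = c("robust", "data_driven"),
                            alpha = 0.05) {
  approach <- match.arg(approach)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  cols <- intersect(c("h", "q"), names(distances))
  if (length(cols) == 0) abort("`distances` must have columns h and/or q")
  lims <- purrr::map_dfr(cols, function(cn) {
    u <- distances[[cn]]
    if (var(u) == 0) abort(paste0("zero variance of ", cn, " distances"))
    if (approach == "data_driven") {
      u0 <- mean(u)
      N <- max(1L, round(2 * u0^2 / var(u)))
    } else {
      m <- median(u); r <- stats::IQR(u)
      if (r == 0) abort(paste0("zero IQR of ", cn,
                               " distances; robust limits undefined"))
      N <- chisq_dof_robust(m, r)
      u0 <- m * N / qchisq(0.5, N)
    }
    tibble::tibble(distance = cn, u0 = u0, N = as.integer(N),
                   limit = u0 * qchisq(1 - alpha, N) / N)
  })
  flags <- tibble::tibble(sample = distances$sample %||%
                            as.character(seq_len(nrow(distances))))
  for (cn in cols) {
    lim <- lims$limit[lims$distance == cn]
    flags[[cn]] <- distances[[cn]]
    flags[[paste0("flag_", cn)]] <- distances[[cn]] > lim
  }
  flags$flag <- Reduce(`|`, flags[paste0("flag_", cols)])
  structure(list(approach = approach, alpha = alpha,
                 limits = lims, flags = flags),
            class = "critical_limits")
}

#' Spectral outlier screen: PCA + Mahalanobis, then PLS residual limits
#'
#' Convenience wrapper used by the pipeline: PCA on the pre-treated spectra
#' (components chosen as the smallest k whose cumulative explained variance
#' reaches `var_target`), Mahalanobis flagging on the scores, then a PLS fit
#' against the response with robust critical limits on score/orthogonal
#' distances. The union of both flag sets is reported.
#'
#' @param spectra pre-treated spectra tibble.
#' @param y response vector aligned with the rows.
#' @param ncomp PLS components for the residual screen.
#' @param alpha_mahalanobis,alpha_limits flagging levels; the removal
#'   level defaults to 0.01 (outliers), while 0.05 marks extremes only.
#' @param var_target cumulative-variance target for the PCA screen.
#' @return tibble: `sample_id`, `d2`, `h`, `q`, `flag_mahalanobis`,
#'   `flag_limits`, `flag`.
#' @export
screen_outliers <- function(spectra, y, ncomp = 5, alpha_mahalanobis = 0.025,
                            alpha_limits = 0.01, var_target = 0.95) {
  m <- spectra_matrix(spectra)
  pca <- pca_fit(m)
  k <- max(2L, min(which(pca$cumulative >= var_target)))
  k <- min(k, nrow(m) - 1L)
  mh <- mahalanobis_flag(pca$scores[, seq_len(k), drop = FALSE],
                         alpha = alpha_mahalanobis)
  fit <- fit_simpls(m, y, ncomp)
  dist <- pls_distances(fit, m)
  cl <- critical_limits(dist, approach = "robust", alpha = alpha_limits)
  tibble::tibble(sample_id = spectra$sample_id,
                 d2 = mh$d2, h = dist$h, q = dist$q,
                 flag_mahalanobis = mh$flag,
                 flag_limits = cl$flags$flag,
                 flag = mh$flag | cl$flags$flag)
}
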