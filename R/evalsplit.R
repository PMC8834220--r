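#' Kennard-Stone sample partitioning
#'
#' Deterministic maximin selection of a representative calibration subset:
#' the first two picks are the pair at maximal Euclidean distance; each
#' further pick maximizes its minimum distance to the already-selected set.
#' Ties break on the lowest original row index. Selection stops at
#' `round(fraction * n)` training samples; the rest form the test set.
#' Distances should be computed on the normalized (min-max scaled)
#' predictors.
#'
#' @param X numeric matrix of (normalized) predictors.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @return a `ks_split` list: integer vectors `train` and `test`, and
#'   `order` (the selection order of the training rows).
#' @examples
#' kennard_stone(matrix(c(0, 1, 10)), fraction = 2 / 3)
#' @export
kennard_stone <- function(X, fraction = 0.8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) abort("need at least 2 samples to split")
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  n_train <- max(2L, min(n - 1L, round(fraction * n)))
  D <- as.matrix(stats::dist(X))
  # maximal pair, lowest indices on ties
  mx <- max(D)
  pair <- which(D == mx, arr.ind = TRUE)
  pair <- pair[order(pmin(pair[, 1], pair[, 2]),
                     pmax(pair[, 1], pair[, 2])), , drop = FALSE]
  sel <- sort(c(pair[1, 1], pair[1, 2]))
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- which.max(mind)              # first maximum = lowest index tie-break
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  sel <- unname(sel)
  structure(list(train = sort(sel), test = setdiff(seq_len(n), sel),
                 order = sel),
            class = "ks_split")
}

#' Calibration performance metrics
#'
#' For a (reference, predicted) pair: bias = mean(pred - ref),
#' RMSE = sqrt(mean((pred - ref)^2)), SEP = sample SD of the residuals,
#' R2 = 1 - SSE/SST (coefficient of determination; the squared Pearson
#' correlation is reported alongside), and RPD = SD(reference)/SEP. The
#' identity RMSE^2 = SEP^2 (n-1)/n + bias^2 holds exactly.
#'
#' @param y_ref reference values (length >= 2, non-constant).
#' @param y_pred predicted values, same length.
#' @param set optional label of the evaluation set.
#' @return one-row tibble: `set`, `n`, `r.squared`, `pearson.r.squared`,
#'   `rmse`, `bias`, `sep`, `rpd`.
#' @export
fit_metrics <- function(y_ref, y_pred, set = NA_character_) {
  y_ref <- as.numeric(y_ref); y_pred <- as.numeric(y_pred)
  if (length(y_ref) != length(y_pred)) abort("length mismatch")
  n <- length(y_ref)
  if (n < 2) abort("need at least 2 observations")
  if (var(y_ref) == 0) abort("reference values are constant")
  e <- y_pred - y_ref
  sep <- sd(e)
  if (sep == 0 && mean(e) != 0) {
    abort("constant nonzero residual: SEP = 0, RPD undefined")
  }
  tibble::tibble(
    set = set, n = n,
    r.squared = 1 - sum(e^2) / sum((y_ref - mean(y_ref))^2),
    pearson.r.squared = if (var(y_pred) > 0) cor(y_ref, y_pred)^2 else 0,
    rmse = sqrt(mean(e^2)),
    bias = mean(e),
    sep = sep,
    rpd = if (sep > 0) sd(y_ref) / sep else Inf)
}
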