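#' SIMPLS partial least squares regression (single response)
#'
#' Direct SIMPLS: weight vectors are computed from the successively deflated
#' covariance vector s = X'y, giving orthonormal X-scores without deflating
#' X itself. Coefficients are nested — the model fitted with `ncomp = A`
#' contains the coefficient vectors of all smaller component counts — which
#' makes leave-one-out component selection cheap.
#'
#' @param X numeric predictor matrix (n x p); centered internally.
#' @param y numeric response vector; centered internally.
#' @param ncomp number of latent components A, at most `min(n - 1, p)`.
#' @return a `nir_pls` object: weights `R` (p x A), orthonormal scores `T`
#'   (n x A), loadings `P` (p x A), y-loadings `q`, per-component
#'   coefficient matrix `coefs` (p x A, column a = coefficients using the
#'   first a components), final `coef`, `x_mean`, `y_mean`, `fitted`,
#'   `residuals`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- X[, 1] - 2 * X[, 3] + rnorm(20, 0, .1)
#' fit <- fit_simpls(X, y, ncomp = 2)
#' glance(fit)
#' @export
fit_simpls <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) abort("need at least 2 samples")
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (var(y) == 0) abort("response has zero variance")
  a_max <- min(n - 1, p)
  if (ncomp > a_max) {
    warn(paste0("ncomp reduced from ", ncomp, " to ", a_max))
    ncomp <- a_max
  }
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean

  s <- drop(crossprod(Xc, yc))
  R <- matrix(0, p, ncomp); Tm <- matrix(0, n, ncomp)
  P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  V <- matrix(0, p, ncomp)
  tol <- 1e-12 * max(abs(s), 1)
  a_used <- 0
  for (a in seq_len(ncomp)) {
    r <- s
    t_a <- drop(Xc %*% r)
    nt <- sqrt(sum(t_a^2))
    if (!is.finite(nt) || nt < tol) {
      warn(paste0("rank deficiency: truncating at ", a - 1, " components"))
      break
    }
    t_a <- t_a / nt; r <- r / nt
    p_a <- drop(crossprod(Xc, t_a))
    q_a <- sum(yc * t_a)
    v <- p_a
    if (a > 1) v <- v - V[, seq_len(a - 1), drop = FALSE] %*%
        drop(crossprod(V[, seq_len(a - 1), drop = FALSE], p_a))
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    s <- s - v * sum(v * s)
    R[, a] <- r; Tm[, a] <- t_a; P[, a] <- p_a; q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0) abort("X has no covariance with y; cannot fit")
  idx <- seq_len(a_used)
  R <- R[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
  P <- P[, idx, drop = FALSE]; q <- q[idx]
  coefs <- sapply(idx, function(a)
    drop(R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]))
  coefs <- matrix(coefs, nrow = p,
                  dimnames = list(colnames(X), paste0("A", idx)))
  beta <- coefs[, a_used]
  fitted <- drop(y_mean + Xc %*% beta)
  structure(list(ncomp = a_used, R = R, scores = Tm, P = P, q = q,
                 coefs = coefs, coef = beta, x_mean = x_mean, y_mean = y_mean,
                 fitted = fitted, residuals = y - fitted, n = n, p = p),
            class = "nir_pls")
}

#' @rdname fit_simpls
#' @param object fitted `nir_pls` model.
#' @param newdata matrix with `p` columns.
#' @param ... ignored.
#' @export
predict.nir_pls <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    abort(paste0("newdata has ", ncol(newdata), " columns, model expects ",
                 object$p))
  }
  beta <- object$coefs[, ncomp]
  drop(object$y_mean + sweep(newdata, 2, object$x_mean) %*% beta)
}

#' Leave-one-out cross-validation for SIMPLS component selection
#'
#' For every left-out sample the model is refitted on the remaining n - 1
#' rows and the sample predicted at every candidate component count;
#' RMSECV(A) is minimized, taking the first minimum on ties.
#'
#' @inheritParams fit_simpls
#' @param ncomp_max largest candidate component count, at most
#'   `min(n - 2, p)`.
#' @return a `nir_pls_cv` list: tibble `rmsecv` (ncomp, rmsecv), selected
#'   `ncomp`, matrix `predictions` (n x A_max) of LOO predictions, and
#'   `loo_pred` at the selected count.
#' @export
loo_cv <- function(X, y, ncomp_max) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) abort("leave-one-out needs at least 3 samples")
  a_max <- min(n - 2, ncol(X))
  if (ncomp_max > a_max) {
    warn(paste0("ncomp_max reduced from ", ncomp_max, " to ", a_max))
    ncomp_max <- a_max
  }
  pred <- matrix(NA_real_, n, ncomp_max)
  for (i in seq_len(n)) {
    fit <- fit_simpls(X[-i, , drop = FALSE], y[-i], ncomp_max)
    for (a in seq_len(min(fit$ncomp, ncomp_max))) {
      pred[i, a] <- predict(fit, X[i, , drop = FALSE], ncomp = a)
    }
    if (fit$ncomp < ncomp_max) {
      pred[i, (fit$ncomp + 1):ncomp_max] <- pred[i, fit$ncomp]
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  sel <- which.min(rmsecv)              # first minimum on ties
  structure(list(rmsecv = tibble::tibble(ncomp = seq_len(ncomp_max),
                                         rmsecv = rmsecv),
                 ncomp = sel, predictions = pred, loo_pred = pred[, sel]),
            class = "nir_pls_cv")
}

#' Jack-knife inference for PLS coefficients
#'
#' The samples are split into `n_segments` groups (default: delete-one);
#' the model is refitted at fixed `ncomp` with each segment removed and the
#' Tukey jack-knife variance of each coefficient is computed across the
#' segment estimates. t statistics use df = segments - 1; p-values are
#' two-sided. A degenerate SE of 0 yields p = 0 for a nonzero coefficient
#' and p = 1 for a zero one.
#'
#' @inheritParams fit_simpls
#' @param n_segments number of jack-knife segments, between 2 and n.
#' @param level confidence level for the intervals.
#' @return a `nir_jackknife` tibble: `term`, `estimate`, `se`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`; attribute `n_segments`.
#' @export
jackknife_beta <- function(X, y, ncomp, n_segments = nrow(X), level = 0.95) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n_segments < 2 || n_segments > n) {
    abort("`n_segments` must be between 2 and n")
  }
  full <- fit_simpls(X, y, ncomp)
  seg <- split(seq_len(n), rep(seq_len(n_segments), length.out = n))
  if (any(lengths(seg) < 1)) abort("empty jack-knife segment")
  B <- vapply(seg, function(idx) {
    fit_simpls(X[-idx, , drop = FALSE], y[-idx], full$ncomp)$coef
  }, numeric(ncol(X)))
  B <- matrix(B, nrow = ncol(X))        # p x g
  g <- n_segments
  bbar <- rowMeans(B)
  se <- sqrt((g - 1) / g * rowSums((B - bbar)^2))
  est <- full$coef
  stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf) * sign(est))
  pv <- ifelse(se > 0, 2 * pt(-abs(est / se), df = g - 1),
               ifelse(est == 0, 1, 0))
  crit <- stats::qt(1 - (1 - level) / 2, df = g - 1)
  out <- tibble::tibble(
    term = colnames(X) %||% paste0("x", seq_len(ncol(X))),
    estimate = est, se = se, statistic = stat, p.value = pv,
    conf.low = est - crit * se, conf.high = est + crit * se)
  attr(out, "n_segments") <- g
  class(out) <- c("nir_jackknife", class(out))
  out
}

#' @export
print.nir_pls <- function(x, ...) {
  cat("SIMPLS regression: ", x$ncomp, " components, n = ", x$n,
      ", p = ", x$p, "\n", sep = "")
  cat("RMSE (fit): ", signif(sqrt(mean(x$residuals^2)), 4), "\n", sep = "")
  invisible(x)
}

#' Broom-style accessors for PLS fits
#'
#' `tidy()` returns one row per predictor with its regression coefficient
#' (merged with jack-knife inference when supplied); `glance()` returns a
#' one-row model summary.
#'
#' @param x a `nir_pls` model.
#' @param jackknife optional [jackknife_beta()] result for the same model.
#' @param ... ignored.
#' @method tidy nir_pls
#' @export
tidy.nir_pls <- function(x, jackknife = NULL, ...) {
  out <- tibble::tibble(
    term = names(x$coef) %||% paste0("x", seq_len(x$p)),
    wavenumber = suppressWarnings(as.numeric(names(x$coef))),
    estimate = unname(x$coef))
  if (!is.null(jackknife)) {
    out <- dplyr::left_join(out,
      dplyr::select(tibble::as_tibble(jackknife), "term", "se",
                    "statistic", "p.value"),
      by = "term")
  }
  out
}

#' @rdname tidy.nir_pls
#' @method glance nir_pls
#' @export
glance.nir_pls <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, n = x$n, p = x$p,
                 rmse = sqrt(mean(x$residuals^2)),
                 r.squared = 1 - sum(x$residuals^2) /
                   sum((x$fitted + x$residuals - x$y_mean)^2))
}
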