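# Independent oracle implementations used only in tests. These deliberately
# take the textbook route (explicit loops, deflation of X) so they share no
# code path with the package.

# NIPALS PLS1: X-deflation algorithm; spans the same Krylov space as SIMPLS
# for a single response, so fitted values must agree at any component count.
nipals_pls1 <- function(X, y, A) {
  X <- as.matrix(X); y <- as.numeric(y)
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean); f <- y - y_mean
  W <- NULL; P <- NULL; Q <- NULL; TT <- NULL
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    q <- sum(f * t) / sum(t^2)
    E <- E - tcrossprod(t, p)
    f <- f - q * t
    W <- cbind(W, w); P <- cbind(P, p); Q <- c(Q, q); TT <- cbind(TT, t)
  }
  beta <- W %*% solve(crossprod(P, W), Q)
  list(fitted = drop(y_mean + sweep(X, 2, x_mean) %*% beta),
       beta = drop(beta))
}

# exhaustive greedy Kennard-Stone re-implementation
ks_oracle <- function(X, n_train) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(NA, NA); bestd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(k) min(D[k, sel]))
    sel <- c(sel, cand[which.max(md)])
  }
  sort(sel)
}

# windowed least-squares polynomial fit evaluated at the window center
sg_point_oracle <- function(x, i, window, polyorder, deriv, h) {
  half <- (window - 1) / 2
  idx <- (i - half):(i + half)
  t <- seq(-half, half)
  fit <- lm(x[idx] ~ poly(t, polyorder, raw = TRUE))
  cf <- coef(fit)
  factorial(deriv) * unname(cf[deriv + 1]) / h^deriv
}

# tiny deterministic spectra table for IO / transform tests
toy_spectra <- function() {
  spectra_tbl(c("s1", "s2"),
              rbind(c(0.10, 0.25, 0.50), c(0.20, 0.45, 0.90)),
              grid = c(6000, 5000, 4000),
              meta = tibble::tibble(block = c(1, 2)))
}

tiny_study <- function(seed = 1) {
  make_fixture("tiny", seed = seed)
}
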