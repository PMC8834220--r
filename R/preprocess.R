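#' Standard normal variate transform
#'
#' Scatter correction that centers and scales every spectrum (row) to mean 0
#' and sample SD 1 (n-1 denominator). Removes per-spectrum additive and
#' multiplicative distortions.
#'
#' @param spectra a spectra tibble.
#' @return a spectra tibble of the same shape.
#' @export
snv <- function(spectra) {
  m <- spectra_matrix(spectra)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    abort(paste0("constant spectrum, SNV undefined for sample: ",
                 spectra$sample_id[which(s == 0)[1]]))
  }
  set_spectra_matrix(spectra, (m - mu) / s)
}

msc_apply <- function(m, ref) {
  t(apply(m, 1, function(x) {
    b <- cov(x, ref) / var(ref)
    a <- mean(x) - b * mean(ref)
    (x - a) / b
  }))
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed (ordinary least squares) on a reference
#' spectrum; the fitted intercept and slope are removed:
#' corrected = (x - a) / b. The reference defaults to the column-mean
#' spectrum of the input, which is the training set when MSC is fitted
#' inside a pipeline.
#'
#' @param spectra a spectra tibble.
#' @param reference optional reference spectrum (length = grid length);
#'   defaults to the column mean of `spectra`.
#' @return list with `spectra` (corrected) and `transform` (a fitted
#'   transform holding the reference for later re-application).
#' @export
msc <- function(spectra, reference = NULL) {
  m <- spectra_matrix(spectra)
  ref <- reference %||% colMeans(m)
  if (length(ref) != ncol(m)) {
    abort("MSC reference length must match the grid")
  }
  if (var(ref) == 0) {
    abort("MSC reference spectrum has zero variance")
  }
  list(spectra = set_spectra_matrix(spectra, msc_apply(m, ref)),
       transform = structure(list(method = "msc", reference = ref),
                             class = "fitted_transform"))
}

sg_matrices <- function(window, polyorder, deriv) {
  if (window %% 2 != 1) abort("Savitzky-Golay window must be odd")
  if (polyorder >= window) abort("polynomial order must be < window")
  if (deriv > polyorder) abort("derivative order must be <= polynomial order")
  half <- (window - 1) / 2
  x <- seq(-half, half)
  A <- outer(x, 0:polyorder, "^")
  Pinv <- solve(crossprod(A), t(A))      # poly coefficients from window values
  # derivative design: d^deriv/dx^deriv of x^k evaluated at each window point
  Ad <- sapply(0:polyorder, function(k) {
    if (k < deriv) rep(0, window)
    else (factorial(k) / factorial(k - deriv)) * x^(k - deriv)
  })
  F <- Ad %*% Pinv                       # window x window projection
  list(center = F[half + 1, ], edge = F, half = half)
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial filtering of each spectrum: every point is
#' replaced by the value (or `deriv`-th derivative) of the polynomial of
#' order `polyorder` fitted to the surrounding `window` points. Edge points
#' use the polynomial fitted to the first/last window (polynomial
#' extrapolation). Derivatives are returned per cm^-1, i.e. scaled by the
#' grid spacing to the power `-deriv`; the sign of a descending instrument
#' grid is handled.
#'
#' @param spectra a spectra tibble.
#' @param window odd window width (points), default 15.
#' @param polyorder polynomial order, default 2; must be < `window`.
#' @param deriv derivative order, default 0; must be <= `polyorder`.
#' @return a spectra tibble of the same shape.
#' @export
savgol <- function(spectra, window = 15, polyorder = 2, deriv = 0) {
  m <- spectra_matrix(spectra)
  grid <- spectra_grid(spectra)
  if (ncol(m) < window) abort("window wider than the grid")
  d <- diff(grid)
  if (max(abs(d - d[1])) > 1e-8 * max(abs(d))) {
    abort("Savitzky-Golay requires an equally spaced grid")
  }
  h <- d[1]                              # signed spacing, cm^-1 per index
  sg <- sg_matrices(window, polyorder, deriv)
  L <- ncol(m)
  half <- sg$half
  out <- matrix(0, nrow(m), L)
  # interior by convolution, edges by the end-window polynomial fits
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    f <- stats::filter(x, rev(sg$center), sides = 2)
    out[i, ] <- as.numeric(f)
    out[i, 1:half] <- sg$edge[1:half, , drop = FALSE] %*% x[1:(2 * half + 1)]
    out[i, (L - half + 1):L] <-
      sg$edge[(half + 2):(2 * half + 1), , drop = FALSE] %*% x[(L - 2 * half):L]
  }
  if (deriv > 0) out <- out / h^deriv
  set_spectra_matrix(spectra, out)
}

#' Fit-and-apply column scalers
#'
#' Column-wise scaling with constants learned on the training matrix only:
#' `mean_center` subtracts training column means; `minmax` maps training
#' columns onto \[0, 1\]. The same constants are applied to `apply_to`
#' (values may then fall outside \[0, 1\]). The fitted constants are
#' returned so the transform can be re-applied exactly.
#'
#' @param train numeric matrix used to learn the constants.
#' @param apply_to optional matrix transformed with the training constants.
#' @param mode `"mean_center"` or `"minmax"`.
#' @return list with `train`, `applied` (or NULL) and `transform`.
#' @export
fit_apply_scaler <- function(train, apply_to = NULL,
                             mode = c("mean_center", "minmax")) {
  mode <- match.arg(mode)
  train <- as.matrix(train)
  if (nrow(train) == 0) abort("training matrix is empty")
  if (mode == "mean_center") {
    ctr <- colMeans(train)
    tr <- structure(list(method = "mean_center", center = ctr),
                    class = "fitted_transform")
  } else {
    lo <- apply(train, 2, min)
    hi <- apply(train, 2, max)
    if (any(hi <= lo)) {
      bad <- which(hi <= lo)[1]
      nm <- colnames(train)[bad] %||% as.character(bad)
      abort(paste0("constant column under minmax scaling: ", nm))
    }
    tr <- structure(list(method = "minmax", min = lo, max = hi),
                    class = "fitted_transform")
  }
  list(train = apply_scaler(train, tr),
       applied = if (!is.null(apply_to)) apply_scaler(as.matrix(apply_to), tr),
       transform = tr)
}

#' @rdname fit_apply_scaler
#' @param m matrix to transform with previously learned constants.
#' @param transform a fitted transform from [fit_apply_scaler()].
#' @export
apply_scaler <- function(m, transform) {
  m <- as.matrix(m)
  switch(transform$method,
    mean_center = sweep(m, 2, transform$center),
    minmax = sweep(sweep(m, 2, transform$min),
                   2, transform$max - transform$min, "/"),
    abort(paste0("not a scaler transform: ", transform$method)))
}

#' Pre-treatment chains
#'
#' A pre-treatment is an ordered list of steps applied to spectra in list
#' order. Steps: `"snv"`, `"msc"`, `"savgol"` (parameters `window`,
#' `polyorder`, `deriv`), `"mean_center"`. `fit_pretreatment()` learns any
#' constants (MSC reference, column means) on the training spectra;
#' `apply_pretreatment()` re-applies them without re-estimation, so test
#' rows never influence fitted constants.
#'
#' @param steps character vector of step names, or a list of
#'   `list(method = , ...)` specs with parameters.
#' @param train training spectra tibble.
#' @return `fit_pretreatment()` returns a `pretreatment_fit` with the
#'   transformed training spectra in `$spectra`.
#' @examples
#' sp <- spectra_tbl(c("a", "b"), rbind(c(1, 2, 4), c(2, 4, 8)),
#'                   grid = c(12, 8, 4))
#' fit <- fit_pretreatment(sp, "snv")
#' apply_pretreatment(fit, sp)
#' @export
fit_pretreatment <- function(train, steps) {
  steps <- normalize_steps(steps)
  fitted <- list()
  cur <- train
  for (st in steps) {
    res <- switch(st$method,
      snv = list(spectra = snv(cur), transform = list(method = "snv")),
      msc = msc(cur),
      savgol = list(
        spectra = savgol(cur, window = st$window %||% 15,
                         polyorder = st$polyorder %||% 2,
                         deriv = st$deriv %||% 0),
        transform = c(list(method = "savgol"),
                      st[setdiff(names(st), "method")])),
      mean_center = {
        sc <- fit_apply_scaler(spectra_matrix(cur), mode = "mean_center")
        list(spectra = set_spectra_matrix(cur, sc$train),
             transform = sc$transform)
      },
      abort(paste0("unknown pre-treatment step: ", st$method)))
    fitted <- c(fitted, list(res$transform))
    cur <- res$spectra
  }
  structure(list(steps = fitted, spectra = cur), class = "pretreatment_fit")
}

#' @rdname fit_pretreatment
#' @param fit a `pretreatment_fit`.
#' @param spectra new spectra to transform with the fitted constants.
#' @export
apply_pretreatment <- function(fit, spectra) {
  stopifnot(inherits(fit, "pretreatment_fit"))
  cur <- spectra
  for (st in fit$steps) {
    cur <- switch(st$method,
      snv = snv(cur),
      msc = set_spectra_matrix(cur, msc_apply(spectra_matrix(cur),
                                              st$reference)),
      savgol = savgol(cur, window = st$window %||% 15,
                      polyorder = st$polyorder %||% 2,
                      deriv = st$deriv %||% 0),
      mean_center = set_spectra_matrix(
        cur, apply_scaler(spectra_matrix(cur), st)))
  }
  cur
}

normalize_steps <- function(steps) {
  if (is.character(steps)) steps <- lapply(steps, function(s) list(method = s))
  if (!is.null(steps$method)) steps <- list(steps)
  lapply(steps, function(st) {
    if (is.null(st$method)) abort("each pre-treatment step needs a `method`")
    if (st$method == "savgol") {
      w <- st$window %||% 15; p <- st$polyorder %||% 2; d <- st$deriv %||% 0
      if (w %% 2 != 1 || p >= w || d > p) {
        abort("savgol requires odd window > polyorder >= deriv")
      }
    }
    st
  })
}

#' Label for a pre-treatment chain
#' @param steps as in [fit_pretreatment()].
#' @return single string, e.g. `"snv+mean_center"`.
#' @export
pretreatment_label <- function(steps) {
  paste(vapply(normalize_steps(steps), function(s) s$method, character(1)),
        collapse = "+")
}
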