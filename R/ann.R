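#' Specification of the feed-forward regression network
#'
#' A three-layer fully connected network sized by the number of selected
#' predictors n: input layer n + 1 units, hidden layer ceil((n + 1) / 2)
#' units, one linear output unit. ReLU activations with He-normal
#' initialization on the two inner layers, L1 penalty on their weights,
#' Adam optimization of the mean squared error with mean absolute error
#' monitoring, mini-batches of 32, and a 0.2 validation split of the
#' training rows used to pick the best epoch.
#'
#' The `plus_one` switch controls how the "+1" input unit is realized:
#' `"constant"` (default) appends a constant-1 column to X so the input
#' dimension literally equals n + 1; `"none"` keeps the n predictors and
#' only the layer widths follow the n + 1 rule.
#'
#' @param n_predictors number of predictors n (>= 1).
#' @param l1_lambda L1 penalty weight on the first two layers' weights.
#' @param epochs training epochs (default 1000).
#' @param batch_size mini-batch size (default 32).
#' @param validation_split fraction of training rows held out for epoch
#'   selection, in (0, 1).
#' @param seed integer seed driving initialization, the validation split
#'   and batch shuffling.
#' @param learning_rate,beta1,beta2,epsilon Adam hyper-parameters.
#' @param plus_one `"constant"` or `"none"`.
#' @return an `ann_spec` list with derived `input_width` and
#'   `hidden_width`.
#' @export
ann_spec <- function(n_predictors, l1_lambda = 1e-4, epochs = 1000,
                     batch_size = 32, validation_split = 0.2, seed = 1L,
                     learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     epsilon = 1e-8, plus_one = c("constant", "none")) {
  plus_one <- match.arg(plus_one)
  if (n_predictors < 1) abort("need at least one predictor")
  if (epochs < 1 || batch_size < 1) abort("epochs and batch size must be >= 1")
  if (validation_split <= 0 || validation_split >= 1) {
    abort("validation_split must be in (0, 1)")
  }
  n <- as.integer(n_predictors)
  structure(list(n_predictors = n,
                 input_width = n + 1L,
                 hidden_width = as.integer(ceiling((n + 1) / 2)),
                 l1_lambda = l1_lambda, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_split = validation_split, seed = as.integer(seed),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, plus_one = plus_one),
            class = "ann_spec")
}

#' @rdname ann_spec
#' @param X predictor matrix with n columns.
#' @export
add_plus_one <- function(X, spec) {
  X <- as.matrix(X)
  if (spec$plus_one == "constant") cbind(X, const1 = 1) else X
}

he_init <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

#' Build the network with seeded He-normal initial weights
#'
#' @param spec an [ann_spec()].
#' @return a `nir_ann` object with weight matrices `W1`, `W2`, `W3` and
#'   zero biases; ReLU on the first two layers, linear output.
#' @export
build_ann <- function(spec) {
  stopifnot(inherits(spec, "ann_spec"))
  d_in <- if (spec$plus_one == "constant") spec$n_predictors + 1L
          else spec$n_predictors
  set.seed(spec$seed)
  w <- list(W1 = he_init(d_in, spec$input_width),
            b1 = numeric(spec$input_width),
            W2 = he_init(spec$input_width, spec$hidden_width),
            b2 = numeric(spec$hidden_width),
            W3 = he_init(spec$hidden_width, 1L),
            b3 = numeric(1L))
  structure(list(weights = w, spec = spec, d_in = d_in, history = NULL),
            class = "nir_ann")
}

ann_forward <- function(w, X) {
  Z1 <- sweep(X %*% w$W1, 2, w$b1, "+")
  H1 <- pmax(Z1, 0)
  Z2 <- sweep(H1 %*% w$W2, 2, w$b2, "+")
  H2 <- pmax(Z2, 0)
  yhat <- drop(H2 %*% w$W3 + w$b3)
  list(Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, yhat = yhat)
}

ann_backward <- function(w, X, y, fw, l1) {
  m <- nrow(X)
  d_y <- matrix(2 * (fw$yhat - y) / m, m, 1)
  gW3 <- crossprod(fw$H2, d_y)
  gb3 <- sum(d_y)
  dH2 <- (d_y %*% t(w$W3)) * (fw$Z2 > 0)
  gW2 <- crossprod(fw$H1, dH2) + l1 * sign(w$W2)
  gb2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(w$W2)) * (fw$Z1 > 0)
  gW1 <- crossprod(X, dH1) + l1 * sign(w$W1)
  gb1 <- colSums(dH1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train the network
#'
#' Adam on the L1-penalized mean squared error. A seeded split holds out
#' `validation_split` of the rows; training history (MSE loss and MAE on
#' both partitions) is recorded every epoch and the weights of the best
#' validation-loss epoch are restored at the end.
#'
#' @param net a [build_ann()] network.
#' @param X predictor matrix (already min-max scaled; pass through
#'   [add_plus_one()] first when `plus_one = "constant"`).
#' @param y response vector.
#' @return the trained `nir_ann`; `$history` is a tibble (epoch, loss, mae,
#'   val_loss, val_mae), `$best_epoch` the restored epoch.
#' @export
train_ann <- function(net, X, y) {
  stopifnot(inherits(net, "nir_ann"))
  spec <- net$spec
  X <- as.matrix(X); y <- as.numeric(y)
  if (ncol(X) != net$d_in) {
    abort(paste0("X has ", ncol(X), " columns, network expects ", net$d_in))
  }
  set.seed(spec$seed + 1L)
  n <- nrow(X)
  n_val <- max(1L, round(spec$validation_split * n))
  perm <- sample.int(n)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]

  w <- net$weights
  mstate <- lapply(w, function(z) z * 0)
  vstate <- lapply(w, function(z) z * 0)
  step <- 0
  hist <- matrix(NA_real_, spec$epochs, 4,
                 dimnames = list(NULL, c("loss", "mae", "val_loss", "val_mae")))
  best <- list(loss = Inf, epoch = NA_integer_, w = w)
  ntr <- nrow(Xtr)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1, ntr, by = spec$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + spec$batch_size - 1, ntr)]
      fw <- ann_forward(w, Xtr[idx, , drop = FALSE])
      g <- ann_backward(w, Xtr[idx, , drop = FALSE], ytr[idx], fw,
                        spec$l1_lambda)
      step <- step + 1
      for (k in names(w)) {
        mstate[[k]] <- spec$beta1 * mstate[[k]] + (1 - spec$beta1) * g[[k]]
        vstate[[k]] <- spec$beta2 * vstate[[k]] + (1 - spec$beta2) * g[[k]]^2
        mhat <- mstate[[k]] / (1 - spec$beta1^step)
        vhat <- vstate[[k]] / (1 - spec$beta2^step)
        w[[k]] <- w[[k]] - spec$learning_rate * mhat /
          (sqrt(vhat) + spec$epsilon)
      }
    }
    etr <- ann_forward(w, Xtr)$yhat - ytr
    eva <- ann_forward(w, Xva)$yhat - yva
    hist[ep, ] <- c(mean(etr^2), mean(abs(etr)), mean(eva^2), mean(abs(eva)))
    if (!all(is.finite(hist[ep, ]))) {
      abort(paste0("non-finite loss at epoch ", ep))
    }
    if (hist[ep, "val_loss"] < best$loss) {
      best <- list(loss = hist[ep, "val_loss"], epoch = ep, w = w)
    }
  }
  net$weights <- best$w
  net$best_epoch <- best$epoch
  net$split <- list(train = tr_idx, val = val_idx)
  net$history <- tibble::tibble(epoch = seq_len(spec$epochs),
                                loss = hist[, "loss"], mae = hist[, "mae"],
                                val_loss = hist[, "val_loss"],
                                val_mae = hist[, "val_mae"])
  net
}

#' @rdname train_ann
#' @param object trained `nir_ann`.
#' @param newdata matrix conformable with the network input.
#' @param ... ignored.
#' @export
predict.nir_ann <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d_in) {
    abort(paste0("newdata has ", ncol(newdata),
                 " columns, network expects ", object$d_in))
  }
  ann_forward(object$weights, newdata)$yhat
}

#' @export
print.nir_ann <- function(x, ...) {
  s <- x$spec
  cat("Feed-forward network ", s$input_width, ":", s$hidden_width, ":1",
      " (ReLU/ReLU/linear)\n", sep = "")
  if (!is.null(x$history)) {
    cat("trained ", s$epochs, " epochs; best epoch ", x$best_epoch,
        " (val MSE ", signif(min(x$history$val_loss), 4), ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname train_ann
#' @param x trained `nir_ann`.
#' @method glance nir_ann
#' @export
glance.nir_ann <- function(x, ...) {
  tibble::tibble(input_width = x$spec$input_width,
                 hidden_width = x$spec$hidden_width,
                 epochs = x$spec$epochs,
                 best_epoch = x$best_epoch %||% NA_integer_,
                 val_loss = if (is.null(x$history)) NA_real_
                            else min(x$history$val_loss),
                 l1_lambda = x$spec$l1_lambda)
}
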