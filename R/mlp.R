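#' Multilayer perceptron: initialisation, forward pass, gradients
#'
#' A fully connected regression MLP with logistic (standard sigmoid,
#' `1 / (1 + exp(-t))`) hidden units and a linear output unit. Weights are
#' Glorot-uniform initialised (`limit = sqrt(6 / (fan_in + fan_out))`),
#' biases start at zero. Dropout, when used during training, acts only on
#' the last hidden layer — the connections into the output unit — with
#' inverted scaling (`1 / (1 - rate)`) at train time so inference needs no
#' correction.
#'
#' @param layer_sizes integer vector `[n_inputs, hidden sizes..., 1]`.
#' @param seed integer seed for the weight draw.
#' @return `mlp_init()`: an object of class `mlp` with elements `sizes`,
#'   `W` (list of weight matrices, one per layer transition) and `b` (list
#'   of bias vectors).
#' @name mlp
#' @examples
#' m <- mlp_init(c(3, 2, 1), seed = 1)
#' mlp_forward(m, matrix(0, 1, 3))
NULL

#' @noRd
logistic <- function(t) 1 / (1 + exp(-t))

#' @rdname mlp
#' @export
mlp_init <- function(layer_sizes, seed = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L))
    stopf("layer_sizes needs >= 2 entries, all >= 1")
  with_seed(seed, {
    nl <- length(layer_sizes) - 1L
    W <- vector("list", nl)
    b <- vector("list", nl)
    for (l in seq_len(nl)) {
      fan_in <- layer_sizes[l]
      fan_out <- layer_sizes[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      b[[l]] <- numeric(fan_out)
    }
    structure(list(sizes = layer_sizes, W = W, b = b), class = "mlp")
  })
}

# Forward pass keeping all layer activations (for backprop).
# `dropout_mask`: optional scaled multiplier on the last hidden layer.
# Returns the activation list `A` (post-mask, as fed to the next layer) and
# `H_last`, the unmasked last-hidden activation needed for its derivative.
#' @noRd
mlp_forward_full <- function(m, X, dropout_mask = NULL) {
  nl <- length(m$W)
  A <- vector("list", nl + 1L)
  A[[1L]] <- X
  H_last <- NULL
  for (l in seq_len(nl)) {
    Z <- A[[l]] %*% m$W[[l]]
    Z <- sweep(Z, 2L, m$b[[l]], "+")
    A[[l + 1L]] <- if (l < nl) logistic(Z) else Z
    if (l == nl - 1L) {
      H_last <- A[[l + 1L]]
      if (!is.null(dropout_mask))
        A[[l + 1L]] <- sweep(A[[l + 1L]], 2L, dropout_mask, "*")
    }
  }
  list(A = A, H_last = H_last)
}

#' Forward pass (inference)
#'
#' @param m an `mlp`.
#' @param X numeric matrix with `m$sizes[1]` columns.
#' @return `mlp_forward()`: numeric vector of predictions. No dropout is
#'   applied at inference.
#' @rdname mlp
#' @export
mlp_forward <- function(m, X) {
  stopifnot(inherits(m, "mlp"))
  X <- as.matrix(X)
  if (ncol(X) != m$sizes[1L])
    stopf("input has %d columns; network expects %d", ncol(X), m$sizes[1L])
  fw <- mlp_forward_full(m, X)
  drop(fw$A[[length(fw$A)]])
}

#' Mean-squared-error loss and backpropagated gradients
#'
#' @param y numeric target vector, length `nrow(X)`.
#' @param dropout_rate rate in `[0, 1)` applied between the last hidden
#'   layer and the output; 0 disables dropout.
#' @param dropout_mask optional explicit multiplier vector for the last
#'   hidden layer (length = last hidden size). When `NULL` and
#'   `dropout_rate > 0`, a Bernoulli mask scaled by `1 / (1 - rate)` is
#'   drawn.
#' @return `mlp_gradients()`: list with `mse`, `gW` and `gb` (gradients of
#'   the MSE with respect to every weight matrix and bias vector).
#' @rdname mlp
#' @export
mlp_gradients <- function(m, X, y, dropout_rate = 0, dropout_mask = NULL) {
  stopifnot(inherits(m, "mlp"))
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stopf("y length %d != %d rows", length(y), nrow(X))
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stopf("non-finite training inputs")
  nl <- length(m$W)
  if (is.null(dropout_mask) && dropout_rate > 0 && nl >= 2L) {
    keep <- stats::runif(m$sizes[nl]) >= dropout_rate
    dropout_mask <- keep / (1 - dropout_rate)
  }
  fw <- mlp_forward_full(m, X, dropout_mask)
  A <- fw$A
  n <- nrow(X)
  pred <- drop(A[[nl + 1L]])
  resid <- pred - y
  mse <- mean(resid^2)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  delta <- matrix(2 * resid / n, n, 1L)          # dMSE/d(output)
  for (l in nl:1) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(m$W[[l]])
      act <- A[[l]]
      if (l == nl && !is.null(dropout_mask)) {
        # last hidden: activation fed forward was mask * sigma(z)
        delta <- sweep(delta, 2L, dropout_mask, "*")
        act <- fw$H_last
      }
      delta <- delta * act * (1 - act)           # logistic derivative
    }
  }
  list(mse = mse, gW = gW, gb = gb)
}

#' Evaluate a model: MSE and coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the mean of `y`. A
#' zero-variance target makes `R^2` undefined; it is returned as `NA` with a
#' warning.
#'
#' @return `mlp_evaluate()`: list with `mse` and `r2`.
#' @rdname mlp
#' @export
mlp_evaluate <- function(m, X, y) {
  pred <- mlp_forward(m, X)
  mse <- mean((pred - y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero-variance target: R^2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sum((pred - y)^2) / ss_tot
  list(mse = mse, r2 = r2)
}
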