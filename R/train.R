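#' Training configuration
#'
#' Bundles every knob of the two trainers. The defaults are the values used
#' throughout the evolutionary search: RMSprop with mini-batches of 50, a
#' fixed learning rate of 0.01, up to 5000 epochs, early stopping after 10
#' validation evaluations without improvement (one evaluation per epoch),
#' and 50% dropout between the last hidden layer and the output. Rprop+
#' runs full-batch with the canonical constants of the
#' resilient-backpropagation-with-backtracking scheme.
#'
#' @param optimizer `"rmsprop"` (mini-batch, used during the search) or
#'   `"rprop_plus"` (full-batch resilient backpropagation with weight
#'   backtracking, used for the final predictive model).
#' @param learning_rate RMSprop step size.
#' @param batch_size RMSprop mini-batch size.
#' @param max_epochs training budget.
#' @param patience consecutive validation evaluations without improvement
#'   tolerated before stopping.
#' @param dropout_rate dropout rate on the last hidden layer during
#'   training; `0` disables.
#' @param rmsprop_decay,rmsprop_epsilon RMSprop accumulator decay and
#'   numerical floor.
#' @param eta_plus,eta_minus,delta0,delta_min,delta_max Rprop+ step-size
#'   adaptation constants.
#' @param seed optional seed fixing batch shuffling and dropout masks.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = c("rmsprop", "rprop_plus"),
                         learning_rate = 0.01, batch_size = 50,
                         max_epochs = 5000, patience = 10, dropout_rate = 0.5,
                         rmsprop_decay = 0.9, rmsprop_epsilon = 1e-8,
                         eta_plus = 1.2, eta_minus = 0.5, delta0 = 0.1,
                         delta_min = 1e-6, delta_max = 50, seed = NULL) {
  optimizer <- match.arg(optimizer)
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  if (patience < 1) stopf("patience must be >= 1")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), dropout_rate = dropout_rate,
                 rmsprop_decay = rmsprop_decay,
                 rmsprop_epsilon = rmsprop_epsilon, eta_plus = eta_plus,
                 eta_minus = eta_minus, delta0 = delta0,
                 delta_min = delta_min, delta_max = delta_max, seed = seed),
            class = "train_config")
}

# Flatten / unflatten all parameters for the per-weight Rprop bookkeeping.
#' @noRd
params_flatten <- function(m) c(unlist(m$W), unlist(m$b))

#' @noRd
params_unflatten <- function(m, v) {
  pos <- 0L
  for (l in seq_along(m$W)) {
    k <- length(m$W[[l]])
    m$W[[l]][] <- v[(pos + 1L):(pos + k)]
    pos <- pos + k
  }
  for (l in seq_along(m$b)) {
    k <- length(m$b[[l]])
    m$b[[l]][] <- v[(pos + 1L):(pos + k)]
    pos <- pos + k
  }
  m
}

#' @noRd
grads_flatten <- function(g) c(unlist(g$gW), unlist(g$gb))

# One Rprop+ update on flat vectors. `state` carries delta, prev_grad and
# prev_step; on a gradient sign flip the previous step is reverted and the
# stored gradient zeroed (the "+" backtracking variant).
#' @noRd
rprop_step <- function(w, g, state, cfg) {
  s <- g * state$prev_grad
  up <- s > 0
  down <- s < 0
  state$delta[up] <- pmin(state$delta[up] * cfg$eta_plus, cfg$delta_max)
  state$delta[down] <- pmax(state$delta[down] * cfg$eta_minus, cfg$delta_min)
  step <- -sign(g) * state$delta
  step[down] <- -state$prev_step[down]   # backtrack
  g[down] <- 0
  w <- w + step
  state$prev_grad <- g
  state$prev_step <- step
  list(w = w, state = state)
}

#' @noRd
rprop_state_init <- function(n, cfg) {
  list(delta = rep(cfg$delta0, n), prev_grad = numeric(n),
       prev_step = numeric(n))
}

#' Train an MLP
#'
#' Runs the optimizer named in `config` with optional early stopping: when
#' a validation set is supplied, the validation MSE is evaluated once per
#' epoch and training stops after `patience` consecutive evaluations
#' without improvement; the returned model is the best-validation snapshot
#' ever seen, never a later, worse one.
#'
#' @param m an [mlp_init()] model.
#' @param X,y training inputs and target.
#' @param X_val,y_val optional validation split for early stopping.
#' @param config a [train_config()].
#' @return A list with `model` (trained `mlp`), `history` (data frame with
#'   `epoch`, `train_mse`, `val_mse`), `best_val_mse` and `stopped_early`.
#' @export
train_mlp <- function(m, X, y, X_val = NULL, y_val = NULL,
                      config = train_config()) {
  stopifnot(inherits(m, "mlp"), inherits(config, "train_config"))
  X <- as.matrix(X)
  if (nrow(X) == 0L) stopf("empty training set")
  has_val <- !is.null(X_val)
  if (has_val && nrow(as.matrix(X_val)) == 0L) stopf("empty validation set")
  with_seed(config$seed, {
    if (config$optimizer == "rmsprop")
      train_loop_rmsprop(m, X, y, X_val, y_val, config)
    else
      train_loop_rprop(m, X, y, X_val, y_val, config)
  })
}

#' @noRd
train_loop_rmsprop <- function(m, X, y, X_val, y_val, cfg) {
  n <- nrow(X)
  has_val <- !is.null(X_val)
  cache <- rep(0, length(params_flatten(m)))
  best <- m; best_val <- Inf; stall <- 0L; stopped <- FALSE
  hist <- vector("list", cfg$max_epochs)
  epoch_done <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    last_mse <- NA_real_
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      g <- mlp_gradients(m, X[idx, , drop = FALSE], y[idx],
                         dropout_rate = cfg$dropout_rate)
      gv <- grads_flatten(g)
      cache <- cfg$rmsprop_decay * cache + (1 - cfg$rmsprop_decay) * gv^2
      wv <- params_flatten(m) -
        cfg$learning_rate * gv / (sqrt(cache) + cfg$rmsprop_epsilon)
      m <- params_unflatten(m, wv)
      last_mse <- g$mse
    }
    val_mse <- if (has_val) mean((mlp_forward(m, X_val) - y_val)^2) else NA_real_
    hist[[epoch]] <- c(epoch, last_mse, val_mse)
    epoch_done <- epoch
    if (has_val) {
      if (val_mse < best_val) { best_val <- val_mse; best <- m; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= cfg$patience) { stopped <- TRUE; break }
    }
  }
  hist <- do.call(rbind, hist[seq_len(epoch_done)])
  colnames(hist) <- c("epoch", "train_mse", "val_mse")
  list(model = if (has_val) best else m,
       history = as.data.frame(hist),
       best_val_mse = if (has_val) best_val else NA_real_,
       stopped_early = stopped)
}

#' @noRd
train_loop_rprop <- function(m, X, y, X_val, y_val, cfg) {
  has_val <- !is.null(X_val)
  wv <- params_flatten(m)
  state <- rprop_state_init(length(wv), cfg)
  best <- m; best_val <- Inf; stall <- 0L; stopped <- FALSE
  hist <- vector("list", cfg$max_epochs)
  epoch_done <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    g <- mlp_gradients(m, X, y, dropout_rate = cfg$dropout_rate)
    upd <- rprop_step(wv, grads_flatten(g), state, cfg)
    wv <- upd$w; state <- upd$state
    m <- params_unflatten(m, wv)
    val_mse <- if (has_val) mean((mlp_forward(m, X_val) - y_val)^2) else NA_real_
    hist[[epoch]] <- c(epoch, g$mse, val_mse)
    epoch_done <- epoch
    if (has_val) {
      if (val_mse < best_val) { best_val <- val_mse; best <- m; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= cfg$patience) { stopped <- TRUE; break }
    }
  }
  hist <- do.call(rbind, hist[seq_len(epoch_done)])
  colnames(hist) <- c("epoch", "train_mse", "val_mse")
  list(model = if (has_val) best else m,
       history = as.data.frame(hist),
       best_val_mse = if (has_val) best_val else NA_real_,
       stopped_early = stopped)
}
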