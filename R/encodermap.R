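#' Sketch-map sigmoid parameters
#'
#' The sigmoid `SIG(D) = 1 - (1 + (2^(a/b) - 1) (D/sigma)^a)^(-b/a)`
#' selects the band of distances a projection should preserve: it maps 0 to
#' 0, `sigma` to exactly 0.5, and saturates to 1 for large distances.
#'
#' @param sigma Distance scale (> 0), in the units of the space the sigmoid
#'   acts on (feature units for the high-dimensional side, projection units
#'   for the 2D side).
#' @param a,b Shape exponents (> 0) controlling how sharply distances below
#'   and above `sigma` are compressed.
#' @return Object of class `bmbs_sigmoid`.
#' @export
sigmoid_params <- function(sigma, a, b) {
  if (sigma <= 0 || a <= 0 || b <= 0)
    stop_domain("sigmoid parameters must be positive")
  structure(list(sigma = sigma, a = a, b = b), class = "bmbs_sigmoid")
}

#' Evaluate the sketch-map sigmoid
#'
#' @param distance Non-negative distance(s).
#' @param params A [sigmoid_params()].
#' @return Values in `[0, 1)`, strictly increasing in `distance`.
#' @export
sketch_sigmoid <- function(distance, params) {
  if (any(distance < 0)) stop_domain("distances must be non-negative")
  cc <- 2^(params$a / params$b) - 1
  1 - (1 + cc * (distance / params$sigma)^params$a)^(-params$b / params$a)
}

# d SIG / d D; equals 0 at D = 0 when a > 1 (the only parameter regime used
# here), so coincident points contribute no gradient.
sketch_sigmoid_deriv <- function(distance, params) {
  cc <- 2^(params$a / params$b) - 1
  u <- (distance / params$sigma)^params$a
  params$b * cc * distance^(params$a - 1) / params$sigma^params$a *
    (1 + cc * u)^(-params$b / params$a - 1)
}

#' Encodermap hyperparameters
#'
#' Defaults follow the canonical parameter set used for projecting
#' tri-ubiquitin RMD features: 10,000 training steps, 3 hidden layers of
#' 300 tanh neurons in encoder and decoder, high-dimensional sigmoid
#' (sigma 20, a 12, b 10), 2D sigmoid (sigma 1, a 2, b 10), loss weights
#' k_a = 1 and k_s = 500. Batch size, optimizer (Adam) and learning rate
#' are implementation choices, fully configurable and logged.
#'
#' @param n_steps Training steps (minibatches).
#' @param n_layers Hidden layers per half of the autoencoder.
#' @param n_neurons Neurons per hidden layer.
#' @param sig_high,sig_low [sigmoid_params()] for the high-dimensional and
#'   2D distances.
#' @param k_a,k_s Weights of the reconstruction and sketch losses.
#' @param reg_strength L2 penalty coefficient on network weights.
#' @param reg_bottleneck L2 penalty coefficient on bottleneck magnitudes.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param rng_seed Seed for initialisation and batch sampling.
#' @param standardize Standardise feature columns before training (off by
#'   default: RMD features share units).
#' @return Object of class `bmbs_em_hp`.
#' @export
encodermap_hyperparams <- function(n_steps = 10000L, n_layers = 3L,
                                   n_neurons = 300L,
                                   sig_high = sigmoid_params(20, 12, 10),
                                   sig_low = sigmoid_params(1, 2, 10),
                                   k_a = 1, k_s = 500,
                                   reg_strength = 1e-4,
                                   reg_bottleneck = 1e-4,
                                   batch_size = 256L,
                                   learning_rate = 1e-3,
                                   rng_seed = 1L,
                                   standardize = FALSE) {
  stopifnot(n_steps >= 1L, n_layers >= 1L, n_neurons >= 1L, batch_size >= 2L,
            learning_rate > 0, k_a >= 0, k_s >= 0,
            reg_strength >= 0, reg_bottleneck >= 0)
  structure(
    list(n_steps = as.integer(n_steps), n_layers = as.integer(n_layers),
         n_neurons = as.integer(n_neurons), sig_high = sig_high,
         sig_low = sig_low, k_a = k_a, k_s = k_s,
         reg_strength = reg_strength, reg_bottleneck = reg_bottleneck,
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         rng_seed = as.integer(rng_seed), standardize = isTRUE(standardize)),
    class = "bmbs_em_hp"
  )
}

#' Mean reconstruction distance (autoencoder loss)
#'
#' `L_auto = mean_i D(X_i, Xtilde_i)` with D the Euclidean distance: zero
#' iff the reconstruction is perfect.
#'
#' @param X_batch,X_reconstructed Matrices of equal shape.
#' @return Non-negative scalar.
#' @export
auto_loss <- function(X_batch, X_reconstructed) {
  X_batch <- rbind(X_batch); X_reconstructed <- rbind(X_reconstructed)
  if (!all(dim(X_batch) == dim(X_reconstructed)))
    stop_domain("shape mismatch between batch and reconstruction")
  mean(sqrt(rowSums((X_batch - X_reconstructed)^2)))
}

#' Sketch-map loss between high-dimensional and projected batches
#'
#' `L_sketch = (1/N) * sum_{i != j} (SIG_h(D(X_i, X_j)) -
#' SIG_l(D(x_i, x_j)))^2`: pairwise distances of the inputs and of their 2D
#' projections, each passed through its own sigmoid, compared over all
#' ordered pairs within the batch and averaged over the batch size.
#'
#' @param X_batch High-dimensional batch (`N x d`).
#' @param x_batch Projected batch (`N x 2`).
#' @param sig_high,sig_low [sigmoid_params()] for the two spaces.
#' @return Non-negative scalar.
#' @export
sketch_loss <- function(X_batch, x_batch, sig_high, sig_low) {
  X_batch <- rbind(X_batch); x_batch <- rbind(x_batch)
  N <- nrow(X_batch)
  if (N < 2L) stop_domain("sketch loss needs a batch of at least 2")
  if (nrow(x_batch) != N) stop_domain("batch length mismatch")
  Dh <- as.matrix(dist(X_batch))
  Dl <- as.matrix(dist(x_batch))
  M <- sketch_sigmoid(Dh, sig_high) - sketch_sigmoid(Dl, sig_low)
  diag(M) <- 0
  sum(M^2) / N
}

# ---- internal MLP machinery -------------------------------------------------

mlp_init <- function(dims) {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    s <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(runif(dims[l] * dims[l + 1L], -s, s), dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# Forward pass; tanh on all layers but the last (linear). Returns the
# activations of every layer (A[[1]] is the input) for backprop.
mlp_forward <- function(X, net) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  A
}

# Backprop given the gradient w.r.t. the (linear) output layer. Returns
# per-parameter gradients and the gradient w.r.t. the input.
mlp_backward <- function(dOut, A, net) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  d <- dOut
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], d)
    gb[[l]] <- colSums(d)
    dA <- tcrossprod(d, net$W[[l]])
    if (l > 1L) d <- dA * (1 - A[[l]]^2)  # tanh'
  }
  list(gW = gW, gb = gb, dIn = dA)
}

adam_new <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0))
}

adam_step <- function(net, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * g$gW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * g$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * g$gb[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * g$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

sum_sq_weights <- function(net) sum(vapply(net$W, function(w) sum(w^2), 1))

# Loss components and parameter gradients for one batch. Returns NULL grads
# when grad = FALSE (evaluation only).
em_batch_eval <- function(Xb, enc, dec, hp, grad = TRUE) {
  nb <- nrow(Xb)
  Ae <- mlp_forward(Xb, enc)
  z <- Ae[[length(Ae)]]
  Ad <- mlp_forward(z, dec)
  Xr <- Ad[[length(Ad)]]

  diffR <- Xr - Xb
  rn <- sqrt(rowSums(diffR^2))
  l_auto <- mean(rn)

  Dh <- as.matrix(dist(Xb))
  Dl <- as.matrix(dist(z))
  Sh <- sketch_sigmoid(Dh, hp$sig_high)
  Sl <- sketch_sigmoid(Dl, hp$sig_low)
  M <- Sh - Sl
  diag(M) <- 0
  l_sketch <- sum(M^2) / nb

  l_reg <- hp$reg_strength * (sum_sq_weights(enc) + sum_sq_weights(dec)) +
    hp$reg_bottleneck * mean(rowSums(z^2))
  total <- hp$k_a * l_auto + hp$k_s * l_sketch + l_reg

  out <- list(auto = l_auto, sketch = l_sketch, reg = l_reg, total = total,
              z = z, Xr = Xr)
  if (!grad) return(out)

  dXr <- hp$k_a * diffR / (nb * pmax(rn, 1e-12))
  gdec <- mlp_backward(dXr, Ad, dec)
  dz <- gdec$dIn

  if (hp$k_s > 0) {
    Slp <- sketch_sigmoid_deriv(Dl, hp$sig_low)
    Slp[!is.finite(Slp)] <- 0
    Q <- -(2 / nb) * M * Slp
    Wm <- 2 * Q / pmax(Dl, 1e-12)
    diag(Wm) <- 0
    dz <- dz + hp$k_s * (rowSums(Wm) * z - Wm %*% z)
  }
  dz <- dz + hp$reg_bottleneck * 2 * z / nb

  genc <- mlp_backward(dz, Ae, enc)
  for (l in seq_along(enc$W))
    genc$gW[[l]] <- genc$gW[[l]] + 2 * hp$reg_strength * enc$W[[l]]
  for (l in seq_along(dec$W))
    gdec$gW[[l]] <- gdec$gW[[l]] + 2 * hp$reg_strength * dec$W[[l]]

  out$genc <- genc
  out$gdec <- gdec
  out
}

# ---- public training API ----------------------------------------------------

#' Train an encodermap-style autoencoder on a feature matrix
#'
#' Minimises `k_a * L_auto + k_s * L_sketch + Reg` by minibatch Adam, where
#' `L_auto` is the mean Euclidean reconstruction distance, `L_sketch`
#' matches sigmoid-transformed pairwise distances between the inputs and
#' the 2D bottleneck within each minibatch, and `Reg` is an L2 penalty on
#' weights plus an L2 penalty on bottleneck magnitudes. Training is
#' deterministic given `hp$rng_seed`; the per-step loss decomposition is
#' recorded in the returned history.
#'
#' @param features Numeric matrix `frames x d` (finite, non-empty).
#' @param hp An [encodermap_hyperparams()].
#' @return Object of class `bmbs_encodermap`: encoder/decoder parameters,
#'   `input_width`, `history` (one row per step: auto, sketch, reg, total),
#'   the hyperparameter snapshot and the indices of the final batch.
#' @export
train_map <- function(features, hp = encodermap_hyperparams()) {
  X <- as.matrix(features)
  if (nrow(X) == 0L || !all(is.finite(X)))
    stop_domain("features must be non-empty and finite")
  stopifnot(inherits(hp, "bmbs_em_hp"))
  center <- NULL; scale_ <- NULL
  if (hp$standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  }
  d <- ncol(X)
  h <- hp$n_neurons
  dims_enc <- c(d, rep(h, hp$n_layers), 2L)
  dims_dec <- c(2L, rep(h, hp$n_layers), d)
  history <- matrix(NA_real_, hp$n_steps, 4L,
                    dimnames = list(NULL, c("auto", "sketch", "reg", "total")))
  last_batch <- NULL
  with_seed(hp$rng_seed, {
    enc <- mlp_init(dims_enc)
    dec <- mlp_init(dims_dec)
    st_e <- adam_new(enc); st_d <- adam_new(dec)
    nb <- min(hp$batch_size, nrow(X))
    for (step in seq_len(hp$n_steps)) {
      idx <- sample.int(nrow(X), nb, replace = nrow(X) < hp$batch_size)
      ev <- em_batch_eval(X[idx, , drop = FALSE], enc, dec, hp, grad = TRUE)
      if (!is.finite(ev$total))
        stop_domain(sprintf("training diverged (non-finite loss) at step %d", step))
      history[step, ] <- c(ev$auto, ev$sketch, ev$reg, ev$total)
      up <- adam_step(enc, ev$genc, st_e, hp$learning_rate, step)
      enc <- up$net; st_e <- up$st
      up <- adam_step(dec, ev$gdec, st_d, hp$learning_rate, step)
      dec <- up$net; st_d <- up$st
      last_batch <- idx
    }
    structure(
      list(encoder = enc, decoder = dec, input_width = d,
           history = history, hp = hp, last_batch = last_batch,
           center = center, scale = scale_),
      class = "bmbs_encodermap"
    )
  })
}

#' @export
print.bmbs_encodermap <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf(
    "Trained map: %d-D input -> 2D, %d x %d hidden, %d steps (loss %.4g -> %.4g)\n",
    x$input_width, x$hp$n_layers, x$hp$n_neurons, n,
    x$history[1L, "total"], x$history[n, "total"]))
  invisible(x)
}

#' Project features through a trained map
#'
#' Pure function of the trained encoder parameters: no retraining, no
#' randomness, identical inputs give identical points.
#'
#' @param map A [train_map()] result.
#' @param features Matrix whose width matches the map's input width.
#' @return `n x 2` matrix of projected points.
#' @export
project_map <- function(map, features) {
  stopifnot(inherits(map, "bmbs_encodermap"))
  X <- as.matrix(features)
  if (ncol(X) != map$input_width)
    stop_domain(sprintf("feature width %d does not match map input width %d",
                        ncol(X), map$input_width))
  if (!is.null(map$center))
    X <- sweep(sweep(X, 2L, map$center), 2L, map$scale, "/")
  A <- mlp_forward(X, map$encoder)
  pts <- A[[length(A)]]
  dimnames(pts) <- NULL
  pts
}

#' Recompute loss components of a trained map on a batch
#'
#' Evaluates the reconstruction, sketch and regularisation losses at the
#' stored parameters, e.g. to audit that the logged total equals
#' `k_a * auto + k_s * sketch + reg`.
#'
#' @param map A [train_map()] result.
#' @param features The training feature matrix.
#' @param idx Batch row indices (default: the final training batch).
#' @return Named list `auto`, `sketch`, `reg`, `total`.
#' @export
evaluate_losses <- function(map, features, idx = NULL) {
  idx <- idx %||% map$last_batch
  X <- as.matrix(features)
  if (!is.null(map$center))
    X <- sweep(sweep(X, 2L, map$center), 2L, map$scale, "/")
  ev <- em_batch_eval(X[idx, , drop = FALSE], map$encoder, map$decoder,
                      map$hp, grad = FALSE)
  ev[c("auto", "sketch", "reg", "total")]
}

#' Save / load a trained map
#'
#' Single-archive serialisation of parameters, hyperparameters and input
#' width.
#'
#' @param map A `bmbs_encodermap`.
#' @param path File path.
#' @return `write_map`: `path` invisibly; `read_map`: the map.
#' @export
write_map <- function(map, path) {
  saveRDS(map, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  map <- readRDS(path)
  if (!inherits(map, "bmbs_encodermap")) stop_format("not a trained map archive")
  map
}
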