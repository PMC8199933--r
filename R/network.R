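# Fully-connected network engine: forward pass, backpropagation, Adam.
# Parameters are lists of weight matrices W[[l]] (fan_in x fan_out) and bias
# vectors b[[l]]; batches are row-major (samples x features).

.activations <- c("relu", "leaky_relu", "tanh", "sigmoid", "linear")

act_fun <- function(z, name) {
  switch(name,
    relu = pmax(z, 0),
    leaky_relu = ifelse(z > 0, z, 0.2 * z),
    tanh = tanh(z),
    sigmoid = 1 / (1 + exp(-z)),
    linear = z,
    stop("unknown activation: ", name))
}

# derivative wrt pre-activation, given pre-activation z and activation a
act_grad <- function(z, a, name) {
  switch(name,
    relu = (z > 0) * 1,
    leaky_relu = ifelse(z > 0, 1, 0.2),
    tanh = 1 - a^2,
    sigmoid = a * (1 - a),
    linear = z * 0 + 1,
    stop("unknown activation: ", name))
}

#' Fully-connected network specification and initialization
#'
#' Creates an initialized multilayer perceptron.  `layer_sizes` lists the
#' widths including input and output; `activations` gives one activation
#' per weight layer (`length(layer_sizes) - 1`), chosen among `"relu"`,
#' `"leaky_relu"`, `"tanh"`, `"sigmoid"`, `"linear"`.  Weights use He
#' initialization for (leaky-)ReLU layers and Glorot otherwise; biases
#' start at zero.
#'
#' @param layer_sizes integer vector of layer widths.
#' @param activations character vector of activation names.
#' @param init_seed optional integer seed for reproducible initialization.
#' @return Object of class `mit_network` with `sizes`, `activations`, `W`,
#'   `b`.
#' @export
network_spec <- function(layer_sizes, activations, init_seed = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  L <- length(layer_sizes) - 1L
  if (L < 1L) stop("need at least one weight layer")
  if (length(activations) != L)
    stop("`activations` must name one activation per weight layer (",
         L, " expected)")
  if (!all(activations %in% .activations))
    stop("unknown activation(s): ",
         paste(setdiff(activations, .activations), collapse = ", "))
  init <- function() {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      fi <- layer_sizes[l]; fo <- layer_sizes[l + 1L]
      if (activations[l] %in% c("relu", "leaky_relu")) {
        W[[l]] <- matrix(stats::rnorm(fi * fo, 0, sqrt(2 / fi)), fi, fo)
      } else {
        lim <- sqrt(6 / (fi + fo))
        W[[l]] <- matrix(stats::runif(fi * fo, -lim, lim), fi, fo)
      }
      b[[l]] <- rep(0, fo)
    }
    list(W = W, b = b)
  }
  par <- with_seed(init_seed, init())
  structure(list(sizes = layer_sizes, activations = activations,
                 W = par$W, b = par$b, init_seed = init_seed),
            class = "mit_network")
}

#' @export
print.mit_network <- function(x, ...) {
  cat(sprintf("Fully-connected network {%s}, activations [%s], %d parameters\n",
              paste(x$sizes, collapse = " "),
              paste(x$activations, collapse = ", "),
              sum(vapply(x$W, length, 1L)) + sum(vapply(x$b, length, 1L))))
  invisible(x)
}

#' Forward pass through a network
#'
#' Applies the affine map plus activation of every layer in turn:
#' `a[l+1] = f(a[l] %*% W[l] + b[l])`.  Deterministic given the
#' parameters.
#'
#' @param net `mit_network`.
#' @param x input vector (length = first layer size) or batch matrix
#'   (`n x size`).
#' @return Output vector or `n x out` matrix, matching the input form.
#' @export
forward_pass <- function(net, x) {
  stopifnot(inherits(net, "mit_network"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != net$sizes[1])
    stop(sprintf("input has %d features; network expects %d",
                 ncol(X), net$sizes[1]))
  for (l in seq_along(net$W))
    X <- act_fun(sweep(X %*% net$W[[l]], 2, net$b[[l]], "+"), net$activations[l])
  if (vec) drop(X) else X
}

# Forward pass keeping per-layer pre-activations and activations.
net_forward_cache <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1L]] <- act_fun(Z[[l]], net$activations[l])
  }
  list(A = A, Z = Z)
}

# Backpropagation: dOut is dLoss/dA_out (n x out). Returns parameter
# gradients and the gradient wrt the network input.
net_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- dA * act_grad(cache$Z[[l]], cache$A[[l + 1L]], net$activations[l])
    gW[[l]] <- crossprod(cache$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, net$W[[l]])
  }
  list(gW = gW, gb = gb, dX = dA)
}

adam_init <- function(net) {
  list(t = 0L,
       mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0),
       vb = lapply(net$b, function(b) b * 0))
}

# One Adam update; l2 adds weight decay 2 * l2 * W to the weight gradients
# (biases are not decayed). Returns the updated net and optimizer state.
adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, l2 = 0) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    gw <- grads$gW[[l]] + 2 * l2 * net$W[[l]]
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * gw
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * gw^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    gb <- grads$gb[[l]]
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * gb
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * gb^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

# Clamp probabilities away from 0/1 before taking logs.
clamp01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
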