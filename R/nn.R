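# Minimal dense-network machinery used by the autoencoders and the WGAN.
# Everything is plain matrix algebra: a network is a list of dense layers
# (weights `W` of shape n_in x n_out, bias `b`, activation name, and a flag
# for dropout after the layer); training code drives forward/backward
# passes and an Adam or RMSProp update explicitly.

act_forward <- function(name, z, leaky_slope = 0.01) {
  switch(name,
    linear = z,
    relu = pmax(z, 0),
    relu1 = pmin(pmax(z, 0), 1),  # ReLU capped at 1 (output layer)
    sigmoid = 1 / (1 + exp(-z)),
    tanh = tanh(z),
    leaky_relu = ifelse(z > 0, z, leaky_slope * z),
    stopf("unknown activation '%s'", name))
}

# derivative of the activation w.r.t. its pre-activation z
act_grad <- function(name, z, a, leaky_slope = 0.01) {
  switch(name,
    linear = 1,
    relu = (z > 0) * 1,
    relu1 = (z > 0 & z < 1) * 1,
    sigmoid = a * (1 - a),
    tanh = 1 - a^2,
    leaky_relu = ifelse(z > 0, 1, leaky_slope),
    stopf("unknown activation '%s'", name))
}

# Glorot (Xavier) uniform initialisation, the Keras Dense default.
nn_dense <- function(n_in, n_out, activation, dropout_after = FALSE) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out),
       activation = activation,
       dropout_after = dropout_after)
}

# dims: c(n_in, n_h1, ..., n_out); activations: one per layer;
# dropout_after: logical per layer (dropout applied to that layer's output
# during training).
nn_mlp <- function(dims, activations, dropout_after = NULL) {
  n_layers <- length(dims) - 1L
  stopifnot(length(activations) == n_layers)
  if (is.null(dropout_after)) dropout_after <- rep(FALSE, n_layers)
  layers <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    layers[[i]] <- nn_dense(dims[i], dims[i + 1], activations[i],
                            dropout_after[i])
  }
  structure(list(layers = layers, dims = dims), class = "nn_mlp")
}

# Forward pass. With training = TRUE, inverted dropout with rate
# `dropout_rate` is applied after every layer flagged dropout_after.
# Returns list(out, cache) where cache[[i]] holds the layer input X,
# pre-activation Z, activation A and dropout mask.
nn_forward <- function(net, x, dropout_rate = 0, training = FALSE,
                       leaky_slope = 0.01) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  cache <- vector("list", length(net$layers))
  a <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    z <- a %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    out <- act_forward(ly$activation, z, leaky_slope)
    mask <- NULL
    if (training && ly$dropout_after && dropout_rate > 0) {
      mask <- matrix(stats::rbinom(length(out), 1, 1 - dropout_rate),
                     nrow(out), ncol(out)) / (1 - dropout_rate)
      out <- out * mask
    }
    cache[[i]] <- list(x = a, z = z, a = out, mask = mask)
    a <- out
  }
  list(out = a, cache = cache)
}

# Backward pass from the gradient of the loss w.r.t. the network output.
# Returns list(grads = per-layer list(W, b), dx = gradient w.r.t. input).
nn_backward <- function(net, cache, d_out, leaky_slope = 0.01) {
  grads <- vector("list", length(net$layers))
  da <- d_out
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    if (!is.null(cc$mask)) da <- da * cc$mask
    # recover pre-dropout activation for the derivative where needed
    a_pre <- if (is.null(cc$mask)) cc$a else cc$a / ifelse(cc$mask == 0, 1, cc$mask)
    dz <- da * act_grad(ly$activation, cc$z, a_pre, leaky_slope)
    grads[[i]] <- list(W = crossprod(cc$x, dz), b = colSums(dz))
    da <- tcrossprod(dz, ly$W)
  }
  list(grads = grads, dx = da)
}

# ---- optimizers ------------------------------------------------------------

opt_init <- function(net, type = c("adam", "rmsprop"), lr,
                     beta1 = 0.9, beta2 = 0.999, rho = 0.9, eps = 1e-7) {
  type <- match.arg(type)
  state <- lapply(net$layers, function(ly) {
    z <- list(W = ly$W * 0, b = ly$b * 0)
    if (type == "adam") list(mW = z$W, vW = z$W, mb = z$b, vb = z$b)
    else list(sW = z$W, sb = z$b)
  })
  list(type = type, lr = lr, beta1 = beta1, beta2 = beta2, rho = rho,
       eps = eps, t = 0L, state = state)
}

opt_step <- function(opt, net, grads) {
  opt$t <- opt$t + 1L
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    s <- opt$state[[i]]
    if (opt$type == "adam") {
      s$mW <- opt$beta1 * s$mW + (1 - opt$beta1) * g$W
      s$vW <- opt$beta2 * s$vW + (1 - opt$beta2) * g$W^2
      s$mb <- opt$beta1 * s$mb + (1 - opt$beta1) * g$b
      s$vb <- opt$beta2 * s$vb + (1 - opt$beta2) * g$b^2
      mhW <- s$mW / (1 - opt$beta1^opt$t)
      vhW <- s$vW / (1 - opt$beta2^opt$t)
      mhb <- s$mb / (1 - opt$beta1^opt$t)
      vhb <- s$vb / (1 - opt$beta2^opt$t)
      net$layers[[i]]$W <- net$layers[[i]]$W - opt$lr * mhW / (sqrt(vhW) + opt$eps)
      net$layers[[i]]$b <- net$layers[[i]]$b - opt$lr * mhb / (sqrt(vhb) + opt$eps)
    } else {
      s$sW <- opt$rho * s$sW + (1 - opt$rho) * g$W^2
      s$sb <- opt$rho * s$sb + (1 - opt$rho) * g$b^2
      net$layers[[i]]$W <- net$layers[[i]]$W - opt$lr * g$W / (sqrt(s$sW) + opt$eps)
      net$layers[[i]]$b <- net$layers[[i]]$b - opt$lr * g$b / (sqrt(s$sb) + opt$eps)
    }
    opt$state[[i]] <- s
  }
  list(opt = opt, net = net)
}

# clip all parameters into [-clip, clip] (classic WGAN Lipschitz constraint)
nn_clip <- function(net, clip) {
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$W <- clamp(net$layers[[i]]$W, -clip, clip)
    net$layers[[i]]$b <- clamp(net$layers[[i]]$b, -clip, clip)
  }
  net
}

nn_max_abs_param <- function(net) {
  max(vapply(net$layers,
             function(ly) max(abs(ly$W), if (length(ly$b)) abs(ly$b) else 0),
             numeric(1)))
}

# parameter count of a dense network (weights + biases)
nn_n_params <- function(net) {
  sum(vapply(net$layers, function(ly) length(ly$W) + length(ly$b),
             numeric(1)))
}

# Binary cross-entropy (per-entry mean) and its gradient w.r.t. the
# prediction; predictions clamped away from {0,1}.
bce_loss <- function(x, a, eps = 1e-7) {
  a <- clamp(a, eps, 1 - eps)
  -mean(x * log(a) + (1 - x) * log(1 - a))
}

# For the gradient the clamp is much wider (0.01): with a capped-linear
# output unit the raw factor (a - x) / (a (1 - a)) can reach 1/eps, and a
# single such spike inflates Adam's second-moment estimate enough to damp
# a parameter's updates for thousands of steps. Bounding the factor at
# ~100 (elementwise gradient clipping) keeps the optimizer well scaled.
bce_grad <- function(x, a, scale, eps = 0.01) {
  a <- clamp(a, eps, 1 - eps)
  (a - x) / (a * (1 - a)) / scale
}
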