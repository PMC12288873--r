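#' Bottleneck size rule
#'
#' The latent dimension of a section autoencoder is the section's input
#' size divided by 100, rounded up — a fixed 100x compression target.
#'
#' @param input_dim number of variants in the section, `>= 1`.
#' @return Integer bottleneck dimension.
#' @export
bottleneck_size <- function(input_dim) {
  if (any(input_dim < 1)) stopf("input_dim must be >= 1")
  as.integer(ceiling(input_dim / 100))
}

#' Geometrically spaced hidden-layer sizes
#'
#' The three encoder hidden layers interpolate geometrically between the
#' input and the bottleneck: the interior points of a five-point geometric
#' progression, rounded to the nearest integer (minimum 1). The decoder
#' mirrors them.
#'
#' @param input_dim section input size.
#' @param bottleneck_dim latent size, `1 <= bottleneck_dim <= input_dim`.
#' @return Integer vector of three hidden sizes, non-increasing.
#' @export
hidden_sizes <- function(input_dim, bottleneck_dim) {
  if (input_dim < 1 || bottleneck_dim < 1 || bottleneck_dim > input_dim)
    stopf("need input_dim >= bottleneck_dim >= 1")
  r <- (bottleneck_dim / input_dim)^(1 / 4)
  h <- round(input_dim * r^(1:3))
  as.integer(pmax(h, 1))
}

#' Autoencoder architecture specification
#'
#' Describes a section autoencoder: three geometrically spaced hidden
#' layers on each side of the bottleneck, dropout between consecutive
#' hidden layers (20% for the classical AE, 40% for the VAE), a linear
#' bottleneck for the VAE (mean and log-variance heads) and a
#' ReLU-capped-at-1 output layer.
#'
#' @param input_dim number of variants the model reconstructs.
#' @param variational `TRUE` for a VAE, `FALSE` for a classical AE.
#' @param activation hidden-layer activation: `"relu"`, `"sigmoid"`,
#'   `"tanh"` or `"leaky_relu"`.
#' @param dropout_rate dropout between hidden layers; defaults to 0.4
#'   (VAE) or 0.2 (AE).
#' @param leaky_slope negative-side slope used when
#'   `activation = "leaky_relu"`.
#' @return A `net_spec` list with the resolved layer sizes.
#' @export
net_spec <- function(input_dim, variational = TRUE,
                     activation = c("sigmoid", "relu", "tanh", "leaky_relu"),
                     dropout_rate = NULL, leaky_slope = 0.01) {
  activation <- match.arg(activation)
  if (input_dim < 1) stopf("input_dim must be >= 1")
  bn <- bottleneck_size(input_dim)
  hd <- hidden_sizes(input_dim, bn)
  structure(list(
    input_dim = as.integer(input_dim),
    hidden_dims = hd,
    bottleneck_dim = bn,
    hidden_activation = activation,
    bottleneck_activation = if (variational) "linear" else activation,
    output_activation = "relu1",
    dropout_rate = dropout_rate %||% (if (variational) 0.4 else 0.2),
    leaky_slope = leaky_slope,
    variational = isTRUE(variational)), class = "net_spec")
}

#' Training configuration for autoencoders
#'
#' @param validation_fraction fraction of haplotype rows held out for
#'   validation (seeded random split).
#' @param patience epochs without validation-loss improvement before
#'   training halts; defaults to 30 for the slow-converging sigmoid/tanh
#'   activations and 10 otherwise (resolved at [train_autoencoder()] time
#'   when `NULL`).
#' @param max_epochs upper bound on epochs; early stopping usually fires
#'   first.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed RNG seed for the split, initialisation, shuffling and
#'   dropout; `NULL` uses the current RNG stream.
#' @return A `train_config` list.
#' @export
train_config <- function(validation_fraction = 0.2, patience = NULL,
                         max_epochs = 1000, batch_size = 32,
                         learning_rate = 1e-3, seed = NULL) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stopf("validation_fraction must be in (0, 1)")
  if (!is.null(patience) && patience < 1) stopf("patience must be >= 1")
  structure(list(validation_fraction = validation_fraction,
                 patience = patience, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = seed),
            class = "train_config")
}

default_patience <- function(activation) {
  if (activation %in% c("sigmoid", "tanh")) 30L else 10L
}

#' Build an (untrained) section autoencoder
#'
#' Classical AE: one dense stack input -> h1 -> h2 -> h3 -> bottleneck ->
#' h3 -> h2 -> h1 -> output, hidden activation throughout, bottleneck with
#' the hidden activation, output ReLU capped at 1, dropout between
#' consecutive hidden layers. VAE: the bottleneck is replaced by linear
#' mean and log-variance heads with reparameterised sampling; the loss
#' adds a KL divergence to a standard normal.
#'
#' @param spec a [net_spec()].
#' @return An object of class `hs_autoencoder`.
#' @export
build_autoencoder <- function(spec) {
  stopifnot(inherits(spec, "net_spec"))
  d <- spec$input_dim; h <- spec$hidden_dims; bn <- spec$bottleneck_dim
  act <- spec$hidden_activation
  if (spec$variational) {
    encoder <- nn_mlp(c(d, h), rep(act, 3),
                      dropout_after = c(TRUE, TRUE, FALSE))
    w_mu <- nn_dense(h[3], bn, "linear")
    w_lv <- nn_dense(h[3], bn, "linear")
    # start the posterior narrow (sd ~ 0.08) so the decoder sees signal,
    # not noise, in its first epochs; the KL term then widens it
    w_lv$b <- rep(-5, bn)
    decoder <- nn_mlp(c(bn, rev(h), d), c(rep(act, 3), "relu1"),
                      dropout_after = c(TRUE, TRUE, FALSE, FALSE))
    # output units start mid-range, inside the capped-ReLU active region
    decoder$layers[[4]]$b <- rep(0.5, d)
    model <- list(spec = spec, encoder = encoder, w_mu = w_mu, w_lv = w_lv,
                  decoder = decoder)
  } else {
    net <- nn_mlp(c(d, h, bn, rev(h), d),
                  c(rep(act, 3), act, rep(act, 3), "relu1"),
                  dropout_after = c(TRUE, TRUE, FALSE, FALSE,
                                    TRUE, TRUE, FALSE, FALSE))
    net$layers[[8]]$b <- rep(0.5, d)
    model <- list(spec = spec, net = net)
  }
  structure(model, class = "hs_autoencoder")
}

#' @export
#' @method print hs_autoencoder
print.hs_autoencoder <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<hs_autoencoder> %s %s: %d -> (%s) -> %d, dropout %.0f%%\n",
              if (s$variational) "VAE" else "AE", s$hidden_activation,
              s$input_dim, paste(s$hidden_dims, collapse = ", "),
              s$bottleneck_dim, 100 * s$dropout_rate))
  if (!is.null(x$val_accuracy))
    cat(sprintf("  trained: validation accuracy %.4f (best epoch %d)\n",
                x$val_accuracy, x$best_epoch))
  invisible(x)
}

# total trainable parameter count (dense weights + biases)
n_params <- function(model) {
  if (model$spec$variational) {
    nn_n_params(model$encoder) + nn_n_params(model$decoder) +
      length(model$w_mu$W) + length(model$w_mu$b) +
      length(model$w_lv$W) + length(model$w_lv$b)
  } else {
    nn_n_params(model$net)
  }
}

# one VAE forward pass; z_eps NULL means deterministic z = mu
vae_forward <- function(model, x, training = FALSE, z_eps = NULL) {
  sp <- model$spec
  dr <- if (training) sp$dropout_rate else 0
  enc <- nn_forward(model$encoder, x, dr, training, sp$leaky_slope)
  h3 <- enc$out
  mu <- sweep(h3 %*% model$w_mu$W, 2, model$w_mu$b, "+")
  lv <- sweep(h3 %*% model$w_lv$W, 2, model$w_lv$b, "+")
  lv <- clamp(lv, -15, 15)
  z <- if (is.null(z_eps)) mu else mu + exp(0.5 * lv) * z_eps
  dec <- nn_forward(model$decoder, z, dr, training, sp$leaky_slope)
  list(enc = enc, mu = mu, lv = lv, z = z, dec = dec, out = dec$out)
}

# training losses (reconstruction summed over sites, KL summed over latent
# dims, both averaged over the batch)
vae_loss <- function(x, fwd) {
  n <- nrow(x)
  a <- clamp(fwd$out, 1e-7, 1 - 1e-7)
  recon <- -sum(x * log(a) + (1 - x) * log(1 - a)) / n
  kl <- -0.5 * sum(1 + fwd$lv - fwd$mu^2 - exp(fwd$lv)) / n
  list(total = recon + kl, recon = recon, kl = kl)
}

# single Adam step on one minibatch; returns updated model + optimizer
ae_train_step <- function(model, opt, x) {
  sp <- model$spec
  n <- nrow(x)
  if (sp$variational) {
    eps <- matrix(stats::rnorm(n * sp$bottleneck_dim), n)
    fwd <- vae_forward(model, x, training = TRUE, z_eps = eps)
    d_out <- bce_grad(x, fwd$out, scale = n)
    back_dec <- nn_backward(model$decoder, fwd$dec$cache, d_out,
                            sp$leaky_slope)
    dz <- back_dec$dx
    dmu <- dz + fwd$mu / n
    dlv <- dz * eps * 0.5 * exp(0.5 * fwd$lv) + 0.5 * (exp(fwd$lv) - 1) / n
    h3 <- fwd$enc$out
    g_mu <- list(W = crossprod(h3, dmu), b = colSums(dmu))
    g_lv <- list(W = crossprod(h3, dlv), b = colSums(dlv))
    dh3 <- tcrossprod(dmu, model$w_mu$W) + tcrossprod(dlv, model$w_lv$W)
    back_enc <- nn_backward(model$encoder, fwd$enc$cache, dh3, sp$leaky_slope)
    grads <- c(back_enc$grads, list(g_mu, g_lv), back_dec$grads)
    # flatten into one pseudo-network for the optimizer
    flat <- list(layers = c(model$encoder$layers,
                            list(model$w_mu, model$w_lv),
                            model$decoder$layers))
    res <- opt_step(opt, flat, grads)
    ne <- length(model$encoder$layers)
    model$encoder$layers <- res$net$layers[seq_len(ne)]
    model$w_mu <- res$net$layers[[ne + 1]]
    model$w_lv <- res$net$layers[[ne + 2]]
    model$decoder$layers <- res$net$layers[-seq_len(ne + 2)]
    list(model = model, opt = res$opt)
  } else {
    fwd <- nn_forward(model$net, x, sp$dropout_rate, training = TRUE,
                      leaky_slope = sp$leaky_slope)
    d_out <- bce_grad(x, fwd$out, scale = n * sp$input_dim)
    back <- nn_backward(model$net, fwd$cache, d_out, sp$leaky_slope)
    res <- opt_step(opt, model$net, back$grads)
    model$net <- res$net
    list(model = model, opt = res$opt)
  }
}

# deterministic validation loss (no dropout; VAE uses z = mu)
ae_eval_loss <- function(model, x) {
  sp <- model$spec
  if (sp$variational) {
    fwd <- vae_forward(model, x, training = FALSE, z_eps = NULL)
    vae_loss(x, fwd)$total
  } else {
    fwd <- nn_forward(model$net, x, 0, FALSE, sp$leaky_slope)
    bce_loss(x, fwd$out)
  }
}

# pull the optimizer's flattened layer list for a model
ae_flat_net <- function(model) {
  if (model$spec$variational) {
    list(layers = c(model$encoder$layers, list(model$w_mu, model$w_lv),
                    model$decoder$layers))
  } else model$net
}

#' Train a section autoencoder with early stopping
#'
#' Splits haplotype rows 80/20 into training and validation (seeded random
#' permutation), minimises binary cross-entropy (plus KL for the VAE) with
#' Adam, monitors validation loss, halts after `patience` epochs without
#' improvement, and restores the best-performing weights. The reported
#' performance metric is the validation reconstruction accuracy: the
#' fraction of entries equal to the input after binarising the
#' mean-decoded reconstruction at 0.5.
#'
#' @param model an untrained [build_autoencoder()] model.
#' @param x binary matrix (haplotypes x variants) or [haplotype_matrix()].
#' @param cfg a [train_config()].
#' @return The trained model with `val_accuracy`, `best_epoch`,
#'   `best_val_loss` and a per-epoch `history` data frame attached.
#' @export
train_autoencoder <- function(model, x, cfg = train_config()) {
  stopifnot(inherits(model, "hs_autoencoder"))
  if (inherits(x, "haplotype_matrix")) x <- x$data
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 5) stopf("need at least 5 haplotypes for an 80/20 split (got %d)", n)
  if (ncol(x) != model$spec$input_dim)
    stopf("data has %d variants but the model expects %d", ncol(x),
          model$spec$input_dim)
  patience <- cfg$patience %||% default_patience(model$spec$hidden_activation)
  with_seed(cfg$seed, {
    idx <- sample.int(n)
    n_val <- max(1L, floor(cfg$validation_fraction * n))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    x_tr <- x[tr_idx, , drop = FALSE]
    x_val <- x[val_idx, , drop = FALSE]
    opt <- opt_init(ae_flat_net(model), "adam", cfg$learning_rate)
    best <- list(loss = Inf, model = model, epoch = 0L)
    wait <- 0L
    hist <- list()
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nrow(x_tr))
      starts <- seq(1, nrow(x_tr), by = cfg$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + cfg$batch_size - 1, nrow(x_tr))]
        step <- ae_train_step(model, opt, x_tr[rows, , drop = FALSE])
        model <- step$model
        opt <- step$opt
      }
      val_loss <- ae_eval_loss(model, x_val)
      hist[[epoch]] <- data.frame(epoch = epoch, val_loss = val_loss)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, model = model, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    model <- best$model
    model$best_epoch <- best$epoch
    model$best_val_loss <- best$loss
    model$history <- do.call(rbind, hist)
    model$val_accuracy <- reconstruction_accuracy(model, x_val)
    model
  })
}

#' Encode haplotypes into the latent space
#'
#' Returns the bottleneck activations (AE) or the latent means (VAE); the
#' deterministic representation used for downstream WGAN training.
#'
#' @param model a trained `hs_autoencoder`.
#' @param x binary matrix or [haplotype_matrix()] over the model's section.
#' @return Numeric matrix, haplotypes x bottleneck_dim.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "hs_autoencoder"))
  if (inherits(x, "haplotype_matrix")) x <- x$data
  x <- as.matrix(x); storage.mode(x) <- "double"
  if (ncol(x) != model$spec$input_dim)
    stopf("data has %d variants but the model expects %d", ncol(x),
          model$spec$input_dim)
  if (model$spec$variational) {
    vae_forward(model, x, training = FALSE)$mu
  } else {
    enc_layers <- seq_len(4)  # h1, h2, h3, bottleneck
    sub <- list(layers = model$net$layers[enc_layers])
    nn_forward(sub, x, 0, FALSE, model$spec$leaky_slope)$out
  }
}

#' Latent mean and log-variance of a VAE projection
#'
#' @param model a trained variational `hs_autoencoder`.
#' @param x binary matrix or [haplotype_matrix()].
#' @return List with matrices `mean` and `logvar`.
#' @export
vae_project <- function(model, x) {
  stopifnot(inherits(model, "hs_autoencoder"), model$spec$variational)
  if (inherits(x, "haplotype_matrix")) x <- x$data
  x <- as.matrix(x); storage.mode(x) <- "double"
  fwd <- vae_forward(model, x, training = FALSE)
  list(mean = fwd$mu, logvar = fwd$lv)
}

#' Decode latent codes into reconstructed haplotype probabilities
#'
#' `mode = "mean"` decodes the latent values as given; `mode = "sample"`
#' first draws one reparameterised sample per row around them, which
#' requires a per-row `logvar` matrix (the VAE's log-variance head output).
#'
#' @param model a trained `hs_autoencoder`.
#' @param z latent matrix (haplotypes x bottleneck_dim).
#' @param mode `"mean"` or `"sample"`.
#' @param logvar log-variance matrix matching `z`, required for
#'   `mode = "sample"`.
#' @return Matrix of reconstruction values in `[0, 1]`.
#' @export
decode <- function(model, z, mode = c("mean", "sample"), logvar = NULL) {
  stopifnot(inherits(model, "hs_autoencoder"))
  mode <- match.arg(mode)
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$spec$bottleneck_dim)
    stopf("latent has %d dims but the model expects %d", ncol(z),
          model$spec$bottleneck_dim)
  if (mode == "sample") {
    if (is.null(logvar))
      stopf("mode = \"sample\" needs a logvar matrix (see vae_project())")
    if (!all(dim(logvar) == dim(z))) stopf("logvar dims must match z")
    z <- z + exp(0.5 * logvar) * matrix(stats::rnorm(length(z)), nrow(z))
  }
  if (model$spec$variational) {
    nn_forward(model$decoder, z, 0, FALSE, model$spec$leaky_slope)$out
  } else {
    sub <- list(layers = model$net$layers[5:8])
    nn_forward(sub, z, 0, FALSE, model$spec$leaky_slope)$out
  }
}

#' Binarize reconstruction probabilities
#'
#' @param x numeric matrix in `[0, 1]`.
#' @param threshold values `>= threshold` map to 1.
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(x, threshold = 0.5) {
  out <- (x >= threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Reconstruction accuracy of a model on a dataset
#'
#' Fraction of matrix entries recovered exactly after encode, mean-decode
#' and binarisation at 0.5.
#'
#' @param model a trained `hs_autoencoder`.
#' @param x binary matrix or [haplotype_matrix()].
#' @return Scalar accuracy in `[0, 1]`.
#' @export
reconstruction_accuracy <- function(model, x) {
  if (inherits(x, "haplotype_matrix")) x <- x$data
  x <- as.matrix(x)
  rec <- binarize(decode(model, encode(model, x)))
  mean(rec == x)
}
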