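#' Wasserstein GAN configuration
#'
#' Defaults follow the classic weight-clipped WGAN recipe: RMSProp at
#' learning rate 5e-5 for both networks, five critic updates per generator
#' update, weights clipped to ±0.01, checkpoints every 10 000 epochs over
#' a 30 000-epoch run. One "epoch" is one loop of `n_critic` critic
#' updates plus one generator update on sampled minibatches.
#'
#' @param noise_dim dimension of the Gaussian noise prior.
#' @param learning_rate RMSProp learning rate for both networks.
#' @param n_critic critic updates per generator update.
#' @param clip_value critic weights are clipped to ± this after each
#'   critic update (Lipschitz constraint).
#' @param checkpoint_every epochs between saved checkpoints.
#' @param total_epochs training length.
#' @param batch_size minibatch size.
#' @param min_hidden lower bound on hidden-layer widths after the
#'   divide-by-10/5/2 (generator) and 10/50/100 (critic) sizing rules.
#'   At paper scale (latent dimension in the hundreds or thousands) the
#'   bound is inactive; at desk scale it prevents the ratios from
#'   producing width-1 layers — a width-1 generator layer confines
#'   samples to a one-dimensional manifold and a width-1 critic cannot
#'   express variance-sensitive witnesses, so the adversarial game
#'   equilibrates in mode collapse.
#' @param standardize centre/scale latent columns to unit variance for
#'   critic and generator training; generated samples are returned on the
#'   original scale. With a fixed clip value the critic's response is
#'   proportional to input scale, so heavy-tailed unstandardised codes
#'   train poorly.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A `wgan_config` list.
#' @export
wgan_config <- function(noise_dim = 1000, learning_rate = 5e-5, n_critic = 5,
                        clip_value = 0.01, checkpoint_every = 10000,
                        total_epochs = 30000, batch_size = 64,
                        min_hidden = 8, standardize = TRUE, seed = NULL) {
  if (n_critic < 1) stopf("n_critic must be >= 1")
  if (clip_value <= 0) stopf("clip_value must be > 0")
  if (min_hidden < 1) stopf("min_hidden must be >= 1")
  if (checkpoint_every > total_epochs)
    stopf("checkpoint_every must be <= total_epochs")
  structure(list(noise_dim = as.integer(noise_dim),
                 learning_rate = learning_rate,
                 n_critic = as.integer(n_critic), clip_value = clip_value,
                 checkpoint_every = as.integer(checkpoint_every),
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 min_hidden = as.integer(min_hidden),
                 standardize = isTRUE(standardize), seed = seed),
            class = "wgan_config")
}

# generator sizing: hidden layers T/10, T/5, T/2 (floor), ReLU; output T
# with the latent space's activation
generator_dims <- function(target_dim, noise_dim, min_hidden = 1L) {
  h <- pmax(target_dim %/% c(10L, 5L, 2L), min_hidden)
  c(noise_dim, h, target_dim)
}

# critic sizing: hidden layers T/10, T/50, T/100 (floor), ReLU; single
# linear output
critic_dims <- function(target_dim, min_hidden = 1L) {
  h <- target_dim %/% c(10L, 50L, 100L)
  if (any(h < min_hidden))
    warnf("latent dimension %d leaves critic hidden layers below %d; %s",
          target_dim, min_hidden, "raising them to the floor")
  c(target_dim, pmax(h, min_hidden), 1L)
}

#' Draw standard-normal noise for the generator
#'
#' @param n number of samples.
#' @param noise_dim noise dimension.
#' @param seed optional seed (restores the caller's RNG state).
#' @return `n x noise_dim` matrix of i.i.d. N(0, 1) draws.
#' @export
sample_noise <- function(n, noise_dim, seed = NULL) {
  if (n < 1) stopf("n must be >= 1")
  with_seed(seed, matrix(stats::rnorm(n * noise_dim), nrow = n))
}

#' Wasserstein critic and generator losses
#'
#' The critic maximises the score gap between real and simulated samples,
#' so its loss is `mean(scores_fake) - mean(scores_real)`; the generator's
#' loss is `-mean(scores_fake)`.
#'
#' @param scores_real,scores_fake critic scores on real / generated
#'   batches.
#' @return Scalar loss.
#' @export
critic_loss <- function(scores_real, scores_fake) {
  if (length(scores_real) == 0 || length(scores_fake) == 0)
    stopf("empty score vector")
  mean(scores_fake) - mean(scores_real)
}

#' @rdname critic_loss
#' @export
generator_loss <- function(scores_fake) {
  if (length(scores_fake) == 0) stopf("empty score vector")
  -mean(scores_fake)
}

#' Train a Wasserstein GAN on concatenated latent codes
#'
#' Each epoch performs `n_critic` critic updates — every update on a fresh
#' real minibatch and a fresh generated minibatch, with critic weights
#' clipped to `±clip_value` afterwards — followed by one generator update,
#' both via RMSProp. Checkpoints (generator + critic weights, epoch,
#' running losses) are kept every `checkpoint_every` epochs and at the
#' end.
#'
#' @param latent a [latent_matrix()] or plain numeric matrix of per-sample
#'   latent codes (rows = haplotypes).
#' @param cfg a [wgan_config()].
#' @param checkpoint_dir optional directory; checkpoints are additionally
#'   serialised there as `checkpoint_<epoch>.rds`.
#' @param verbose print a progress line at every checkpoint.
#' @return An object of class `hs_wgan`: generator, critic, checkpoints,
#'   per-epoch loss history, and the latent section offsets/activation for
#'   downstream decoding.
#' @export
train_wgan <- function(latent, cfg = wgan_config(), checkpoint_dir = NULL,
                       verbose = FALSE) {
  offsets <- NULL
  activation <- "linear"
  if (inherits(latent, "latent_matrix")) {
    offsets <- latent$section_offsets
    activation <- latent$activation
    latent <- latent$values
  }
  latent <- as.matrix(latent)
  n <- nrow(latent)
  target_dim <- ncol(latent)
  if (n < cfg$batch_size)
    stopf("need at least batch_size (%d) latent rows, got %d",
          cfg$batch_size, n)
  scaling <- NULL
  if (cfg$standardize) {
    ctr <- colMeans(latent)
    scl <- apply(latent, 2, stats::sd)
    scl[scl == 0] <- 1
    latent <- sweep(sweep(latent, 2, ctr), 2, scl, "/")
    scaling <- list(center = ctr, scale = scl)
    activation <- "linear"  # standardised codes are zero-centred
  }
  with_seed(cfg$seed, {
    gen <- nn_mlp(generator_dims(target_dim, cfg$noise_dim, cfg$min_hidden),
                  c("relu", "relu", "relu", activation))
    cri <- nn_mlp(critic_dims(target_dim, cfg$min_hidden),
                  c("relu", "relu", "relu", "linear"))
    # small positive bias keeps narrow (floored) ReLU layers from starting
    # dead: a width-1 hidden layer with a negative weight would otherwise
    # never receive gradient
    for (i in 1:3) {
      gen$layers[[i]]$b <- gen$layers[[i]]$b + 0.05
      cri$layers[[i]]$b <- cri$layers[[i]]$b + 0.05
    }
    opt_g <- opt_init(gen, "rmsprop", cfg$learning_rate)
    opt_c <- opt_init(cri, "rmsprop", cfg$learning_rate)
    checkpoints <- list()
    hist_epoch <- integer()
    hist_closs <- numeric()
    hist_gloss <- numeric()
    for (epoch in seq_len(cfg$total_epochs)) {
      closs <- NA_real_
      for (k in seq_len(cfg$n_critic)) {
        rows <- sample.int(n, cfg$batch_size, replace = n < cfg$batch_size)
        real <- latent[rows, , drop = FALSE]
        noise <- matrix(stats::rnorm(cfg$batch_size * cfg$noise_dim),
                        cfg$batch_size)
        fake <- nn_forward(gen, noise)$out
        fr <- nn_forward(cri, real)
        ff <- nn_forward(cri, fake)
        closs <- critic_loss(fr$out, ff$out)
        # d(loss)/d(score): +1/b on fake scores, -1/b on real scores
        b <- cfg$batch_size
        g_fake <- nn_backward(cri, ff$cache, matrix(1 / b, b, 1))$grads
        g_real <- nn_backward(cri, fr$cache, matrix(-1 / b, b, 1))$grads
        grads <- mapply(function(a, c) list(W = a$W + c$W, b = a$b + c$b),
                        g_fake, g_real, SIMPLIFY = FALSE)
        res <- opt_step(opt_c, cri, grads)
        opt_c <- res$opt
        cri <- nn_clip(res$net, cfg$clip_value)
      }
      # generator update (critic held fixed)
      noise <- matrix(stats::rnorm(cfg$batch_size * cfg$noise_dim),
                      cfg$batch_size)
      gf <- nn_forward(gen, noise)
      cf <- nn_forward(cri, gf$out)
      gloss <- generator_loss(cf$out)
      d_score <- matrix(-1 / cfg$batch_size, cfg$batch_size, 1)
      d_fake <- nn_backward(cri, cf$cache, d_score)$dx
      g_gen <- nn_backward(gen, gf$cache, d_fake)$grads
      res <- opt_step(opt_g, gen, g_gen)
      opt_g <- res$opt
      gen <- res$net
      hist_epoch <- c(hist_epoch, epoch)
      hist_closs <- c(hist_closs, closs)
      hist_gloss <- c(hist_gloss, gloss)
      if (epoch %% cfg$checkpoint_every == 0 || epoch == cfg$total_epochs) {
        ck <- list(epoch = epoch, generator = gen, critic = cri,
                   critic_loss = closs, generator_loss = gloss,
                   noise_dim = cfg$noise_dim, target_dim = target_dim,
                   section_offsets = offsets, activation = activation,
                   scaling = scaling)
        class(ck) <- "wgan_checkpoint"
        checkpoints[[as.character(epoch)]] <- ck
        if (!is.null(checkpoint_dir)) {
          dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
          saveRDS(ck, file.path(checkpoint_dir,
                                sprintf("checkpoint_%d.rds", epoch)))
        }
        if (verbose)
          message(sprintf("epoch %d: critic loss %.4f, generator loss %.4f",
                          epoch, closs, gloss))
      }
    }
    structure(list(generator = gen, critic = cri, checkpoints = checkpoints,
                   history = data.frame(epoch = hist_epoch,
                                        critic_loss = hist_closs,
                                        generator_loss = hist_gloss),
                   config = cfg, target_dim = target_dim,
                   section_offsets = offsets, activation = activation,
                   scaling = scaling),
              class = "hs_wgan")
  })
}

#' Generate latent samples from a trained WGAN
#'
#' Deterministic given `seed`; columns align with the latent matrix's
#' section offsets so the output can be split and decoded per section.
#'
#' @param checkpoint a `wgan_checkpoint` (element of `$checkpoints`) or a
#'   trained `hs_wgan` object (its final state is used).
#' @param n number of samples to generate.
#' @param seed optional RNG seed.
#' @return `n x target_dim` matrix of generated latent codes.
#' @export
wgan_generate <- function(checkpoint, n, seed = NULL) {
  if (inherits(checkpoint, "hs_wgan")) {
    gen <- checkpoint$generator
    noise_dim <- checkpoint$config$noise_dim
  } else if (inherits(checkpoint, "wgan_checkpoint")) {
    gen <- checkpoint$generator
    noise_dim <- checkpoint$noise_dim
  } else stopf("not a WGAN checkpoint")
  noise <- sample_noise(n, noise_dim, seed)
  out <- nn_forward(gen, noise)$out
  sc <- checkpoint$scaling
  if (!is.null(sc)) {
    out <- sweep(sweep(out, 2, sc$scale, "*"), 2, sc$center, "+")
  }
  out
}
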