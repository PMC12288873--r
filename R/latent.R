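#' Concatenated per-section latent representation
#'
#' @param values numeric matrix, haplotypes x total latent dims.
#' @param section_offsets data frame with columns `section`, `first`,
#'   `last`: the 1-based column range each section occupies. Ranges must
#'   partition the columns.
#' @param activation activation tag of the bottleneck that produced the
#'   values (`"linear"` for VAE means).
#' @return A `latent_matrix` object.
#' @export
latent_matrix <- function(values, section_offsets, activation = "linear") {
  values <- as.matrix(values)
  so <- section_offsets
  stopifnot(all(c("section", "first", "last") %in% names(so)))
  if (nrow(so) > 0) {
    if (so$first[1] != 1L || so$last[nrow(so)] != ncol(values) ||
        (nrow(so) > 1 && any(so$first[-1] != so$last[-nrow(so)] + 1L)))
      stopf("section offsets do not partition the latent columns")
  }
  structure(list(values = values, section_offsets = so,
                 activation = activation), class = "latent_matrix")
}

#' @export
dim.latent_matrix <- function(x) dim(x$values)

#' @export
#' @method print latent_matrix
print.latent_matrix <- function(x, ...) {
  cat(sprintf("<latent_matrix> %d haplotypes x %d latent dims (%d sections, %s bottleneck)\n",
              nrow(x$values), ncol(x$values), nrow(x$section_offsets),
              x$activation))
  invisible(x)
}

#' Train per-section autoencoders and encode the panel
#'
#' Trains one autoencoder per section of `plan` (independent seeded runs)
#' and concatenates the per-section latent codes into a [latent_matrix()]
#' ready for WGAN training.
#'
#' @param hm a [haplotype_matrix()].
#' @param plan a [segmentation_plan] over `hm`.
#' @param variational `TRUE` for VAEs (default), `FALSE` for classical AEs.
#' @param activation hidden-layer activation for every section model.
#' @param cfg a [train_config()]; its `seed` derives one child seed per
#'   section.
#' @param verbose print one line per trained section.
#' @return An object of class `section_codec`: the trained `models`, the
#'   `latent` matrix, per-section `accuracies`, and the plan/positions
#'   needed to decode.
#' @export
encode_sections <- function(hm, plan, variational = TRUE,
                            activation = "sigmoid",
                            cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  validate_plan(plan, ncol(hm$data))
  sec <- plan$sections
  models <- vector("list", nrow(sec))
  codes <- vector("list", nrow(sec))
  acc <- numeric(nrow(sec))
  for (k in seq_len(nrow(sec))) {
    sub <- hm$data[, sec$first[k]:sec$last[k], drop = FALSE]
    spec <- net_spec(ncol(sub), variational = variational,
                     activation = activation)
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(cfg$seed, k)
    model <- with_seed(cfg_k$seed, build_autoencoder(spec))
    model <- train_autoencoder(model, sub, cfg_k)
    models[[k]] <- model
    codes[[k]] <- encode(model, sub)
    acc[k] <- model$val_accuracy
    if (verbose)
      message(sprintf("section %d [%d variants -> %d dims]: accuracy %.4f",
                      k, ncol(sub), spec$bottleneck_dim, acc[k]))
  }
  dims <- vapply(codes, ncol, integer(1))
  last <- cumsum(dims)
  offsets <- data.frame(section = seq_len(nrow(sec)),
                        first = c(1L, utils::head(last, -1) + 1L),
                        last = last)
  latent <- latent_matrix(do.call(cbind, codes), offsets,
                          activation = if (variational) "linear"
                                       else activation)
  structure(list(models = models, latent = latent, accuracies = acc,
                 plan = plan, chrom = hm$chrom, positions = hm$positions,
                 variant_ids = hm$variant_ids),
            class = "section_codec")
}

#' @export
#' @method print section_codec
print.section_codec <- function(x, ...) {
  cat(sprintf("<section_codec> %d section model(s); %d -> %d dims; mean accuracy %.4f\n",
              length(x$models), length(x$positions), ncol(x$latent$values),
              mean(x$accuracies)))
  invisible(x)
}

#' Decode concatenated latent codes back into haplotypes
#'
#' Splits the latent columns by the codec's section offsets, decodes each
#' block with its section model and binarises at 0.5.
#'
#' @param codec a [encode_sections()] result.
#' @param z latent matrix (e.g. [wgan_generate()] output); defaults to the
#'   codec's own latent codes.
#' @param mode decoding mode passed to [decode()]; `"sample"` only works
#'   for `z` rows that came from [vae_project()] with known log-variances.
#' @param sample_ids optional row labels for the result.
#' @return A [haplotype_matrix()] with the codec's positions.
#' @export
decode_sections <- function(codec, z = NULL, mode = "mean",
                            sample_ids = NULL) {
  stopifnot(inherits(codec, "section_codec"))
  if (is.null(z)) z <- codec$latent$values
  if (inherits(z, "latent_matrix")) z <- z$values
  z <- as.matrix(z)
  so <- codec$latent$section_offsets
  if (ncol(z) != so$last[nrow(so)])
    stopf("latent has %d columns; codec expects %d", ncol(z),
          so$last[nrow(so)])
  blocks <- lapply(seq_len(nrow(so)), function(k) {
    zi <- z[, so$first[k]:so$last[k], drop = FALSE]
    binarize(decode(codec$models[[k]], zi, mode = mode))
  })
  haplotype_matrix(do.call(cbind, blocks), codec$positions,
                   chrom = codec$chrom, variant_ids = codec$variant_ids,
                   sample_ids = sample_ids %||%
                     paste0("syn", seq_len(nrow(z))))
}
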