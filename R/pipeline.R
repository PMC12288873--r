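#' Pooled within-section LD preservation
#'
#' Vectorises every section's within-section LD block for the reference
#' and the synthetic panel and returns the Pearson correlation across all
#' entries — the single-number summary of how well pairwise association
#' structure survives compression and generation.
#'
#' @param ref,syn [haplotype_matrix()]s over the same variants.
#' @param plan a [segmentation_plan] covering them.
#' @return Scalar correlation in `[-1, 1]` (0 if either side is constant).
#' @export
ld_preservation <- function(ref, syn, plan) {
  validate_plan(plan, ncol(ref$data))
  if (ncol(ref$data) != ncol(syn$data)) stopf("variant sets differ")
  acc_r <- list()
  acc_s <- list()
  for (k in seq_len(nrow(plan$sections))) {
    rng <- plan$sections$first[k]:plan$sections$last[k]
    acc_r[[k]] <- as.vector(ld_matrix(ref, rng, rng))
    acc_s[[k]] <- as.vector(ld_matrix(syn, rng, rng))
  }
  vr <- unlist(acc_r)
  vs <- unlist(acc_s)
  if (stats::sd(vr) == 0 || stats::sd(vs) == 0) return(0)
  stats::cor(vr, vs)
}

#' Score WGAN checkpoints and select the best
#'
#' Mirrors how a full-scale run picks its stopping point: each saved
#' checkpoint generates `n` samples, which are decoded and scored by
#' within-section LD preservation minus mean allele-frequency drift; the
#' checkpoint with the highest score is returned.
#'
#' @param wgan a trained `hs_wgan`.
#' @param codec the [encode_sections()] codec used to decode.
#' @param ref the reference [haplotype_matrix()].
#' @param plan the [segmentation_plan] behind the codec.
#' @param n samples generated per checkpoint.
#' @param seed seed for generation (same for every checkpoint, so the
#'   comparison is paired).
#' @return List with `best` (the winning checkpoint), `scores` (one row
#'   per checkpoint: epoch, mean drift, LD preservation, score) and
#'   `synthetic` (the decoded panel from the winning checkpoint).
#' @export
select_checkpoint <- function(wgan, codec, ref, plan, n = 100, seed = NULL) {
  stopifnot(inherits(wgan, "hs_wgan"))
  rows <- lapply(wgan$checkpoints, function(ck) {
    syn <- decode_sections(codec, wgan_generate(ck, n, seed = seed))
    drift <- freq_drift(ref, syn)$mean_drift
    ldp <- ld_preservation(ref, syn, plan)
    data.frame(epoch = ck$epoch, mean_drift = drift, ld_preservation = ldp,
               score = ldp - drift)
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  best_i <- which.max(scores$score)
  best <- wgan$checkpoints[[best_i]]
  list(best = best, scores = scores,
       synthetic = decode_sections(codec, wgan_generate(best, n, seed = seed)))
}
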