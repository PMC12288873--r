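#' Per-variant alternate-allele frequencies
#'
#' @param hm a [haplotype_matrix()] or binary matrix.
#' @return Numeric vector of column means.
#' @export
allele_frequencies <- function(hm) {
  if (inherits(hm, "haplotype_matrix")) hm <- hm$data
  colMeans(hm)
}

#' Allele-frequency drift between a reference and a synthetic panel
#'
#' Drift is the per-variant absolute difference of alternate-allele
#' frequencies; a "disappearing" mutation is present in the reference but
#' absent from the synthetic panel.
#'
#' @param ref,syn [haplotype_matrix()]s (or binary matrices) over the same
#'   variants in the same order.
#' @return List with `drift` (per variant), `mean_drift`, `max_drift`,
#'   `n_disappeared` and the two frequency vectors.
#' @export
freq_drift <- function(ref, syn) {
  f_ref <- allele_frequencies(ref)
  f_syn <- allele_frequencies(syn)
  if (length(f_ref) != length(f_syn))
    stopf("variant sets differ: %d vs %d", length(f_ref), length(f_syn))
  if (inherits(ref, "haplotype_matrix") && inherits(syn, "haplotype_matrix") &&
      !identical(ref$variant_ids, syn$variant_ids))
    stopf("variant identifiers differ between panels")
  drift <- abs(f_ref - f_syn)
  list(drift = drift, mean_drift = mean(drift),
       max_drift = if (length(drift)) max(drift) else NA_real_,
       n_disappeared = sum(f_ref > 0 & f_syn == 0),
       f_ref = f_ref, f_syn = f_syn)
}

#' Signed pairwise linkage disequilibrium block
#'
#' Entry (i, j) is the Pearson correlation of allele indicator columns i
#' and j across haplotypes, so both positive and negative LD are visible.
#' Monomorphic columns (undefined correlation) yield 0 by convention.
#'
#' @param hm a [haplotype_matrix()] or binary matrix.
#' @param range_a,range_b variant (column) index vectors; default all
#'   columns.
#' @return `length(range_a) x length(range_b)` matrix in `[-1, 1]`.
#' @export
ld_matrix <- function(hm, range_a = NULL, range_b = NULL) {
  if (inherits(hm, "haplotype_matrix")) hm <- hm$data
  if (nrow(hm) < 2) stopf("need at least 2 haplotypes for LD")
  range_a <- range_a %||% seq_len(ncol(hm))
  range_b <- range_b %||% seq_len(ncol(hm))
  a <- hm[, range_a, drop = FALSE]
  b <- hm[, range_b, drop = FALSE]
  r <- suppressWarnings(stats::cor(a, b))
  r[!is.finite(r)] <- 0
  r
}

# normalized Hamming distances from each row of `x` to each row of `y`
hamming_matrix <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  m <- ncol(x)
  if (ncol(y) != m) stopf("sequence lengths differ: %d vs %d", m, ncol(y))
  # d_ij = sum(x_i) + sum(y_j) - 2 * x_i . y_j
  d <- outer(rowSums(x), rowSums(y), "+") - 2 * tcrossprod(x, y)
  pmax(d, 0) / m
}

#' Edit scores to the nearest reference haplotypes
#'
#' The edit score of a synthetic haplotype is its Hamming distance to a
#' reference haplotype divided by the sequence length, in `[0, 1]`; 0
#' means an exact copy of a reference sample. Returns the `k` smallest
#' scores in ascending order (1st..k-th nearest neighbours).
#'
#' @param syn_sample binary vector of length M.
#' @param reference a [haplotype_matrix()] or binary matrix with M columns.
#' @param k number of nearest neighbours, `<=` reference rows.
#' @return Numeric vector of length `k`.
#' @export
edit_score <- function(syn_sample, reference, k = 1) {
  if (inherits(reference, "haplotype_matrix")) reference <- reference$data
  syn_sample <- matrix(as.numeric(syn_sample), nrow = 1)
  if (ncol(syn_sample) != ncol(reference))
    stopf("sequence length %d does not match reference (%d variants)",
          ncol(syn_sample), ncol(reference))
  if (k > nrow(reference)) stopf("k exceeds the number of reference rows")
  d <- hamming_matrix(syn_sample, reference)[1, ]
  sort(d, partial = seq_len(k))[seq_len(k)]
}

#' Nearest-neighbour edit-score trend (copy-detection diagnostic)
#'
#' For every reference haplotype: edit scores to its 1st–3rd nearest
#' *other* reference haplotypes. For every synthetic haplotype: scores to
#' its 1st–3rd nearest reference haplotypes. A generator that copies
#' training samples shows 1st-NN scores near 0 with a sharp jump to the
#' 2nd NN; an interpolating generator shows a steady increase. The jump
#' ratio `(mean2 - mean1) / (mean3 - mean2)` summarises this: values far
#' above 1 indicate the copy scenario.
#'
#' @param ref,syn [haplotype_matrix()]s or binary matrices with equal
#'   column counts.
#' @return List with per-rank score matrices (`ref_scores`, `syn_scores`,
#'   columns = rank 1..3), per-rank means, `jump_ratio` and
#'   `min_first_nn` (the smallest synthetic 1st-NN score).
#' @export
novelty_trend <- function(ref, syn) {
  if (inherits(ref, "haplotype_matrix")) ref <- ref$data
  if (inherits(syn, "haplotype_matrix")) syn <- syn$data
  d_rr <- hamming_matrix(ref, ref)
  diag(d_rr) <- Inf  # exclude self-distance
  ref_scores <- t(apply(d_rr, 1, function(d) sort(d, partial = 1:3)[1:3]))
  d_sr <- hamming_matrix(syn, ref)
  syn_scores <- t(apply(d_sr, 1, function(d) sort(d, partial = 1:3)[1:3]))
  colnames(ref_scores) <- colnames(syn_scores) <- paste0("nn", 1:3)
  syn_means <- colMeans(syn_scores)
  denom <- syn_means[3] - syn_means[2]
  jump <- if (denom == 0) Inf else (syn_means[2] - syn_means[1]) / denom
  list(ref_scores = ref_scores, syn_scores = syn_scores,
       ref_means = colMeans(ref_scores), syn_means = syn_means,
       jump_ratio = unname(jump), min_first_nn = min(syn_scores[, 1]))
}

#' Shuffle haplotype rows independently within each section
#'
#' Permutes the row order of every section's column block independently
#' and re-concatenates: marginal (per-variant) frequencies are untouched
#' but any cross-section association is destroyed. This is the chance
#' control for the coherence test.
#'
#' @param syn a [haplotype_matrix()].
#' @param plan a [segmentation_plan] covering `syn`.
#' @param seed optional RNG seed.
#' @return A [haplotype_matrix()] of the same shape.
#' @export
shuffle_sections <- function(syn, plan, seed = NULL) {
  stopifnot(inherits(syn, "haplotype_matrix"))
  validate_plan(plan, ncol(syn$data))
  with_seed(seed, {
    out <- syn$data
    n <- nrow(out)
    for (k in seq_len(nrow(plan$sections))) {
      cols <- plan$sections$first[k]:plan$sections$last[k]
      out[, cols] <- out[sample.int(n), cols, drop = FALSE]
    }
    haplotype_matrix(out, syn$positions, chrom = syn$chrom,
                     variant_ids = syn$variant_ids,
                     sample_ids = syn$sample_ids)
  })
}

#' Cross-section coherence of a synthetic panel
#'
#' For every adjacent section pair, computes the cross-section LD block in
#' the reference, the synthetic and the section-shuffled synthetic panels,
#' and correlates the vectorised synthetic/shuffled blocks with the
#' reference block. Coherent synthetic data must correlate strictly higher
#' than its shuffled version, whose cross-section LD is destroyed by
#' construction. Also returns reference-fitted PCA projections of all
#' three panels for plotting.
#'
#' @param ref,syn [haplotype_matrix()]s over the same variants.
#' @param plan a [segmentation_plan] covering them.
#' @param seed seed for the shuffle.
#' @return List with `per_pair` (data frame of per-pair correlations),
#'   `syn_coherence`, `shuffled_coherence` (means over pairs), and `pca`
#'   (scores of ref/syn/shuffled in the reference PC1-2 plane).
#' @export
coherence_test <- function(ref, syn, plan, seed = NULL) {
  stopifnot(inherits(ref, "haplotype_matrix"),
            inherits(syn, "haplotype_matrix"))
  validate_plan(plan, ncol(ref$data))
  if (ncol(ref$data) != ncol(syn$data)) stopf("variant sets differ")
  shuf <- shuffle_sections(syn, plan, seed = seed)
  sec <- plan$sections
  n_pairs <- nrow(sec) - 1L
  if (n_pairs < 1) stopf("coherence needs at least two sections")
  cor_vec <- function(a, b) {
    va <- as.vector(a); vb <- as.vector(b)
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(0)
    stats::cor(va, vb)
  }
  rows <- lapply(seq_len(n_pairs), function(k) {
    ra <- sec$first[k]:sec$last[k]
    rb <- sec$first[k + 1]:sec$last[k + 1]
    ld_ref <- ld_matrix(ref, ra, rb)
    data.frame(pair = k,
               syn = cor_vec(ld_ref, ld_matrix(syn, ra, rb)),
               shuffled = cor_vec(ld_ref, ld_matrix(shuf, ra, rb)))
  })
  per_pair <- do.call(rbind, rows)
  # PCA fitted on the reference only; others projected into that space
  ctr <- colMeans(ref$data)
  x_ref <- sweep(ref$data, 2, ctr)
  pc <- stats::prcomp(x_ref, center = FALSE, scale. = FALSE, rank. = 2)
  project <- function(hm) sweep(hm$data, 2, ctr) %*% pc$rotation
  list(per_pair = per_pair,
       syn_coherence = mean(per_pair$syn),
       shuffled_coherence = mean(per_pair$shuffled),
       shuffled = shuf,
       pca = list(ref = project(ref), syn = project(syn),
                  shuffled = project(shuf)))
}

#' Ancestry-switch metaprofile
#'
#' Consumes per-sample ancestry label sequences (e.g. Chromopainter-style
#' paintings: one most-probable ancestry label per variant) and computes,
#' at every position, the fraction of samples whose label differs from the
#' previous position — the within-sample switch frequency. Position 1 has
#' no predecessor and is 0.
#'
#' @param paintings character/integer matrix (samples x positions) or list
#'   of equal-length label vectors.
#' @return Numeric vector of per-position switch frequencies.
#' @export
ancestry_switch_metaprofile <- function(paintings) {
  if (is.list(paintings)) {
    if (length(unique(lengths(paintings))) > 1)
      stopf("ragged painting input: sequences differ in length")
    paintings <- do.call(rbind, paintings)
  }
  paintings <- as.matrix(paintings)
  l <- ncol(paintings)
  if (l == 0) return(numeric(0))
  prof <- numeric(l)
  if (l > 1) {
    sw <- paintings[, -1, drop = FALSE] != paintings[, -l, drop = FALSE]
    prof[-1] <- colMeans(sw)
  }
  prof
}

#' Correlation between two ancestry-switch metaprofiles
#'
#' @param ref_profile,syn_profile equal-length switch-frequency vectors.
#' @return Pearson correlation over positions (1 if both are constant and
#'   equal).
#' @export
metaprofile_correlation <- function(ref_profile, syn_profile) {
  if (length(ref_profile) != length(syn_profile))
    stopf("profiles differ in length")
  if (stats::sd(ref_profile) == 0 && stats::sd(syn_profile) == 0)
    return(if (all(ref_profile == syn_profile)) 1 else 0)
  if (stats::sd(ref_profile) == 0 || stats::sd(syn_profile) == 0) return(0)
  stats::cor(ref_profile, syn_profile)
}

#' Read ancestry paintings from a TSV file
#'
#' Expected layout: one row per sample; first column the sample id, then
#' one ancestry label per variant.
#'
#' @param path TSV path.
#' @return Character matrix (samples x positions) with sample-id rownames.
#' @export
read_paintings <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(matrix(character(), 0, 0))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(unique(lengths(fields))) > 1)
    stopf("ragged painting input: rows differ in length")
  mat <- do.call(rbind, lapply(fields, `[`, -1))
  rownames(mat) <- vapply(fields, `[`, character(1), 1)
  mat
}

#' Compare autoencoder accuracy between hotspot-split and intact bins
#'
#' Wilcoxon–Mann–Whitney test that bins split internally by a hotspot
#' reconstruct worse than intact bins.
#'
#' @param accuracies per-section reconstruction accuracies.
#' @param split logical flags from [flag_split_bins()].
#' @return `htest` object (one-sided: split < intact).
#' @export
split_bin_accuracy_test <- function(accuracies, split) {
  if (length(accuracies) != length(split)) stopf("length mismatch")
  stats::wilcox.test(accuracies[split], accuracies[!split],
                     alternative = "less", exact = FALSE)
}
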