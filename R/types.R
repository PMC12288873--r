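#' Phased haplotype matrix
#'
#' The universal sample representation of the pipeline: a binary matrix of
#' haplotypes (rows) by variant sites (columns), with 1-based genomic
#' positions. When built from a phased VCF every donor contributes two rows
#' (left and right allele of the `a|b` genotype), labelled `"<sample>_A"`
#' and `"<sample>_B"`.
#'
#' @param data integer/numeric matrix of 0/1 allele indicators,
#'   haplotypes x variants.
#' @param positions strictly increasing 1-based bp coordinates, one per
#'   column of `data`.
#' @param chrom chromosome label.
#' @param variant_ids optional variant identifiers (defaults to
#'   `"<chrom>_<pos>"`).
#' @param sample_ids optional haplotype labels (defaults to `hap1..hapN`).
#'
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `chrom`, `positions`, `variant_ids`, `sample_ids` and `data`.
#' @export
haplotype_matrix <- function(data, positions, chrom = "chr1",
                             variant_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "integer"
  m <- ncol(data)
  n <- nrow(data)
  positions <- as.numeric(positions)
  if (length(positions) != m)
    stopf("length(positions) [%d] != ncol(data) [%d]", length(positions), m)
  if (m > 1 && any(diff(positions) <= 0))
    stopf("positions must be strictly increasing")
  if (n * m > 0 && !all(data %in% c(0L, 1L)))
    stopf("haplotype data must be binary (0/1)")
  variant_ids <- as.character(variant_ids %||%
    (if (m > 0) paste0(chrom, "_", format(positions, scientific = FALSE, trim = TRUE)) else character()))
  if (length(variant_ids) != m)
    stopf("length(variant_ids) != number of variants")
  sample_ids <- as.character(sample_ids %||%
    (if (n > 0) paste0("hap", seq_len(n)) else character()))
  if (length(sample_ids) != n)
    stopf("length(sample_ids) != number of haplotypes")
  dimnames(data) <- list(sample_ids, variant_ids)
  structure(
    list(chrom = as.character(chrom)[1], positions = positions,
         variant_ids = variant_ids, sample_ids = sample_ids, data = data),
    class = "haplotype_matrix"
  )
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$data)

#' @export
#' @method print haplotype_matrix
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %s: %d haplotypes x %d variants\n",
              x$chrom, nrow(x$data), ncol(x$data)))
  if (ncol(x$data) > 0)
    cat(sprintf("  positions %s..%s; mean alt frequency %.3f\n",
                format(x$positions[1], scientific = FALSE),
                format(x$positions[length(x$positions)], scientific = FALSE),
                mean(x$data)))
  invisible(x)
}

#' Extract a contiguous variant window of a haplotype matrix
#'
#' @param hm a [haplotype_matrix()].
#' @param first,last 1-based inclusive column (variant) indices.
#' @return A `haplotype_matrix` over the selected variants.
#' @export
subset_variants <- function(hm, first, last) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  m <- ncol(hm$data)
  if (first < 1 || last > m || first > last + 1)
    stopf("invalid variant window [%d, %d] for M=%d", first, last, m)
  idx <- if (first > last) integer() else seq.int(first, last)
  haplotype_matrix(hm$data[, idx, drop = FALSE], hm$positions[idx],
                   chrom = hm$chrom, variant_ids = hm$variant_ids[idx],
                   sample_ids = hm$sample_ids)
}

#' Recombination-rate map
#'
#' Ordered genomic intervals with a recombination rate in cM/Mb.
#' Intervals are stored 1-based with inclusive start and exclusive end.
#'
#' @param chrom chromosome label (recycled).
#' @param start,end interval bounds, `start < end` elementwise.
#' @param rate non-negative recombination rate in cM/Mb.
#' @return A `recomb_map` data frame with columns `chrom`, `start`, `end`,
#'   `rate`, sorted by `start`.
#' @export
recomb_map <- function(chrom = character(), start = numeric(),
                       end = numeric(), rate = numeric()) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), rate = as.numeric(rate),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$start >= df$end))
      stopf("recombination map: start must be < end for every interval")
    if (any(df$rate < 0))
      stopf("recombination map: negative rate")
    df <- df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("recomb_map", "data.frame")
  df
}

#' Filtered recombination hotspot loci
#'
#' Single base-pair hotspot positions with their interval intensity,
#' sorted by position. Produced by [filter_hotspots()].
#'
#' @param position 1-based bp positions, strictly increasing after sorting.
#' @param intensity rates in cM/Mb.
#' @return A `hotspot_set` data frame with columns `position`, `intensity`.
#' @export
hotspot_set <- function(position = numeric(), intensity = numeric()) {
  df <- data.frame(position = as.numeric(position),
                   intensity = as.numeric(intensity))
  if (nrow(df) > 0) {
    df <- df[order(df$position), , drop = FALSE]
    rownames(df) <- NULL
    if (any(diff(df$position) == 0))
      stopf("hotspot positions must be unique")
  }
  class(df) <- c("hotspot_set", "data.frame")
  df
}
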