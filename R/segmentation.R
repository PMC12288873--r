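#' Segmentation configuration
#'
#' Thresholds controlling hotspot filtering and section building. Defaults
#' follow the reference protocol: hotspot intervals at or below 5 cM/Mb are
#' discarded as low signal, loci within 5 kb of a stronger hotspot are
#' treated as diffuse signal around it, and sections hold between 500 and
#' 5000 mutations.
#'
#' @param rate_threshold cM/Mb; intervals with rate `<=` this are removed.
#' @param proximity_radius bp; a locus within this distance of a retained
#'   higher-intensity locus is discarded.
#' @param min_mutations minimum variants per section.
#' @param max_mutations maximum variants per section.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(rate_threshold = 5, proximity_radius = 5000,
                                min_mutations = 500, max_mutations = 5000) {
  if (min_mutations < 1 || min_mutations > max_mutations)
    stopf("need 0 < min_mutations <= max_mutations")
  if (proximity_radius < 0) stopf("proximity_radius must be >= 0")
  structure(list(rate_threshold = rate_threshold,
                 proximity_radius = proximity_radius,
                 min_mutations = as.integer(min_mutations),
                 max_mutations = as.integer(max_mutations)),
            class = "segmentation_config")
}

new_segmentation_plan <- function(sections, n_artificial, n_ignored_hotspots,
                                  n_variants) {
  structure(list(sections = sections,
                 n_artificial = as.integer(n_artificial),
                 n_ignored_hotspots = as.integer(n_ignored_hotspots),
                 n_variants = as.integer(n_variants)),
            class = "segmentation_plan")
}

#' @export
#' @method print segmentation_plan
print.segmentation_plan <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_plan> %d section(s) over %d variants; ",
                     "%d artificial hotspot(s), %d ignored hotspot(s)\n"),
              nrow(x$sections), x$n_variants, x$n_artificial,
              x$n_ignored_hotspots))
  invisible(x)
}

#' Section lengths of a segmentation plan
#' @param plan a `segmentation_plan`.
#' @return Integer vector of variants per section.
#' @export
section_lengths <- function(plan) {
  with(plan$sections, as.integer(last - first + 1L))
}

# Sections must partition [1, n_variants]: disjoint, contiguous, complete.
validate_plan <- function(plan, n_variants) {
  sec <- plan$sections
  if (n_variants == 0) {
    if (nrow(sec) != 0) stopf("non-empty plan over zero variants")
    return(invisible(TRUE))
  }
  if (nrow(sec) == 0) stopf("empty plan over %d variants", n_variants)
  if (sec$first[1] != 1L)
    stopf("plan does not start at variant 1")
  if (sec$last[nrow(sec)] != n_variants)
    stopf("plan does not cover the final variant (gap or overshoot)")
  if (nrow(sec) > 1 && any(sec$first[-1] != sec$last[-nrow(sec)] + 1L))
    stopf("plan sections are not contiguous (gap or overlap)")
  if (any(sec$first > sec$last)) stopf("empty section in plan")
  invisible(TRUE)
}

#' Filter a recombination map into single-base hotspot loci
#'
#' Three steps: (1) intervals with rate `<= rate_threshold` are removed;
#' (2) survivors are reduced to their centre `floor((start + end) / 2)`;
#' (3) loci are visited in decreasing intensity order and any locus within
#' `proximity_radius` of an already-retained stronger locus is discarded
#' (diffuse signal around the true hotspot). Equal-intensity ties retain
#' the smaller position. Result is sorted by position.
#'
#' @param map a [recomb_map()].
#' @param cfg a [segmentation_config()].
#' @return A [hotspot_set()].
#' @export
filter_hotspots <- function(map, cfg = segmentation_config()) {
  keep <- map$rate > cfg$rate_threshold
  if (!any(keep)) return(hotspot_set())
  centre <- floor((map$start[keep] + map$end[keep]) / 2)
  inten <- map$rate[keep]
  ord <- order(-inten, centre)
  centre <- centre[ord]
  inten <- inten[ord]
  kept_pos <- numeric(0)
  kept_int <- numeric(0)
  for (i in seq_along(centre)) {
    if (length(kept_pos) == 0 ||
        all(abs(kept_pos - centre[i]) > cfg$proximity_radius)) {
      kept_pos <- c(kept_pos, centre[i])
      kept_int <- c(kept_int, inten[i])
    }
  }
  hotspot_set(kept_pos, kept_int)
}

#' Partition variants into hotspot-delimited sections
#'
#' Scans variants left to right, accumulating them into the current
#' section. Crossing a hotspot closes the section if it holds at least
#' `min_mutations` variants (boundary kind `"real_hotspot"`); otherwise the
#' short run is merged and the hotspot counted as ignored (see
#' `merge_mode`). If the accumulator reaches `max_mutations` before a
#' hotspot, the section closes immediately at an `"artificial_hotspot"`
#' placed midway between the last included and the next variant. The final
#' run closes with kind `"chromosome_end"`, merging backward when shorter
#' than `min_mutations`.
#'
#' @param hm a [haplotype_matrix()].
#' @param hs a [hotspot_set()] on the same chromosome.
#' @param cfg a [segmentation_config()].
#' @param merge_mode what to do with a sub-minimum run at a hotspot:
#'   `"backward"` (default) appends it to the previously closed section and
#'   restarts accumulation after the hotspot; `"forward"` keeps the run
#'   open across the hotspot. With no previous section the run always stays
#'   open. Either way the hotspot is counted ignored.
#' @return A `segmentation_plan`; sections are 1-based inclusive variant
#'   index ranges with boundary kind and boundary bp position.
#' @export
segment_by_hotspots <- function(hm, hs, cfg = segmentation_config(),
                                merge_mode = c("backward", "forward")) {
  merge_mode <- match.arg(merge_mode)
  pos <- hm$positions
  m <- length(pos)
  if (m == 0)
    return(new_segmentation_plan(
      data.frame(first = integer(), last = integer(), kind = character(),
                 boundary_pos = numeric()), 0L, 0L, 0L))
  hpos <- if (nrow(hs) > 0) hs$position else numeric(0)
  # hotspots before the first variant or at/after the last bound no data
  hpos <- hpos[hpos >= pos[1] & hpos < pos[m]]

  first <- integer(); last <- integer(); kind <- character()
  bpos <- numeric()
  n_art <- 0L
  n_ign <- 0L
  close_section <- function(f, l, k, b) {
    first <<- c(first, f); last <<- c(last, l)
    kind <<- c(kind, k); bpos <<- c(bpos, b)
  }
  h <- 1L
  acc_start <- 1L
  for (j in seq_len(m)) {
    # variant j joins the accumulator
    if (j - acc_start + 1L == cfg$max_mutations) {
      if (j < m) {
        close_section(acc_start, j, "artificial_hotspot",
                      floor((pos[j] + pos[j + 1]) / 2))
        n_art <- n_art + 1L
      } else {
        # max reached on the final variant: this is the chromosome end
        close_section(acc_start, j, "chromosome_end", pos[m])
      }
      acc_start <- j + 1L
    }
    if (j == m) break
    # hotspots after variant j and before variant j+1 (a hotspot exactly
    # on a variant position lies after that variant)
    while (h <= length(hpos) && hpos[h] >= pos[j] && hpos[h] < pos[j + 1]) {
      count <- j + 1L - acc_start  # 0 when the accumulator just closed
      if (count >= cfg$min_mutations) {
        close_section(acc_start, j, "real_hotspot", hpos[h])
        acc_start <- j + 1L
      } else {
        n_ign <- n_ign + 1L
        if (merge_mode == "backward" && length(first) > 0) {
          if (count > 0) {               # append short run to the previous
            k <- length(first)           # section, which now ends at the
            last[k] <- j                 # ignored hotspot
            bpos[k] <- hpos[h]
          }
          acc_start <- j + 1L
        }
        # forward mode / no previous section: the run stays open
      }
      h <- h + 1L
    }
  }
  if (acc_start <= m) {
    count <- m - acc_start + 1L
    if (count < cfg$min_mutations && length(first) > 0) {
      k <- length(first)
      last[k] <- m
      kind[k] <- "chromosome_end"
      bpos[k] <- pos[m]
    } else {
      close_section(acc_start, m, "chromosome_end", pos[m])
    }
  }
  sec <- data.frame(first = first, last = last, kind = kind,
                    boundary_pos = bpos)
  plan <- new_segmentation_plan(sec, n_art, n_ign, m)
  validate_plan(plan, m)
  plan
}

#' Naive equal-size binning of variants
#'
#' Contiguous bins of `bin_size` mutations with a possibly shorter tail;
#' the comparison baseline for hotspot-aware segmentation.
#'
#' @param hm a [haplotype_matrix()].
#' @param bin_size variants per bin, `>= 1`.
#' @return A `segmentation_plan` with zero artificial/ignored counters;
#'   every boundary has kind `"naive_bin"` except the final
#'   `"chromosome_end"`.
#' @export
segment_naive <- function(hm, bin_size) {
  if (bin_size < 1) stopf("bin_size must be >= 1")
  bin_size <- as.integer(bin_size)
  m <- ncol(hm$data)
  if (m == 0)
    return(new_segmentation_plan(
      data.frame(first = integer(), last = integer(), kind = character(),
                 boundary_pos = numeric()), 0L, 0L, 0L))
  first <- seq.int(1L, m, by = bin_size)
  last <- pmin(first + bin_size - 1L, m)
  kind <- c(rep("naive_bin", length(first) - 1L), "chromosome_end")
  bpos <- ifelse(last < m, floor((hm$positions[last] +
                                  hm$positions[pmin(last + 1L, m)]) / 2),
                 hm$positions[m])
  plan <- new_segmentation_plan(
    data.frame(first = first, last = last, kind = kind, boundary_pos = bpos),
    0L, 0L, m)
  validate_plan(plan, m)
  plan
}

#' Flag sections split internally by a hotspot
#'
#' A section is flagged when some hotspot position lies strictly between
#' its first and last variant position — such bins separate mutations from
#' the neighbours they are co-inherited with, which degrades autoencoder
#' reconstruction accuracy.
#'
#' @param plan a `segmentation_plan` over `hm`.
#' @param hm a [haplotype_matrix()].
#' @param hs a [hotspot_set()].
#' @return Logical vector, one entry per section.
#' @export
flag_split_bins <- function(plan, hm, hs) {
  validate_plan(plan, ncol(hm$data))
  if (nrow(plan$sections) == 0) return(logical(0))
  hpos <- if (nrow(hs) > 0) hs$position else numeric(0)
  vapply(seq_len(nrow(plan$sections)), function(k) {
    lo <- hm$positions[plan$sections$first[k]]
    hi <- hm$positions[plan$sections$last[k]]
    any(hpos > lo & hpos < hi)
  }, logical(1))
}
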