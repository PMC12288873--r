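# Shared fixtures and independent brute-force oracles used across tests.

random_hm <- function(n = 6, m = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  haplotype_matrix(matrix(rbinom(n * m, 1, 0.5), n, m),
                   positions = sort(sample.int(m * 50, m)))
}

write_vcf_text <- function(path, records,
                           samples = paste0("S", seq_len(2))) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(pos, gts, id = ".", alt = "T", chrom = "chr1") {
  paste(c(chrom, pos, id, "A", alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Brute-force hotspot pruning: greedy by decreasing intensity (ties:
# smaller position first), pairwise distance check against everything
# already kept.
oracle_filter_hotspots <- function(start, end, rate, threshold = 5,
                                   radius = 5000) {
  keep <- rate > threshold
  centre <- floor((start[keep] + end[keep]) / 2)
  inten <- rate[keep]
  ord <- order(-inten, centre)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (abs(centre[k] - centre[i]) <= radius) ok <- FALSE
    }
    if (ok) kept <- c(kept, i)
  }
  kept <- kept[order(centre[kept])]
  data.frame(position = centre[kept], intensity = inten[kept])
}

# Straightforward re-implementation of the hotspot-bounded scan, kept
# deliberately naive (explicit per-variant loop, rbind accumulation).
oracle_segment <- function(positions, hpos, min_m, max_m,
                           merge_mode = "backward") {
  m <- length(positions)
  empty <- data.frame(first = integer(), last = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  if (m == 0) return(list(sections = empty, n_art = 0L, n_ign = 0L))
  hpos <- sort(hpos)
  hpos <- hpos[hpos >= positions[1] & hpos < positions[m]]
  secs <- empty
  start <- 1L; n_art <- 0L; n_ign <- 0L
  for (j in seq_len(m)) {
    if (j - start + 1L == max_m) {
      if (j < m) {
        secs <- rbind(secs, data.frame(first = start, last = j,
                                       kind = "artificial_hotspot"))
        n_art <- n_art + 1L
      } else {
        secs <- rbind(secs, data.frame(first = start, last = j,
                                       kind = "chromosome_end"))
      }
      start <- j + 1L
    }
    if (j < m) {
      for (hh in hpos[hpos >= positions[j] & hpos < positions[j + 1]]) {
        cnt <- j + 1L - start
        if (cnt >= min_m) {
          secs <- rbind(secs, data.frame(first = start, last = j,
                                         kind = "real_hotspot"))
          start <- j + 1L
        } else {
          n_ign <- n_ign + 1L
          if (merge_mode == "backward" && nrow(secs) > 0) {
            if (cnt > 0) secs$last[nrow(secs)] <- j
            start <- j + 1L
          }
        }
      }
    }
  }
  if (start <= m) {
    cnt <- m - start + 1L
    if (cnt < min_m && nrow(secs) > 0) {
      secs$last[nrow(secs)] <- m
      secs$kind[nrow(secs)] <- "chromosome_end"
    } else {
      secs <- rbind(secs, data.frame(first = start, last = m,
                                     kind = "chromosome_end"))
    }
  }
  list(sections = secs, n_art = n_art, n_ign = n_ign)
}

# LD by direct haplotype counting: r = (p11 - pA pB) / sqrt(...)
oracle_ld <- function(a, b) {
  p11 <- mean(a == 1 & b == 1)
  pa <- mean(a); pb <- mean(b)
  den <- sqrt(pa * (1 - pa) * pb * (1 - pb))
  if (den == 0) return(0)
  (p11 - pa * pb) / den
}
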