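#' Simulation configuration for a block-LD haplotype population
#'
#' Parameters of the founder-copy simulator: a small set of founder
#' haplotypes is drawn from a U-shaped allele-frequency spectrum, and each
#' simulated haplotype copies one founder left to right, switching to a
#' random founder at each recombination hotspot with probability
#' `crossover_prob`, then receives per-site flip noise. The result has
#' strong within-block LD and weaker cross-block LD delimited exactly at
#' the hotspot positions — the structure the hotspot-segmentation pipeline
#' assumes.
#'
#' @param n_founders number of founder haplotypes (`>= 2`).
#' @param n_haplotypes number of simulated haplotypes (rows).
#' @param n_variants number of variant sites (columns).
#' @param hotspot_positions bp positions of recombination hotspots; must
#'   lie inside the simulated span (variants sit at
#'   `spacing, 2*spacing, ...`).
#' @param crossover_prob per-hotspot probability of switching founders.
#' @param mutation_flip_prob per-site probability of flipping the copied
#'   allele.
#' @param maf_shape1,maf_shape2 Beta parameters of the founder allele
#'   frequency spectrum, truncated to `[maf_min, maf_max]`. The default
#'   Beta(0.5, 0.5) gives the U-shaped spectrum typical of site-frequency
#'   data while keeping most variants above a >= 3-haplotype filter at
#'   fixture sizes.
#' @param maf_min,maf_max truncation bounds for founder frequencies.
#' @param spacing bp between consecutive variant positions.
#' @param hotspot_rate cM/Mb rate emitted for hotspot intervals in the
#'   matching recombination map (above the default 5 cM/Mb threshold).
#' @param background_rate cM/Mb rate of non-hotspot intervals.
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 20, n_haplotypes = 500,
                       n_variants = 600, hotspot_positions = numeric(),
                       crossover_prob = 0.5, mutation_flip_prob = 0.01,
                       maf_shape1 = 0.5, maf_shape2 = 0.5,
                       maf_min = 0.05, maf_max = 0.95,
                       spacing = 100, hotspot_rate = 10,
                       background_rate = 0, seed = NULL) {
  if (n_founders < 2) stopf("n_founders must be >= 2")
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_flip_prob < 0 || mutation_flip_prob > 1)
    stopf("probabilities must be in [0, 1]")
  span <- n_variants * spacing
  if (length(hotspot_positions) &&
      (any(hotspot_positions <= spacing) || any(hotspot_positions >= span)))
    stopf("hotspot positions must lie strictly inside (%d, %d)",
          spacing, span)
  structure(as.list(environment())[c(
    "n_founders", "n_haplotypes", "n_variants", "hotspot_positions",
    "crossover_prob", "mutation_flip_prob", "maf_shape1", "maf_shape2",
    "maf_min", "maf_max", "spacing", "hotspot_rate", "background_rate",
    "seed")], class = "sim_config")
}

#' Simulate a phased haplotype population with hotspot-delimited block LD
#'
#' See [sim_config()] for the generative model. Returns the haplotype
#' matrix, a matching recombination map whose intervals exceed the
#' filtering threshold exactly at the hotspot positions, and a truth
#' record of the founder assignment of every haplotype block.
#'
#' @param cfg a [sim_config()].
#' @return List with `hm` ([haplotype_matrix()]), `map` ([recomb_map()]),
#'   `hotspots` (true hotspot bp positions), `founders` (founder allele
#'   matrix) and `truth` (haplotypes x blocks founder-index matrix).
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$n_variants
    positions <- cfg$spacing * seq_len(m)
    # founder allele frequencies: truncated U-shaped Beta spectrum
    p <- stats::rbeta(m, cfg$maf_shape1, cfg$maf_shape2)
    p <- clamp(p, cfg$maf_min, cfg$maf_max)
    founders <- matrix(stats::rbinom(cfg$n_founders * m, 1, rep(p, each = cfg$n_founders)),
                       nrow = cfg$n_founders)
    hp <- sort(cfg$hotspot_positions)
    # block k holds variants with position in (hotspot[k-1], hotspot[k]]
    # (a hotspot exactly on a variant position leaves it left of the break,
    #  matching the segmentation convention)
    block_of <- findInterval(positions, hp, left.open = TRUE) + 1L
    n_blocks <- length(hp) + 1L
    n <- cfg$n_haplotypes
    truth <- matrix(0L, n, n_blocks)
    data <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      cur <- sample.int(cfg$n_founders, 1)
      for (b in seq_len(n_blocks)) {
        if (b > 1 && stats::runif(1) < cfg$crossover_prob)
          cur <- sample.int(cfg$n_founders, 1)
        truth[i, b] <- cur
        cols <- which(block_of == b)
        data[i, cols] <- founders[cur, cols]
      }
    }
    if (cfg$mutation_flip_prob > 0) {
      flips <- matrix(stats::rbinom(n * m, 1, cfg$mutation_flip_prob), n, m)
      data <- (data + flips) %% 2L
    }
    storage.mode(data) <- "integer"
    hm <- haplotype_matrix(data, positions, chrom = "chr1")
    # matching recombination map: narrow high-rate interval centred on
    # each hotspot, background elsewhere
    half <- max(1, floor(cfg$spacing / 4))
    starts <- pmax(1, hp - half)
    ends <- hp + half
    # centre floor((start+end)/2) must recover hp exactly
    ends <- ends + (hp * 2 - starts - ends)
    chromlen <- cfg$spacing * (m + 1)
    bg_start <- c(1, ends + 1)
    bg_end <- c(starts - 1, chromlen)
    keep_bg <- bg_start < bg_end
    map <- recomb_map(
      chrom = "chr1",
      start = c(starts, bg_start[keep_bg]),
      end = c(ends, bg_end[keep_bg]),
      rate = c(rep(cfg$hotspot_rate, length(hp)),
               rep(cfg$background_rate, sum(keep_bg))))
    list(hm = hm, map = map, hotspots = hp, founders = founders,
         truth = truth, config = cfg)
  })
}

#' Write a simulated population to disk as VCF + recombination map
#'
#' Files round-trip through [read_phased_vcf()] /
#' [read_recomb_map()] bit-exactly.
#'
#' @param pop a [simulate_population()] result.
#' @param dir output directory (created if missing).
#' @param coords coordinate dialect for the map file.
#' @return Invisibly, a list with the two file paths.
#' @export
write_fixture <- function(pop, dir, coords = "bed") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(dir, "population.vcf")
  mapf <- file.path(dir, "recomb_map.tsv")
  write_phased_vcf(pop$hm, vcf)
  write_recomb_map(pop$map, mapf, coords = coords)
  invisible(list(vcf = vcf, map = mapf))
}
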