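cfg_small <- function(min = 2, max = 20, radius = 5000, thr = 5) {
  segmentation_config(rate_threshold = thr, proximity_radius = radius,
                      min_mutations = min, max_mutations = max)
}

test_that("filter_hotspots removes weak intervals, reduces to centres and prunes by proximity", {
  # rates {3, 5, 6} with threshold 5: only the 6 survives (<= is removed)
  map <- recomb_map(chrom = rep("chr1", 3), start = c(100, 300, 500),
                    end = c(200, 400, 600), rate = c(3, 5, 6))
  hs <- filter_hotspots(map, cfg_small())
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$position, floor((500 + 600) / 2))

  # proximity pruning: centres 100 (rate 10), 4000 (8), 20000 (6)
  map2 <- recomb_map(chrom = rep("chr1", 3), start = c(99, 3999, 19999),
                     end = c(101, 4001, 20001), rate = c(10, 8, 6))
  hs2 <- filter_hotspots(map2, cfg_small())
  expect_equal(hs2$position, c(100, 20000))
  expect_equal(hs2$intensity, c(10, 6))

  # equal-intensity tie 2 kb apart: exactly one retained, the earlier one
  map3 <- recomb_map(chrom = rep("chr1", 2), start = c(999, 2999),
                     end = c(1001, 3001), rate = c(7, 7))
  hs3 <- filter_hotspots(map3, cfg_small())
  expect_equal(hs3$position, 1000)

  expect_equal(nrow(filter_hotspots(recomb_map(), cfg_small())), 0L)
})

test_that("filter_hotspots matches the brute-force oracle and satisfies pruning invariants", {
  for (seed in 1:40) {
    set.seed(seed)
    k <- sample(1:25, 1)
    start <- sort(sample.int(60000, k))
    end <- start + sample(1:2000, k, replace = TRUE)
    rate <- round(runif(k, 0, 12), 2)
    cfg <- cfg_small(radius = sample(c(0, 1000, 5000), 1))
    hs <- filter_hotspots(recomb_map(rep("chr1", k), start, end, rate), cfg)
    orc <- oracle_filter_hotspots(start, end, rate, cfg$rate_threshold,
                                  cfg$proximity_radius)
    expect_equal(hs$position, orc$position)
    expect_equal(hs$intensity, orc$intensity)
    # no retained pair within the radius
    if (nrow(hs) > 1)
      expect_true(all(diff(hs$position) > cfg$proximity_radius))
    # every retained locus exceeds the rate threshold
    expect_true(all(hs$intensity > cfg$rate_threshold))
  }
})

test_that("segment_by_hotspots reproduces the worked small cases", {
  # no hotspots: one chromosome_end section
  hm <- haplotype_matrix(matrix(0L, 2, 10), 1:10)
  plan <- segment_by_hotspots(hm, hotspot_set(), cfg_small(2, 20))
  expect_equal(nrow(plan$sections), 1L)
  expect_equal(plan$sections$kind, "chromosome_end")
  expect_equal(section_lengths(plan), 10L)

  # hotspot between variants 5 and 6
  plan2 <- segment_by_hotspots(hm, hotspot_set(5.5, 10), cfg_small(2, 20))
  expect_equal(plan2$sections$first, c(1L, 6L))
  expect_equal(plan2$sections$last, c(5L, 10L))
  expect_equal(plan2$sections$kind, c("real_hotspot", "chromosome_end"))

  # max splits 12 variants into 5, 5, 2 with two artificial hotspots
  hm12 <- haplotype_matrix(matrix(0L, 2, 12), 1:12)
  plan3 <- segment_by_hotspots(hm12, hotspot_set(), cfg_small(2, 5))
  expect_equal(section_lengths(plan3), c(5L, 5L, 2L))
  expect_equal(plan3$n_artificial, 2L)
  expect_equal(plan3$sections$kind,
               c("artificial_hotspot", "artificial_hotspot",
                 "chromosome_end"))

  # empty input
  empty <- haplotype_matrix(matrix(integer(), 2, 0), numeric())
  expect_equal(nrow(segment_by_hotspots(empty, hotspot_set(),
                                        cfg_small())$sections), 0L)
})

test_that("sub-minimum runs merge backward and the hotspot is counted ignored", {
  hm <- haplotype_matrix(matrix(0L, 2, 10), 1:10)
  # hotspots after variant 4 and after variant 5: second run has 1 < min 3
  plan <- segment_by_hotspots(hm, hotspot_set(c(4.5, 5.5), c(10, 10)),
                              cfg_small(3, 20))
  expect_equal(plan$sections$first, c(1L, 6L))
  expect_equal(plan$sections$last, c(5L, 10L))
  expect_equal(plan$n_ignored_hotspots, 1L)

  # forward mode keeps the run open across the ignored hotspot
  planf <- segment_by_hotspots(hm, hotspot_set(c(4.5, 5.5), c(10, 10)),
                               cfg_small(3, 20), merge_mode = "forward")
  expect_equal(planf$sections$first, c(1L, 5L))
  expect_equal(planf$sections$last, c(4L, 10L))
  expect_equal(planf$n_ignored_hotspots, 1L)
})

test_that("segment_by_hotspots matches the brute-force oracle on random instances", {
  t0 <- Sys.time()
  mismatches <- character(0)
  for (seed in 1:100) {
    set.seed(1000 + seed)
    m <- sample(0:200, 1)
    positions <- sort(sample.int(5000, m))
    n_h <- sample(0:12, 1)
    hpos <- sort(runif(n_h, 0, 5100))
    min_m <- sample(1:30, 1)
    max_m <- min_m + sample(0:60, 1)
    mode <- sample(c("backward", "forward"), 1)
    hm <- haplotype_matrix(matrix(0L, 2, m), positions)
    hs <- if (n_h > 0) hotspot_set(hpos, rep(10, n_h)) else hotspot_set()
    plan <- segment_by_hotspots(hm, hs, cfg_small(min_m, max_m),
                                merge_mode = mode)
    orc <- oracle_segment(positions, hpos, min_m, max_m, mode)
    same <- identical(plan$sections$first, orc$sections$first) &&
      identical(plan$sections$last, orc$sections$last) &&
      identical(plan$sections$kind, orc$sections$kind) &&
      plan$n_artificial == orc$n_art &&
      plan$n_ignored_hotspots == orc$n_ign &&
      (m == 0 || (plan$sections$first[1] == 1L &&
                  plan$sections$last[nrow(plan$sections)] == m))
    if (!same) mismatches <- c(mismatches, sprintf("instance %d", seed))
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_identical(mismatches, character(0))
  expect_lt(elapsed, 10)
})

test_that("raising min_mutations never increases the number of sections", {
  for (seed in 1:30) {
    set.seed(2000 + seed)
    m <- sample(50:200, 1)
    positions <- sort(sample.int(5000, m))
    hpos <- sort(runif(sample(1:10, 1), 0, 5100))
    hm <- haplotype_matrix(matrix(0L, 2, m), positions)
    hs <- hotspot_set(hpos, rep(10, length(hpos)))
    mins <- sort(sample(1:40, 3))
    ns <- vapply(mins, function(mm) {
      nrow(segment_by_hotspots(hm, hs, cfg_small(mm, 60))$sections)
    }, integer(1))
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("segment_naive produces equal bins with a short tail", {
  hm <- random_hm(n = 2, m = 10, seed = 5)
  expect_equal(section_lengths(segment_naive(hm, 4)), c(4L, 4L, 2L))
  expect_equal(section_lengths(segment_naive(hm, 10)), 10L)
  plan <- segment_naive(hm, 4)
  expect_equal(plan$n_artificial, 0L)
  expect_equal(plan$n_ignored_hotspots, 0L)
  empty <- haplotype_matrix(matrix(integer(), 2, 0), numeric())
  expect_equal(nrow(segment_naive(empty, 4)$sections), 0L)
  expect_error(segment_naive(hm, 0), "bin_size")
})

test_that("flag_split_bins uses strict interiority", {
  hm <- haplotype_matrix(matrix(0L, 2, 10), c(1:5, 96:100))
  plan <- segment_naive(hm, 5)  # sections span positions 1-5 and 96-100
  expect_equal(flag_split_bins(plan, hm, hotspot_set(3, 10)),
               c(TRUE, FALSE))
  # hotspot exactly on the last position of a section: not split
  expect_equal(flag_split_bins(plan, hm, hotspot_set(5, 10)),
               c(FALSE, FALSE))
  expect_equal(flag_split_bins(plan, hm, hotspot_set()), c(FALSE, FALSE))
})
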