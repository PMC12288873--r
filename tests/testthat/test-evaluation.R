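test_that("freq_drift reports per-variant drift and disappearing mutations", {
  ref <- matrix(c(1, 1, 0, 0,
                  1, 0, 0, 0,
                  1, 1, 1, 1), 4, 3)
  syn <- matrix(c(0, 0, 0, 0,
                  1, 0, 0, 0,
                  1, 1, 1, 0), 4, 3)
  fd <- freq_drift(ref, syn)
  expect_equal(fd$drift, c(0.5, 0, 0.25))     # hand-computed column means
  expect_equal(fd$n_disappeared, 1L)          # column 1: 0.5 -> 0
  expect_equal(fd$mean_drift, 0.25)

  same <- freq_drift(ref, ref)
  expect_equal(same$drift, rep(0, 3))
  expect_equal(same$n_disappeared, 0L)

  expect_error(freq_drift(ref, syn[, 1:2]), "differ")
})

test_that("ld_matrix gives signed correlations with the monomorphic-zero convention", {
  a <- c(1, 1, 0, 0)
  expect_equal(ld_matrix(cbind(a, a))[1, 2], 1)
  expect_equal(ld_matrix(cbind(a, 1 - a))[1, 2], -1)
  expect_equal(ld_matrix(cbind(a, c(1, 0, 0, 1)))[1, 2], 0)
  # monomorphic column -> 0, not NA
  expect_equal(ld_matrix(cbind(a, c(1, 1, 1, 1)))[1, 2], 0)
})

test_that("ld_matrix equals the haplotype-count oracle on random matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- matrix(rbinom(36, 1, runif(1, 0.2, 0.8)), 6, 6)
    r <- ld_matrix(x)
    for (i in 1:6) for (j in 1:6) {
      expect_equal(r[i, j], oracle_ld(x[, i], x[, j]), tolerance = 1e-12)
    }
  }
})

test_that("edit_score is the normalized Hamming distance to nearest neighbours", {
  ref <- rbind(rep(0, 10), rep(1, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(edit_score(rep(0, 10), ref, k = 1), 0)
  expect_equal(edit_score(rep(0, 10), ref, k = 3), c(0, 0.3, 1))
  expect_equal(edit_score(c(rep(1, 3), rep(0, 7)), ref, k = 1), 0)
  expect_error(edit_score(rep(0, 5), ref), "length")
  expect_error(edit_score(rep(0, 10), ref, k = 4), "k exceeds")
})

test_that("edit score satisfies metric axioms on random vectors", {
  set.seed(42)
  for (i in 1:25) {
    m <- sample(5:40, 1)
    x <- rbinom(m, 1, 0.5); y <- rbinom(m, 1, 0.5); z <- rbinom(m, 1, 0.5)
    dxy <- mean(x != y); dyx <- mean(y != x)
    dxz <- mean(x != z); dzy <- mean(z != y)
    expect_identical(dxy, dyx)                       # symmetry
    expect_lte(dxy, dxz + dzy + 1e-12)               # triangle inequality
    expect_gte(dxy, 0); expect_lte(dxy, 1)           # [0, 1] scaling
    expect_equal(edit_score(x, rbind(y), 1), dxy)    # implementation agrees
  }
})

test_that("novelty_trend flags the copy scenario and steady interpolation", {
  set.seed(7)
  ref <- matrix(rbinom(20 * 100, 1, 0.5), 20, 100)
  # exact copies: 1st-NN all zero
  nt_copy <- novelty_trend(ref, ref[1:5, , drop = FALSE])
  expect_equal(unname(nt_copy$syn_scores[, 1]), rep(0, 5))
  expect_equal(nt_copy$min_first_nn, 0)
  # one bit flipped: 1st-NN exactly 0.01
  syn <- ref[1:5, , drop = FALSE]
  for (i in 1:5) syn[i, i] <- 1 - syn[i, i]
  nt_flip <- novelty_trend(ref, syn)
  expect_equal(unname(nt_flip$syn_scores[, 1]), rep(0.01, 5))
  # reference self-scores exclude self (all > 0 for distinct rows)
  expect_true(all(nt_flip$ref_scores > 0))
  # ranks are ordered
  expect_true(all(diff(t(nt_flip$syn_scores)) >= 0))
})

test_that("shuffle_sections preserves marginal frequencies and destroys cross-section LD", {
  set.seed(11)
  pop <- simulate_population(sim_config(
    n_founders = 8, n_haplotypes = 120, n_variants = 60,
    hotspot_positions = c(2050, 4050), crossover_prob = 0.5,
    mutation_flip_prob = 0, seed = 11))
  plan <- segment_by_hotspots(
    pop$hm, hotspot_set(pop$hotspots, rep(10, 2)),
    segmentation_config(min_mutations = 2, max_mutations = 100))
  expect_equal(nrow(plan$sections), 3L)
  shuf <- shuffle_sections(pop$hm, plan, seed = 5)
  expect_equal(allele_frequencies(shuf), allele_frequencies(pop$hm))
  expect_false(identical(shuf$data, pop$hm$data))

  # single-section plan is a pure row permutation
  one <- segment_naive(pop$hm, ncol(pop$hm$data))
  shuf1 <- shuffle_sections(pop$hm, one, seed = 5)
  expect_equal(sort(unname(apply(shuf1$data, 1, paste, collapse = ""))),
               sort(unname(apply(pop$hm$data, 1, paste, collapse = ""))))

  # cross-section |LD| collapses towards zero after shuffling
  s1 <- plan$sections$first[1]:plan$sections$last[1]
  s2 <- plan$sections$first[2]:plan$sections$last[2]
  ld_before <- mean(abs(ld_matrix(pop$hm, s1, s2)))
  ld_after <- mean(abs(ld_matrix(shuf, s1, s2)))
  ld_within <- mean(abs(ld_matrix(pop$hm, s1, s1)))
  expect_lt(ld_after, ld_before)
  expect_lt(ld_after, ld_within)
})

test_that("coherence_test scores identical data at 1 and shuffled data near 0", {
  pop <- simulate_population(sim_config(
    n_founders = 6, n_haplotypes = 150, n_variants = 60,
    hotspot_positions = 3050, crossover_prob = 0.2,
    mutation_flip_prob = 0, seed = 3))
  plan <- segment_by_hotspots(
    pop$hm, hotspot_set(pop$hotspots, 10),
    segmentation_config(min_mutations = 2, max_mutations = 100))
  res <- coherence_test(pop$hm, pop$hm, plan, seed = 9)
  expect_equal(res$syn_coherence, 1)
  expect_lt(res$shuffled_coherence, 1)
  # crossover_prob 0.2 leaves strong cross-section LD; shuffling kills it
  expect_lt(abs(res$shuffled_coherence), 0.2)
  expect_equal(dim(res$pca$ref), c(150L, 2L))
})

test_that("ancestry metaprofiles count within-sample switches", {
  p <- matrix("AFR", 10, 8)
  expect_equal(ancestry_switch_metaprofile(p), rep(0, 8))
  p[1, 5:8] <- "EUR"  # one sample of ten switches at position 5
  prof <- ancestry_switch_metaprofile(p)
  expect_equal(prof[5], 0.1)
  expect_equal(prof[-5], rep(0, 7))
  expect_equal(metaprofile_correlation(prof, prof), 1)
  expect_error(ancestry_switch_metaprofile(list(c("A", "B"), c("A"))),
               "ragged")
})

test_that("paintings round-trip through the TSV reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tAFR\tAFR\tEUR", "s2\tEAS\tEAS\tEAS"), f)
  p <- read_paintings(f)
  expect_equal(dim(p), c(2L, 3L))
  expect_equal(rownames(p), c("s1", "s2"))
  expect_equal(ancestry_switch_metaprofile(p), c(0, 0, 0.5))
})
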