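test_that("R2 and D from a hand-computed haplotype table", {
  # 10 gametes: 4 AB, 4 ab, 1 Ab, 1 aB  ->  P_AB = 0.4, P_A = P_B = 0.5
  h1 <- c(rep(1, 4), rep(0, 4), 1, 0)
  h2 <- c(rep(1, 4), rep(0, 4), 0, 1)
  ld <- ld_r2_pair(h1, h2)
  expect_equal(ld$D, 0.15)
  expect_equal(ld$r2, 0.36)
  expect_false(ld$monomorphic)
})

test_that("independence gives R2 = 0 and perfect association R2 = 1", {
  expect_equal(ld_from_freqs(0.25, 0.5, 0.5)$r2, 0)        # P_AB = P_A P_B
  expect_equal(ld_from_freqs(0.5, 0.5, 0.5)$r2, 1)         # no recombinants
  expect_true(is.na(ld_from_freqs(0, 0, 0.5)$r2))          # monomorphic locus
  expect_true(ld_from_freqs(0, 0, 0.5)$monomorphic)
})

test_that("R2 equals the squared allele-indicator correlation exactly", {
  set.seed(11)
  for (k in 1:30) {
    n <- sample(10:40, 1)
    h1 <- rbinom(n, 1, runif(1, 0.2, 0.8))
    h2 <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sd(h1) == 0 || sd(h2) == 0) next
    expect_equal(ld_r2_pair(h1, h2)$r2, cor(h1, h2)^2, tolerance = 1e-12)
  }
})

test_that("two complementary haplotypes give R2 = 1 for every pair", {
  H <- rbind(matrix(0, 6, 4), matrix(1, 6, 4))  # gametes all 0s or all 1s
  pop <- make_test_pop(H, positions = c(0.1, 0.5, 1.2, 2.0))
  ld <- ld_decay_profile(pop, max_distance = 3, bin_width = 0.5)
  expect_true(all(abs(na.omit(ld$profile$mean_r2) - 1) < 1e-12))
  expect_equal(ld$adjacent_mean_r2, 1)
})

test_that("independent per-locus shuffling collapses LD to the sampling floor", {
  set.seed(3)
  spec <- genome_spec(n_markers = 80, n_qtl = 0, chromosome_length = 20,
                      mutation_rate = 0, candidate_factor = 1)
  pop <- run_historical(spec, n_generations = 15, n_female = 30, n_male = 30,
                        size = 200)
  Hperm <- apply(pop$H, 2L, sample)
  null_pop <- make_test_pop(Hperm, pop$spec$loci$position)
  ld <- ld_decay_profile(null_pop, max_distance = 20, bin_width = 20)
  # E[r2] under independence is about 1/(number of gametes)
  expect_lt(abs(ld$adjacent_mean_r2 - 1 / nrow(Hperm)), 0.01)
  # while the unshuffled population keeps real short-range LD above the floor
  real <- ld_decay_profile(pop, max_distance = 20, bin_width = 20)
  expect_gt(real$adjacent_mean_r2, ld$adjacent_mean_r2)
})

test_that("LD decays with distance in a drifted population", {
  set.seed(5)
  spec <- genome_spec(n_markers = 120, n_qtl = 0, chromosome_length = 100,
                      candidate_factor = 1)
  pop <- run_historical(spec, n_generations = 40, n_female = 25, n_male = 25,
                        size = 80)
  ld <- ld_decay_profile(pop, max_distance = 50, bin_width = 10)
  prof <- ld$profile[!is.na(ld$profile$mean_r2), ]
  expect_gt(prof$mean_r2[1], prof$mean_r2[nrow(prof)])
})
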