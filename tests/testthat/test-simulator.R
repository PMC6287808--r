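test_that("phase demographies produce the stated population sizes", {
  set.seed(1)
  spec <- genome_spec(n_markers = 40, n_qtl = 10, candidate_factor = 1)
  pop <- run_historical(spec, n_generations = 2, size = 1000)
  expect_equal(pop_size(pop), 1000)
  ext <- run_extended(pop, n_generations = 2)
  expect_equal(pop_size(ext), 500)
  # zero generations returns the phase input unchanged
  expect_identical(run_extended(pop, n_generations = 0), pop)
  f <- run_historical(spec, n_generations = 0, n_female = 50, n_male = 50,
                      size = 200)
  expect_equal(pop_size(f), 200)
  expect_true(all(f$meta$sire == 0))
  expect_error(run_historical(spec, 1, n_female = 0), "invalid demography")
  expect_error(run_historical(spec, 1, n_female = 600, n_male = 600,
                              size = 1000), "invalid demography")
})

test_that("neutral drift leaves the expected allele frequency unchanged", {
  spec <- genome_spec(n_markers = 1, n_qtl = 0, mutation_rate = 0,
                      candidate_factor = 1)
  set.seed(99)
  drift <- t(replicate(20, {
    pop <- run_historical(spec, n_generations = 0, n_female = 50,
                          n_male = 50, size = 150)
    p0 <- allele_freq(pop)
    for (g in 1:25) {
      pop <- conifergs:::random_mating_generation(pop, 50, 50, 150,
                                                  "g", 0)
    }
    c(p0 = p0, p1 = allele_freq(pop))
  }))
  d <- drift[, "p1"] - drift[, "p0"]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("a bottleneck erodes heterozygosity on average", {
  spec <- genome_spec(n_markers = 60, n_qtl = 0, mutation_rate = 0,
                      candidate_factor = 1)
  set.seed(4)
  loss <- replicate(12, {
    pop <- run_historical(spec, n_generations = 1, n_female = 40, n_male = 40,
                          size = 120)
    h0 <- expected_heterozygosity(pop)
    bott <- run_extended(pop, n_generations = 6, n_female = 8, n_male = 8,
                         size = 40)
    h0 - expected_heterozygosity(bott)
  })
  expect_gt(mean(loss), 0)
})

test_that("meiosis obeys the Haldane map expectation at 10 cM", {
  spec <- genome_spec(n_markers = 2, n_qtl = 0, chromosome_length = 150,
                      candidate_factor = 1)
  spec$loci$position <- c(20, 30)
  h1 <- c(0L, 0L); h2 <- c(1L, 1L)
  set.seed(10)
  gam <- replicate(10000, recombine(h1, h2, spec))
  rec_frac <- mean(gam[1, ] != gam[2, ])
  expect_equal(rec_frac, (1 - exp(-0.2)) / 2, tolerance = 0.11)
  expect_lt(abs(rec_frac - 0.0906), 0.01)
  # every allele comes from a parental haplotype
  expect_true(all(gam %in% 0:1))
  # with a vanishing map length the gamete is one intact parental haplotype
  spec0 <- spec
  spec0$chromosome_length <- 1e-9
  spec0$loci$position <- c(1e-10, 2e-10)
  g0 <- replicate(50, recombine(c(0L, 1L), c(1L, 0L), spec0))
  expect_true(all(apply(g0, 2, function(g)
    identical(g, c(0L, 1L)) || identical(g, c(1L, 0L)))))
})

test_that("panel finalization enforces the initial-MAF rule", {
  set.seed(6)
  spec <- genome_spec(n_markers = 50, n_qtl = 20, chromosome_length = 100,
                      candidate_factor = 4)
  pop <- run_historical(spec, n_generations = 10, n_female = 30, n_male = 30,
                        size = 100)
  fin <- finalize_panel(pop)
  expect_equal(fin$spec$n_markers, 50)
  expect_equal(sum(fin$spec$loci$type == "marker"), 50)
  expect_equal(sum(fin$spec$loci$type == "qtl"), 20)
  p <- allele_freq(fin, "marker")
  expect_true(all(pmin(p, 1 - p) > 0.10))
  pq <- allele_freq(fin, "qtl")
  expect_true(all(pq > 0 & pq < 1))
  expect_identical(finalize_panel(fin), fin)  # idempotent
})

recent_setup <- function(seed, n_generations = 2) {
  set.seed(seed)
  spec <- genome_spec(n_markers = 60, n_qtl = 40, chromosome_length = 100,
                      candidate_factor = 2)
  pop <- run_historical(spec, n_generations = 8, n_female = 60, n_male = 60,
                        size = 200)
  pop <- finalize_panel(pop)
  trait <- trait_model(pop, h2 = 0.5)
  run_recent(pop, trait, n_generations = n_generations)
}

test_that("the breeding phase has the stated family and ramet structure", {
  rec <- recent_setup(17)
  g1 <- rec$generations[[1]]
  expect_equal(pop_size(g1$pop), 32 * 2 * 15)  # 64 circular crosses x 15
  fam <- table(paste(g1$pop$meta$sire, g1$pop$meta$dam))
  expect_equal(length(fam), 64L)
  expect_true(all(fam == 15))
  # each parent appears in exactly two crosses
  par_use <- table(c(g1$pop$meta$sire[!duplicated(paste(g1$pop$meta$sire,
                                                        g1$pop$meta$dam))],
                     g1$pop$meta$dam[!duplicated(paste(g1$pop$meta$sire,
                                                       g1$pop$meta$dam))]))
  expect_true(all(par_use == 2))
  expect_equal(nrow(g1$phenotypes), 4 * 960)
  expect_true(all(table(g1$phenotypes$clone_id) == 4))
  # pedigree closure: all parents drawn from the recorded parent set
  expect_true(all(g1$pop$meta$sire %in% g1$parents))
  expect_true(all(g1$pop$meta$dam %in% g1$parents))
  # evaluation returns one EBV and accuracy per clone
  expect_length(g1$eval$ebv, 960)
  expect_true(all(g1$eval$accuracy_r >= 0 & g1$eval$accuracy_r <= 1))
})

test_that("selection on EBVs moves mean TBV upward across generations", {
  ups <- vapply(1:5, function(s) {
    rec <- recent_setup(100 + s, n_generations = 3)
    tr <- rec$trait
    mean(true_breeding_value(rec$generations[[3]]$pop, tr)) >
      mean(true_breeding_value(rec$generations[[1]]$pop, tr))
  }, logical(1))
  expect_gte(sum(ups), 4)
})
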