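make_drifted_pop <- function(seed = 1, n_markers = 30, n_qtl = 40,
                             size = 300) {
  set.seed(seed)
  spec <- genome_spec(n_markers = n_markers, n_qtl = n_qtl,
                      chromosome_length = 50, candidate_factor = 1)
  run_historical(spec, n_generations = 5, n_female = 50, n_male = 50,
                 size = size)
}

test_that("QTL effects are rescaled to the target additive variance exactly", {
  pop <- make_drifted_pop()
  tr <- trait_model(pop, h2 = 0.5, seed = 2)
  tbv <- true_breeding_value(pop, tr)
  expect_equal(var(tbv), 300, tolerance = 1e-9)
  expect_lt(abs(mean(tbv)), 1e-9)
})

test_that("residual variance follows the heritability identity", {
  pop <- make_drifted_pop()
  expect_equal(trait_model(pop, h2 = 0.5, seed = 2)$sigma2_e, 255)
  expect_equal(trait_model(pop, h2 = 0.2, seed = 2)$sigma2_e, 1155)
  expect_error(trait_model(pop, h2 = 1.2), "h2 must be")
  expect_error(trait_model(pop, h2 = 0.9), "not positive")
})

test_that("TBV matches the Hardy-Weinberg enumeration oracle", {
  # two loci at frequency 0.5 with effects +1/-1: exact variance is 1.0
  expect_equal(oracle_hw_tbv_var(c(1, -1), c(0.5, 0.5)), 1.0)
  set.seed(9)
  n <- 20000
  H <- matrix(rbinom(2 * n * 2, 1, 0.5), nrow = 2 * n)
  pop <- make_test_pop(H, positions = c(1, 2), types = c("qtl", "qtl"))
  tr <- list(qtl_effects = c(1, -1), ref_mean = c(0, 0))
  class(tr) <- "trait_model"
  tbv <- true_breeding_value(pop, tr, center = FALSE)
  expect_equal(var(tbv), 1.0, tolerance = 0.05)
  # single heterozygote vs reference homozygote differs by the effect
  Hp <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(0L, 0L))
  p2 <- make_test_pop(Hp, positions = c(1, 2), types = c("qtl", "qtl"))
  tr2 <- list(qtl_effects = c(2.5, 0), ref_mean = c(0, 0))
  class(tr2) <- "trait_model"
  tb <- true_breeding_value(p2, tr2, center = FALSE)
  expect_equal(tb[2] - tb[1], 2.5)
  expect_equal(tb[1], 0)  # zero-count convention, centring disabled
})

test_that("phenotypes decompose exactly and share clone effects across ramets", {
  pop <- make_drifted_pop(seed = 3)
  tr <- trait_model(pop, h2 = 0.2, seed = 4)
  phe <- simulate_phenotypes(pop, tr, n_ramets = 4, seed = 5)
  expect_equal(nrow(phe), 4 * pop_size(pop))
  expect_equal(phe$phenotype, phe$tbv + phe$nonadditive + phe$residual)
  shared <- tapply(phe$nonadditive, phe$clone_id, function(x) diff(range(x)))
  expect_true(all(shared == 0))
  # zero-variance override: phenotype collapses to TBV
  tr0 <- tr
  tr0$sigma2_d <- 0
  tr0$sigma2_e <- 0
  phe0 <- simulate_phenotypes(pop, tr0, n_ramets = 2, seed = 6)
  expect_equal(phe0$phenotype, phe0$tbv)
})

test_that("phenotypic variance components are recovered empirically", {
  set.seed(31)
  accum <- replicate(6, {
    pop <- make_drifted_pop(seed = sample.int(1e6, 1), size = 400)
    tr <- trait_model(pop, h2 = 0.5)
    phe <- simulate_phenotypes(pop, tr, n_ramets = 4)
    cm <- tapply(phe$residual, phe$clone_id, mean)
    c(var_p = var(phe$phenotype), var_d = var(phe$nonadditive[phe$ramet_index == 1]),
      var_cm_res = var(as.numeric(cm)))
  })
  m <- rowMeans(accum)
  expect_equal(unname(m["var_p"]), 600, tolerance = 0.05)
  expect_equal(unname(m["var_d"]), 45, tolerance = 0.15)
  # clone-mean residual variance is sigma2_e / 4
  expect_equal(unname(m["var_cm_res"]), 255 / 4, tolerance = 0.15)
  # slope of phenotype on TBV is ~1 (independent noise)
  pop <- make_drifted_pop(seed = 77, size = 400)
  tr <- trait_model(pop, h2 = 0.5)
  phe <- simulate_phenotypes(pop, tr, n_ramets = 4)
  expect_equal(unname(coef(lm(phenotype ~ tbv, phe))[2]), 1, tolerance = 0.1)
})
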