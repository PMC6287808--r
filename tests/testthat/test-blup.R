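test_that("tabular relationship matrix reproduces textbook kinships", {
  # 1,2 founders; 3,4 full sibs of (1,2); 5 half sib of 3 via shared sire 1
  ped <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 1), dam = c(0, 0, 2, 2, 0))
  A <- build_A(ped)
  expect_equal(unname(A[1:2, 1:2]), diag(2))          # unrelated founders
  expect_equal(A["1", "3"], 0.5)                      # parent-offspring
  expect_equal(A["3", "4"], 0.5)                      # full sibs
  expect_equal(A["3", "5"], 0.25)                     # half sibs
  # offspring of a parent-offspring mating is inbred: diagonal 1.25
  ped2 <- rbind(ped, data.frame(id = 6, sire = 1, dam = 3))
  expect_equal(build_A(ped2)["6", "6"], 1.25)
  expect_error(build_A(data.frame(id = 1:2, sire = c(2, 0), dam = c(0, 0))),
               "cyclic or unordered")
  expect_error(build_A(data.frame(id = 1:2, sire = c(0, 9), dam = c(0, 0))),
               "not closed")
})

test_that("equal phenotypes give zero EBVs", {
  ped <- data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 2))
  A <- build_A(ped)
  fit <- solve_mme(rep(3.7, 8), clone = rep(1:4, each = 2), A = A,
                   sigma2_a = 300, sigma2_d = 45, sigma2_e = 255)
  expect_equal(fit$ebv, rep(0, 4), tolerance = 1e-10)
  expect_equal(fit$mu, 3.7, tolerance = 1e-10)
})

test_that("MME solutions equal brute-force GLS on random small instances", {
  set.seed(21)
  for (k in 1:20) {
    nf <- sample(2:4, 1)
    no <- sample(2:4, 1)
    ped <- random_pedigree(nf, no)
    A <- build_A(ped)
    n_rec <- sample(4:12, 1)
    clone <- sample(nrow(A), n_rec, replace = TRUE)
    y <- rnorm(n_rec, sd = 5)
    s2a <- runif(1, 50, 400); s2d <- runif(1, 10, 100)
    s2e <- runif(1, 50, 400)
    fit <- solve_mme(y, clone, A, s2a, s2d, s2e)
    orc <- oracle_gls(y, clone, A, s2a, s2d, s2e)
    expect_equal(fit$mu, orc$mu, tolerance = 1e-8)
    expect_equal(fit$ebv, orc$ebv, tolerance = 1e-8)
    expect_true(all(fit$accuracy >= 0 & fit$accuracy <= 1))
  }
})

test_that("vanishing residual splits records in the a:d variance ratio", {
  y <- c(2, -1, 4)
  A <- diag(3)
  fit <- solve_mme(y, clone = 1:3, A = A, sigma2_a = 300, sigma2_d = 100,
                   sigma2_e = 1e-6)
  expect_equal(fit$ebv, (300 / 400) * (y - mean(y)), tolerance = 1e-4)
})

test_that("clone-mean fast path equals the full record-level MME", {
  set.seed(5)
  ped <- random_pedigree(3, 5)
  A <- build_A(ped)
  n_ramets <- 4
  clones_with_rec <- 4:8
  y <- rnorm(length(clones_with_rec) * n_ramets, sd = 8)
  clone <- rep(clones_with_rec, each = n_ramets)
  full <- solve_mme(y, clone, A, 300, 45, 255)
  ybar <- tapply(y, clone, mean)
  fast <- conifergs:::blup_animal_means(
    as.numeric(ybar), idx = clones_with_rec,
    m = rep(n_ramets, length(clones_with_rec)), A = A,
    sigma2_a = 300, sigma2_d = 45, sigma2_e = 255)
  expect_equal(fast$mu, full$mu, tolerance = 1e-8)
  expect_equal(fast$ebv, full$ebv, tolerance = 1e-8)
  expect_equal(fast$accuracy, full$accuracy, tolerance = 1e-8)
})

test_that("more ramet records never reduce PEV accuracy, and EBVs shrink", {
  A <- build_A(random_pedigree(2, 3))
  set.seed(8)
  y1 <- rnorm(3, sd = 10)
  f1 <- solve_mme(y1, clone = 3:5, A = A, 300, 45, 255)
  y2 <- c(y1, rnorm(1, sd = 10))
  f2 <- solve_mme(y2, clone = c(3:5, 3L), A = A, 300, 45, 255)
  expect_gte(f2$accuracy[3] + 1e-12, f1$accuracy[3])
  # shrinkage: EBV variance below TBV variance in expectation
  set.seed(12)
  vr <- replicate(30, {
    pop_tbv <- rnorm(5, sd = sqrt(300))
    y <- rep(pop_tbv, each = 2) + rnorm(10, sd = sqrt(300))
    f <- solve_mme(y, clone = rep(1:5, each = 2), A = diag(5), 300, 45, 255)
    c(var(f$ebv), var(pop_tbv))
  })
  expect_lt(mean(vr[1, ]), mean(vr[2, ]))
})

test_that("realized accuracy handles exact and degenerate inputs", {
  expect_equal(realized_accuracy(1:10, 1:10), 1)
  expect_equal(realized_accuracy(1:10, -(1:10)), -1)
  set.seed(2)
  expect_lt(abs(realized_accuracy(rnorm(2000), rnorm(2000))), 0.08)
  expect_warning(out <- realized_accuracy(rep(1, 5), 1:5), "zero-variance")
  expect_true(is.na(out))
})
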