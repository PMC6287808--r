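# Independent oracles used across the suite. Each re-derives its quantity by
# brute force, without calling the implementation path it checks.

# Year-by-year deployment oracle: walk the calendar one year at a time,
# recording when each breeding cycle's material becomes usable and what the
# newest usable merit is at each rotation start. Timings are re-stated here
# from the published option table rather than taken from the engine.
oracle_timings <- function(option) {
  tab <- list(
    FS_s   = c(G = 17, t_cs = 14, t_sd = 8),
    FS_c   = c(G = 17, t_cs = 14, t_sd = 1),
    FSCA_s = c(G = 14, t_cs = 14, t_sd = 5),
    FSCA_c = c(G = 14, t_cs = 14, t_sd = 1),
    GS_s   = c(G = 9,  t_cs = 9,  t_sd = 5),
    GS_c   = c(G = 9,  t_cs = 9,  t_sd = 1),
    GSTG_s = c(G = 7,  t_cs = 7,  t_sd = 5),
    GSTG_c = c(G = 7,  t_cs = 7,  t_sd = 1)
  )
  tab[[option]]
}

oracle_deployment_total <- function(option, n_rotations = 8,
                                    rotation_length = 25) {
  tm <- oracle_timings(option)
  horizon <- rotation_length * (n_rotations - 1)
  newest <- 0
  total <- 0
  next_rotation_start <- 0
  for (year in 0:horizon) {
    # material of cycle i is usable from year t_cs + G(i-1) + t_sd - 1 on
    i <- 0
    repeat {
      i <- i + 1
      avail <- tm[["t_cs"]] + tm[["G"]] * (i - 1) + tm[["t_sd"]] - 1
      if (avail > year) break
      if (i > newest) newest <- i
    }
    if (year == next_rotation_start) {
      total <- total + newest
      next_rotation_start <- next_rotation_start + rotation_length
    }
  }
  total
}

# Generalized least squares oracle for the mixed model
# y = 1 mu + Za a + Zd d + e, by explicit inversion of
# V = Za A Za' s2a + Zd Zd' s2d + I s2e.
oracle_gls <- function(y, clone, A, s2a, s2d, s2e) {
  n <- length(y)
  q <- nrow(A)
  dlev <- sort(unique(clone))
  Za <- matrix(0, n, q); Za[cbind(seq_len(n), clone)] <- 1
  Zd <- matrix(0, n, length(dlev))
  Zd[cbind(seq_len(n), match(clone, dlev))] <- 1
  V <- Za %*% A %*% t(Za) * s2a + Zd %*% t(Zd) * s2d + diag(n) * s2e
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- as.numeric((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  a <- as.numeric(s2a * A %*% t(Za) %*% Vi %*% (y - mu))
  list(mu = mu, ebv = a)
}

# Random small pedigree with parents preceding offspring.
random_pedigree <- function(n_founder, n_offspring) {
  n <- n_founder + n_offspring
  sire <- dam <- integer(n)
  for (i in (n_founder + 1):n) {
    pr <- sample(seq_len(i - 1), 2)
    sire[i] <- pr[1]
    dam[i] <- pr[2]
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam)
}

# Enumerate all two-locus genotypes under Hardy-Weinberg and independence,
# returning the exact breeding-value variance for given effects/frequencies.
oracle_hw_tbv_var <- function(effects, freqs) {
  stopifnot(length(effects) == length(freqs))
  counts <- expand.grid(rep(list(0:2), length(effects)))
  w <- rep(1, nrow(counts))
  for (j in seq_along(freqs)) {
    p <- freqs[j]
    gp <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    w <- w * gp[counts[[j]] + 1]
  }
  tbv <- as.matrix(counts) %*% effects
  m <- sum(w * tbv)
  sum(w * (tbv - m)^2)
}

# Tiny population with explicitly supplied haplotypes (loci in map order).
make_test_pop <- function(H, positions, types = NULL,
                          sex = NULL, chromosome_length = max(positions) + 1) {
  n <- nrow(H) / 2
  if (is.null(types)) types <- rep("marker", length(positions))
  spec <- genome_spec(n_markers = max(1, sum(types == "marker")),
                      n_qtl = sum(types == "qtl"),
                      chromosome_length = chromosome_length,
                      candidate_factor = 1)
  spec$loci <- data.frame(position = positions, type = types,
                          stringsAsFactors = FALSE)
  spec$n_markers <- sum(types == "marker")
  spec$n_qtl <- sum(types == "qtl")
  spec$finalized <- TRUE
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = n)
  meta <- data.frame(id = seq_len(n), sire = 0L, dam = 0L, sex = sex,
                     generation = "test", stringsAsFactors = FALSE)
  conifergs:::new_pop(H, meta, spec)
}
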