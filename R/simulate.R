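#' Meiosis: one recombinant gamete
#'
#' Crossover count is Poisson with mean `chromosome_length / 100` (one
#' expected crossover per Morgan) and crossover points are uniform on the map:
#' the Haldane model, no interference. Every gamete allele is copied from one
#' of the two parental haplotypes.
#'
#' @param hap1,hap2 Integer 0/1 vectors, the parent's two haplotypes over all
#'   loci of `spec`, in map order.
#' @param spec A [genome_spec()].
#' @return Integer 0/1 gamete vector.
#' @export
recombine <- function(hap1, hap2, spec) {
  stopifnot(length(hap1) == nrow(spec$loci), length(hap2) == length(hap1))
  recombine_cpp(as.integer(hap1), as.integer(hap2),
                spec$loci$position, spec$chromosome_length)
}

## One generation of random union of gametes: dam/sire are row indices into
## pop$meta; returns the offspring haplotype matrix.
drop_offspring <- function(pop, dam, sire, mutation_rate) {
  drop_gametes_cpp(pop$H, pop$spec$loci$position,
                   as.integer(dam), as.integer(sire),
                   pop$spec$chromosome_length, mutation_rate)
}

next_meta <- function(n, dam_id, sire_id, generation, id_start) {
  data.frame(
    id = id_start + seq_len(n) - 1L,
    sire = as.integer(sire_id),
    dam = as.integer(dam_id),
    sex = sample(c("F", "M"), n, replace = TRUE),
    generation = generation,
    stringsAsFactors = FALSE
  )
}

random_mating_generation <- function(pop, n_female, n_male, size, generation,
                                     mutation_rate) {
  fem <- which(pop$meta$sex == "F")
  mal <- which(pop$meta$sex == "M")
  if (length(fem) < n_female || length(mal) < n_male) {
    stop("not enough parents of each sex: need ", n_female, "F + ", n_male,
         "M, have ", length(fem), "F + ", length(mal), "M")
  }
  fem <- sample(fem, n_female)
  mal <- sample(mal, n_male)
  dam <- sample(fem, size, replace = TRUE)
  sire <- sample(mal, size, replace = TRUE)
  H <- drop_offspring(pop, dam, sire, mutation_rate)
  new_pop(H, next_meta(size, pop$meta$id[dam], pop$meta$id[sire], generation,
                       max(pop$meta$id) + 1L), pop$spec)
}

#' Historical burn-in phase
#'
#' Creates a founder population and runs `n_generations` of random union of
#' gametes at constant population size with recurrent mutation and no
#' selection. The default demography is 500 generations with 300 female and
#' 300 male parents at a constant size of 1000, which establishes
#' mutation-drift equilibrium and baseline linkage disequilibrium.
#'
#' @param spec A [genome_spec()].
#' @param n_generations Number of historical generations (default 500).
#' @param n_female,n_male Parents drawn each generation (defaults 300/300).
#' @param size Constant population size (default 1000).
#' @param seed Optional integer seed set before any random draw.
#' @return A `gs_pop` for the final generation.
#' @export
run_historical <- function(spec, n_generations = 500L, n_female = 300L,
                           n_male = 300L, size = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_generations >= 0)
  if (n_female < 1 || n_male < 1 || size < 2)
    stop("invalid demography: need at least one parent of each sex")
  if (n_female + n_male > size)
    stop("invalid demography: n_female + n_male exceeds population size")
  pop <- founder_population(spec, size)
  for (g in seq_len(n_generations)) {
    pop <- random_mating_generation(pop, n_female, n_male, size,
                                    paste0("hist", g), spec$mutation_rate)
  }
  pop
}

#' Extended phase (population bottleneck)
#'
#' Continues random mating from the historical population at a reduced size:
#' by default 10 generations with 100 female and 100 male parents at constant
#' size 500, with mutation still active. The tighter bottleneck inflates
#' linkage disequilibrium towards the level of a closed breeding population.
#'
#' @param pop Output of [run_historical()].
#' @param n_generations Number of generations (default 10).
#' @param n_female,n_male Parents per generation (defaults 100/100).
#' @param size Constant population size (default 500).
#' @param seed Optional integer seed.
#' @return A `gs_pop` for the final extended generation.
#' @export
run_extended <- function(pop, n_generations = 10L, n_female = 100L,
                         n_male = 100L, size = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pop, "gs_pop"), n_generations >= 0)
  if (n_female < 1 || n_male < 1)
    stop("invalid demography: need at least one parent of each sex")
  spec <- pop$spec
  for (g in seq_len(n_generations)) {
    pop <- random_mating_generation(pop, n_female, n_male, size,
                                    paste0("ext", g), spec$mutation_rate)
  }
  pop
}

## Circular mating: 64 parents on a ring alternating F/M in EBV-rank order;
## each parent is mated to both neighbours -> 64 crosses, each parent used
## exactly twice.
circular_crosses <- function(fem_idx, mal_idx) {
  stopifnot(length(fem_idx) == length(mal_idx))
  ring <- integer(2L * length(fem_idx))
  ring[seq(1L, length(ring), by = 2L)] <- fem_idx
  ring[seq(2L, length(ring), by = 2L)] <- mal_idx
  nxt <- c(ring[-1L], ring[1L])
  data.frame(a = ring, b = nxt)
}

#' Recent discrete generations under selection
#'
#' Runs the breeding phase: each generation selects 32 female and 32 male
#' parents on pedigree-BLUP EBVs (random in generation 1, when no phenotypes
#' exist yet), mates them in a circular design in which each parent is
#' crossed twice (64 crosses), generates 15 offspring per family (960 clones)
#' and phenotypes 4 ramets per clone. No mutation occurs in this phase. Each
#' generation is evaluated twice with Henderson's mixed-model equations on a
#' rolling two-generation pedigree (see the package vignette): a full
#' clone-mean evaluation over all ramets (`eval$ebv`, the genomic-training
#' response) and a single-record evaluation (`eval$sel_ebv`) that drives
#' parent selection and the forward-selection comparator.
#'
#' @param pop Population entering the breeding program (e.g. the output of
#'   [run_extended()]).
#' @param trait A [trait_model()] built on a reference population.
#' @param n_generations Number of discrete generations (default 10).
#' @param n_parents_per_sex Parents selected per sex (default 32).
#' @param n_per_family Offspring per cross (default 15).
#' @param n_ramets Clonal copies phenotyped per offspring (default 4).
#' @param seed Optional integer seed.
#' @return A `gs_recent` object: list with one element per generation, each
#'   holding `pop`, `phenotypes`, `eval` (per-clone EBV and PEV-based
#'   accuracy) and the realized accuracy bookkeeping, plus the trait model.
#' @export
run_recent <- function(pop, trait, n_generations = 10L,
                       n_parents_per_sex = 32L, n_per_family = 15L,
                       n_ramets = 4L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pop, "gs_pop"), inherits(trait, "trait_model"),
            n_generations >= 1)
  spec <- pop$spec
  gens <- vector("list", n_generations)
  parent_pop <- pop
  parent_crit <- NULL   # EBVs of candidate parents; NULL -> random selection
  parent_means <- NULL  # clone means of the parent generation's phenotypes
  for (g in seq_len(n_generations)) {
    sel <- select_parents(parent_pop, parent_crit, n_parents_per_sex)
    crosses <- circular_crosses(sel$fem, sel$mal)
    dam <- rep(ifelse(parent_pop$meta$sex[crosses$a] == "F",
                      crosses$a, crosses$b), each = n_per_family)
    sire <- rep(ifelse(parent_pop$meta$sex[crosses$a] == "M",
                       crosses$a, crosses$b), each = n_per_family)
    H <- drop_offspring(parent_pop, dam, sire, 0)  # no mutation, recent phase
    n_off <- length(dam)
    off <- new_pop(H, next_meta(n_off, parent_pop$meta$id[dam],
                                parent_pop$meta$id[sire],
                                paste0("recent", g),
                                max(parent_pop$meta$id) + 1L), spec)
    phe <- simulate_phenotypes(off, trait, n_ramets = n_ramets)
    ev <- tryCatch(
      evaluate_generation(off, parent_pop, sel, phe, trait, parent_means),
      error = function(e) stop("evaluation failed in recent generation ", g,
                               ": ", conditionMessage(e), call. = FALSE)
    )
    gens[[g]] <- list(pop = off, phenotypes = phe, eval = ev,
                      parents = parent_pop$meta$id[c(sel$fem, sel$mal)])
    ybar <- tapply(phe$phenotype, phe$clone_id, mean)
    one <- phe[phe$ramet_index == 1L, ]
    parent_means <- data.frame(id = as.integer(names(ybar)),
                               ybar = as.numeric(ybar),
                               m = as.numeric(tapply(phe$phenotype,
                                                     phe$clone_id, length)),
                               y1 = one$phenotype[match(as.integer(names(ybar)),
                                                        one$clone_id)])
    parent_pop <- off
    parent_crit <- ev$sel_ebv
  }
  structure(list(generations = gens, trait = trait, spec = spec),
            class = "gs_recent")
}

## Pick the top n per sex on the criterion (random when crit is NULL), and
## return row indices ordered by criterion rank (used for the mating ring).
select_parents <- function(pop, crit, n_per_sex) {
  meta <- pop$meta
  if (is.null(crit)) crit <- sample(pop_size(pop))
  stopifnot(length(crit) == pop_size(pop))
  pick <- function(sex) {
    cand <- which(meta$sex == sex)
    if (length(cand) < n_per_sex)
      stop("not enough ", sex, " candidates: ", length(cand), " < ", n_per_sex)
    cand[order(-crit[cand], meta$id[cand])][seq_len(n_per_sex)]
  }
  list(fem = pick("F"), mal = pick("M"))
}

## Rolling two-generation animal model: grandparents enter as pedigree
## founders, the 64 parents carry their own records from the previous
## generation (when phenotyped), and the offspring carry theirs. The clone
## (non-additive) effect is absorbed exactly for balanced ramet data: the
## residual variance of an m-ramet clone mean is sigma2_d + sigma2_e / m.
##
## Two evaluations are run on the same pedigree:
##   * the full clone-mean evaluation (all ramets) -> `ebv`, `accuracy_r`,
##     the response and weights for genomic training;
##   * a single-record evaluation (one ramet per clone) -> `sel_ebv`,
##     `sel_accuracy`, the criterion used to pick parents and the forward-
##     selection comparator. The breeding program's selection operates at
##     single-record accuracy (~sqrt(h2) plus pedigree information), the
##     regime the reported selection accuracies correspond to.
evaluate_generation <- function(off, parent_pop, sel, phe, trait,
                                parent_means = NULL) {
  par_rows <- c(sel$fem, sel$mal)
  par_id <- parent_pop$meta$id[par_rows]
  par_sire <- parent_pop$meta$sire[par_rows]
  par_dam <- parent_pop$meta$dam[par_rows]
  gp_id <- setdiff(sort(unique(c(par_sire, par_dam))), 0L)
  ids <- c(gp_id, par_id, off$meta$id)
  ng <- length(gp_id)
  np <- length(par_id)
  no <- pop_size(off)
  to_idx <- function(parent) {
    i <- match(parent, ids)
    ifelse(is.na(i), 0L, i)
  }
  sire <- c(rep(0L, ng), to_idx(par_sire), to_idx(off$meta$sire))
  dam <- c(rep(0L, ng), to_idx(par_dam), to_idx(off$meta$dam))
  A <- tabular_a_cpp(as.integer(sire), as.integer(dam))
  off_slice <- ng + np + seq_len(no)

  ybar_o <- tapply(phe$phenotype, phe$clone_id, mean)
  ord <- match(off$meta$id, as.integer(names(ybar_o)))
  one <- phe[phe$ramet_index == 1L, ]
  y1_o <- one$phenotype[match(off$meta$id, one$clone_id)]
  m_full <- as.numeric(tapply(phe$phenotype, phe$clone_id, length)[ord])

  run_fit <- function(y_off, m_off, par_y, par_m) {
    y <- y_off
    m <- m_off
    idx <- off_slice
    if (!is.null(parent_means)) {
      hit <- match(par_id, parent_means$id)
      ok <- !is.na(hit)
      y <- c(par_y[hit[ok]], y)
      m <- c(par_m[hit[ok]], m)
      idx <- c(ng + which(ok), idx)
    }
    blup_animal_means(y, idx = idx, m = m, A = A,
                      sigma2_a = trait$sigma2_a, sigma2_d = trait$sigma2_d,
                      sigma2_e = trait$sigma2_e)
  }
  full <- run_fit(as.numeric(ybar_o[ord]), m_full,
                  parent_means$ybar, parent_means$m)
  single <- run_fit(y1_o, rep(1, no), parent_means$y1,
                    if (is.null(parent_means)) NULL else
                      rep(1, nrow(parent_means)))
  list(ebv = full$ebv[off_slice],
       accuracy_r = full$accuracy[off_slice],
       sel_ebv = single$ebv[off_slice],
       sel_accuracy = single$accuracy[off_slice],
       mu = full$mu, method = "BLUP")
}

#' @export
print.gs_recent <- function(x, ...) {
  ng <- length(x$generations)
  cat("Recent breeding phase:", ng, "generations,",
      pop_size(x$generations[[ng]]$pop), "clones per generation\n")
  invisible(x)
}
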