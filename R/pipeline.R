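#' Simulate one replicate of the breeding program
#'
#' Runs genome construction, the historical and extended phases, then — for
#' each requested heritability — draws a trait model on the population
#' entering the breeding phase and runs the ten recent discrete generations
#' under BLUP selection. All randomness flows from `seed`.
#'
#' @param config A [default_config()]-style configuration.
#' @param seed Integer seed for this replicate.
#' @return List: `spec`, `base` (population entering the recent phase) and
#'   `runs`, a named list (by h2) of `gs_recent` objects.
#' @export
simulate_replicate <- function(config = default_config(), seed = 1L) {
  set.seed(seed)
  g <- config$genome
  spec <- genome_spec(n_markers = g$n_markers, n_qtl = g$n_qtl,
                      chromosome_length = g$chromosome_length,
                      mutation_rate = g$mutation_rate,
                      min_initial_maf = g$min_initial_maf)
  dh <- config$demography$historical
  de <- config$demography$extended
  base <- run_historical(spec, dh$n_generations, dh$n_female, dh$n_male,
                         dh$size)
  base <- run_extended(base, de$n_generations, de$n_female, de$n_male,
                       de$size)
  base <- finalize_panel(base)
  dr <- config$demography$recent
  tr <- config$trait
  runs <- list()
  for (h2 in tr$h2) {
    trait <- trait_model(base, h2 = h2, sigma2_a = tr$sigma2_a,
                         nonadd_prop = tr$nonadd_prop,
                         gamma_shape = tr$gamma_shape,
                         gamma_scale = tr$gamma_scale)
    runs[[as.character(h2)]] <- run_recent(
      base, trait, n_generations = dr$n_generations,
      n_parents_per_sex = dr$n_parents_per_sex,
      n_per_family = dr$n_per_family, n_ramets = dr$n_ramets)
  }
  list(spec = spec, base = base, runs = runs)
}

## Pool the training candidates (clones of the training generations) of one
## recent-phase run: ids, EBVs, PEV accuracies and marker genotypes. EBVs
## come from each generation's rolling evaluation (deviations from its
## evaluation base).
training_pool <- function(recent, generations) {
  gens <- recent$generations[generations]
  ids <- unlist(lapply(gens, function(g) g$pop$meta$id))
  ebv <- unlist(lapply(gens, function(g) g$eval$ebv))
  r <- unlist(lapply(gens, function(g) g$eval$accuracy_r))
  X <- do.call(rbind, lapply(gens, function(g) genotype_matrix(g$pop, "marker")))
  colnames(X) <- paste0("snp", seq_len(ncol(X)))
  list(ids = ids, ebv = ebv, r = r, X = X)
}

#' Evaluate one genomic-selection scenario on a simulated replicate
#'
#' Takes a simulated replicate, a heritability, a training-population size
#' and a marker-panel size; samples the training clones from the training
#' generations, fits BayesC on their EBVs with de-regression weights,
#' predicts GEBVs for the generation-10 prediction clones, and accounts
#' selection gain for GS (selecting 9/960 on GEBV) and FS (selecting on EBV),
#' both measured on true breeding values.
#'
#' @param sim Output of [simulate_replicate()].
#' @param h2 Heritability selecting the run (must be in `config$trait$h2`).
#' @param tp_size Training-population size (clones).
#' @param panel Number of markers to use; a random subset of the simulated
#'   panel when smaller than it.
#' @param config Configuration (for BayesC, selection and training settings).
#' @param seed Integer seed for training sampling and the Gibbs chain.
#' @param train_rows Optional explicit training rows into the pooled
#'   training generations (overrides random sampling); used by
#'   [run_experiment()] to nest training sets across factorial cells so that
#'   cell comparisons are paired.
#' @param snp_cols Optional explicit marker columns (overrides random
#'   subsampling), for the same reason.
#' @return One-row data frame with accuracies and gains.
#' @export
run_scenario <- function(sim, h2, tp_size, panel, config = default_config(),
                         seed = 1L, train_rows = NULL, snp_cols = NULL) {
  set.seed(seed)
  recent <- sim$runs[[as.character(h2)]]
  if (is.null(recent)) stop("no simulated run for h2 = ", h2)
  trait <- recent$trait
  pool <- training_pool(recent, config$evaluation$training_generations)
  if (tp_size > length(pool$ids))
    stop("training size ", tp_size, " exceeds the pool of ",
         length(pool$ids), " clones")
  take <- if (is.null(train_rows)) sample(length(pool$ids), tp_size) else
    train_rows[seq_len(tp_size)]
  if (is.null(snp_cols)) {
    snp_cols <- if (panel < ncol(pool$X)) sort(sample(ncol(pool$X), panel))
      else seq_len(ncol(pool$X))
  } else {
    snp_cols <- sort(snp_cols[seq_len(panel)])
  }
  Xtr <- pool$X[take, snp_cols, drop = FALSE]
  w <- deregression_weights(h2, pool$r[take], config$bayesc$c_weight)
  bc <- config$bayesc
  fit <- run_bayesc(Xtr, pool$ebv[take], weights = w,
                    config = bayesc_config(pi = bc$pi, nu_a = bc$nu_a,
                                           nu_e = bc$nu_e, n_iter = bc$n_iter,
                                           burn_in = bc$burn_in,
                                           c_weight = bc$c_weight),
                    sigma2_a = trait$sigma2_a, maf_min = bc$maf_min)
  ng <- length(recent$generations)
  pred <- recent$generations[[ng]]
  Xpred <- genotype_matrix(pred$pop, "marker")[, snp_cols, drop = FALSE]
  colnames(Xpred) <- colnames(Xtr)
  gebv <- predict_gebv(fit, Xpred)
  tbv <- true_breeding_value(pred$pop, trait)
  nsel <- config$selection$n_selected
  # FS deploys the full clonal field test: its comparator is the clone-mean
  # EBV, not the single-record criterion that drives recurrent selection
  gs <- select_top(gebv, tbv, n = nsel, clone_id = pred$pop$meta$id)
  fs <- select_top(pred$eval$ebv, tbv, n = nsel, clone_id = pred$pop$meta$id)
  data.frame(
    h2 = h2, tp_size = tp_size, panel = panel,
    n_snp_used = length(fit$kept),
    gebv_accuracy = gebv_accuracy(gebv, tbv),
    ebv_accuracy = realized_accuracy(pred$eval$ebv, tbv),
    gain_gs = gs$gain_per_generation,
    gain_fs = fs$gain_per_generation
  )
}

#' Run the full simulation experiment
#'
#' Executes `config$replicates` independent replicates of the breeding
#' program and, within each, the factorial of heritabilities, training sizes
#' and marker panels. Returns the per-cell results, their replicate-mean
#' summary with standard errors, a marker-panel LD summary at the start of
#' the breeding phase, and the per-year gain and deployment tables derived
#' from the replicate-mean gains at the densest panel. When `out_dir` is
#' given, all tables, the resolved configuration and a run manifest are
#' written there as plain text.
#'
#' @param config A `gs_config`.
#' @param out_dir Optional output directory.
#' @return List of class `gs_experiment`: `cells`, `summary`, `ld`,
#'   `gain_table`, `deployment_table`, `config`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL) {
  cells <- list()
  lds <- list()
  for (rep in seq_len(config$replicates)) {
    sim <- simulate_replicate(config, seed = derive_seed(config$seed, rep))
    for (panel in config$evaluation$panels) {
      set.seed(derive_seed(config$seed, rep, stage = panel))
      snp_cols <- if (panel < sim$spec$n_markers)
        sort(sample(sim$spec$n_markers, panel)) else seq_len(sim$spec$n_markers)
      sub <- subset_markers(sim$base, snp_cols)
      ld <- ld_decay_profile(sub, max_distance = 2, bin_width = 0.1)
      lds[[length(lds) + 1L]] <- data.frame(
        replicate = rep, panel = panel,
        adjacent_mean_r2 = ld$adjacent_mean_r2)
    }
    # Nested training and marker subsets: within a replicate, a smaller
    # training set (or panel) is a prefix of the larger one, so factorial
    # cells are paired and trend contrasts are not diluted by independent
    # subsampling noise.
    set.seed(derive_seed(config$seed, rep, stage = 999L))
    pool_n <- length(config$evaluation$training_generations) *
      config$demography$recent$n_parents_per_sex * 2L *
      config$demography$recent$n_per_family
    train_perm <- sample(pool_n)
    marker_perm <- sample(sim$spec$n_markers)
    stage <- 0L
    for (h2 in config$trait$h2) {
      for (tp in config$evaluation$tp_sizes) {
        for (panel in config$evaluation$panels) {
          stage <- stage + 1L
          row <- run_scenario(sim, h2, tp, panel, config,
                              seed = derive_seed(config$seed, rep,
                                                 stage = 1000L + stage),
                              train_rows = train_perm,
                              snp_cols = marker_perm)
          row$replicate <- rep
          cells[[length(cells) + 1L]] <- row
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  ld <- do.call(rbind, lds)
  summ <- summarise_cells(cells)
  top_panel <- max(config$evaluation$panels)
  gains <- summ[summ$panel == top_panel,
                c("h2", "tp_size", "gebv_gain_mean", "ebv_gain_mean")]
  names(gains) <- c("h2", "tp_size", "gain_gs", "gain_fs")
  gain_tab <- gain_rate_table(gains)
  dep_tab <- deployment_gain_table(gains)
  out <- structure(list(cells = cells, summary = summ, ld = ld,
                        gain_table = gain_tab, deployment_table = dep_tab,
                        config = config),
                   class = "gs_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

subset_markers <- function(pop, snp_cols) {
  midx <- marker_idx(pop$spec)
  keep_loci <- sort(c(midx[snp_cols], qtl_idx(pop$spec)))
  spec2 <- pop$spec
  spec2$loci <- pop$spec$loci[keep_loci, , drop = FALSE]
  spec2$n_markers <- length(snp_cols)
  new_pop(pop$H[, keep_loci, drop = FALSE], pop$meta, spec2)
}

summarise_cells <- function(cells) {
  key <- interaction(cells$h2, cells$tp_size, cells$panel, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  se <- function(v) stats::sd(v) / sqrt(length(v))
  data.frame(
    h2 = agg(cells$h2, function(x) x[1]),
    tp_size = as.integer(agg(cells$tp_size, function(x) x[1])),
    panel = as.integer(agg(cells$panel, function(x) x[1])),
    n = as.integer(agg(cells$h2, length)),
    gebv_acc_mean = agg(cells$gebv_accuracy, mean),
    gebv_acc_se = agg(cells$gebv_accuracy, se),
    ebv_acc_mean = agg(cells$ebv_accuracy, mean),
    ebv_acc_se = agg(cells$ebv_accuracy, se),
    gebv_gain_mean = agg(cells$gain_gs, mean),
    gebv_gain_se = agg(cells$gain_gs, se),
    ebv_gain_mean = agg(cells$gain_fs, mean),
    ebv_gain_se = agg(cells$gain_fs, se)
  )
}

#' @export
print.gs_experiment <- function(x, ...) {
  cat("Simulation experiment:", max(x$cells$replicate), "replicates,",
      nrow(x$summary), "factorial cells\n")
  print(x$summary[, c("h2", "tp_size", "panel", "gebv_acc_mean",
                      "ebv_acc_mean")], digits = 3)
  invisible(x)
}

write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(exp$cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$ld, file.path(out_dir, "ld.csv"), row.names = FALSE)
  utils::write.csv(exp$gain_table, file.path(out_dir, "gain_per_year.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$deployment_table,
                   file.path(out_dir, "deployment_gain.csv"),
                   row.names = FALSE)
  write_config(exp$config, file.path(out_dir, "config.yaml"))
  yaml::write_yaml(list(package = "conifergs",
                        version = as.character(utils::packageVersion("conifergs")),
                        date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                        seed = exp$config$seed,
                        replicates = exp$config$replicates),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
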