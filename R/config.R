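#' Default run configuration
#'
#' Two presets: `"full"` mirrors the study conditions (500-generation
#' historical burn-in, 4,900-marker panel by default, training populations of
#' 800-3,000 clones, 40,000 MCMC iterations), `"desk"` is a reduced setting
#' for interactive work and the test suite (panels up to 600 markers,
#' training populations up to 500 clones, 2,000 iterations).
#' The demography is identical in both presets — the burn-in is what creates
#' the linkage-disequilibrium regime under study and is cheap here — and the
#' demography, trait and selection settings are the study conditions
#' themselves, not tuning knobs.
#'
#' @param scale `"desk"` or `"full"`.
#' @return Nested configuration list of class `gs_config`.
#' @export
default_config <- function(scale = c("desk", "full")) {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  structure(list(
    scale = scale,
    seed = 1L,
    replicates = 10L,
    genome = list(
      n_markers = if (desk) 600L else 4900L,
      n_qtl = 350L,
      chromosome_length = 150,
      mutation_rate = 1e-5,
      min_initial_maf = 0.10
    ),
    demography = list(
      historical = list(n_generations = 500L,
                        n_female = 300L, n_male = 300L, size = 1000L),
      extended = list(n_generations = 10L, n_female = 100L, n_male = 100L,
                      size = 500L),
      recent = list(n_generations = 10L, n_parents_per_sex = 32L,
                    n_per_family = 15L, n_ramets = 4L)
    ),
    trait = list(h2 = c(0.2, 0.5), sigma2_a = 300, nonadd_prop = 0.15,
                 gamma_shape = 0.5, gamma_scale = 26),
    evaluation = list(
      training_generations = 4:8,
      tp_sizes = if (desk) c(133L, 167L, 333L, 500L) else
        c(800L, 1000L, 2000L, 3000L),
      panels = if (desk) c(150L, 300L, 600L) else
        c(600L, 1200L, 2500L, 4900L)
    ),
    bayesc = list(pi = 0.95, nu_a = 4.2, nu_e = 4,
                  n_iter = if (desk) 2000L else 40000L,
                  burn_in = if (desk) 200L else 4000L,
                  c_weight = 0.5, maf_min = 0.01),
    selection = list(n_selected = 9L),
    deployment = list(n_rotations = 8L, rotation_length = 25)
  ), class = "gs_config")
}

#' @export
print.gs_config <- function(x, ...) {
  cat("gs_config (", x$scale, " scale): ", x$replicates, " replicates, ",
      x$genome$n_markers, " markers, burn-in ",
      x$demography$historical$n_generations, " generations\n", sep = "")
  invisible(x)
}

#' Read / write a run configuration
#'
#' Configurations serialize to YAML; a run's resolved configuration plus its
#' seed reproduce its outputs exactly.
#'
#' @param path File path.
#' @return `read_config()` returns a `gs_config`; `write_config()` returns
#'   the path invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(if (!is.null(cfg$scale)) cfg$scale else "desk")
  structure(utils::modifyList(unclass(base), cfg), class = "gs_config")
}

#' @rdname read_config
#' @param config A `gs_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## Deterministic per-stage seed stream below 2^31.
derive_seed <- function(seed, rep, stage = 0L) {
  as.integer((as.numeric(seed) + 77003 * rep + 104729 * stage) %% 2147483629)
}
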