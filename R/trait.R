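#' Trait model: gamma QTL effects scaled to a target additive variance
#'
#' QTL allele-substitution effect magnitudes are drawn from a gamma
#' distribution (shape 0.50, scale 26) with random +/- signs, then rescaled by
#' a single constant so that the variance of true breeding values over the
#' reference population equals `sigma2_a` exactly. True breeding values are
#' centred on the reference-population mean, so the base population has mean
#' TBV zero. Non-additive (clone-level) variance is `nonadd_prop * sigma2_a`
#' and the residual variance is solved from the narrow-sense heritability
#' h2 = sigma2_a / (sigma2_a + sigma2_d + sigma2_e).
#'
#' @param pop Reference population (`gs_pop`) supplying QTL genotypes; the
#'   population entering the breeding phase is the natural choice.
#' @param h2 Narrow-sense heritability, in (0, 1); the simulated traits use 0.2
#'   (diameter growth) and 0.5 (wood density).
#' @param sigma2_a Target additive variance in squared trait units
#'   (default 300).
#' @param nonadd_prop Non-additive variance as a fraction of `sigma2_a`
#'   (default 0.15).
#' @param gamma_shape,gamma_scale Gamma parameters for effect magnitudes
#'   (defaults 0.50 and 26).
#' @param seed Optional integer seed.
#' @return A `trait_model` with the scaled per-QTL effects, the reference
#'   allele-count means used for centring, and the variance components.
#' @export
trait_model <- function(pop, h2, sigma2_a = 300, nonadd_prop = 0.15,
                        gamma_shape = 0.50, gamma_scale = 26, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pop, "gs_pop"))
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  sigma2_d <- nonadd_prop * sigma2_a
  sigma2_e <- sigma2_a / h2 - sigma2_a - sigma2_d
  if (sigma2_e <= 0)
    stop("residual variance is not positive: h2 too high for the given ",
         "non-additive fraction")
  G <- genotype_matrix(pop, "qtl")
  if (ncol(G) < 1) stop("genome has no QTL")
  raw <- stats::rgamma(ncol(G), shape = gamma_shape, scale = gamma_scale) *
    sample(c(-1, 1), ncol(G), replace = TRUE)
  tbv_raw <- as.numeric(G %*% raw)
  v <- stats::var(tbv_raw)
  if (v <= 0) stop("all QTL are monomorphic in the reference population; ",
                   "cannot scale effects to the target variance")
  effects <- raw * sqrt(sigma2_a / v)
  structure(
    list(
      qtl_effects = effects,
      ref_mean = colMeans(G),
      h2 = h2,
      sigma2_a = sigma2_a,
      sigma2_d = sigma2_d,
      sigma2_e = sigma2_e,
      gamma_shape = gamma_shape,
      gamma_scale = gamma_scale
    ),
    class = "trait_model"
  )
}

#' @export
print.trait_model <- function(x, ...) {
  cat("Trait: h2 =", x$h2, " sigma2_a =", x$sigma2_a,
      " sigma2_d =", x$sigma2_d, " sigma2_e =", round(x$sigma2_e, 3), "\n")
  invisible(x)
}

#' True breeding values
#'
#' TBV is the sum over QTL of the centred allele count times the
#' allele-substitution effect; centring uses the reference-population allele
#' means stored in the trait model, so the reference population has mean TBV
#' (numerically) zero.
#'
#' @param pop A `gs_pop`.
#' @param trait A [trait_model()].
#' @param center Set `FALSE` to use raw allele counts (zero-count convention).
#' @return Numeric vector, one TBV per individual, in trait units.
#' @export
true_breeding_value <- function(pop, trait, center = TRUE) {
  G <- genotype_matrix(pop, "qtl")
  stopifnot(ncol(G) == length(trait$qtl_effects))
  if (center) G <- sweep(G, 2L, trait$ref_mean)
  as.numeric(G %*% trait$qtl_effects)
}

#' Ramet-level phenotypes
#'
#' Each clone receives a non-additive deviation ~ N(0, sigma2_d) shared by all
#' of its ramets, and each ramet record an independent residual
#' ~ N(0, sigma2_e). The phenotype is exactly TBV + non-additive + residual.
#'
#' @param pop A `gs_pop` of clones.
#' @param trait A [trait_model()].
#' @param n_ramets Ramets (records) per clone, default 4.
#' @param seed Optional integer seed.
#' @return Data frame with one row per ramet: `clone_id`, `ramet_index`,
#'   `phenotype`, `tbv`, `nonadditive`, `residual`.
#' @export
simulate_phenotypes <- function(pop, trait, n_ramets = 4L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pop, "gs_pop"), inherits(trait, "trait_model"),
            n_ramets >= 1)
  n <- pop_size(pop)
  tbv <- true_breeding_value(pop, trait)
  d <- stats::rnorm(n, 0, sqrt(trait$sigma2_d))
  e <- stats::rnorm(n * n_ramets, 0, sqrt(trait$sigma2_e))
  out <- data.frame(
    clone_id = rep(pop$meta$id, each = n_ramets),
    ramet_index = rep(seq_len(n_ramets), times = n),
    tbv = rep(tbv, each = n_ramets),
    nonadditive = rep(d, each = n_ramets),
    residual = e
  )
  out$phenotype <- out$tbv + out$nonadditive + out$residual
  out[, c("clone_id", "ramet_index", "phenotype", "tbv", "nonadditive",
          "residual")]
}
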