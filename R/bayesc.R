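#' BayesC sampler configuration
#'
#' Defaults follow the simulated program's settings: prior null fraction pi = 0.95, prior
#' degrees of freedom 4.2 for the common SNP-effect variance, 40,000 MCMC
#' iterations of which 4,000 are discarded as burn-in, and c = 0.5 for the
#' fraction of genetic variance not captured by the markers in the Garrick
#' weighting formula.
#'
#' @param pi Prior fraction of SNPs with exactly zero effect.
#' @param nu_a Prior degrees of freedom of the common SNP-effect variance.
#' @param nu_e Prior degrees of freedom of the residual variance.
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Discarded iterations.
#' @param c_weight Fraction of genetic variance not explained by the SNPs,
#'   used in the de-regression weights.
#' @param s2_a Prior scale of the SNP-effect variance; `NULL` derives it at
#'   chain start from the expected per-SNP variance
#'   sigma2_a / ((1 - pi) * sum_j 2 p_j q_j).
#' @param fit_intercept Sample an overall mean (default TRUE).
#' @param update_sigma_a,update_sigma_e Sample the variance components
#'   (default TRUE); fixing them gives the conjugate single-site sampler used
#'   in closed-form checks.
#' @return List of class `bayesc_config`.
#' @export
bayesc_config <- function(pi = 0.95, nu_a = 4.2, nu_e = 4,
                          n_iter = 40000L, burn_in = 4000L, c_weight = 0.5,
                          s2_a = NULL, fit_intercept = TRUE,
                          update_sigma_a = TRUE, update_sigma_e = TRUE) {
  stopifnot(pi >= 0, pi < 1 || pi == 1, n_iter > burn_in, burn_in >= 0,
            c_weight >= 0)
  structure(list(pi = pi, nu_a = nu_a, nu_e = nu_e, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), c_weight = c_weight,
                 s2_a = s2_a, fit_intercept = fit_intercept,
                 update_sigma_a = update_sigma_a,
                 update_sigma_e = update_sigma_e),
            class = "bayesc_config")
}

#' De-regression weights for EBV response variables
#'
#' Garrick-style weight for clone i:
#' w_i = ((1 - h2)/h2) / (c + (1 - r_i^2)/r_i^2), where r_i is the accuracy of
#' the clone's EBV and c the fraction of genetic variance not explained by
#' the markers. In the sampler the residual variance of record i is scaled by
#' 1 / w_i. Records with r_i = 0 have infinite residual variance; they
#' receive weight NA with a warning and should be dropped.
#'
#' @param h2 Narrow-sense heritability in (0, 1).
#' @param r Vector of EBV accuracies in (0, 1].
#' @param c_weight Unexplained-variance fraction (default 0.5).
#' @return Numeric weight vector.
#' @export
deregression_weights <- function(h2, r, c_weight = 0.5) {
  stopifnot(h2 > 0, h2 < 1, all(r <= 1 + 1e-12))
  w <- ((1 - h2) / h2) / (c_weight + (1 - r^2) / r^2)
  if (any(r <= 0)) {
    warning(sum(r <= 0), " record(s) with zero accuracy excluded ",
            "(infinite residual variance)")
    w[r <= 0] <- NA_real_
  }
  w
}

#' Estimate SNP effects by BayesC
#'
#' Gibbs sampler for the mixture model in which each SNP has a zero effect
#' with prior probability pi and otherwise a normal effect with a common
#' variance (scaled inverse chi-square prior). The response is the vector of
#' clone EBVs; per-clone weights scale the residual variance. SNPs that are
#' monomorphic or below `maf_min` in the training genotypes are dropped
#' before sampling. Genotypes are centred on their training-set means, and
#' the same centring is reused at prediction time.
#'
#' @param X Training genotype matrix (clones x SNPs, allele counts 0/1/2),
#'   with column names identifying the SNPs.
#' @param y Response per clone (EBVs).
#' @param weights Optional per-clone weights (see [deregression_weights()]);
#'   default all 1.
#' @param config A [bayesc_config()].
#' @param sigma2_a Additive genetic variance of the trait, used to derive the
#'   prior scale of the SNP-effect variance (default 300).
#' @param maf_min Minimum training minor allele frequency for a SNP to enter
#'   the model (default 0.01).
#' @param seed Optional integer seed.
#' @return Object of class `bayesc_fit`: posterior-mean `snp_effects` and
#'   `inclusion_prob` (all input SNPs; dropped SNPs get effect 0 and
#'   inclusion NA), `mu`, variance means, the centring vector and the kept
#'   SNP names.
#' @export
run_bayesc <- function(X, y, weights = NULL, config = bayesc_config(),
                       sigma2_a = 300, maf_min = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 2)
  if (!all(is.finite(y))) stop("non-finite response values")
  if (is.null(colnames(X))) colnames(X) <- paste0("snp", seq_len(ncol(X)))
  if (is.null(weights)) weights <- rep(1, nrow(X))
  keep_rec <- !is.na(weights)
  X <- X[keep_rec, , drop = FALSE]
  y <- y[keep_rec]
  weights <- weights[keep_rec]
  p_all <- colMeans(X) / 2
  maf <- pmin(p_all, 1 - p_all)
  keep <- maf >= maf_min
  if (!any(keep)) stop("no polymorphic SNP passes the MAF filter")
  Xk <- X[, keep, drop = FALSE]
  p <- p_all[keep]
  center <- 2 * p
  Xc <- sweep(Xk, 2L, center)
  sum2pq <- sum(2 * p * (1 - p))
  exp_var <- if (config$pi < 1) sigma2_a / ((1 - config$pi) * sum2pq) else
    sigma2_a / sum2pq
  s2_a <- if (is.null(config$s2_a)) {
    if (config$nu_a > 2) exp_var * (config$nu_a - 2) / config$nu_a else exp_var
  } else config$s2_a
  # In fixed-variance mode the supplied prior scale IS the SNP-effect
  # variance; otherwise it is only the chain's starting value.
  if (!config$update_sigma_a && !is.null(config$s2_a)) exp_var <- config$s2_a
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  s2_e0 <- 0.5 * vy
  fit <- bayesc_gibbs_cpp(
    Xc, y, weights,
    pi = config$pi, nu_a = config$nu_a, s2_a = s2_a,
    nu_e = config$nu_e, s2_e = s2_e0,
    sigma2_a_init = exp_var, sigma2_e_init = s2_e0,
    n_iter = config$n_iter, burn_in = config$burn_in,
    fit_intercept = config$fit_intercept,
    update_sigma_a = config$update_sigma_a,
    update_sigma_e = config$update_sigma_e
  )
  effects <- numeric(length(keep))
  incl <- rep(NA_real_, length(keep))
  effects[keep] <- fit$snp_effects
  incl[keep] <- fit$inclusion_prob
  structure(
    list(snp_effects = stats::setNames(effects, colnames(X)),
         inclusion_prob = stats::setNames(incl, colnames(X)),
         kept = colnames(X)[keep],
         center = stats::setNames(center, colnames(X)[keep]),
         mu = fit$mu, sigma2_snp = fit$sigma2_snp, sigma2_e = fit$sigma2_e,
         config = config, method = "BayesC"),
    class = "bayesc_fit"
  )
}

#' @export
print.bayesc_fit <- function(x, ...) {
  cat("BayesC fit:", length(x$kept), "SNPs in model; mean inclusion",
      round(mean(x$inclusion_prob, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' Predict genomic breeding values
#'
#' GEBV = X a-hat over the SNPs kept in training, with the training-set
#' centring applied, so GEBVs are expressed as deviations from the training
#' mean.
#'
#' @param fit A [run_bayesc()] fit.
#' @param X_pred Prediction genotype matrix (clones x SNPs) whose columns
#'   cover the training SNPs (matched by name).
#' @return Numeric GEBV vector, one per prediction clone.
#' @export
predict_gebv <- function(fit, X_pred) {
  stopifnot(inherits(fit, "bayesc_fit"), is.matrix(X_pred))
  if (is.null(colnames(X_pred)))
    colnames(X_pred) <- paste0("snp", seq_len(ncol(X_pred)))
  miss <- setdiff(fit$kept, colnames(X_pred))
  if (length(miss) > 0)
    stop("prediction genotypes missing SNPs: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  Xp <- X_pred[, fit$kept, drop = FALSE]
  Xp <- sweep(Xp, 2L, fit$center)
  as.numeric(Xp %*% fit$snp_effects[fit$kept])
}

#' Realized accuracy of GEBVs
#'
#' Pearson correlation between GEBVs and true breeding values over the
#' prediction clones.
#'
#' @param gebv Predicted genomic breeding values.
#' @param tbv True breeding values.
#' @return Correlation (NA with a warning if degenerate).
#' @export
gebv_accuracy <- function(gebv, tbv) realized_accuracy(gebv, tbv)
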