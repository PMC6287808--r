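#' Linkage disequilibrium from haplotype frequencies
#'
#' D is the deviation of the observed haplotype frequency from the product of
#' allele frequencies, `D = P_AB - P_A * P_B`, and R2 the squared correlation
#' `D^2 / (P_A P_a P_B P_b)`. Undefined (NA, with `monomorphic = TRUE`) when
#' either locus is monomorphic.
#'
#' @param p_ab Observed frequency of the AB haplotype.
#' @param p_a,p_b Observed frequencies of alleles A and B.
#' @return List with `D`, `r2`, the frequency table and a `monomorphic` flag.
#' @export
ld_from_freqs <- function(p_ab, p_a, p_b) {
  stopifnot(p_ab >= 0, p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1,
            p_ab <= min(p_a, p_b) + 1e-12)
  D <- p_ab - p_a * p_b
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  mono <- denom <= 0
  list(D = D,
       r2 = if (mono) NA_real_ else D^2 / denom,
       P_AB = p_ab, P_A = p_a, P_a = 1 - p_a, P_B = p_b, P_b = 1 - p_b,
       monomorphic = mono)
}

#' Linkage disequilibrium between two loci from haplotypes
#'
#' @param h1,h2 0/1 allele indicator vectors over the same gametes.
#' @return As [ld_from_freqs()].
#' @export
ld_r2_pair <- function(h1, h2) {
  stopifnot(length(h1) == length(h2), length(h1) > 0)
  ld_from_freqs(mean(h1 == 1 & h2 == 1), mean(h1 == 1), mean(h2 == 1))
}

#' LD decay profile over a marker panel
#'
#' Computes R2 for all marker pairs closer than `max_distance` on the map,
#' bins them by distance, and summarises the mean R2 of physically adjacent
#' marker pairs (the panel-level LD summary used when comparing panels).
#' Monomorphic loci yield undefined R2 and are excluded from all averages
#' (counted in `n_excluded`). Empty bins are reported as NA, not zero.
#'
#' @param pop A `gs_pop`.
#' @param max_distance Largest pair distance in cM to tabulate (default 5).
#' @param bin_width Bin width in cM (default 0.1).
#' @return List: `profile` (data frame distance-bin midpoint, mean R2, number
#'   of pairs), `adjacent_mean_r2`, `n_pairs`, `n_excluded`.
#' @export
ld_decay_profile <- function(pop, max_distance = 5, bin_width = 0.1) {
  cols <- marker_idx(pop$spec)
  if (length(cols) < 2) stop("need at least 2 markers")
  pos <- pop$spec$loci$position[cols]
  H <- pop$H[, cols, drop = FALSE]
  sds <- apply(H, 2L, stats::sd)
  poly <- sds > 0
  n_excluded <- sum(!poly)
  r2_pair <- function(i, j) {
    if (!poly[i] || !poly[j]) return(NA_real_)
    suppressWarnings(stats::cor(H[, i], H[, j])^2)
  }
  ii <- integer(0); jj <- integer(0)
  M <- length(cols)
  for (i in seq_len(M - 1L)) {
    j <- i + 1L
    while (j <= M && pos[j] - pos[i] <= max_distance) {
      ii <- c(ii, i); jj <- c(jj, j); j <- j + 1L
    }
  }
  dist <- pos[jj] - pos[ii]
  r2 <- mapply(r2_pair, ii, jj)
  bins <- floor(dist / bin_width)
  mids <- (sort(unique(bins)) + 0.5) * bin_width
  prof <- data.frame(
    distance = mids,
    mean_r2 = as.numeric(tapply(r2, bins, mean, na.rm = TRUE)),
    n_pairs = as.integer(tapply(!is.na(r2), bins, sum))
  )
  prof$mean_r2[prof$n_pairs == 0L] <- NA_real_
  adj <- mapply(r2_pair, seq_len(M - 1L), seq(2L, M))
  list(profile = prof,
       adjacent_mean_r2 = mean(adj, na.rm = TRUE),
       n_pairs = length(r2),
       n_excluded = n_excluded)
}

#' Plot an LD decay profile
#'
#' @param ld Output of [ld_decay_profile()].
#' @param ... Passed to [plot()].
#' @export
plot_ld_decay <- function(ld, ...) {
  graphics::plot(ld$profile$distance, ld$profile$mean_r2, type = "b",
                 xlab = "distance (cM)", ylab = expression(mean ~ R^2), ...)
  invisible(ld)
}
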