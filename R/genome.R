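#' Genome specification for the forward simulator
#'
#' Defines a single chromosome carrying a neutral SNP marker panel and a set
#' of bi-allelic QTL. Marker and QTL positions are drawn uniformly on the map
#' (continuous positions, so the two sets are disjoint) using the current RNG
#' state; call [set.seed()] beforehand for reproducibility.
#'
#' @param n_markers Number of neutral SNP markers on the chromosome. The simulated
#'   design uses panels of 600, 1200, 2500, 4900 and 8000 markers on one
#'   chromosome, standing in for 7K-90K genome-wide panels.
#' @param n_qtl Number of bi-allelic QTL controlling the trait (default 350).
#' @param chromosome_length Map length in centimorgans (default 150).
#' @param mutation_rate Recurrent (allele-flip) mutation probability per locus
#'   per gamete, active in the historical and extended phases only
#'   (default 1e-5).
#' @param min_initial_maf Lower bound on the minor allele frequency of panel
#'   markers at the start of the breeding (recent) phase (default 0.10); see
#'   [finalize_panel()].
#' @param candidate_factor Surplus factor of candidate loci simulated through
#'   the burn-in, from which the final panel is drawn at the start of the
#'   breeding phase by [finalize_panel()] (default 3).
#' @return An object of class `genome_spec`: a list with the map, the locus
#'   table (`position` in cM, `type` = "marker"/"qtl") and the parameters.
#' @export
genome_spec <- function(n_markers = 600L, n_qtl = 350L,
                        chromosome_length = 150, mutation_rate = 1e-5,
                        min_initial_maf = 0.10, candidate_factor = 3) {
  stopifnot(n_markers >= 1, n_qtl >= 0, chromosome_length > 0,
            mutation_rate >= 0, min_initial_maf >= 0, min_initial_maf < 0.5,
            candidate_factor >= 1)
  nm <- ceiling(n_markers * candidate_factor)
  nq <- ceiling(n_qtl * candidate_factor)
  pos_m <- stats::runif(nm, 0, chromosome_length)
  pos_q <- if (nq > 0) stats::runif(nq, 0, chromosome_length) else numeric(0)
  loci <- data.frame(
    position = c(pos_m, pos_q),
    type = rep(c("marker", "qtl"), c(nm, nq)),
    stringsAsFactors = FALSE
  )
  loci <- loci[order(loci$position), , drop = FALSE]
  rownames(loci) <- NULL
  structure(
    list(
      chromosome_length = chromosome_length,
      n_markers = as.integer(n_markers),
      n_qtl = as.integer(n_qtl),
      loci = loci,
      mutation_rate = mutation_rate,
      min_initial_maf = min_initial_maf,
      finalized = FALSE
    ),
    class = "genome_spec"
  )
}

#' Fix the marker panel and QTL set at the start of the breeding phase
#'
#' Draws the final SNP panel among candidate marker loci whose minor allele
#' frequency in the current population exceeds `min_initial_maf`, and the
#' final QTL set among segregating candidate QTL. This mirrors how panels are
#' assembled in practice (and in forward simulators): loci are chosen to be
#' informative in the population entering the breeding program, after
#' burn-in drift has run its course. The handful of panel markers that later
#' drift below the usable range during the breeding phase are removed by the
#' MAF filter of [run_bayesc()].
#'
#' @param pop A `gs_pop` whose spec still carries candidate loci.
#' @return The population restricted to the selected loci, with a finalized
#'   spec (`n_markers` markers, `n_qtl` QTL).
#' @export
finalize_panel <- function(pop) {
  spec <- pop$spec
  if (isTRUE(spec$finalized)) return(pop)
  p <- allele_freq(pop)
  maf <- pmin(p, 1 - p)
  mi <- marker_idx(spec)
  qi <- qtl_idx(spec)
  m_ok <- mi[maf[mi] > spec$min_initial_maf]
  q_ok <- qi[p[qi] > 0 & p[qi] < 1]
  if (length(m_ok) < spec$n_markers)
    stop("only ", length(m_ok), " candidate markers exceed MAF ",
         spec$min_initial_maf, "; need ", spec$n_markers,
         " (increase candidate_factor)")
  if (length(q_ok) < spec$n_qtl)
    stop("only ", length(q_ok), " candidate QTL segregate; need ", spec$n_qtl)
  keep <- sort(c(sample(m_ok, spec$n_markers), sample(q_ok, spec$n_qtl)))
  spec2 <- spec
  spec2$loci <- spec$loci[keep, , drop = FALSE]
  rownames(spec2$loci) <- NULL
  spec2$finalized <- TRUE
  new_pop(pop$H[, keep, drop = FALSE], pop$meta, spec2)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome: 1 chromosome,", x$chromosome_length, "cM;",
      x$n_markers, "markers,", x$n_qtl, "QTL;",
      "mutation rate", format(x$mutation_rate), "\n")
  invisible(x)
}

marker_idx <- function(spec) which(spec$loci$type == "marker")
qtl_idx <- function(spec) which(spec$loci$type == "qtl")

#' Founder population in linkage equilibrium
#'
#' Draws founder haplotypes locus by locus at allele frequencies uniform on
#' (min_initial_maf, 1 - min_initial_maf), i.e. every marker satisfies the
#' initial minor-allele-frequency bound and loci start in linkage
#' equilibrium. Linkage disequilibrium then accrues through the historical
#' burn-in (mutation-drift equilibrium design).
#'
#' @param spec A [genome_spec()].
#' @param n Number of founder individuals.
#' @return A `gs_pop` object: haplotype matrix `H` (2n rows, one pair of rows
#'   per individual; columns are loci in map order), and `meta` with
#'   id/sire/dam/sex/generation.
#' @export
founder_population <- function(spec, n) {
  stopifnot(inherits(spec, "genome_spec"), n >= 2)
  L <- nrow(spec$loci)
  freq <- stats::runif(L, spec$min_initial_maf, 1 - spec$min_initial_maf)
  H <- matrix(stats::rbinom(2L * n * L, 1L, rep(freq, each = 2L * n)),
              nrow = 2L * n, ncol = L)
  new_pop(H, meta = data.frame(
    id = seq_len(n),
    sire = 0L, dam = 0L,
    sex = sample(c("F", "M"), n, replace = TRUE),
    generation = "founder",
    stringsAsFactors = FALSE
  ), spec = spec)
}

new_pop <- function(H, meta, spec) {
  stopifnot(nrow(H) == 2L * nrow(meta))
  structure(list(H = H, meta = meta, spec = spec), class = "gs_pop")
}

#' @export
print.gs_pop <- function(x, ...) {
  cat("Population:", nrow(x$meta), "individuals (",
    unique(x$meta$generation)[1], "...),", ncol(x$H), "loci\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `gs_pop`.
#' @return Integer count.
#' @export
pop_size <- function(pop) nrow(pop$meta)

#' Genotype matrix (allele counts)
#'
#' @param pop A `gs_pop`.
#' @param loci `"marker"`, `"qtl"` or `"all"`, or an integer vector of locus
#'   columns.
#' @return Integer matrix, individuals by loci, entries 0/1/2 counting the
#'   "1" allele.
#' @export
genotype_matrix <- function(pop, loci = "all") {
  cols <- resolve_loci(pop$spec, loci)
  H <- pop$H[, cols, drop = FALSE]
  n <- pop_size(pop)
  H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
}

resolve_loci <- function(spec, loci) {
  if (is.character(loci)) {
    switch(loci,
      all = seq_len(nrow(spec$loci)),
      marker = marker_idx(spec),
      qtl = qtl_idx(spec),
      stop("unknown locus set: ", loci)
    )
  } else {
    as.integer(loci)
  }
}

#' Allele frequencies of the "1" allele
#' @inheritParams genotype_matrix
#' @return Numeric vector of frequencies in [0, 1].
#' @export
allele_freq <- function(pop, loci = "all") {
  cols <- resolve_loci(pop$spec, loci)
  colMeans(pop$H[, cols, drop = FALSE])
}

#' Expected heterozygosity (2pq averaged over loci)
#' @inheritParams genotype_matrix
#' @return Mean of 2p(1-p) over the requested loci.
#' @export
expected_heterozygosity <- function(pop, loci = "marker") {
  p <- allele_freq(pop, loci)
  mean(2 * p * (1 - p))
}
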