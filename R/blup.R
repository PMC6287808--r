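#' Additive (numerator) relationship matrix
#'
#' Tabular-method recursion over the full pedigree, including inbreeding
#' accumulation on the diagonal. Parents must precede their offspring in the
#' pedigree; unknown parents are coded 0 or NA.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam` (ids, not row
#'   numbers; 0/NA for founders).
#' @return Symmetric relationship matrix with founder diagonal 1, dimnames
#'   set to the ids.
#' @export
build_A <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  known_s <- !is.na(ped$sire) & ped$sire != 0
  known_d <- !is.na(ped$dam) & ped$dam != 0
  if (any(known_s & is.na(s)) || any(known_d & is.na(d)))
    stop("pedigree not closed: parent id missing from the pedigree")
  s[!known_s] <- 0L; d[!known_d] <- 0L
  if (any(s >= seq_along(s) & s > 0) || any(d >= seq_along(d) & d > 0))
    stop("pedigree is cyclic or unordered: parents must precede offspring")
  A <- tabular_a_cpp(as.integer(s), as.integer(d))
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Solve Henderson's mixed-model equations
#'
#' Fits the individual-tree model y = mu + Z_a a + Z_d d + e with
#' var(a) = A sigma2_a, var(d) = I sigma2_d over clones (ramets of a clone
#' share one non-additive effect, distinct clones are uncorrelated) and
#' var(e) = I sigma2_e. Variance components are taken as known (the
#' simulation truth). EBV accuracy is computed from the prediction error
#' variance: r_i = sqrt(1 - PEV_i / (A_ii sigma2_a)).
#'
#' @param y Phenotype vector, one entry per record (ramet).
#' @param clone Integer index into the rows of `A` giving the clone (genetic
#'   individual) of each record. Individuals in `A` without records (e.g.
#'   parents) still receive EBVs through the relationship matrix.
#' @param A Additive relationship matrix (see [build_A()]).
#' @param sigma2_a,sigma2_d,sigma2_e Known variance components.
#' @return List of class `gs_eval`: `mu`, `ebv` (length `nrow(A)`),
#'   `accuracy` (PEV-based, same length), `d` (clone effects for clones with
#'   records) and `method = "BLUP"`.
#' @export
solve_mme <- function(y, clone, A, sigma2_a, sigma2_d, sigma2_e) {
  n <- length(y)
  stopifnot(length(clone) == n, nrow(A) == ncol(A),
            all(clone >= 1), all(clone <= nrow(A)),
            sigma2_a > 0, sigma2_d > 0, sigma2_e > 0)
  q <- nrow(A)
  dlev <- sort(unique(clone))
  nd <- length(dlev)
  Za <- matrix(0, n, q); Za[cbind(seq_len(n), clone)] <- 1
  Zd <- matrix(0, n, nd); Zd[cbind(seq_len(n), match(clone, dlev))] <- 1
  W <- cbind(1, Za, Zd)
  M <- crossprod(W)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("relationship matrix is singular (duplicated genotypes?)"))
  ia <- 1L + seq_len(q)
  id <- 1L + q + seq_len(nd)
  M[ia, ia] <- M[ia, ia] + Ainv * (sigma2_e / sigma2_a)
  M[id, id] <- M[id, id] + diag(nd) * (sigma2_e / sigma2_d)
  rhs <- crossprod(W, y)
  Cinv <- tryCatch(solve(M), error = function(e)
    stop("mixed-model equations are singular: mean, additive and ",
         "non-additive terms are confounded for this design"))
  sol <- Cinv %*% rhs
  pev <- diag(Cinv)[ia] * sigma2_e
  acc <- sqrt(pmax(0, pmin(1, 1 - pev / (diag(A) * sigma2_a))))
  structure(list(mu = sol[1L], ebv = as.numeric(sol[ia]),
                 accuracy = acc, d = as.numeric(sol[id]),
                 clone_levels = dlev, method = "BLUP"),
            class = "gs_eval")
}

## Fast path used by the recent-phase evaluator: animal model on clone means
## with known heterogeneous residual variance R_i = sigma2_d + sigma2_e / m_i
## (exact absorption of the clone effect for balanced records, D = I).
## idx maps each mean to a row of A; individuals without records get EBVs via A.
blup_animal_means <- function(ybar, idx, m, A, sigma2_a, sigma2_d, sigma2_e) {
  q <- nrow(A)
  n <- length(ybar)
  stopifnot(length(idx) == n, length(m) == n)
  Rinv <- 1 / (sigma2_d + sigma2_e / m)
  Ainv <- solve(A)
  # coefficient matrix for (mu, a)
  M <- matrix(0, q + 1L, q + 1L)
  M[1L, 1L] <- sum(Rinv)
  zr <- numeric(q); zr[idx] <- Rinv
  M[1L, -1L] <- zr
  M[-1L, 1L] <- zr
  ZRZ <- matrix(0, q, q); diag(ZRZ)[idx] <- Rinv
  M[-1L, -1L] <- ZRZ + Ainv / sigma2_a
  rhs <- numeric(q + 1L)
  rhs[1L] <- sum(Rinv * ybar)
  ra <- numeric(q); ra[idx] <- Rinv * ybar
  rhs[-1L] <- ra
  Cinv <- solve(M)
  sol <- Cinv %*% rhs
  pev <- diag(Cinv)[-1L]  # already on the variance scale (R is explicit)
  acc <- sqrt(pmax(0, pmin(1, 1 - pev / (diag(A) * sigma2_a))))
  list(mu = sol[1L], ebv = as.numeric(sol[-1L]), accuracy = acc)
}

#' Realized accuracy of an evaluation
#'
#' Pearson correlation between predicted and true breeding values over a set
#' of clones (the simulation makes the truth available). This is the realized
#' counterpart of the PEV-based accuracy and the quantity reported when
#' selection methods are compared.
#'
#' @param ebv Predicted breeding values (EBV or GEBV).
#' @param tbv True breeding values for the same clones.
#' @return Correlation, or NA with a warning if the predictions have zero
#'   variance.
#' @export
realized_accuracy <- function(ebv, tbv) {
  stopifnot(length(ebv) == length(tbv), length(ebv) >= 3)
  if (stats::sd(ebv) == 0 || stats::sd(tbv) == 0) {
    warning("zero-variance input: realized accuracy undefined")
    return(NA_real_)
  }
  stats::cor(ebv, tbv)
}
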