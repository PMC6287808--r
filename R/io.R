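#' Export genotypes as VCF
#'
#' Writes the marker (or all) loci of a population as a minimal VCF 4.2 file
#' on one pseudo-chromosome, with cM positions scaled to integer base pairs
#' at 1 cM = 1,000,000 bp. Haplotypes are written phased (`0|1`).
#'
#' @param pop A `gs_pop`.
#' @param path Output file path (plain text, uncompressed).
#' @param loci Locus set as in [genotype_matrix()].
#' @return The path, invisibly.
#' @export
write_vcf <- function(pop, path, loci = "marker") {
  cols <- resolve_loci(pop$spec, loci)
  pos_bp <- as.integer(round(pop$spec$loci$position[cols] * 1e6)) + 1L
  ids <- paste0(substr(pop$spec$loci$type[cols], 1, 1), cols)
  n <- pop_size(pop)
  a1 <- t(pop$H[seq(1L, 2L * n, 2L), cols, drop = FALSE])
  a2 <- t(pop$H[seq(2L, 2L * n, 2L), cols, drop = FALSE])
  gt <- matrix(paste0(a1, "|", a2), nrow = length(cols))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=conifergs",
    sprintf("##contig=<ID=1,length=%d>",
            as.integer(pop$spec$chromosome_length * 1e6) + 2L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("ind", pop$meta$id)), collapse = "\t")
  )
  body <- paste("1", pos_bp, ids, "A", "G", ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export genotypes in PLINK text format
#'
#' Writes `<prefix>.ped` / `<prefix>.map`. Alleles are coded A (0) and G (1);
#' map positions carry both the cM coordinate and the scaled bp coordinate.
#'
#' @param pop A `gs_pop`.
#' @param prefix Output path prefix.
#' @param loci Locus set as in [genotype_matrix()].
#' @return The prefix, invisibly.
#' @export
write_plink <- function(pop, prefix, loci = "marker") {
  cols <- resolve_loci(pop$spec, loci)
  n <- pop_size(pop)
  code <- c("A", "G")
  a1 <- pop$H[seq(1L, 2L * n, 2L), cols, drop = FALSE] + 1L
  a2 <- pop$H[seq(2L, 2L * n, 2L), cols, drop = FALSE] + 1L
  geno <- matrix("", n, 2L * length(cols))
  geno[, seq(1L, ncol(geno), 2L)] <- code[a1]
  geno[, seq(2L, ncol(geno), 2L)] <- code[a2]
  ped <- cbind("FAM1", paste0("ind", pop$meta$id),
               ifelse(pop$meta$sire == 0, "0", paste0("ind", pop$meta$sire)),
               ifelse(pop$meta$dam == 0, "0", paste0("ind", pop$meta$dam)),
               ifelse(pop$meta$sex == "M", "1", "2"), "-9", geno)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(chr = 1L,
                    id = paste0(substr(pop$spec$loci$type[cols], 1, 1), cols),
                    cm = pop$spec$loci$position[cols],
                    bp = as.integer(round(pop$spec$loci$position[cols] * 1e6)) + 1L)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Export a pedigree as CSV
#'
#' One row per individual (or per ramet when `n_ramets` is given) with
#' columns id, sire, dam, sex, generation, clone_id, ramet_index.
#'
#' @param pop A `gs_pop`.
#' @param path Output path.
#' @param n_ramets If given, expand each clone to this many ramet rows.
#' @return The path, invisibly.
#' @export
write_pedigree_csv <- function(pop, path, n_ramets = NULL) {
  m <- pop$meta
  out <- data.frame(id = m$id, sire = m$sire, dam = m$dam, sex = m$sex,
                    generation = m$generation, clone_id = m$id,
                    ramet_index = 1L)
  if (!is.null(n_ramets) && n_ramets > 1) {
    out <- out[rep(seq_len(nrow(out)), each = n_ramets), ]
    out$ramet_index <- rep(seq_len(n_ramets), times = nrow(m))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export phenotype records as CSV
#'
#' @param phenotypes Data frame from [simulate_phenotypes()].
#' @param path Output path.
#' @param blind Drop the simulation-truth columns (tbv, nonadditive,
#'   residual) so downstream evaluation cannot peek at the truth.
#' @return The path, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path, blind = FALSE) {
  cols <- if (blind) c("clone_id", "ramet_index", "phenotype") else
    names(phenotypes)
  utils::write.csv(phenotypes[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Export estimated SNP effects as CSV
#'
#' @param fit A [run_bayesc()] fit.
#' @param path Output path.
#' @param positions Optional named cM positions for the SNPs.
#' @return The path, invisibly.
#' @export
write_snp_effects <- function(fit, path, positions = NULL) {
  snp <- names(fit$snp_effects)
  out <- data.frame(snp_id = snp,
                    position_cM = if (is.null(positions)) NA_real_ else
                      as.numeric(positions[snp]),
                    posterior_mean_effect = as.numeric(fit$snp_effects),
                    inclusion_prob = as.numeric(fit$inclusion_prob))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export per-clone breeding values as CSV
#'
#' @param ids Clone ids.
#' @param ebv Estimated (or genomic) breeding values.
#' @param accuracy Per-clone accuracies (PEV-based for BLUP).
#' @param method `"BLUP"` or `"BayesC"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ebv_csv <- function(ids, ebv, accuracy, method, path) {
  utils::write.csv(data.frame(clone_id = ids, ebv = ebv,
                              accuracy_r = accuracy, method = method),
                   path, row.names = FALSE)
  invisible(path)
}
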