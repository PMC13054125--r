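#' Read a BLUPF90-style SNP file
#'
#' Each line is an animal id, whitespace, and a contiguous string of genotype
#' codes: 0/1/2 copies of the counted allele, 5 = missing.  All rows must have
#' the same number of markers.
#'
#' @param path file path.
#' @return object of class `geno`: list with `ids` and an integer `codes`
#'   matrix (animals x markers, rownames = ids).
#' @export
read_snp_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop2("empty SNP file: ", path)
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  codes_str <- trimws(sub("^\\S+\\s+", "", lines))
  widths <- nchar(codes_str)
  if (length(unique(widths)) != 1L)
    stop2("ragged SNP rows: line ", which(widths != widths[1])[1],
          " has ", widths[which(widths != widths[1])[1]], " codes, expected ",
          widths[1])
  bad <- grepl("[^0125]", codes_str)
  if (any(bad))
    stop2("invalid genotype code on line ", which(bad)[1],
          " (only 0/1/2/5 allowed)")
  m <- widths[1]
  codes <- matrix(
    as.integer(unlist(strsplit(codes_str, "", fixed = TRUE), use.names = FALSE)),
    nrow = length(lines), ncol = m, byrow = TRUE,
    dimnames = list(parts, NULL))
  new_geno(parts, codes)
}

new_geno <- function(ids, codes) {
  stopifnot(nrow(codes) == length(ids))
  rownames(codes) <- ids
  structure(list(ids = as.character(ids), codes = codes), class = "geno")
}

#' Write a BLUPF90-style SNP file
#' @param g a `geno` object.
#' @param path output path.
#' @export
write_snp_file <- function(g, path) {
  writeLines(paste(g$ids, apply(g$codes, 1, paste0, collapse = "")), path)
  invisible(path)
}

#' @export
print.geno <- function(x, ...) {
  cat("Genotypes:", length(x$ids), "animals x", ncol(x$codes), "markers\n")
  invisible(x)
}

# per-marker allele frequency of the counted allele, missing excluded
allele_freq <- function(codes) {
  miss <- codes == 5L
  cnt <- colSums(codes * !miss)
  nonmiss <- colSums(!miss)
  ifelse(nonmiss > 0, cnt / (2 * nonmiss), NA_real_)
}

#' SNP quality control
#'
#' Removes markers failing, in this order: call rate below `call_rate`; minor
#' allele frequency below `maf`; monomorphic markers; deviation of observed
#' from expected (Hardy-Weinberg) heterozygote frequency above `hwe_dev`.
#' The removal counts attribute each marker to the first rule it fails.
#'
#' @param g a `geno` object.
#' @param call_rate,maf,hwe_dev thresholds; defaults 0.90, 0.05, 0.15.
#' @return list with `geno` (filtered `geno` object) and `report` (class
#'   `qc_report`): per-rule removal counts, retained marker indices and the
#'   thresholds used.
#' @export
snp_qc <- function(g, call_rate = 0.90, maf = 0.05, hwe_dev = 0.15) {
  codes <- g$codes
  if (!ncol(codes)) stop2("empty genotype matrix")
  miss <- codes == 5L
  cr <- colMeans(!miss)
  p <- allele_freq(codes)
  mafv <- pmin(p, 1 - p)
  het_obs <- colSums((codes == 1L)) / pmax(colSums(!miss), 1L)
  het_exp <- 2 * p * (1 - p)
  fail_cr <- cr < call_rate
  fail_maf <- !fail_cr & (is.na(mafv) | mafv < maf)
  fail_mono <- !fail_cr & !fail_maf & (p == 0 | p == 1)
  fail_hwe <- !fail_cr & !fail_maf & !fail_mono &
    abs(het_obs - het_exp) > hwe_dev
  keep <- !(fail_cr | fail_maf | fail_mono | fail_hwe)
  if (!any(keep)) stop2("all markers removed by QC")
  report <- structure(list(
    n_input = ncol(codes),
    removed_call_rate = sum(fail_cr),
    removed_maf = sum(fail_maf),
    removed_monomorphic = sum(fail_mono),
    removed_het_deviation = sum(fail_hwe),
    n_retained = sum(keep),
    retained = which(keep),
    thresholds = list(call_rate = call_rate, maf = maf, hwe_dev = hwe_dev)),
    class = "qc_report")
  list(geno = new_geno(g$ids, codes[, keep, drop = FALSE]), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC:", x$n_input, "markers in,", x$n_retained, "retained\n")
  cat(sprintf("  removed: call rate %d, MAF %d, monomorphic %d, het deviation %d\n",
              x$removed_call_rate, x$removed_maf, x$removed_monomorphic,
              x$removed_het_deviation))
  invisible(x)
}

#' Genomic relationship matrix (VanRaden method I)
#'
#' `G = ZZ' / (2 sum_j p_j (1 - p_j))` with `Z = M - 2P`, using observed
#' (pooled, across-breed) allele frequencies.  Missing codes are imputed to
#' `2 p_j` before centering, which leaves them with zero contribution.
#'
#' @param g a `geno` object (after QC; monomorphic markers are an error).
#' @return dense symmetric matrix with rownames/colnames the animal ids.
#' @export
g_matrix <- function(g) {
  codes <- g$codes
  p <- allele_freq(codes)
  if (any(p == 0 | p == 1))
    stop2("monomorphic markers present; run snp_qc() first")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop2("zero denominator in VanRaden G")
  M <- codes
  miss <- M == 5L
  if (any(miss)) M[miss] <- rep(2 * p, each = nrow(M))[miss]
  Z <- M - matrix(2 * p, nrow(M), ncol(M), byrow = TRUE)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(g$ids, g$ids)
  G
}

#' Blend G with the pedigree relationship matrix of genotyped animals
#'
#' `(1 - beta) G + beta A22`, the PREGSF90-style default that guarantees an
#' invertible genomic matrix.
#'
#' @param G,A22 conformable symmetric matrices over the same animals.
#' @param beta blending weight in `[0, 1)`; default 0.05.
#' @export
blend_g <- function(G, A22, beta = 0.05) {
  if (!is.numeric(beta) || beta < 0 || beta >= 1)
    stop2("beta must be in [0, 1)")
  if (!all(dim(G) == dim(A22))) stop2("G and A22 are not conformable")
  (1 - beta) * G + beta * A22
}

chol_or_null <- function(M) tryCatch(chol(M), error = function(e) NULL)

#' Single-step H-inverse
#'
#' Combined pedigree-genomic relationship inverse:
#' `H^-1 = A^-1 + [0 0; 0 tau G^-1 - omega A22^-1]`, with the second block on
#' the genotyped animals.  With an empty genotyped set this is exactly `A^-1`.
#'
#' @param ainv sparse `A^-1` over all animals (from [a_inverse()]).
#' @param G genomic relationship matrix of the genotyped animals (blended).
#' @param A22 pedigree relationship matrix of the genotyped animals.
#' @param genotyped_idx integer pedigree indices (rows of `ainv`) of the
#'   genotyped animals, in the row order of `G`.
#' @param tau,omega scaling factors of the genomic and pedigree corrections;
#'   defaults 1.0 and 1.0.
#' @return object of class `hstructure`: list with the sparse `Hinv`, its
#'   log-determinant counterpart `logdet_H`, and the inputs.
#' @export
h_inverse <- function(ainv, G = NULL, A22 = NULL, genotyped_idx = integer(),
                      tau = 1, omega = 1) {
  ainv <- forceSymmetric2(ainv)
  if (length(genotyped_idx) == 0L) {
    Hinv <- ainv
  } else {
    if (is.null(G) || is.null(A22))
      stop2("G and A22 required when genotyped animals are present")
    if (nrow(G) != length(genotyped_idx) || nrow(A22) != length(genotyped_idx))
      stop2("G/A22 dimensions do not match the genotyped index")
    Rg <- chol_or_null(G)
    if (is.null(Rg))
      stop2("G is singular; blend it with A22 first (see blend_g)")
    Ra <- chol_or_null(A22)
    if (is.null(Ra)) stop2("A22 is singular")
    block <- tau * chol2inv(Rg) - omega * chol2inv(Ra)
    n <- nrow(ainv)
    ng <- length(genotyped_idx)
    Bi <- Matrix::sparseMatrix(
      i = rep(genotyped_idx, times = ng),
      j = rep(genotyped_idx, each = ng),
      x = as.numeric(block), dims = c(n, n))
    Hinv <- forceSymmetric2(ainv + Bi)
  }
  logdet_H <- -sparse_logdet(Hinv)
  structure(list(Hinv = Hinv, logdet_K = logdet_H,
                 genotyped_idx = genotyped_idx, tau = tau, omega = omega),
            class = "hstructure")
}

#' Assemble the single-step structure from raw pieces
#'
#' Convenience wrapper: QC, VanRaden G, blending, A22 and H-inverse in one
#' call.
#'
#' @param ped a `ped` object.
#' @param g a `geno` object whose ids are a subset of the pedigree.
#' @param beta blending weight passed to [blend_g()].
#' @param tau,omega passed to [h_inverse()].
#' @param qc apply [snp_qc()] first (default TRUE).
#' @return an `hstructure` object (see [h_inverse()]); the QC report is
#'   attached as element `qc_report`.
#' @export
h_structure <- function(ped, g, beta = 0.05, tau = 1, omega = 1, qc = TRUE) {
  rep_out <- NULL
  if (qc) {
    q <- snp_qc(g)
    g <- q$geno
    rep_out <- q$report
  }
  idx <- ped_index(ped, g$ids)
  G <- g_matrix(g)
  A22 <- a22_matrix(ped, g$ids)
  Gb <- blend_g(G, A22, beta)
  hs <- h_inverse(a_inverse(ped), Gb, A22, idx, tau = tau, omega = omega)
  hs$qc_report <- rep_out
  hs
}
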