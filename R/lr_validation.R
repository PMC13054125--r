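#' Forward-validation split
#'
#' Selects the validation cohort: animals born in the last `last_k_years`
#' birth years that are phenotyped, have no progeny in the pedigree (young
#' selection candidates) and, if `require_genotype`, are genotyped.  The
#' partial dataset is the phenotype table with the validation animals'
#' records removed; validation animals keep their pedigree (and genotypes)
#' in the partial fit.
#'
#' @param phen phenotype table.
#' @param ped a `ped` object.
#' @param last_k_years how many recent birth years form the cohort
#'   (default 2).
#' @param require_genotype restrict to genotyped animals.
#' @param genotyped_ids ids of genotyped animals (needed when
#'   `require_genotype = TRUE`).
#' @return object of class `validation_split`: `validation_ids`,
#'   `phen_whole`, `phen_partial`, `years`.
#' @export
forward_split <- function(phen, ped, last_k_years = 2,
                          require_genotype = FALSE, genotyped_ids = NULL) {
  if (!length(phen$birth_year)) stop2("phenotypes lack birth years")
  cutoff <- max(phen$birth_year) - last_k_years + 1
  tab <- ped$tab
  has_progeny <- tab$id %in% c(tab$sire, tab$dam)
  cand <- phen$id[phen$birth_year >= cutoff]
  cand <- setdiff(cand, tab$id[has_progeny])
  if (require_genotype) {
    if (is.null(genotyped_ids))
      stop2("require_genotype = TRUE but no genotyped_ids given")
    cand <- intersect(cand, genotyped_ids)
  }
  if (!length(cand)) stop2("empty validation set")
  partial <- phen[!(phen$id %in% cand), , drop = FALSE]
  if (!nrow(partial))
    stop2("partial dataset has no phenotypes left")
  structure(list(validation_ids = cand, phen_whole = phen,
                 phen_partial = partial,
                 years = sort(unique(phen$birth_year[phen$birth_year >= cutoff]))),
            class = "validation_split")
}

#' @export
print.validation_split <- function(x, ...) {
  cat("Forward split: ", length(x$validation_ids), " validation animals (",
      paste(range(x$years), collapse = "-"), "), ",
      nrow(x$phen_partial), "/", nrow(x$phen_whole),
      " phenotypes in the partial set\n", sep = "")
  invisible(x)
}

#' LR-method prediction accuracy
#'
#' `rho = sqrt( cov(u_w, u_p) / ((1 - F_bar) sigma_u2) )`: the covariance
#' between whole-data and partial-data predictions of the validation
#' animals, scaled by their expected genetic variance.  A negative
#' covariance (accuracy undefined) is mapped to 0 with a warning.
#'
#' @param u_p,u_w partial- and whole-data predicted breeding values, aligned
#'   on the validation animals.
#' @param F_bar mean inbreeding coefficient of the validation animals.
#' @param sigma_u2 additive genetic variance of the trait.
#' @export
lr_accuracy <- function(u_p, u_w, F_bar, sigma_u2) {
  if (!length(u_p) || length(u_p) != length(u_w))
    stop2("u_p and u_w must be non-empty and aligned")
  if (sigma_u2 <= 0) stop2("sigma_u2 must be positive")
  if (F_bar < 0 || F_bar >= 1) stop2("F_bar must be in [0, 1)")
  cv <- cov(u_w, u_p)
  if (cv < 0) {
    warning("negative cov(u_w, u_p); accuracy set to 0", call. = FALSE)
    return(0)
  }
  sqrt(cv / ((1 - F_bar) * sigma_u2))
}

#' LR-method dispersion
#'
#' Slope of the regression of whole-data on partial-data predictions:
#' `b = cov(u_w, u_p) / var(u_p)`.  1 in the absence of
#' inflation/deflation.
#'
#' @inheritParams lr_accuracy
#' @export
lr_dispersion <- function(u_p, u_w) {
  if (!length(u_p) || length(u_p) != length(u_w))
    stop2("u_p and u_w must be non-empty and aligned")
  vp <- var(u_p)
  if (vp <= 0) stop2("var(u_p) is zero")
  cov(u_w, u_p) / vp
}

#' LR-method bias
#'
#' `mu = (mean(u_p) - mean(u_w)) / sqrt(sigma_u2)`: the mean difference
#' between partial and whole predictions, standardised by the additive
#' genetic standard deviation.  0 when unbiased.  Set
#' `standardise = "variance"` to divide by `sigma_u2` itself (the literal
#' printed denominator) instead of its square root.
#'
#' @inheritParams lr_accuracy
#' @param standardise `"sd"` (default) or `"variance"`.
#' @export
lr_bias <- function(u_p, u_w, sigma_u2, standardise = c("sd", "variance")) {
  standardise <- match.arg(standardise)
  if (sigma_u2 <= 0) stop2("sigma_u2 must be positive")
  den <- if (standardise == "sd") sqrt(sigma_u2) else sigma_u2
  (mean(u_p) - mean(u_w)) / den
}

#' All three LR statistics at once
#'
#' @inheritParams lr_accuracy
#' @return object of class `lr_stats`: `rho`, `b`, `mu`, `n_validation`.
#' @export
lr_stats <- function(u_p, u_w, F_bar, sigma_u2) {
  structure(list(rho = lr_accuracy(u_p, u_w, F_bar, sigma_u2),
                 b = lr_dispersion(u_p, u_w),
                 mu = lr_bias(u_p, u_w, sigma_u2),
                 n_validation = length(u_p)), class = "lr_stats")
}

#' @export
print.lr_stats <- function(x, ...) {
  cat(sprintf("LR validation (n = %d): rho = %.3f, b = %.3f, mu = %.3f\n",
              x$n_validation, x$rho, x$b, x$mu))
  invisible(x)
}

#' Run a forward validation for one model / variance-component source
#'
#' Fits the whole and the partial systems at the (externally supplied, fixed)
#' variance components and computes accuracy, dispersion and bias over the
#' validation animals.  `sigma_u2` of the accuracy and bias denominators is
#' the supplied component (by convention, the whole-data estimate of the
#' model being validated); `F_bar` is the mean inbreeding of the validation
#' animals.
#'
#' @param split a `validation_split`.
#' @param spec a `model_spec`.
#' @param ped,cov,comp population objects as in [build_design()].
#' @param vc a `var_fit` or list with `sigma_u2`, `sigma_e2`.
#' @param relmat optional `hstructure` for `relationship = "H"`.
#' @param ... passed to [build_design()].
#' @return an `lr_stats` object; the two solution sets are attached as
#'   attributes `u_p` and `u_w`.
#' @export
run_validation <- function(split, spec, ped, cov = NULL, comp = NULL, vc,
                           relmat = NULL, ...) {
  sys_w <- build_design(split$phen_whole, spec, cov, comp, ped,
                        relmat = relmat, ...)
  sys_p <- build_design(split$phen_partial, spec, cov, comp, ped,
                        relmat = relmat, ...)
  sol_w <- solve_blup(sys_w, vc)
  sol_p <- solve_blup(sys_p, vc)
  vidx <- ped_index(ped, split$validation_ids)
  u_w <- sol_w$u[vidx]
  u_p <- sol_p$u[vidx]
  F_bar <- mean(ped$tab$F[vidx])
  su2 <- if (is.list(vc)) vc$sigma_u2 else vc[1]
  out <- lr_stats(u_p, u_w, F_bar, su2)
  attr(out, "u_p") <- u_p
  attr(out, "u_w") <- u_w
  attr(out, "F_bar") <- F_bar
  out
}
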