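#' Akaike information criterion
#'
#' `AIC = -2 lnL + 2 p`, with `p` the number of estimated (variance)
#' parameters.
#'
#' @param lnL log-likelihood.
#' @param p number of estimated parameters (>= 1).
#' @export
aic <- function(lnL, p) {
  if (p < 1) stop2("p must be >= 1")
  -2 * lnL + 2 * p
}

#' Bayesian information criterion
#'
#' `BIC = -2 lnL + log(n) p`; the BIC-AIC gap is therefore
#' `(log(n) - 2) p` exactly.
#'
#' @param lnL log-likelihood.
#' @param p number of estimated parameters.
#' @param n sample size (>= 2).
#' @export
bic <- function(lnL, p, n) {
  if (p < 1) stop2("p must be >= 1")
  if (n < 2) stop2("n must be >= 2")
  -2 * lnL + log(n) * p
}

#' Likelihood-ratio test between a less and a more parameterised model
#'
#' `LRT = -2 (lnL_less - lnL_more)`, referred to a chi-squared upper tail
#' with `df` degrees of freedom.  A negative statistic (possible when REML
#' likelihoods are compared across different fixed-effect structures) is
#' reported as computed, with a warning, and its p-value set to 1.
#'
#' @param lnL_less,lnL_more log-likelihoods of the nested pair.
#' @param df degrees of freedom (>= 1).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(lnL_less, lnL_more, df) {
  if (df < 1) stop2("df must be >= 1")
  stat <- -2 * (lnL_less - lnL_more)
  if (stat < 0)
    warning("negative LRT statistic: the less parameterised model has the ",
            "higher (restricted) likelihood", call. = FALSE)
  list(statistic = stat, df = df,
       p_value = if (stat < 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Burnham-Anderson support labels from AIC differences
#'
#' Relative to the minimum AIC: a difference of at most 2 indicates
#' substantial support; between 4 and 7, considerably less; above 10,
#' essentially none.  The guideline leaves the bands (2,4) and (7,10]
#' unnamed; those are labelled `intermediate`.
#'
#' @param aics numeric vector of AIC values (>= 2 models).
#' @return data.frame with `aic`, `delta` and `support`.
#' @export
aic_support <- function(aics) {
  if (length(aics) < 2) stop2("need at least two models")
  delta <- aics - min(aics)
  support <- ifelse(delta <= 2, "substantial",
             ifelse(delta >= 4 & delta <= 7, "considerably_less",
             ifelse(delta > 10, "essentially_none", "intermediate")))
  data.frame(aic = aics, delta = delta, support = support,
             row.names = names(aics))
}

#' Compare a set of fitted models
#'
#' Builds the comparison table (lnL, p, n, AIC, BIC, delta-AIC, support) and
#' all pairwise likelihood-ratio tests against the most parameterised model
#' of the set.  `p` counts the estimated variance components (2 per
#' single-trait fit); `n` is the record count of each fit.  REML
#' likelihoods of models with different fixed effects are not strictly
#' comparable; this mirrors standard animal-breeding practice and is the
#' caveat behind occasional negative LRT statistics.
#'
#' @param fits named list of `var_fit` objects.
#' @param lrt_df degrees of freedom convention for the pairwise tests:
#'   `"total"` (default) uses the difference in total estimated parameters
#'   (fixed + variance), or supply a fixed integer.
#' @return object of class `model_comparison`: list with `table` and `lrt`.
#' @export
compare_models <- function(fits, lrt_df = "total") {
  stopifnot(length(fits) >= 1)
  nm <- names(fits) %||% paste0("fit", seq_along(fits))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(model = nm[i], lnL = f$loglik, p = f$p_var, n = f$n,
               sigma_u2 = f$sigma_u2, sigma_e2 = f$sigma_e2, h2 = f$h2,
               aic = aic(f$loglik, f$p_var),
               bic = bic(f$loglik, f$p_var, f$n))
  }))
  sup <- aic_support(setNames(tab$aic, tab$model))
  tab$delta_aic <- sup$delta
  tab$support <- sup$support
  lrt_tab <- NULL
  if (length(fits) >= 2) {
    full <- which.max(vapply(fits, function(f) f$p_fixed + f$p_var, 0))
    others <- setdiff(seq_along(fits), full)
    lrt_tab <- do.call(rbind, lapply(others, function(i) {
      df <- if (identical(lrt_df, "total"))
        max(1L, (fits[[full]]$p_fixed + fits[[full]]$p_var) -
              (fits[[i]]$p_fixed + fits[[i]]$p_var))
      else as.integer(lrt_df)
      r <- suppressWarnings(lrt(fits[[i]]$loglik, fits[[full]]$loglik, df))
      data.frame(comparison = paste(nm[i], "vs", nm[full]),
                 statistic = r$statistic, df = r$df, p_value = r$p_value)
    }))
  }
  structure(list(table = tab, lrt = lrt_tab), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 6)
  if (!is.null(x$lrt)) {
    cat("\nLikelihood-ratio tests:\n")
    print(x$lrt, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
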