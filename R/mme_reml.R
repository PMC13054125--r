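#' Model specification for the five fixed-effect parameterisations
#'
#' All models share contemporary group, embryo transfer, age at ultrasound
#' and cow age at calving (linear + quadratic) as fixed effects, and the
#' direct additive genetic effect and residual as random effects.  The five
#' rosters then add:
#'
#' * `M1`: nothing else
#' * `M2`: breed-type fractions (NABC) + combined heterosis
#' * `M3`: NABC + combined heterosis + combined recombination
#' * `M4`: NABC + combined recombination + specific heterosis (6 pairs)
#' * `M5`: NABC + specific heterosis + specific recombination (6 + 6 pairs)
#'
#' @param model one of `"M1"` ... `"M5"`.
#' @param relationship `"A"` (pedigree BLUP) or `"H"` (single-step ssGBLUP).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model = c("M1", "M2", "M3", "M4", "M5"),
                       relationship = c("A", "H")) {
  model <- match.arg(model)
  relationship <- match.arg(relationship)
  structure(list(
    model = model,
    relationship = relationship,
    nabc = model != "M1",
    het = model %in% c("M2", "M3"),
    rec = model %in% c("M3", "M4"),
    specific_het = model %in% c("M4", "M5"),
    specific_rec = model == "M5"), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  on <- c("CG", "ET", "age_us", "cow_age", "cow_age^2",
          if (x$nabc) "NABC", if (x$het) "Het", if (x$rec) "Recomb",
          if (x$specific_het) "Specific_het", if (x$specific_rec) "Specific_rec")
  cat(x$model, "(", x$relationship, "):", paste(on, collapse = " + "), "\n")
  invisible(x)
}

#' Build the mixed-model system for one model
#'
#' Applies the contemporary-group filter (groups with fewer than `min_cg`
#' records are excluded), builds the fixed-effect matrix `X` (CG dummies
#' absorb the intercept; embryo transfer as a 2-level class; age at
#' ultrasound as 30-day-bin classes by default or as a linear covariate; cow
#' age as centred linear + quadratic covariates; breed fractions as 3 of the
#' 4 types - type A, the largest, is dropped to avoid collinearity with the
#' CG block), the record-to-animal incidence `Z`, and attaches the
#' relationship inverse (`A^-1` computed from the pedigree, or a supplied
#' single-step `hstructure`).
#'
#' Columns with zero variance after the CG filter (effects with no
#' information in the data) are dropped with a message; any remaining rank
#' deficiency is an error listing the aliased columns.
#'
#' @param phen phenotype data.frame (`id`, `y`, `cg`, `et`, `age_us`,
#'   `cow_age`, `birth_year`).
#' @param spec a `model_spec`.
#' @param cov covariate table ([covariate_table()]); may be `NULL` for M1.
#' @param comp a `breed_comp`; may be `NULL` for M1.
#' @param ped a `ped` object.
#' @param relmat optional `hstructure` (required when
#'   `spec$relationship == "H"`); when `NULL` with `"A"`, `A^-1` is built
#'   from the pedigree.
#' @param age_us_mode `"class"` (default) or `"covariate"`.
#' @param min_cg minimum records per contemporary group (default 10).
#' @param on_alias what to do with genuinely aliased (rank-deficient)
#'   columns: `"error"` (default) or `"drop"` them with a message, the
#'   BLUPF90-style behaviour used by the experiment pipeline.
#' @return object of class `mme_system` with the pieces needed by
#'   [reml_loglik()], [ai_reml()] and [solve_blup()].
#' @export
build_design <- function(phen, spec, cov = NULL, comp = NULL, ped,
                         relmat = NULL, age_us_mode = c("class", "covariate"),
                         min_cg = 10, on_alias = c("error", "drop")) {
  age_us_mode <- match.arg(age_us_mode)
  on_alias <- match.arg(on_alias)
  stopifnot(inherits(spec, "model_spec"), inherits(ped, "ped"))
  keep_cg <- names(which(table(phen$cg) >= min_cg))
  phen <- phen[phen$cg %in% keep_cg, , drop = FALSE]
  if (!nrow(phen)) stop2("no records left after the contemporary-group filter")
  ridx <- ped_index(ped, phen$id)

  df <- data.frame(cg = factor(phen$cg), et = factor(phen$et))
  terms <- c("0", "cg")
  if (nlevels(df$et) > 1) terms <- c(terms, "et")
  if (age_us_mode == "class") {
    brk <- seq(floor(min(phen$age_us) / 30) * 30,
               ceiling((max(phen$age_us) + 1) / 30) * 30, by = 30)
    df$age_us <- droplevels(cut(phen$age_us, brk, right = FALSE))
    if (nlevels(df$age_us) > 1) terms <- c(terms, "age_us")
  } else {
    df$age_us <- phen$age_us - mean(phen$age_us)
    terms <- c(terms, "age_us")
  }
  ca <- phen$cow_age - mean(phen$cow_age)
  df$cow_age <- ca
  df$cow_age2 <- ca^2
  terms <- c(terms, "cow_age", "cow_age2")
  if (spec$nabc || spec$het || spec$rec || spec$specific_het ||
      spec$specific_rec) {
    if (is.null(cov)) stop2("covariate table required for model ", spec$model)
    ci <- match(phen$id, cov$id)
    if (anyNA(ci))
      stop2("no covariate row for animal '", phen$id[which(is.na(ci))[1]], "'")
    covp <- cov[ci, , drop = FALSE]
  }
  if (spec$nabc) {
    if (is.null(comp)) stop2("breed composition required for model ", spec$model)
    bi <- match(phen$id, comp$id)
    if (anyNA(bi))
      stop2("no breed composition for animal '",
            phen$id[which(is.na(bi))[1]], "'")
    # 3 of 4 fractions; drop A (the largest) against the CG/intercept block
    df$frac_N <- comp$alpha[bi, "N"]
    df$frac_B <- comp$alpha[bi, "B"]
    df$frac_C <- comp$alpha[bi, "C"]
    terms <- c(terms, "frac_N", "frac_B", "frac_C")
  }
  if (spec$het) { df$het <- covp$het; terms <- c(terms, "het") }
  if (spec$rec) { df$rec <- covp$rec; terms <- c(terms, "rec") }
  if (spec$specific_het) {
    for (lb in PAIR_LABELS) df[[paste0("het_", lb)]] <- covp[[paste0("het_", lb)]]
    terms <- c(terms, paste0("het_", PAIR_LABELS))
  }
  if (spec$specific_rec) {
    for (lb in PAIR_LABELS) df[[paste0("rec_", lb)]] <- covp[[paste0("rec_", lb)]]
    terms <- c(terms, paste0("rec_", PAIR_LABELS))
  }
  X <- model.matrix(stats::as.formula(paste("~", paste(terms, collapse = "+"))),
                    df)
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  # the first CG dummy block absorbs the intercept; keep its first column
  if (any(const)) {
    drop_cols <- colnames(X)[const]
    X <- X[, !const, drop = FALSE]
    message("dropping constant model column(s): ",
            paste(drop_cols, collapse = ", "))
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    if (on_alias == "error")
      stop2("fixed-effect matrix is rank deficient; aliased column(s): ",
            paste(aliased, collapse = ", "))
    message("dropping aliased model column(s): ",
            paste(aliased, collapse = ", "))
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
  }

  n <- nrow(phen)
  q <- ped$n
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = ridx, x = 1, dims = c(n, q))
  if (spec$relationship == "H") {
    if (!inherits(relmat, "hstructure"))
      stop2("relationship 'H' requires an hstructure (see h_structure())")
    Kinv <- relmat$Hinv
    logdet_K <- relmat$logdet_K
  } else if (!is.null(relmat)) {
    Kinv <- forceSymmetric2(relmat$Hinv %||% relmat)
    logdet_K <- relmat$logdet_K %||% -sparse_logdet(Kinv)
  } else {
    Kinv <- a_inverse(ped)
    logdet_K <- a_logdet(ped)
  }
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  W <- cbind(Xs, Z)
  y <- phen$y
  structure(list(
    y = y, X = X, Z = Z, W = W,
    WtW = forceSymmetric2(Matrix::crossprod(W)),
    Wty = as.numeric(Matrix::crossprod(W, y)),
    yty = sum(y^2),
    Kinv = Kinv, logdet_K = logdet_K,
    logdet_XtX = as.numeric(determinant(crossprod(X),
                                        logarithm = TRUE)$modulus),
    n = n, p = ncol(X), q = q,
    ids = phen$id, record_idx = ridx,
    animal_ids = ped$tab$id,
    spec = spec,
    .cache = new.env(parent = emptyenv())), class = "mme_system")
}

#' @export
print.mme_system <- function(x, ...) {
  cat("MME system:", x$n, "records,", x$p, "fixed-effect columns,",
      x$q, "animals (", x$spec$model, "/", x$spec$relationship, ")\n")
  invisible(x)
}

# coefficient matrix of the MME at theta = (sigma_u2, sigma_e2)
mme_c <- function(sys, theta) {
  n <- nrow(sys$WtW)
  q <- sys$q
  pad <- n - q
  Kblk <- Matrix::bdiag(Matrix::Diagonal(pad, 0), sys$Kinv / theta[1])
  forceSymmetric2(sys$WtW / theta[2] + Kblk)
}

mme_chol <- function(sys, C) {
  # reuse the symbolic analysis across evaluations of the same system
  ch <- sys$.cache$pattern
  if (!is.null(ch)) {
    out <- tryCatch(Matrix::update(ch, C), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  sys$.cache$pattern <- ch
  ch
}

# factorise, solve for (beta, u) and return the REML pieces
mme_solve_pieces <- function(sys, theta) {
  C <- mme_c(sys, theta)
  ch <- mme_chol(sys, C)
  rhs <- sys$Wty / theta[2]
  sol <- as.numeric(Matrix::solve(ch, rhs))
  ypy <- (sys$yty - sum(sys$Wty * sol)) / theta[2]
  list(chol = ch, sol = sol, ypy = ypy,
       logdet_C = as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                                 sqrt = FALSE)$modulus))
}

#' REML log-likelihood of a single-trait animal model
#'
#' Error-contrast (restricted) log-likelihood, up to the `-n/2 log(2 pi)`
#' constant, evaluated through the mixed-model-equation factorisation:
#' `-2 lnL = n log(se2) + q log(su2) + log|K| + log|C| - log|X'X| + y'Py`.
#' The `+ log|X'X|/2` term makes the value invariant to invertible
#' reparameterisation of the fixed effects.  With `restricted = FALSE` the
#' (profile-free) ML log-likelihood is returned instead.
#'
#' @param theta numeric `(sigma_u2, sigma_e2)`, both strictly positive.
#' @param sys an `mme_system`.
#' @param restricted REML (default) or ML.
#' @return scalar log-likelihood.
#' @export
reml_loglik <- function(theta, sys, restricted = TRUE) {
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop2("theta must be strictly positive")
  pieces <- mme_solve_pieces(sys, theta)
  if (restricted) {
    -0.5 * (sys$n * log(theta[2]) + sys$q * log(theta[1]) + sys$logdet_K +
            pieces$logdet_C - sys$logdet_XtX + pieces$ypy)
  } else {
    # |V| = |R| |G| |Z'R^-1 Z + K^-1/su2|
    Cuu <- forceSymmetric2(Matrix::crossprod(sys$Z) / theta[2] +
                           sys$Kinv / theta[1])
    logdet_Cuu <- sparse_logdet(Cuu)
    -0.5 * (sys$n * log(theta[2]) + sys$q * log(theta[1]) + sys$logdet_K +
            logdet_Cuu + pieces$ypy)
  }
}

# tr(K^-1 C^uu)/su2^2-free trace via the exact identity
# d log|C| / d gamma = tr(C^uu K^-1), gamma = 1/su2, by central difference.
trace_kinv_cuu <- function(sys, theta, rel_h = 1e-4) {
  gamma <- 1 / theta[1]
  h <- rel_h * gamma
  ld <- function(g) {
    C <- mme_c(sys, c(1 / g, theta[2]))
    ch <- mme_chol(sys, C)
    as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
  }
  (ld(gamma + h) - ld(gamma - h)) / (2 * h)
}

#' Estimate variance components by AI-REML
#'
#' Average-information REML for the two-component animal model.  Each
#' iteration computes the exact AI matrix from the standard quadratic forms
#' (`AI_ij = f_i' P f_j / 2` with `f_u = Z u_hat / su2`, `f_e = e_hat / se2`)
#' and the REML score (gradient); the update is `theta + AI^-1 score` with
#' step halving, falling back to an EM step whenever the AI update leaves the
#' parameter space.  Convergence: relative parameter change < `tol_theta` or
#' log-likelihood change < `tol_lnl` (at most `max_iter` iterations).
#' Standard errors come from the inverse AI matrix at the optimum; the
#' heritability standard error uses the delta method.
#'
#' Non-convergence and boundary estimates (`sigma_u2` pinned at 1e-10) are
#' flagged on the returned object, not raised as errors.
#'
#' @param sys an `mme_system`.
#' @param init optional starting `(sigma_u2, sigma_e2)`; default
#'   `(0.3, 0.7) * var(y)`.
#' @param max_iter,tol_theta,tol_lnl convergence controls.
#' @param verbose print the iteration trace.
#' @return object of class `var_fit`: estimates, standard errors, `vcov` of
#'   the variance parameters, `h2` and `h2_se`, `loglik`, `iterations`,
#'   `converged`, `boundary`, the iteration `trace`, and the metadata
#'   (`n`, `p_fixed`, `p_var = 2`) used by [aic()] and [bic()].
#' @export
ai_reml <- function(sys, init = NULL, max_iter = 200, tol_theta = 1e-8,
                    tol_lnl = 1e-9, verbose = FALSE) {
  vy <- var(sys$y)
  theta <- init %||% c(0.3 * vy, 0.7 * vy)
  lb <- c(1e-10, 1e-12 * vy)
  ll <- reml_loglik(theta, sys)
  trace <- matrix(c(theta, ll), 1, 3,
                  dimnames = list(NULL, c("sigma_u2", "sigma_e2", "loglik")))
  converged <- FALSE
  boundary <- FALSE
  AI <- NULL
  iter <- 0
  pinned <- 0L

  score_fd <- function(theta) {
    s <- numeric(2)
    for (k in 1:2) {
      h <- 1e-5 * theta[k]
      tp <- theta; tp[k] <- theta[k] + h
      tm <- theta; tm[k] <- max(theta[k] - h, lb[k] / 2)
      s[k] <- (reml_loglik(tp, sys) - reml_loglik(tm, sys)) /
        (tp[k] - tm[k])
    }
    s
  }

  ai_matrix <- function(theta, pieces) {
    sol <- pieces$sol
    u <- sol[(sys$p + 1):length(sol)]
    fitted <- as.numeric(sys$W %*% sol)
    ehat <- sys$y - fitted
    f_u <- as.numeric(sys$Z %*% u) / theta[1]
    f_e <- ehat / theta[2]
    Fm <- cbind(f_u, f_e)
    rhsF <- Matrix::crossprod(sys$W, Fm) / theta[2]
    solF <- as.matrix(Matrix::solve(pieces$chol, rhsF))
    PF <- (Fm - as.matrix(sys$W %*% solF)) / theta[2]
    0.5 * crossprod(Fm, PF)
  }

  em_step <- function(theta, pieces) {
    sol <- pieces$sol
    u <- sol[(sys$p + 1):length(sol)]
    uKu <- as.numeric(Matrix::crossprod(u, sys$Kinv %*% u))
    tr <- trace_kinv_cuu(sys, theta)
    su2 <- (uKu + tr) / sys$q
    se2 <- (sys$yty - sum(sys$Wty * sol)) / (sys$n - sys$p)
    c(su2, se2)
  }

  for (iter in seq_len(max_iter)) {
    pieces <- mme_solve_pieces(sys, theta)
    s <- score_fd(theta)
    AI <- ai_matrix(theta, pieces)
    step <- tryCatch(solve(AI, s), error = function(e) NULL)
    used_em <- FALSE
    theta_new <- NULL
    if (!is.null(step)) {
      cand <- theta + step
      halvings <- 0L
      while (halvings < 12L) {
        if (all(cand > lb)) {
          ll_cand <- reml_loglik(cand, sys)
          if (is.finite(ll_cand) && ll_cand >= ll - 1e-6) {
            theta_new <- cand
            ll_new <- ll_cand
            break
          }
        }
        step <- step / 2
        cand <- theta + step
        halvings <- halvings + 1L
      }
    }
    if (is.null(theta_new)) {
      theta_new <- pmax(em_step(theta, pieces), lb)
      ll_new <- reml_loglik(theta_new, sys)
      used_em <- TRUE
    }
    if (verbose)
      cat(sprintf("iter %3d  su2 %.6g  se2 %.6g  lnL %.6f%s\n", iter,
                  theta_new[1], theta_new[2], ll_new,
                  if (used_em) "  [EM]" else ""))
    trace <- rbind(trace, c(theta_new, ll_new))
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-12))
    dll <- abs(ll_new - ll)
    if (theta_new[1] <= lb[1] * 1.01) {
      pinned <- pinned + 1L
      if (pinned >= 2L) {
        theta <- theta_new; ll <- ll_new
        boundary <- TRUE
        converged <- TRUE
        break
      }
    }
    theta <- theta_new; ll <- ll_new
    if (rel < tol_theta || dll < tol_lnl) {
      converged <- TRUE
      break
    }
  }
  # a fit that collapsed to a numerically negligible heritability is a
  # boundary solution even if the lnL stopping rule fired first
  if (theta[1] <= lb[1] * 10 || theta[1] / sum(theta) < 1e-4) boundary <- TRUE

  pieces <- mme_solve_pieces(sys, theta)
  AI <- ai_matrix(theta, pieces)
  vcov <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vcov), 0))
  h2 <- theta[1] / sum(theta)
  g <- c(theta[2], -theta[1]) / sum(theta)^2
  h2_se <- if (all(is.finite(vcov))) sqrt(max(drop(t(g) %*% vcov %*% g), 0))
           else NA_real_
  structure(list(
    sigma_u2 = theta[1], sigma_e2 = theta[2],
    se_u2 = se[1], se_e2 = se[2], vcov = vcov,
    h2 = h2, h2_se = h2_se,
    loglik = ll, iterations = iter, converged = converged,
    boundary = boundary, trace = trace,
    n = sys$n, p_fixed = sys$p, p_var = 2L,
    model = sys$spec$model, relationship = sys$spec$relationship),
    class = "var_fit")
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("%s/%s: sigma_u2 = %.4f (%.4f), sigma_e2 = %.4f (%.4f), h2 = %.3f (%.3f)\n",
              x$model, x$relationship, x$sigma_u2, x$se_u2, x$sigma_e2,
              x$se_e2, x$h2, x$h2_se))
  cat(sprintf("  lnL = %.4f after %d iterations (converged: %s%s)\n",
              x$loglik, x$iterations, x$converged,
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' Solve the mixed-model equations for fixed effects and breeding values
#'
#' BLUP/ssGBLUP solutions at given variance components: fixed-effect
#' estimates and (G)EBVs for every animal in the pedigree index, phenotyped
#' or not.
#'
#' @param sys an `mme_system`.
#' @param vf a `var_fit`, or a list/vector with `sigma_u2` and `sigma_e2`.
#' @return object of class `blup_solutions`: `beta` (named), `u` (named by
#'   animal id), `theta`.
#' @export
solve_blup <- function(sys, vf) {
  theta <- if (inherits(vf, "var_fit") || is.list(vf))
    c(vf$sigma_u2, vf$sigma_e2) else as.numeric(vf)
  if (any(theta <= 0)) stop2("variance components must be positive")
  pieces <- mme_solve_pieces(sys, theta)
  sol <- pieces$sol
  beta <- setNames(sol[seq_len(sys$p)], colnames(sys$X))
  u <- setNames(sol[(sys$p + 1):length(sol)], sys$animal_ids)
  structure(list(beta = beta, u = u, theta = theta,
                 lambda = theta[2] / theta[1]), class = "blup_solutions")
}

#' @export
print.blup_solutions <- function(x, ...) {
  cat("BLUP solutions:", length(x$beta), "fixed effects,", length(x$u),
      "breeding values (lambda =", signif(x$lambda, 4), ")\n")
  invisible(x)
}

#' Heritability with a delta-method standard error
#'
#' `h2 = sigma_u2 / (sigma_u2 + sigma_e2)`.  Given a fitted `var_fit` the
#' standard error is propagated from the inverse-AI covariance of the
#' variance estimates; given two plain variances the SE is `NA` unless a
#' 2x2 covariance matrix is supplied.
#'
#' @param x a `var_fit`, or `sigma_u2` (numeric).
#' @param sigma_e2 residual variance when `x` is numeric.
#' @param vcov optional 2x2 covariance of `(sigma_u2, sigma_e2)`.
#' @return list with `h2` and `se`.
#' @export
heritability <- function(x, sigma_e2 = NULL, vcov = NULL) {
  if (inherits(x, "var_fit")) return(list(h2 = x$h2, se = x$h2_se))
  su2 <- as.numeric(x)
  se2 <- as.numeric(sigma_e2)
  tot <- su2 + se2
  if (tot <= 0) stop2("variance components sum to zero")
  h2 <- su2 / tot
  se <- NA_real_
  if (!is.null(vcov)) {
    g <- c(se2, -su2) / tot^2
    se <- sqrt(max(drop(t(g) %*% vcov %*% g), 0))
  }
  list(h2 = h2, se = se)
}
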