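# Independent oracles and small fixture builders shared across test files.

# Tabular relationship matrix, written independently of the package
# implementation (scalar recursion instead of vectorised rows).
oracle_tabular_A <- function(sire_idx, dam_idx) {
  n <- length(sire_idx)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire_idx[i]; d <- dam_idx[i]
    if (i > 1) for (j in seq_len(i - 1)) {
      a <- 0
      if (s > 0) a <- a + 0.5 * A[j, s]
      if (d > 0) a <- a + 0.5 * A[j, d]
      A[i, j] <- a
      A[j, i] <- a
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  A
}

# Dense error-contrast REML log-likelihood:
# -1/2 (log|V| + log|X'V^-1X| - log|X'X| + y'Py), V = su2 ZKZ' + se2 I.
oracle_dense_reml <- function(theta, y, X, Z, K) {
  n <- length(y)
  V <- theta[1] * Z %*% K %*% t(Z) + theta[2] * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  ypy <- drop(t(r) %*% Vi %*% y)
  -0.5 * (as.numeric(determinant(V, logarithm = TRUE)$modulus) +
          as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) -
          as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus) +
          ypy)
}

# Dense GLS / selection-index BLUP: u_hat = su2 K Z' V^-1 (y - X beta_gls)
oracle_dense_blup <- function(theta, y, X, Z, K) {
  n <- length(y)
  V <- theta[1] * Z %*% K %*% t(Z) + theta[2] * diag(n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- theta[1] * K %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = drop(beta), u = drop(u))
}

# Direct single-step H (partitioned construction), then inverted:
# H22 = G; H12 = A12 A22^-1 G; H11 = A11 + A12 A22^-1 (G - A22) A22^-1 A21.
oracle_direct_H <- function(A, G, gidx) {
  nidx <- setdiff(seq_len(nrow(A)), gidx)
  A11 <- A[nidx, nidx]; A12 <- A[nidx, gidx]; A22 <- A[gidx, gidx]
  A22i <- solve(A22)
  H <- matrix(0, nrow(A), nrow(A))
  H[gidx, gidx] <- G
  H[nidx, gidx] <- A12 %*% A22i %*% G
  H[gidx, nidx] <- t(H[nidx, gidx])
  H[nidx, nidx] <- A11 + A12 %*% A22i %*% (G - A22) %*% A22i %*% t(A12)
  H
}

# Grid search plus Nelder-Mead refinement of the packaged REML surface
# (independent maximisation route for the AI-REML oracle check).
oracle_reml_argmax <- function(sys, lower = 0.02, upper = 4) {
  vy <- var(sys$y)
  grid <- expand.grid(su2 = vy * seq(lower, upper, length.out = 12),
                      se2 = vy * seq(lower, upper, length.out = 12))
  ll <- apply(grid, 1, function(th) reml_loglik(as.numeric(th), sys))
  start <- as.numeric(grid[which.max(ll), ])
  opt <- optim(log(start), function(lt) -reml_loglik(exp(lt), sys),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  exp(opt$par)
}

# Reparameterise the fixed effects of an mme_system by X -> X T.
reparam_X <- function(sys, Tm) {
  X2 <- sys$X %*% Tm
  Xs <- Matrix::Matrix(X2, sparse = TRUE)
  W <- cbind(Xs, sys$Z)
  sys$X <- X2
  sys$W <- W
  sys$WtW <- as(Matrix::forceSymmetric(Matrix::crossprod(W)), "CsparseMatrix")
  sys$Wty <- as.numeric(Matrix::crossprod(W, sys$y))
  sys$logdet_XtX <- as.numeric(determinant(crossprod(X2),
                                           logarithm = TRUE)$modulus)
  sys$.cache <- new.env(parent = emptyenv())
  sys
}

# small composite population fixtures ---------------------------------------

tiny_sim <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_founders_per_type = c(N = 6, A = 12, B = 6, C = 4),
    n_generations = 3, n_matings_per_gen = 18, offspring_per_mating = 3,
    n_cg = 3, seed = seed), list(...))
  do.call(sim_config, args)
}

# M1-generative world at h2 = 0.2 used by the LR-null experiments
m1_null_config <- function(seed, scale = 1) {
  sim_config(
    n_founders_per_type = c(N = 36, A = 80, B = 38, C = 14),
    n_generations = 5,
    n_matings_per_gen = round(c(135, 135, 135, 135, 60) * scale),
    offspring_per_mating = 5,
    true_sigma_u2 = 0.4, true_sigma_e2 = 1.6,
    breed_type_effects = c(N = 0, A = 0, B = 0, C = 0),
    het_effect = 0, recomb_effect = 0,
    seed = seed)
}

# hand-built 20-animal x 10-marker QC fixture with exactly three violations:
# marker 2 call rate 0.85, marker 5 MAF 0.025, marker 8 het deviation 0.20.
qc_toy <- function() {
  n <- 20
  hwe_marker <- function(n0, n1, n2) rep(c(0L, 1L, 2L), c(n0, n1, n2))
  ok <- hwe_marker(10, 8, 2)           # p = 0.3, het 0.40 vs 0.42
  codes <- cbind(
    m1 = hwe_marker(5, 10, 5),         # p = 0.5, het 0.50
    m2 = c(rep(5L, 3), hwe_marker(5, 8, 4)),  # call rate 17/20 = 0.85
    m3 = ok,
    m4 = hwe_marker(12, 6, 2),         # p = 0.25, het 0.30 vs 0.375
    m5 = c(1L, rep(0L, 19)),           # MAF 1/40 = 0.025
    m6 = hwe_marker(9, 9, 2),          # p = 0.325, het 0.45 vs 0.439
    m7 = ok,
    m8 = hwe_marker(3, 14, 3),         # p = 0.5, het 0.70 vs 0.50 -> dev 0.20
    m9 = hwe_marker(6, 10, 4),         # p = 0.45, het 0.50 vs 0.495
    m10 = hwe_marker(5, 11, 4)         # p = 0.475, het 0.55 vs 0.499
  )
  colnames(codes) <- NULL
  structure(list(ids = sprintf("a%02d", 1:n), codes = codes), class = "geno")
}

# write a geno object's matrix through the exported file writer
geno_from_strings <- function(lines, file = tempfile(fileext = ".txt")) {
  writeLines(lines, file)
  file
}
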