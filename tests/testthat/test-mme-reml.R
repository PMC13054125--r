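# shared medium fixture: M1-generative world, ~300 records
fix_pop <- simulate_population(tiny_sim(
  seed = 77, breed_type_effects = c(N = 0, A = 0, B = 0, C = 0),
  het_effect = 0, recomb_effect = 0,
  true_sigma_u2 = 1, true_sigma_e2 = 1))
fix_sys <- suppressMessages(build_design(
  fix_pop$phen, model_spec("M1", "A"), ped = fix_pop$ped, min_cg = 5))

test_that("model_spec reproduces the five fixed-effect rosters", {
  expect_false(model_spec("M1")$nabc)
  m2 <- model_spec("M2"); m3 <- model_spec("M3")
  m4 <- model_spec("M4"); m5 <- model_spec("M5")
  expect_true(m2$nabc && m2$het && !m2$rec && !m2$specific_het)
  expect_true(m3$het && m3$rec && !m3$specific_het)
  expect_true(m4$rec && m4$specific_het && !m4$het && !m4$specific_rec)
  expect_true(m5$specific_het && m5$specific_rec && !m5$het && !m5$rec)
  expect_error(model_spec("M6"), "arg")
})

test_that("build_design filters small contemporary groups and sizes X", {
  ids <- sprintf("an%02d", 1:31)
  ped <- pedigree(ids, rep(NA, 31), rep(NA, 31))
  phen <- data.frame(id = ids, y = rnorm(31),
                     cg = rep(c("cg1", "cg2", "cg3"), c(12, 10, 9)),
                     et = 0L, age_us = 570L, cow_age = 5,
                     birth_year = 2020L)
  sys <- suppressMessages(build_design(phen, model_spec("M1"), ped = ped))
  expect_equal(sys$n, 22)              # the 9-record group is excluded
  expect_false(any(grepl("cg3", colnames(sys$X))))
  # M1 has no breed/heterosis columns
  expect_false(any(grepl("het|rec|frac", colnames(sys$X))))
  # all groups too small -> error
  expect_error(
    suppressMessages(build_design(phen, model_spec("M1"), ped = ped,
                                  min_cg = 20)),
    "no records")
})

test_that("M2-M5 designs add the covariate blocks", {
  pop <- fix_pop
  # M5 on a tiny two-hundred-record fixture aliases one specific-recombination
  # column; the default contract is an error naming it, and "drop" proceeds
  expect_error(
    suppressMessages(build_design(pop$phen, model_spec("M5"), pop$cov,
                                  pop$comp, pop$ped, min_cg = 5)),
    "aliased")
  sys5 <- suppressMessages(build_design(pop$phen, model_spec("M5"), pop$cov,
                                        pop$comp, pop$ped, min_cg = 5,
                                        on_alias = "drop"))
  expect_true(any(grepl("^het_", colnames(sys5$X))))
  expect_true(any(grepl("^rec_", colnames(sys5$X))))
  expect_true(all(c("frac_N", "frac_B", "frac_C") %in% colnames(sys5$X)))
  expect_false("frac_A" %in% colnames(sys5$X))
  sys3 <- suppressMessages(build_design(pop$phen, model_spec("M3"), pop$cov,
                                        pop$comp, pop$ped, min_cg = 5))
  expect_true(all(c("het", "rec") %in% colnames(sys3$X)))
  expect_gt(sys5$p, sys3$p)
})

test_that("reml_loglik equals the dense error-contrast formula", {
  # small system for dense linear algebra
  pop <- simulate_population(tiny_sim(
    seed = 3, n_founders_per_type = c(N = 4, A = 6, B = 4, C = 2),
    n_generations = 2, n_matings_per_gen = 10, offspring_per_mating = 3))
  sys <- suppressMessages(build_design(pop$phen, model_spec("M1"),
                                       ped = pop$ped, min_cg = 3))
  K <- a_matrix(pop$ped)
  Z <- as.matrix(sys$Z)
  for (theta in list(c(0.5, 1.5), c(2, 0.7), c(0.425, 1.937))) {
    expect_equal(reml_loglik(theta, sys),
                 oracle_dense_reml(theta, sys$y, sys$X, Z, K),
                 tolerance = 1e-8)
  }
  expect_error(reml_loglik(c(-1, 1), sys), "positive")
})

test_that("reml_loglik is invariant to X reparameterisation and scales", {
  sys <- fix_sys
  theta <- c(0.8, 1.2)
  ll <- reml_loglik(theta, sys)
  set.seed(2)
  Tm <- matrix(rnorm(sys$p^2), sys$p) + diag(sys$p) * 3
  expect_equal(reml_loglik(theta, reparam_X(sys, Tm)), ll, tolerance = 1e-6)

  # scaling y by c and both variances by c^2 shifts lnL by -(n - p) log c
  cc <- 3.7
  sys_sc <- sys
  sys_sc$y <- sys$y * cc
  sys_sc$Wty <- sys$Wty * cc
  sys_sc$yty <- sys$yty * cc^2
  sys_sc$.cache <- new.env(parent = emptyenv())
  expect_equal(reml_loglik(theta * cc^2, sys_sc),
               ll - (sys$n - sys$p) * log(cc), tolerance = 1e-8)
})

test_that("ai_reml agrees with grid + derivative-free maximisation", {
  pop <- simulate_population(tiny_sim(
    seed = 8, n_founders_per_type = c(N = 4, A = 6, B = 4, C = 2),
    n_generations = 2, n_matings_per_gen = 12, offspring_per_mating = 3,
    true_sigma_u2 = 1, true_sigma_e2 = 1))
  sys <- suppressMessages(build_design(pop$phen, model_spec("M1"),
                                       ped = pop$ped, min_cg = 3))
  expect_lte(sys$n, 100)
  fit <- ai_reml(sys)
  expect_true(fit$converged)
  ref <- oracle_reml_argmax(sys)
  expect_equal(c(fit$sigma_u2, fit$sigma_e2), ref, tolerance = 1e-4,
               ignore_attr = TRUE)
  # the optimum dominates a +/-20% local grid of the likelihood surface
  for (fu in c(0.8, 1, 1.2)) for (fe in c(0.8, 1, 1.2)) {
    if (fu == 1 && fe == 1) next
    expect_gte(fit$loglik + 1e-7,
               reml_loglik(c(fit$sigma_u2 * fu, fit$sigma_e2 * fe), sys))
  }
})

test_that("ai_reml flags a boundary fit when sigma_u2 is truly zero", {
  pop <- simulate_population(tiny_sim(
    seed = 10, true_sigma_u2 = 0, true_sigma_e2 = 1.5,
    breed_type_effects = c(N = 0, A = 0, B = 0, C = 0),
    het_effect = 0, recomb_effect = 0))
  sys <- suppressMessages(build_design(pop$phen, model_spec("M1"),
                                       ped = pop$ped, min_cg = 5))
  fit <- ai_reml(sys, max_iter = 100)
  expect_true(fit$boundary)
  expect_lt(fit$h2, 0.02)
})

test_that("H-based fit with no genotyped animals reproduces the A fit", {
  sys_a <- fix_sys
  hs0 <- h_inverse(a_inverse(fix_pop$ped))
  sys_h <- suppressMessages(build_design(
    fix_pop$phen, model_spec("M1", "H"), ped = fix_pop$ped, relmat = hs0,
    min_cg = 5))
  theta <- c(0.9, 1.1)
  expect_equal(reml_loglik(theta, sys_h), reml_loglik(theta, sys_a),
               tolerance = 1e-10)
  fa <- ai_reml(sys_a)
  fh <- ai_reml(sys_h)
  expect_equal(c(fa$sigma_u2, fa$sigma_e2), c(fh$sigma_u2, fh$sigma_e2),
               tolerance = 1e-6)
})

test_that("solve_blup matches the dense GLS oracle and shrinkage limits", {
  pop <- simulate_population(tiny_sim(
    seed = 19, n_founders_per_type = c(N = 4, A = 6, B = 4, C = 2),
    n_generations = 2, n_matings_per_gen = 10, offspring_per_mating = 3))
  sys <- suppressMessages(build_design(pop$phen, model_spec("M1"),
                                       ped = pop$ped, min_cg = 3))
  K <- a_matrix(pop$ped)
  Z <- as.matrix(sys$Z)
  theta <- c(0.7, 1.3)
  sol <- solve_blup(sys, list(sigma_u2 = theta[1], sigma_e2 = theta[2]))
  ora <- oracle_dense_blup(theta, sys$y, sys$X, Z, K)
  expect_equal(unname(sol$u), unname(ora$u), tolerance = 1e-8)
  expect_equal(unname(sol$beta), unname(ora$beta), tolerance = 1e-8)

  # lambda -> infinity: breeding values shrink to zero
  sol0 <- solve_blup(sys, list(sigma_u2 = 1e-9, sigma_e2 = 1.3))
  expect_lt(max(abs(sol0$u)), 1e-5)

  # childless, recordless animal with known parents: exactly parent average
  tab <- pop$ped$tab
  in_ped_only <- setdiff(tab$id, pop$phen$id)
  parents <- c(tab$sire, tab$dam)
  cand <- tab$id[tab$id %in% in_ped_only & !(tab$id %in% parents) &
                 tab$sire_idx > 0 & tab$dam_idx > 0]
  if (length(cand)) {
    i <- match(cand[1], tab$id)
    expect_equal(sol$u[i],
                 0.5 * (sol$u[tab$sire_idx[i]] + sol$u[tab$dam_idx[i]]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("heritability arithmetic and delta-method error", {
  expect_equal(heritability(1, 1)$h2, 0.5)
  v <- matrix(c(0.04, -0.01, -0.01, 0.05), 2)
  h <- heritability(0.4, 1.6, vcov = v)
  expect_equal(h$h2, 0.2)
  g <- c(1.6, -0.4) / 4
  expect_equal(h$se, sqrt(drop(t(g) %*% v %*% g)))
  expect_error(heritability(0, 0), "zero")
})

test_that("M3 recovers nonzero heterosis and recombination coefficients", {
  cfg <- sim_config(
    n_founders_per_type = c(N = 12, A = 26, B = 12, C = 6),
    n_generations = 4, n_matings_per_gen = 50, offspring_per_mating = 4,
    het_effect = 1.0, recomb_effect = -0.6,
    breed_type_effects = c(N = -0.5, A = 0.2, B = 0.6, C = 0.4),
    n_cg = 4, seed = 23)
  pop <- simulate_population(cfg)
  sys <- suppressMessages(build_design(pop$phen, model_spec("M3"), pop$cov,
                                       pop$comp, pop$ped))
  fit <- ai_reml(sys)
  sol <- solve_blup(sys, fit)
  # dense covariance of beta from the inverted coefficient matrix
  C <- as.matrix(crossprod(as.matrix(sys$W)) / fit$sigma_e2) +
    as.matrix(Matrix::bdiag(Matrix::Diagonal(sys$p, 0),
                            a_inverse(pop$ped) / fit$sigma_u2))
  Ci <- solve(C)
  se <- sqrt(diag(Ci)[seq_len(sys$p)])
  bhat <- sol$beta
  expect_lt(abs(bhat["het"] - 1.0), 3 * se[match("het", colnames(sys$X))])
  expect_lt(abs(bhat["rec"] - (-0.6)), 3 * se[match("rec", colnames(sys$X))])
  # frac_N estimates effN - effA (type A is the dropped reference)
  expect_lt(abs(bhat["frac_N"] - (-0.7)),
            3 * se[match("frac_N", colnames(sys$X))])
})
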