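test_that("pedigree simulation: averaging, determinism, structure", {
  # one generation of forced N x A matings: all offspring are (1/2, 1/2, 0, 0)
  cfg <- sim_config(n_founders_per_type = c(N = 8, A = 8, B = 0, C = 0),
                    n_generations = 1, n_matings_per_gen = 8,
                    offspring_per_mating = 2,
                    mating_scheme = "between_types", seed = 2)
  pop <- simulate_pedigree(cfg)
  off <- !pop$ped$tab$founder
  expect_true(all(abs(pop$comp$alpha[off, "N"] - 0.5) < 1e-12))
  expect_true(all(abs(pop$comp$alpha[off, "A"] - 0.5) < 1e-12))

  # same config, same seed: byte-identical
  pop2 <- simulate_pedigree(cfg)
  expect_identical(pop$ped$tab, pop2$ped$tab)
  expect_identical(pop$comp$alpha, pop2$comp$alpha)

  # every non-founder has both parents in earlier rows; fractions average
  pop3 <- simulate_pedigree(tiny_sim(seed = 6))
  tab <- pop3$ped$tab
  nf <- which(!tab$founder)
  expect_true(all(tab$sire_idx[nf] < nf & tab$dam_idx[nf] < nf))
  expect_equal(pop3$comp$alpha[nf, ],
               (pop3$comp$alpha[tab$sire_idx[nf], ] +
                pop3$comp$alpha[tab$dam_idx[nf], ]) / 2,
               ignore_attr = TRUE)

  expect_error(sim_config(n_founders_per_type = c(N = 1, A = 1, B = 0, C = 0)),
               "degenerate")
})

test_that("default 5-generation world brackets the target heterosis", {
  pop <- simulate_pedigree(sim_config(seed = 31))
  cc <- covariate_table(pop$ped, pop$comp)
  tab <- pop$ped$tab
  last <- tab$generation == max(tab$generation)
  mh <- mean(cc$het[last])
  expect_gt(mh, 0.35)
  expect_lt(mh, 0.85)
  # soft calibration checks of the stated world
  expect_lt(abs(mean(tab$F) - 0.015), 0.02)
  expect_lt(max(abs(colMeans(pop$comp$alpha) - c(0.22, 0.50, 0.24, 0.09))),
            0.06)
})

test_that("gene dropping: Mendelian codes and the binomial oracle", {
  cfg <- sim_config(n_founders_per_type = c(N = 10, A = 10, B = 0, C = 0),
                    n_generations = 1, n_matings_per_gen = 10,
                    offspring_per_mating = 4,
                    mating_scheme = "between_types",
                    n_snps = 10000, missing_rate = 0, seed = 12)
  pop <- simulate_pedigree(cfg)
  # fixed alternative frequencies per type make the founder check exact
  freqs <- rbind(N = rep(1, cfg$n_snps), A = rep(0.3, cfg$n_snps),
                 B = 0.5, C = 0.5)
  g <- drop_genotypes(pop$ped, cfg, pop$comp, freqs = freqs)
  tab <- pop$ped$tab
  pure_n <- tab$typeN == 1 & tab$founder
  expect_true(all(g$codes[pure_n, ] == 2L))

  # parents both 0 at a locus -> child 0 (check across all trios at loci
  # where it applies)
  nf <- which(!tab$founder)
  kid <- nf[1]
  s <- tab$sire_idx[kid]; d <- tab$dam_idx[kid]
  zz <- g$codes[s, ] == 0L & g$codes[d, ] == 0L
  if (any(zz)) expect_true(all(g$codes[kid, zz] == 0L))
  hom2 <- g$codes[s, ] == 2L & g$codes[d, ] == 2L
  if (any(hom2)) expect_true(all(g$codes[kid, hom2] == 2L))

  # F1 N x A cohort: observed heterozygosity vs the analytic expectation
  cfg2 <- sim_config(n_founders_per_type = c(N = 10, A = 10, B = 0, C = 0),
                     n_generations = 1, n_matings_per_gen = 10,
                     offspring_per_mating = 4,
                     mating_scheme = "between_types",
                     n_snps = 10000, missing_rate = 0, seed = 12)
  g2 <- drop_genotypes(pop$ped, cfg2, pop$comp)
  fq <- attr(g2, "type_freqs")
  f1 <- which(!tab$founder)
  het_obs <- mean(g2$codes[f1, ] == 1L)
  pN <- fq["N", ]; pA <- fq["A", ]
  het_exp <- mean(pN * (1 - pA) + pA * (1 - pN))
  n_cells <- length(f1) * cfg2$n_snps
  se <- sqrt(het_exp * (1 - het_exp) / n_cells) *
    sqrt(cfg2$n_snps)  # conservative: loci independent, animals are not
  expect_lt(abs(het_obs - het_exp), 3 * max(se, 0.003))

  # determinism of the gene drop
  g3 <- drop_genotypes(pop$ped, cfg2, pop$comp)
  expect_identical(g2$codes, g3$codes)
})

test_that("phenotype simulation: exact decomposition and degenerate cases", {
  cfg <- tiny_sim(seed = 14, true_sigma_e2 = 0)
  pop <- simulate_pedigree(cfg)
  cc <- covariate_table(pop$ped, pop$comp)
  pt <- simulate_phenotypes(pop$ped, pop$comp, cc, cfg)
  ph <- !is.na(pt$truth$y)
  # sigma_e2 = 0: phenotype minus fixed part equals u exactly
  expect_equal(pt$truth$y[ph] - pt$truth$fixed[ph], pt$truth$u[ph],
               tolerance = 1e-12)
  # truth table and phenotype table agree
  expect_equal(pt$phen$y,
               pt$truth$y[match(pt$phen$id, pt$truth$id)])

  # missing covariate row names the animal
  expect_error(simulate_phenotypes(pop$ped, pop$comp, cc[-5, ], cfg),
               cc$id[5])

  # founder u variance matches sigma_u2 (1000+ founders)
  cfgF <- sim_config(n_founders_per_type = c(N = 300, A = 500, B = 300, C = 100),
                     n_generations = 1, n_matings_per_gen = 10,
                     offspring_per_mating = 1, true_sigma_u2 = 2,
                     seed = 15)
  popF <- simulate_pedigree(cfgF)
  ccF <- covariate_table(popF$ped, popF$comp)
  ptF <- simulate_phenotypes(popF$ped, popF$comp, ccF, cfgF)
  uf <- ptF$truth$u[popF$ped$tab$founder]
  se_var <- 2 * sqrt(2 / (length(uf) - 1))
  expect_lt(abs(var(uf) - 2), 3 * se_var)
})

test_that("simulated u/e decomposition recovers h2 near 0.18", {
  # RF-like world: (0.425, 1.937) -> h2 = 0.180; ~5,000 animals per rep
  h2_hat <- vapply(1:8, function(r) {
    cfg <- sim_config(n_founders_per_type = c(N = 40, A = 90, B = 45, C = 15),
                      n_generations = 4, n_matings_per_gen = 240,
                      offspring_per_mating = 5,
                      breed_type_effects = c(N = 0, A = 0, B = 0, C = 0),
                      het_effect = 0, recomb_effect = 0, seed = 500 + r)
    pop <- simulate_pedigree(cfg)
    cc <- covariate_table(pop$ped, pop$comp)
    pt <- simulate_phenotypes(pop$ped, pop$comp, cc, cfg)
    ph <- !is.na(pt$truth$e)
    var(pt$truth$u[ph]) / (var(pt$truth$u[ph]) + var(pt$truth$e[ph]))
  }, 0)
  se <- sd(h2_hat) / sqrt(length(h2_hat))
  expect_lt(abs(mean(h2_hat) - 0.180), 3 * max(se, 0.005))
})

test_that("selective genotyping picks superior young animals", {
  cfg <- tiny_sim(seed = 16, genotyping_fraction = 0.1)
  pop <- simulate_population(cfg)
  # fraction 1.0 selects everyone
  cfg_all <- tiny_sim(seed = 16, genotyping_fraction = 1.0)
  expect_setequal(selective_genotyping(pop$ped, pop$truth, cfg_all),
                  pop$ped$tab$id)
  # rounding contract
  n_expected <- round(0.1 * pop$ped$n)
  expect_length(selective_genotyping(pop$ped, pop$truth, cfg), n_expected)
  # selective beats random in mean true breeding value (same seed)
  cfg_rand <- tiny_sim(seed = 16, genotyping_fraction = 0.1,
                       selective_genotyping = FALSE)
  ids_sel <- selective_genotyping(pop$ped, pop$truth, cfg)
  ids_rnd <- selective_genotyping(pop$ped, pop$truth, cfg_rand)
  u <- setNames(pop$truth$u, pop$truth$id)
  expect_gt(mean(u[ids_sel]), mean(u[ids_rnd]))
  # a fraction selecting nobody errors
  cfg0 <- tiny_sim(seed = 16, genotyping_fraction = 1e-6)
  expect_error(selective_genotyping(pop$ped, pop$truth, cfg0), "no animals")
})

test_that("full population simulation is deterministic and writable", {
  cfg <- tiny_sim(seed = 99, n_snps = 50, genotyping_fraction = 0.2)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$phen, p2$phen)
  expect_identical(p1$geno$codes, p2$geno$codes)
  expect_identical(p1$truth, p2$truth)

  d <- tempfile("popwrite")
  write_population(p1, d)
  expect_true(all(file.exists(file.path(d,
    c("pedigree.csv", "phenotypes.csv", "covariates.csv", "truth.csv",
      "snp.txt", "config.json")))))
  # the written pedigree re-reads into the same relationship structure
  ped2 <- read_pedigree(file.path(d, "pedigree.csv"))
  expect_equal(sort(ped2$tab$id), sort(p1$ped$tab$id))
  expect_equal(inbreeding(ped2)[p1$ped$tab$id], inbreeding(p1$ped))
})
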