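#' Simulation configuration for a composite population
#'
#' Describes the generative world of the synthetic composite-cattle
#' population: a 4-type (N/A/B/C) founder base, several generations of
#' random inter-se mating, gene dropping over an independent-locus SNP panel,
#' and a single-trait phenotype whose generative model mirrors the fullest
#' fixed-effect parameterisation (contemporary group, embryo transfer, age at
#' ultrasound, cow age linear+quadratic, breed-type regressions, combined
#' heterosis and recombination) plus an additive genetic effect with exact
#' pedigree (A-matrix) covariance and an independent residual.
#'
#' Defaults emulate a rump-fat-like trait in a four-type composite herd:
#' founder counts per type proportional to mean breed fractions of roughly
#' (0.22, 0.50, 0.24, 0.09), which puts the equilibrium combined heterosis
#' near 0.66, variance components (0.425, 1.937), about 2% selectively
#' genotyped animals and a scaled-down medium-density panel.
#'
#' @param n_founders_per_type named integer vector (N, A, B, C).
#' @param n_generations number of offspring generations (>= 1).
#' @param n_matings_per_gen matings per generation; scalar or a vector of
#'   length `n_generations` (lets the final cohort be sized independently).
#' @param offspring_per_mating offspring per mating.
#' @param prop_sires fraction of available males used as sires each
#'   generation (bull usage; drives relatedness and inbreeding).
#' @param mating_scheme `"random"` mates within the previous cohort at
#'   random; `"between_types"` forces sire and dam to differ in (founder)
#'   type, useful for F1/F2 fixtures.
#' @param n_snps markers in the panel (0 = no genotypes simulated).
#' @param founder_allele_freq_range per-type allele frequencies are drawn
#'   uniformly in this range, independently per type and locus.
#' @param true_sigma_u2,true_sigma_e2 additive and residual variances.
#' @param trait_mean baseline trait mean.
#' @param breed_type_effects trait units per unit breed fraction (length 4).
#' @param het_effect,recomb_effect trait units per unit combined heterosis /
#'   recombination.
#' @param n_cg contemporary groups per birth-year cohort.
#' @param cg_effect_sd SD of contemporary-group effects.
#' @param et_fraction,et_effect fraction of embryo-transfer calves and the
#'   associated fixed effect.
#' @param age_us_range age at ultrasound (days), uniform.
#' @param age_us_effect trait units per day of age at ultrasound.
#' @param cow_age_range cow age at calving (years), uniform.
#' @param beta1,beta2 linear and quadratic cow-age regression coefficients.
#' @param genotyping_fraction fraction of animals genotyped, in (0, 1].
#' @param selective_genotyping if TRUE, genotyped animals are the top
#'   true-breeding-value fraction within recent birth years.
#' @param genotyping_recent_years how many recent birth years are eligible
#'   for selective genotyping.
#' @param missing_rate per-cell genotype missingness (coded 5).
#' @param seed integer seed; the whole population is reproducible from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders_per_type = c(N = 36, A = 80, B = 38, C = 14),
                       n_generations = 5,
                       n_matings_per_gen = 130,
                       offspring_per_mating = 5,
                       prop_sires = 0.10,
                       mating_scheme = c("random", "between_types"),
                       n_snps = 0,
                       founder_allele_freq_range = c(0.05, 0.95),
                       true_sigma_u2 = 0.425,
                       true_sigma_e2 = 1.937,
                       trait_mean = 3.9,
                       breed_type_effects = c(N = -0.5, A = 0.2, B = 0.6, C = 0.4),
                       het_effect = 0.4,
                       recomb_effect = -0.2,
                       n_cg = 6,
                       cg_effect_sd = 0.5,
                       et_fraction = 0.05,
                       et_effect = 0.3,
                       age_us_range = c(450, 700),
                       age_us_effect = 0.004,
                       cow_age_range = c(2, 14),
                       beta1 = 0.08,
                       beta2 = -0.005,
                       genotyping_fraction = 0.02,
                       selective_genotyping = TRUE,
                       genotyping_recent_years = 3,
                       missing_rate = 0.01,
                       seed = 1L) {
  mating_scheme <- match.arg(mating_scheme)
  if (length(n_founders_per_type) != 4)
    stop2("n_founders_per_type must have 4 entries (N, A, B, C)")
  names(n_founders_per_type) <- BREED_TYPES
  if (n_generations < 1) stop2("n_generations must be >= 1")
  if (sum(n_founders_per_type >= 2) < 2)
    stop2("degenerate config: need at least two types with >= 2 founders")
  if (true_sigma_u2 < 0 || true_sigma_e2 < 0) stop2("variances must be >= 0")
  if (genotyping_fraction <= 0 || genotyping_fraction > 1)
    stop2("genotyping_fraction must be in (0, 1]")
  fr <- founder_allele_freq_range
  if (fr[1] <= 0 || fr[2] >= 1 || fr[1] > fr[2])
    stop2("founder_allele_freq_range must lie inside (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop2("bad missing_rate")
  nm <- rep_len(as.integer(n_matings_per_gen), n_generations)
  cfg <- list(n_founders_per_type = n_founders_per_type,
              n_generations = as.integer(n_generations),
              n_matings_per_gen = nm,
              offspring_per_mating = as.integer(offspring_per_mating),
              prop_sires = prop_sires, mating_scheme = mating_scheme,
              n_snps = as.integer(n_snps),
              founder_allele_freq_range = fr,
              true_sigma_u2 = true_sigma_u2, true_sigma_e2 = true_sigma_e2,
              trait_mean = trait_mean,
              breed_type_effects = setNames(breed_type_effects, BREED_TYPES),
              het_effect = het_effect, recomb_effect = recomb_effect,
              n_cg = as.integer(n_cg), cg_effect_sd = cg_effect_sd,
              et_fraction = et_fraction, et_effect = et_effect,
              age_us_range = age_us_range, age_us_effect = age_us_effect,
              cow_age_range = cow_age_range, beta1 = beta1, beta2 = beta2,
              genotyping_fraction = genotyping_fraction,
              selective_genotyping = isTRUE(selective_genotyping),
              genotyping_recent_years = as.integer(genotyping_recent_years),
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

SIM_BASE_YEAR <- 2016L

#' Simulate a composite-population pedigree
#'
#' Founders are purebred per biological type; each later generation mates
#' sires (a limited `prop_sires` fraction of the previous cohort's males)
#' with dams sampled from the previous cohort's females, so multi-generation
#' crossbreds accumulate.  Breed fractions of a child are the mean of its
#' parents' fractions.  Birth years are assigned by generation.
#'
#' @param config a `sim_config`.
#' @return list with `ped` (a `ped` object carrying `sex`, `generation` and
#'   founder `typeN`..`typeC` columns) and `comp` (a `breed_comp`).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_founders_per_type
  ftype <- rep(BREED_TYPES, times = nf)
  n_f <- length(ftype)
  id <- sprintf("G0_%04d", seq_len(n_f))
  sire <- rep(NA_character_, n_f)
  dam <- rep(NA_character_, n_f)
  year <- rep(SIM_BASE_YEAR, n_f)
  gen <- rep(0L, n_f)
  # guarantee both sexes within each type so between-type schemes work
  sex <- unlist(lapply(split(seq_len(n_f), ftype), function(ix) {
    s <- sample(rep_len(c("M", "F"), length(ix)))
    s
  }), use.names = FALSE)[order(unlist(split(seq_len(n_f), ftype)))]
  type <- ftype

  for (g in seq_len(config$n_generations)) {
    prev <- which(gen == g - 1L)
    if (length(prev) < 2) stop2("generation ", g - 1L, " too small to mate")
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop2("generation ", g - 1L, " lacks one sex entirely")
    n_sires <- max(2L, min(length(males),
                           ceiling(config$prop_sires * length(males))))
    active_sires <- if (length(males) == 1L) males else
      sample(males, n_sires)
    n_mat <- config$n_matings_per_gen[g]
    ms <- sample(active_sires, n_mat, replace = TRUE)
    md <- if (length(females) >= n_mat) sample(females, n_mat) else
      sample(females, n_mat, replace = TRUE)
    if (config$mating_scheme == "between_types") {
      for (k in seq_len(n_mat)) {
        tries <- 0L
        while (type[ms[k]] == type[md[k]] && tries < 50L) {
          md[k] <- sample(females, 1L)
          tries <- tries + 1L
        }
      }
    }
    opm <- config$offspring_per_mating
    n_off <- n_mat * opm
    off_id <- sprintf("G%d_%04d", g, seq_len(n_off))
    id <- c(id, off_id)
    sire <- c(sire, rep(id[ms], each = opm))
    dam <- c(dam, rep(id[md], each = opm))
    year <- c(year, rep(SIM_BASE_YEAR + g, n_off))
    gen <- c(gen, rep(g, n_off))
    sex <- c(sex, sample(c("M", "F"), n_off, replace = TRUE))
    type <- c(type, rep("X", n_off))
  }

  frac <- matrix(0, length(id), 4, dimnames = list(NULL, BREED_TYPES))
  fi <- gen == 0L
  frac[cbind(which(fi), match(type[fi], BREED_TYPES))] <- 1
  extra <- data.frame(sex = sex, generation = gen,
                      typeN = frac[, 1], typeA = frac[, 2],
                      typeB = frac[, 3], typeC = frac[, 4],
                      stringsAsFactors = FALSE)
  ped <- pedigree(id, sire, dam, birth_year = year, extra = extra)
  ff <- data.frame(id = id[fi], typeN = frac[fi, 1], typeA = frac[fi, 2],
                   typeB = frac[fi, 3], typeC = frac[fi, 4])
  comp <- propagate_breed_composition(ped, ff)
  list(ped = ped, comp = comp)
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder genotypes are drawn per locus from type-specific allele
#' frequencies (crossbred-declared founders use their fraction vector as a
#' breed-of-origin mixture); each descendant receives one Mendelian-sampled
#' allele per parent per locus.  Loci are independent (no linkage/LD): the
#' downstream analysis consumes only genotype covariances, and independence
#' keeps the heterozygosity oracle analytic.
#'
#' @param ped a `ped` object (sorted parents-first by construction).
#' @param config a `sim_config` with `n_snps > 0`.
#' @param comp a `breed_comp` for the founder breed-of-origin mixture.
#' @param freqs optional 4 x n_snps matrix of per-type allele frequencies
#'   (drawn from `founder_allele_freq_range` when omitted).
#' @return a `geno` object over all animals (codes 0/1/2, missing 5), with
#'   the per-type frequency matrix attached as attribute `type_freqs`.
#' @export
drop_genotypes <- function(ped, config, comp, freqs = NULL) {
  m <- config$n_snps
  if (m <= 0) stop2("config$n_snps must be positive")
  set.seed(config$seed + 1L)
  fr <- config$founder_allele_freq_range
  if (is.null(freqs))
    freqs <- matrix(runif(4 * m, fr[1], fr[2]), 4, m,
                    dimnames = list(BREED_TYPES, NULL))
  tab <- ped$tab
  n <- ped$n
  codes <- matrix(0L, n, m)
  founders <- which(!(tab$sire_idx > 0L & tab$dam_idx > 0L))
  for (i in founders) {
    al <- comp$alpha[i, ]
    if (max(al) == 1) {
      p <- freqs[which.max(al), ]
      codes[i, ] <- rbinom(m, 2L, p)
    } else {
      # two alleles, each from a breed-of-origin mixture
      b1 <- sample.int(4, m, replace = TRUE, prob = al)
      b2 <- sample.int(4, m, replace = TRUE, prob = al)
      codes[i, ] <- (runif(m) < freqs[cbind(b1, seq_len(m))]) +
                    (runif(m) < freqs[cbind(b2, seq_len(m))])
    }
  }
  n_nonf <- n - length(founders)
  if (n_nonf > 0) {
    u <- runif(2 * n_nonf * m)
    codes <- gene_drop_cpp(codes, tab$sire_idx, tab$dam_idx, u)
  }
  if (config$missing_rate > 0) {
    miss <- runif(length(codes)) < config$missing_rate
    codes[miss] <- 5L
  }
  g <- new_geno(tab$id, codes)
  attr(g, "type_freqs") <- freqs
  g
}

#' Simulate phenotypes and true genetic values
#'
#' Breeding values follow the pedigree exactly: founders are
#' `N(0, sigma_u2)`; non-founders are the parent average plus a Mendelian
#' deviation with variance `0.5 (1 - (F_s + F_d)/2) sigma_u2` (one known
#' parent: `(0.75 - F_known/4) sigma_u2`), so the simulated `u` has covariance
#' `A sigma_u2` exactly.  The phenotype adds contemporary-group, embryo
#' transfer, age-at-ultrasound and cow-age fixed effects, breed-type
#' regressions, combined heterosis and recombination effects, and an
#' independent residual.  Founder generations carry no phenotype (they have
#' no management records), all animals carry a true breeding value.
#'
#' @param ped a `ped` object from [simulate_pedigree()].
#' @param comp a `breed_comp`.
#' @param cov covariate table from [covariate_table()].
#' @param config a `sim_config`.
#' @return list with `phen` (data.frame `id`, `y`, `cg`, `et`, `age_us`,
#'   `cow_age`, `birth_year`) and `truth` (data.frame `id`, `u`, `fixed`,
#'   `e`, `y`; `fixed`/`e`/`y` are `NA` for unphenotyped animals).
#' @export
simulate_phenotypes <- function(ped, comp, cov, config) {
  set.seed(config$seed + 2L)
  tab <- ped$tab
  n <- ped$n
  ci <- match(tab$id, cov$id)
  if (anyNA(ci))
    stop2("no covariate row for animal '", tab$id[which(is.na(ci))[1]], "'")
  cov <- cov[ci, ]

  # breeding values with exact A-covariance
  su2 <- config$true_sigma_u2
  u <- numeric(n)
  z <- rnorm(n)
  for (i in seq_len(n)) {
    s <- tab$sire_idx[i]; d <- tab$dam_idx[i]
    if (s > 0L && d > 0L) {
      msv <- 0.5 * (1 - (tab$F[s] + tab$F[d]) / 2) * su2
      u[i] <- 0.5 * (u[s] + u[d]) + z[i] * sqrt(msv)
    } else if (s > 0L || d > 0L) {
      p <- max(s, d)
      u[i] <- 0.5 * u[p] + z[i] * sqrt((0.75 - tab$F[p] / 4) * su2)
    } else {
      u[i] <- z[i] * sqrt(su2)
    }
  }

  phenotyped <- which(!tab$founder)
  np <- length(phenotyped)
  yr <- tab$birth_year[phenotyped]
  cg_num <- unlist(lapply(split(seq_len(np), yr), function(ix) {
    sample(rep_len(seq_len(config$n_cg), length(ix)))
  }), use.names = FALSE)[order(unlist(split(seq_len(np), yr)))]
  cg <- paste0(yr, "_", cg_num)
  cg_levels <- unique(cg)
  cg_eff <- setNames(rnorm(length(cg_levels), 0, config$cg_effect_sd),
                     cg_levels)
  et <- rbinom(np, 1L, config$et_fraction)
  age_us <- round(runif(np, config$age_us_range[1], config$age_us_range[2]))
  cow_age <- round(runif(np, config$cow_age_range[1],
                         config$cow_age_range[2]), 1)
  fixed <- config$trait_mean +
    cg_eff[cg] +
    config$et_effect * et +
    config$age_us_effect * (age_us - mean(config$age_us_range)) +
    config$beta1 * cow_age + config$beta2 * cow_age^2 +
    drop(comp$alpha[phenotyped, , drop = FALSE] %*% config$breed_type_effects) +
    config$het_effect * cov$het[phenotyped] +
    config$recomb_effect * cov$rec[phenotyped]
  e <- rnorm(np, 0, sqrt(config$true_sigma_e2))
  y <- fixed + u[phenotyped] + e

  truth <- data.frame(id = tab$id, u = u, fixed = NA_real_, e = NA_real_,
                      y = NA_real_, stringsAsFactors = FALSE)
  truth$fixed[phenotyped] <- unname(fixed)
  truth$e[phenotyped] <- e
  truth$y[phenotyped] <- unname(y)
  phen <- data.frame(id = tab$id[phenotyped], y = unname(y), cg = cg,
                     et = et, age_us = age_us, cow_age = cow_age,
                     birth_year = yr, stringsAsFactors = FALSE)
  list(phen = phen, truth = truth)
}

#' Choose the genotyped animals
#'
#' Returns `round(genotyping_fraction * N)` animal ids.  Under selective
#' genotyping the top animals by true breeding value within the most recent
#' birth years are taken (topped up from older cohorts if needed), emulating
#' the genotyping of superior young selection candidates; otherwise the set
#' is uniform random.
#'
#' @param ped a `ped` object.
#' @param truth truth table from [simulate_phenotypes()].
#' @param config a `sim_config`.
#' @return character vector of genotyped animal ids.
#' @export
selective_genotyping <- function(ped, truth, config) {
  set.seed(config$seed + 3L)
  n_g <- round(config$genotyping_fraction * ped$n)
  if (n_g < 1) stop2("genotyping_fraction selects no animals")
  u <- truth$u[match(ped$tab$id, truth$id)]
  if (config$selective_genotyping) {
    cutoff <- max(ped$tab$birth_year) - config$genotyping_recent_years + 1L
    recent <- ped$tab$birth_year >= cutoff
    pool <- order(!recent, -u)  # recent first, then by descending u
    ped$tab$id[pool[seq_len(n_g)]]
  } else {
    sample(ped$tab$id, n_g)
  }
}

#' Simulate a complete population
#'
#' Orchestrates [simulate_pedigree()], [covariate_table()],
#' [simulate_phenotypes()], [drop_genotypes()] (when `n_snps > 0`) and
#' [selective_genotyping()].  Fully deterministic given `config$seed`.
#'
#' @param config a `sim_config`.
#' @return list of class `sim_population` with elements `config`, `ped`,
#'   `comp`, `cov`, `phen`, `truth`, and when genotyped: `geno` (genotyped
#'   subset only) and `genotyped_ids`.
#' @export
simulate_population <- function(config) {
  pc <- simulate_pedigree(config)
  cov <- covariate_table(pc$ped, pc$comp)
  pt <- simulate_phenotypes(pc$ped, pc$comp, cov, config)
  pop <- list(config = config, ped = pc$ped, comp = pc$comp, cov = cov,
              phen = pt$phen, truth = pt$truth)
  if (config$n_snps > 0) {
    g_all <- drop_genotypes(pc$ped, config, pc$comp)
    ids <- selective_genotyping(pc$ped, pt$truth, config)
    keep <- match(ids, g_all$ids)
    pop$geno <- new_geno(ids, g_all$codes[keep, , drop = FALSE])
    pop$genotyped_ids <- ids
  }
  class(pop) <- "sim_population"
  pop
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated composite population:", x$ped$n, "animals,",
      nrow(x$phen), "phenotypes")
  if (!is.null(x$geno)) cat(",", length(x$genotyped_ids), "genotyped")
  cat("\n")
  invisible(x)
}

#' Write a simulated population to plain-text files
#'
#' Writes `pedigree.csv` (animal, sire, dam, birth_year, typeN..typeC; `0` =
#' unknown parent), `phenotypes.csv`, `covariates.csv`, `truth.csv`,
#' `snp.txt` (BLUPF90 dialect, genotyped subset) and `config.json`.
#'
#' @param pop a `sim_population`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- pop$ped$tab
  pedcsv <- data.frame(animal = tab$id,
                       sire = ifelse(is.na(tab$sire), "0", tab$sire),
                       dam = ifelse(is.na(tab$dam), "0", tab$dam),
                       birth_year = tab$birth_year,
                       typeN = pop$comp$alpha[, "N"],
                       typeA = pop$comp$alpha[, "A"],
                       typeB = pop$comp$alpha[, "B"],
                       typeC = pop$comp$alpha[, "C"])
  write.csv(pedcsv, file.path(dir, "pedigree.csv"), row.names = FALSE)
  write.csv(pop$phen, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  write.csv(pop$cov, file.path(dir, "covariates.csv"), row.names = FALSE)
  write.csv(pop$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(pop$geno))
    write_snp_file(pop$geno, file.path(dir, "snp.txt"))
  jsonlite::write_json(unclass(pop$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
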