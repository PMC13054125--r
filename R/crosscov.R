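#' Crossbreeding covariates
#'
#' Heterosis and recombination-loss covariates for composite populations,
#' computed from the breed-of-origin fractions of an animal's sire and dam
#' over the four biological types N, A, B, C.
#'
#' * specific heterosis (Dickerson): `Het_ij = a_s[i] a_d[j] + a_s[j] a_d[i]`
#' * combined heterosis (VanRaden-Sanders): `Het = 1 - sum_i a_s[i] a_d[i]`
#' * combined recombination: `Rec = 1 - sum_i (a_s[i]^2 + a_d[i]^2) / 2`
#' * specific recombination, standard (Kinghorn) form:
#'   `Rec_ij = a_s[i] a_s[j] + a_d[i] a_d[j]`
#'
#' The identities `sum_{i<j} Het_ij = Het` and (standard form)
#' `sum_{i<j} Rec_ij = Rec` hold exactly.  A literal `as_printed` form of the
#' specific recombination coefficient,
#' `(a_s[i]+a_d[j])(a_s[j]+a_d[i]) - Het_ij`, is retained for audit; it is
#' inconsistent with the combined coefficient (it gives 1, not 0, for an
#' F1 of two purebreds) and is not used anywhere by default.
#'
#' @param sire_comp,dam_comp numeric length-4 breed-fraction vectors (order
#'   N, A, B, C), each summing to 1.
#' @param pair character length-2, the two (distinct) types, e.g. `c("N","A")`.
#' @name crosscov
NULL

check_comp <- function(x, what) {
  if (length(x) != 4 || anyNA(x))
    stop2(what, " must be a length-4 fraction vector")
  if (abs(sum(x) - 1) > 1e-6)
    stop2(what, " fractions must sum to 1")
  unname(x)
}

pair_index <- function(pair) {
  i <- match(pair, BREED_TYPES)
  if (anyNA(i)) stop2("unknown biological type in pair")
  if (i[1] == i[2]) stop2("heterosis/recombination is between distinct types")
  i
}

#' @rdname crosscov
#' @export
specific_heterosis <- function(sire_comp, dam_comp, pair) {
  s <- check_comp(sire_comp, "sire_comp"); d <- check_comp(dam_comp, "dam_comp")
  ij <- pair_index(pair)
  s[ij[1]] * d[ij[2]] + s[ij[2]] * d[ij[1]]
}

#' @rdname crosscov
#' @export
combined_heterosis <- function(sire_comp, dam_comp) {
  s <- check_comp(sire_comp, "sire_comp"); d <- check_comp(dam_comp, "dam_comp")
  1 - sum(s * d)
}

#' @rdname crosscov
#' @export
combined_recombination <- function(sire_comp, dam_comp) {
  s <- check_comp(sire_comp, "sire_comp"); d <- check_comp(dam_comp, "dam_comp")
  1 - sum(s^2 + d^2) / 2
}

#' @rdname crosscov
#' @param form `"standard"` (default, Kinghorn) or `"as_printed"` (literal
#'   audit form, see Details).
#' @export
specific_recombination <- function(sire_comp, dam_comp, pair,
                                   form = c("standard", "as_printed")) {
  form <- match.arg(form)
  s <- check_comp(sire_comp, "sire_comp"); d <- check_comp(dam_comp, "dam_comp")
  ij <- pair_index(pair)
  i <- ij[1]; j <- ij[2]
  if (form == "standard") {
    s[i] * s[j] + d[i] * d[j]
  } else {
    (s[i] + d[j]) * (s[j] + d[i]) - (s[i] * d[j] + s[j] * d[i])
  }
}

#' Per-animal crossbreeding covariate table
#'
#' Computes all 14 covariates (combined heterosis and recombination plus the
#' six type-pair specific forms of each) for every animal in a pedigree.
#' Animals with an unknown parent (founders) get zeros: their parental
#' compositions are undefined and they carry no expected cross-bred
#' heterozygosity relative to the declared base.
#'
#' @param ped a `ped` object.
#' @param comp a `breed_comp` object from [propagate_breed_composition()].
#' @return data.frame with columns `id`, `het`, `rec`, `het_NA` ... `het_BC`,
#'   `rec_NA` ... `rec_BC`.
#' @export
covariate_table <- function(ped, comp) {
  S <- comp$alpha_s; D <- comp$alpha_d
  ok <- comp$has_parents
  het <- ifelse(ok, 1 - rowSums(S * D), 0)
  rec <- ifelse(ok, 1 - rowSums(S^2 + D^2) / 2, 0)
  out <- data.frame(id = comp$id, het = het, rec = rec,
                    stringsAsFactors = FALSE)
  for (k in seq_along(TYPE_PAIRS)) {
    ij <- match(TYPE_PAIRS[[k]], BREED_TYPES)
    i <- ij[1]; j <- ij[2]
    out[[paste0("het_", PAIR_LABELS[k])]] <-
      ifelse(ok, S[, i] * D[, j] + S[, j] * D[, i], 0)
    out[[paste0("rec_", PAIR_LABELS[k])]] <-
      ifelse(ok, S[, i] * S[, j] + D[, i] * D[, j], 0)
  }
  out
}
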