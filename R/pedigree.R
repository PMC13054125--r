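#' Build a sorted, recoded pedigree
#'
#' Constructs a pedigree object from animal/sire/dam tokens.  Animals are
#' recoded to consecutive 1-based integers with parents preceding offspring
#' (unknown parents are coded 0), a cycle check is performed, parents that are
#' referenced but never listed as animals are added as unknown-parent founders,
#' and inbreeding coefficients are computed with the Meuwissen-Luo algorithm.
#'
#' @param animal character vector of animal identifiers (must be unique).
#' @param sire,dam parent identifiers; `NA`, `""` or `"0"` mean unknown.
#' @param birth_year optional integer birth years; generation depth is used
#'   when absent.
#' @param extra optional data.frame of additional per-animal columns (e.g.
#'   sex), aligned with `animal`.
#' @return An object of class `ped`: a list with element `tab`, a data.frame
#'   in sorted order with columns `id`, `sire`, `dam`, `birth_year`,
#'   `sire_idx`, `dam_idx`, `founder`, `F`.  Row `i` of `tab` is the animal
#'   with internal code `i`; all relationship matrices produced from the
#'   object share this index.
#' @export
pedigree <- function(animal, sire = NULL, dam = NULL, birth_year = NULL,
                     extra = NULL) {
  animal <- as.character(animal)
  norm_parent <- function(p) {
    if (is.null(p)) return(rep(NA_character_, length(animal)))
    p <- as.character(p)
    p[!is.na(p) & (p == "" | p == "0")] <- NA_character_
    p
  }
  sire <- norm_parent(sire)
  dam <- norm_parent(dam)
  if (anyNA(animal) || any(animal == ""))
    stop2("missing animal identifiers")
  if (anyDuplicated(animal)) {
    dup <- unique(animal[duplicated(animal)])
    stop2("duplicate animal id(s): ", paste(head(dup, 5), collapse = ", "))
  }
  # parents referenced but never defined become unknown-parent founders
  referenced <- setdiff(unique(c(sire, dam)), c(animal, NA_character_))
  if (length(referenced)) {
    animal <- c(animal, referenced)
    sire <- c(sire, rep(NA_character_, length(referenced)))
    dam <- c(dam, rep(NA_character_, length(referenced)))
    if (!is.null(birth_year))
      birth_year <- c(birth_year, rep(NA_integer_, length(referenced)))
    if (!is.null(extra)) {
      pad <- extra[rep(NA_integer_, length(referenced)), , drop = FALSE]
      extra <- rbind(extra, pad)
    }
  }
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])

  # generation level by relaxation; failure to make progress reveals a cycle
  level <- rep(NA_integer_, n)
  level[si == 0L & di == 0L] <- 0L
  repeat {
    todo <- which(is.na(level))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      ls <- if (si[i] == 0L) -1L else level[si[i]]
      ld <- if (di[i] == 0L) -1L else level[di[i]]
      if (!is.na(ls) && !is.na(ld)) {
        level[i] <- max(ls, ld) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) {
      cyc <- animal[is.na(level)]
      stop2("pedigree contains a cycle involving: ",
            paste(head(cyc, 10), collapse = " -> "))
    }
  }
  by <- if (is.null(birth_year)) level else {
    b <- as.integer(birth_year)
    b[is.na(b)] <- min(b, na.rm = TRUE) - 1L
    b
  }
  ord <- order(level, by, idx)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  tab <- data.frame(
    id = animal[ord],
    sire = sire[ord],
    dam = dam[ord],
    birth_year = by[ord],
    sire_idx = ifelse(si[ord] == 0L, 0L, rank[pmax(si[ord], 1L)]),
    dam_idx = ifelse(di[ord] == 0L, 0L, rank[pmax(di[ord], 1L)]),
    stringsAsFactors = FALSE
  )
  tab$founder <- tab$sire_idx == 0L & tab$dam_idx == 0L
  if (!is.null(extra)) tab <- cbind(tab, extra[ord, , drop = FALSE])
  tab$F <- ml_inbreeding_cpp(tab$sire_idx, tab$dam_idx)
  rownames(tab) <- NULL
  structure(list(tab = tab, n = n), class = "ped")
}

#' Read a pedigree CSV file
#'
#' Expects columns `animal`, `sire`, `dam` and optionally `birth_year` plus
#' breed-fraction columns `typeN`, `typeA`, `typeB`, `typeC` (used by
#' [propagate_breed_composition()]).  `0` or empty parent fields mean unknown.
#'
#' @param path path to the CSV file.
#' @return a `ped` object; declared breed fractions, if present, are kept in
#'   the `tab` columns `typeN`..`typeC`.
#' @export
read_pedigree <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(animal = "character"))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop2("pedigree file must have columns: ", paste(need, collapse = ", "))
  extra_cols <- intersect(paste0("type", BREED_TYPES), names(df))
  extra <- if (length(extra_cols)) df[extra_cols] else NULL
  pedigree(df$animal, df$sire, df$dam,
           birth_year = if ("birth_year" %in% names(df)) df$birth_year,
           extra = extra)
}

#' @export
print.ped <- function(x, ...) {
  cat("Pedigree:", x$n, "animals,", sum(x$tab$founder), "founders, mean F =",
      signif(mean(x$tab$F), 3), "\n")
  invisible(x)
}

ped_index <- function(ped, ids) {
  i <- match(as.character(ids), ped$tab$id)
  if (anyNA(i))
    stop2("unknown animal id(s): ",
          paste(head(ids[is.na(i)], 5), collapse = ", "))
  i
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients by the Meuwissen-Luo recursive
#' algorithm (exact, and linear in pedigree depth per animal).  These are the
#' `F` used in the Mendelian-sampling variances of [a_inverse()] and in the
#' LR-method accuracy denominator.
#'
#' @param ped a `ped` object.
#' @return numeric vector of inbreeding coefficients in pedigree (sorted)
#'   order, named by animal id.
#' @export
inbreeding <- function(ped) {
  setNames(ped$tab$F, ped$tab$id)
}

# dense tabular (recursive) A over a recoded subpedigree
tabular_a <- function(sire_idx, dam_idx) {
  n <- length(sire_idx)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire_idx[i]; d <- dam_idx[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[j, s]
      if (d > 0L) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- if (s > 0L && d > 0L) 1 + 0.5 * A[s, d] else 1
  }
  A
}

# ancestor closure (internal indices, sorted ascending)
ancestor_closure <- function(ped, idx) {
  tab <- ped$tab
  keep <- logical(ped$n)
  keep[idx] <- TRUE
  # a single high-to-low pass marks all ancestors (parents have lower index)
  for (i in ped$n:1) {
    if (keep[i]) {
      s <- tab$sire_idx[i]; d <- tab$dam_idx[i]
      if (s > 0L) keep[s] <- TRUE
      if (d > 0L) keep[d] <- TRUE
    }
  }
  which(keep)
}

#' Numerator relationship matrix
#'
#' Additive (numerator) relationship matrix by the tabular method, restricted
#' to the requested animals.  Only the ancestor closure of `ids` is computed.
#'
#' @param ped a `ped` object.
#' @param ids animal ids to keep (default: all animals, in pedigree order).
#' @return a dense symmetric matrix with `dimnames` set to `ids`; diagonal
#'   equals `1 + F`.
#' @export
a_matrix <- function(ped, ids = NULL) {
  tab <- ped$tab
  idx <- if (is.null(ids)) seq_len(ped$n) else ped_index(ped, ids)
  closure <- ancestor_closure(ped, idx)
  remap <- integer(ped$n)
  remap[closure] <- seq_along(closure)
  s <- tab$sire_idx[closure]; d <- tab$dam_idx[closure]
  A <- tabular_a(ifelse(s > 0L, remap[pmax(s, 1L)], 0L),
                 ifelse(d > 0L, remap[pmax(d, 1L)], 0L))
  out <- A[remap[idx], remap[idx], drop = FALSE]
  dimnames(out) <- list(tab$id[idx], tab$id[idx])
  out
}

#' Pedigree relationship matrix of the genotyped animals
#'
#' `A22` of the single-step equations: the numerator relationship matrix
#' restricted to the genotyped subset (computed over the ancestor closure,
#' then subsetted, so it is exact).
#'
#' @param ped a `ped` object.
#' @param genotyped_ids ids of genotyped animals.
#' @return dense symmetric matrix in the order of `genotyped_ids`.
#' @export
a22_matrix <- function(ped, genotyped_ids) {
  if (length(genotyped_ids) == 0L) stop2("empty genotyped id list")
  a_matrix(ped, genotyped_ids)
}

# Mendelian sampling variances (unit additive variance)
mendelian_d <- function(ped) {
  tab <- ped$tab
  s <- tab$sire_idx; d <- tab$dam_idx
  Fs <- ifelse(s > 0L, tab$F[pmax(s, 1L)], NA_real_)
  Fd <- ifelse(d > 0L, tab$F[pmax(d, 1L)], NA_real_)
  ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
  ifelse(s > 0L, 0.75 - 0.25 * Fs,
  ifelse(d > 0L, 0.75 - 0.25 * Fd, 1)))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding-adjusted Mendelian-sampling variances:
#' A^-1 = sum_i alpha_i q_i q_i' with q_i the (1, -1/2, -1/2) incidence of
#' animal i on itself and its known parents and alpha_i = 1/d_i.
#'
#' @param ped a `ped` object.
#' @return sparse symmetric matrix (`dsCMatrix`) over all animals in pedigree
#'   order.
#' @export
a_inverse <- function(ped) {
  tab <- ped$tab
  n <- ped$n
  alpha <- 1 / mendelian_d(ped)
  i <- seq_len(n); s <- tab$sire_idx; d <- tab$dam_idx
  ii <- list(i); jj <- list(i); xx <- list(alpha)
  bs <- s > 0L; bd <- d > 0L
  add <- function(a, b, val) {
    ii[[length(ii) + 1L]] <<- a
    jj[[length(jj) + 1L]] <<- b
    xx[[length(xx) + 1L]] <<- val
  }
  if (any(bs)) {
    add(i[bs], s[bs], -alpha[bs] / 2); add(s[bs], i[bs], -alpha[bs] / 2)
    add(s[bs], s[bs], alpha[bs] / 4)
  }
  if (any(bd)) {
    add(i[bd], d[bd], -alpha[bd] / 2); add(d[bd], i[bd], -alpha[bd] / 2)
    add(d[bd], d[bd], alpha[bd] / 4)
  }
  both <- bs & bd
  if (any(both)) {
    add(s[both], d[both], alpha[both] / 4)
    add(d[both], s[both], alpha[both] / 4)
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n),
                            dimnames = list(tab$id, tab$id))
  forceSymmetric2(M)
}

#' Log-determinant of the numerator relationship matrix
#'
#' `log|A| = sum(log d_i)` from the L'DL decomposition implied by the
#' pedigree; used as the constant term of the REML log-likelihood.
#'
#' @param ped a `ped` object.
#' @return scalar `log|A|`.
#' @export
a_logdet <- function(ped) sum(log(mendelian_d(ped)))

#' Propagate breed composition down a pedigree
#'
#' Founder (unknown-parent) animals must have declared fractions over the four
#' biological types (N, A, B, C) summing to 1; every other animal gets the
#' mean of its parents' fractions.  The parents' own total fractions are
#' recorded per animal as the sire-side and dam-side contributions used by the
#' Dickerson crossbreeding covariates.
#'
#' @param ped a `ped` object.
#' @param founder_fractions data.frame with column `id` plus `typeN`, `typeA`,
#'   `typeB`, `typeC`.  May cover non-founders too (ignored for them); if
#'   omitted, the `typeN`..`typeC` columns stored on the pedigree are used.
#' @return object of class `breed_comp`: list with `id`, `alpha` (n x 4
#'   fractions), `alpha_s`, `alpha_d` (parents' fractions; zero rows when the
#'   parent is unknown) and `has_parents`.
#' @export
propagate_breed_composition <- function(ped, founder_fractions = NULL) {
  tab <- ped$tab
  tcols <- paste0("type", BREED_TYPES)
  if (is.null(founder_fractions)) {
    if (!all(tcols %in% names(tab)))
      stop2("no founder fractions supplied and none stored on the pedigree")
    founder_fractions <- data.frame(id = tab$id, tab[tcols])
  }
  if (!all(c("id", tcols) %in% names(founder_fractions)))
    stop2("founder_fractions needs columns id, ", paste(tcols, collapse = ", "))
  ff <- as.matrix(founder_fractions[tcols])
  rownames(ff) <- as.character(founder_fractions$id)

  n <- ped$n
  alpha <- matrix(NA_real_, n, 4, dimnames = list(tab$id, BREED_TYPES))
  alpha_s <- matrix(0, n, 4, dimnames = list(tab$id, BREED_TYPES))
  alpha_d <- matrix(0, n, 4, dimnames = list(tab$id, BREED_TYPES))
  declared <- match(tab$id, rownames(ff))
  for (i in seq_len(n)) {
    s <- tab$sire_idx[i]; d <- tab$dam_idx[i]
    if (s > 0L && d > 0L) {
      alpha_s[i, ] <- alpha[s, ]
      alpha_d[i, ] <- alpha[d, ]
      alpha[i, ] <- (alpha[s, ] + alpha[d, ]) / 2
    } else {
      j <- declared[i]
      if (is.na(j))
        stop2("animal '", tab$id[i],
              "' has an unknown parent and no declared breed fractions")
      fr <- ff[j, ]
      if (anyNA(fr) || abs(sum(fr) - 1) > 1e-8)
        stop2("breed fractions of '", tab$id[i],
              "' are missing or do not sum to 1")
      alpha[i, ] <- fr
      if (s > 0L) alpha_s[i, ] <- alpha[s, ]
      if (d > 0L) alpha_d[i, ] <- alpha[d, ]
    }
  }
  structure(list(id = tab$id, alpha = alpha, alpha_s = alpha_s,
                 alpha_d = alpha_d,
                 has_parents = tab$sire_idx > 0L & tab$dam_idx > 0L),
            class = "breed_comp")
}

# equivalent complete generations: sum over known ancestors of (1/2)^depth
equivalent_generations <- function(ped) {
  tab <- ped$tab
  ecg <- numeric(ped$n)
  for (i in seq_len(ped$n)) {
    s <- tab$sire_idx[i]; d <- tab$dam_idx[i]
    ecg[i] <- (if (s > 0L) 0.5 * (1 + ecg[s]) else 0) +
              (if (d > 0L) 0.5 * (1 + ecg[d]) else 0)
  }
  ecg
}

#' Pedigree summary statistics
#'
#' @param ped a `ped` object.
#' @return list with number of animals and founders, mean and maximum
#'   equivalent complete generations, mean inbreeding and the count of inbred
#'   animals.
#' @export
pedigree_summary <- function(ped) {
  ecg <- equivalent_generations(ped)
  list(n_animals = ped$n,
       n_founders = sum(ped$tab$founder),
       mean_equivalent_generations = mean(ecg),
       max_equivalent_generations = max(ecg),
       mean_inbreeding = mean(ped$tab$F),
       n_inbred = sum(ped$tab$F > 0))
}
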