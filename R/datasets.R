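## Label sets, reaction assembly and cross-validation folds.
##
## Molecule-type labels are size-intensive (kcal/mol per valence electron);
## reaction-type labels are extensive (kcal/mol). Each label row carries the
## uncorrected THC baseline prediction `y_base` in the same units, so that
## evaluation can always compare a model against "no correction".

#' Build molecule-level label sets
#'
#' `molecule`: the canonical MP3 total energy per valence electron; its
#' baseline prediction is the uncorrected THC-MP3b total.
#' `delta_molecule`: the THC error `E_MP3 - E_MP3b` per valence electron;
#' its baseline prediction is zero (no correction). Both in
#' kcal/mol/electron.
#'
#' @param suites list of [thc_energy_suite()] results.
#' @param kind `"molecule"` or `"delta_molecule"`.
#' @return data frame `id, kind, y, y_base, n_valence`.
#' @export
build_molecule_labels <- function(suites, kind = c("molecule", "delta_molecule")) {
  kind <- match.arg(kind)
  rows <- lapply(suites, function(s) {
    if (is.null(s$breakdowns$canonical) || is.null(s$breakdowns$mp3b))
      stop("build_molecule_labels: species ", s$species_id, " lacks a required variant")
    e_mp3 <- total_energy(s$breakdowns$canonical)
    e_mp3b <- total_energy(s$breakdowns$mp3b)
    nval <- s$system$n_valence
    if (kind == "molecule") {
      y <- hartree_to_kcal(e_mp3) / nval
      y_base <- hartree_to_kcal(e_mp3b) / nval
    } else {
      y <- hartree_to_kcal(e_mp3 - e_mp3b) / nval
      y_base <- 0
    }
    data.frame(id = s$species_id, kind = kind, y = y, y_base = y_base,
               n_valence = nval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stoichiometric reaction energy
#'
#' `dE = sum(nu_i * E_i)` over the scheme members (products positive,
#' reactants negative); with `normalize = TRUE` the result is divided by
#' `sum(|nu_i|)` (a training-only normalization).
#'
#' @param scheme a [reaction_scheme()].
#' @param values named numeric vector of per-species values.
#' @param normalize divide by the total number of reactants and products.
#' @return scalar reaction value in the units of `values`.
#' @export
reaction_energy <- function(scheme, values, normalize = FALSE) {
  missing <- setdiff(scheme$species_id, names(values))
  if (length(missing))
    stop("reaction_energy: missing species value(s): ", paste(missing, collapse = ", "))
  de <- sum(scheme$nu * values[scheme$species_id])
  if (normalize) de / sum(abs(scheme$nu)) else de
}

#' Build reaction-level label sets
#'
#' `reaction`: canonical MP3 reaction energies, baseline the THC-MP3b
#' reaction energies. `delta_reaction`: the THC reaction-energy error,
#' baseline zero. Both in kcal/mol (unnormalized).
#'
#' @param schemes list of [reaction_scheme()]s.
#' @param suites list of [thc_energy_suite()] results covering all members.
#' @param kind `"reaction"` or `"delta_reaction"`.
#' @return data frame `id, kind, y, y_base`.
#' @export
build_reaction_labels <- function(schemes, suites, kind = c("reaction", "delta_reaction")) {
  kind <- match.arg(kind)
  ids <- vapply(suites, function(s) s$species_id, "")
  e_mp3 <- stats::setNames(vapply(suites, function(s)
    hartree_to_kcal(total_energy(s$breakdowns$canonical)), 0), ids)
  e_mp3b <- stats::setNames(vapply(suites, function(s)
    hartree_to_kcal(total_energy(s$breakdowns$mp3b)), 0), ids)
  rows <- lapply(schemes, function(sch) {
    de <- reaction_energy(sch, e_mp3)
    de_b <- reaction_energy(sch, e_mp3b)
    if (kind == "reaction")
      data.frame(id = sch$reaction_id, kind = kind, y = de, y_base = de_b,
                 stringsAsFactors = FALSE)
    else
      data.frame(id = sch$reaction_id, kind = kind, y = de - de_b, y_base = 0,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Deterministic k-fold assignment
#'
#' Seeded shuffle followed by a round-robin split: fold sizes differ by at
#' most one, and the assignment is a pure function of `(N, k, seed)`.
#'
#' @param N number of rows.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices (1..k) per row.
#' @export
make_folds <- function(N, k, seed) {
  if (k > N) stop("make_folds: k must not exceed N")
  if (k < 2L) stop("make_folds: k must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(N)
  fold <- integer(N)
  fold[perm] <- rep_len(seq_len(k), N)
  fold
}

## Save/restore the global RNG state so seeded helpers do not perturb the
## caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
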