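#' Orbital system
#'
#' Container for the canonical orbital data of one closed-shell species:
#' orbital energies (Hartree), the active occupied/virtual partition, the
#' number of frozen-core orbitals, and the active valence-electron count.
#' Frozen orbitals are excluded from all stored blocks; `eps` holds only
#' active orbitals, occupied block first, each block ascending.
#'
#' @param species_id character id of the species.
#' @param eps numeric vector of active orbital energies in Hartree,
#'   occupied block first.
#' @param n_occ_active number of active occupied (spatial) orbitals.
#' @param n_vir number of virtual orbitals.
#' @param n_frozen number of frozen-core orbitals (bookkeeping only).
#' @param e_scf SCF reference energy in Hartree.
#' @return an object of class `orbital_system`.
#' @export
orbital_system <- function(species_id, eps, n_occ_active, n_vir,
                           n_frozen = 0L, e_scf = 0) {
  sys <- structure(
    list(
      species_id = as.character(species_id),
      eps = as.numeric(eps),
      n_occ_active = as.integer(n_occ_active),
      n_vir = as.integer(n_vir),
      n_frozen = as.integer(n_frozen),
      n_valence = 2L * as.integer(n_occ_active),
      e_scf = as.numeric(e_scf)
    ),
    class = "orbital_system"
  )
  validate_orbital_system(sys)
  sys
}

validate_orbital_system <- function(sys) {
  if (sys$n_occ_active < 1L) stop("orbital_system: n_occ_active must be >= 1")
  if (sys$n_vir < 1L) stop("orbital_system: n_vir must be >= 1")
  if (sys$n_frozen < 0L) stop("orbital_system: n_frozen must be >= 0")
  if (length(sys$eps) != sys$n_occ_active + sys$n_vir)
    stop("orbital_system: eps length must equal n_occ_active + n_vir")
  if (!all(is.finite(sys$eps))) stop("orbital_system: eps must be finite")
  occ <- sys$eps[seq_len(sys$n_occ_active)]
  vir <- sys$eps[sys$n_occ_active + seq_len(sys$n_vir)]
  if (max(occ) >= min(vir))
    stop("orbital_system: eps requires a positive HOMO-LUMO gap")
  if (is.unsorted(occ) || is.unsorted(vir))
    stop("orbital_system: eps blocks must be ascending")
  if (sys$n_valence != 2L * sys$n_occ_active)
    stop("orbital_system: n_valence must equal 2 * n_occ_active")
  invisible(sys)
}

#' @export
print.orbital_system <- function(x, ...) {
  cat(sprintf(
    "<orbital_system> %s: %d occ / %d vir (frozen %d), gap %.4f Eh, E_SCF %.6f Eh\n",
    x$species_id, x$n_occ_active, x$n_vir, x$n_frozen,
    homo_lumo_gap(x), x$e_scf
  ))
  invisible(x)
}

#' HOMO-LUMO gap and total eigenvalue span of an orbital system
#'
#' @param sys an `orbital_system`.
#' @return gap / span in Hartree.
#' @export
homo_lumo_gap <- function(sys) {
  sys$eps[sys$n_occ_active + 1L] - sys$eps[sys$n_occ_active]
}

#' @rdname homo_lumo_gap
#' @export
eigenvalue_span <- function(sys) {
  max(sys$eps) - min(sys$eps)
}

#' Density-fitting tensors
#'
#' Three-index density-fitting factors `B[p, q, J]` over the occupied-occupied,
#' occupied-virtual and virtual-virtual orbital-pair blocks, sharing the
#' auxiliary index J. Two-electron integrals in chemists' notation are
#' reconstructed as `(pq|rs) = sum_J B[p,q,J] B[r,s,J]`, which makes the
#' full pair matrix positive semidefinite by construction.
#'
#' @param B_oo,B_ov,B_vv three-index arrays (left orbital, right orbital, J).
#' @return an object of class `df_tensors`.
#' @export
df_tensors <- function(B_oo, B_ov, B_vv) {
  df <- structure(
    list(B_oo = B_oo, B_ov = B_ov, B_vv = B_vv,
         n_aux = dim(B_ov)[3]),
    class = "df_tensors"
  )
  validate_df_tensors(df)
  df
}

validate_df_tensors <- function(df) {
  for (nm in c("B_oo", "B_ov", "B_vv")) {
    B <- df[[nm]]
    if (!is.array(B) || length(dim(B)) != 3L)
      stop(sprintf("df_tensors: %s must be a 3-index array", nm))
    if (!all(is.finite(B))) stop(sprintf("df_tensors: %s must be finite", nm))
    if (dim(B)[3] != df$n_aux)
      stop(sprintf("df_tensors: %s auxiliary dimension mismatch", nm))
  }
  ## same-block pairs (oo, vv) come from real orbital products: B symmetric in (p,q)
  for (nm in c("B_oo", "B_vv")) {
    B <- df[[nm]]
    if (dim(B)[1] != dim(B)[2])
      stop(sprintf("df_tensors: %s must be square in its orbital indices", nm))
    if (max(abs(B - aperm(B, c(2, 1, 3)))) > 1e-10 * max(1, max(abs(B))))
      stop(sprintf("df_tensors: %s must be symmetric in its orbital pair", nm))
  }
  invisible(df)
}

#' Collocation matrices on a THC grid
#'
#' Values of the molecular orbitals of one pair block sampled at grid points:
#' `X_left[p, G]`, `X_right[q, G]`. For the same-occupancy pair types (`oo`,
#' `vv`) the left and right matrices are the same orbital block on the same
#' grid; for `ov` the left factor holds occupied and the right virtual
#' orbitals.
#'
#' @param pair_type one of `"oo"`, `"ov"`, `"vv"`.
#' @param X_left,X_right orbital-by-grid matrices.
#' @param grid_coords optional 3 x n_grid coordinates of the points.
#' @return an object of class `collocation`.
#' @export
collocation <- function(pair_type, X_left, X_right = X_left, grid_coords = NULL) {
  coll <- structure(
    list(pair_type = match.arg(pair_type, c("oo", "ov", "vv")),
         X_left = as.matrix(X_left), X_right = as.matrix(X_right),
         grid_coords = grid_coords, n_grid = ncol(X_left)),
    class = "collocation"
  )
  validate_collocation(coll)
  coll
}

validate_collocation <- function(coll) {
  if (coll$n_grid < 1L) stop("collocation: n_grid must be >= 1")
  if (ncol(coll$X_left) != ncol(coll$X_right))
    stop("collocation: X_left and X_right must share the grid dimension")
  if (!all(is.finite(coll$X_left)) || !all(is.finite(coll$X_right)))
    stop("collocation: entries must be finite")
  if (coll$pair_type %in% c("oo", "vv") &&
      !identical(dim(coll$X_left), dim(coll$X_right)))
    stop("collocation: same-occupancy pair types need matching left/right blocks")
  invisible(coll)
}

#' Subset a collocation to selected grid points
#'
#' @param coll a `collocation`.
#' @param idx integer vector of grid-point indices to keep (in order).
#' @return a `collocation` over the selected points.
#' @export
subset_grid <- function(coll, idx) {
  collocation(
    coll$pair_type,
    coll$X_left[, idx, drop = FALSE],
    coll$X_right[, idx, drop = FALSE],
    grid_coords = if (!is.null(coll$grid_coords)) coll$grid_coords[, idx, drop = FALSE]
  )
}

#' Reaction scheme
#'
#' A signed stoichiometric combination of species: products carry positive
#' stoichiometric numbers, reactants negative.
#'
#' @param reaction_id character id.
#' @param species_id character vector of member species.
#' @param nu integer vector of signed stoichiometric numbers.
#' @return an object of class `reaction_scheme`.
#' @export
reaction_scheme <- function(reaction_id, species_id, nu) {
  rs <- structure(
    list(reaction_id = as.character(reaction_id),
         species_id = as.character(species_id),
         nu = as.integer(nu)),
    class = "reaction_scheme"
  )
  validate_reaction_scheme(rs)
  rs
}

validate_reaction_scheme <- function(rs) {
  if (length(rs$species_id) != length(rs$nu))
    stop("reaction_scheme: species_id and nu lengths differ")
  if (any(rs$nu == 0L)) stop("reaction_scheme: nu must be nonzero")
  if (!any(rs$nu < 0L) || !any(rs$nu > 0L))
    stop(sprintf("reaction_scheme '%s': needs at least one reactant (nu < 0) and one product (nu > 0)",
                 rs$reaction_id))
  if (sum(abs(rs$nu)) < 2L)
    stop(sprintf("reaction_scheme '%s': sum of |nu| must be >= 2", rs$reaction_id))
  invisible(rs)
}

#' @export
print.reaction_scheme <- function(x, ...) {
  lhs <- x$nu < 0
  fmt <- function(i) paste(sprintf("%d %s", abs(x$nu[i]), x$species_id[i]), collapse = " + ")
  cat(sprintf("<reaction_scheme> %s: %s -> %s\n", x$reaction_id,
              fmt(which(lhs)), fmt(which(!lhs))))
  invisible(x)
}
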