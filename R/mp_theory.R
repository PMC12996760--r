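## Closed-shell DF-MP2/MP3 with the 10-component diagrammatic decomposition.
##
## Notation: physicists' two-electron integrals <pr|qs> relate to chemists'
## pair-factorized integrals by <pr|qs> = (pq|rs), and density fitting gives
## (pq|rs) = sum_J B[p,q,J] B[r,s,J]. Occupied labels i,j,m,n; virtuals
## a,b,e,f. Only opposite-spin (spatial-orbital) quantities appear in the
## closed-shell formulas.

#' Integral blocks for the closed-shell MP2/MP3 energy
#'
#' Builds the five dense integral blocks the correlation-energy contractions
#' need, from pair-space integral matrices in chemists' notation:
#' \describe{
#'   \item{g_oovv}{`[i,j,a,b] = <ij|ab> = (ia|jb)` — MP2 / amplitude block}
#'   \item{g_vvvv}{`[a,b,e,f] = <ab|ef> = (ae|bf)` — particle-particle ladder}
#'   \item{g_oooo}{`[m,n,i,j] = <mn|ij> = (mi|nj)` — hole-hole ladder}
#'   \item{g_ovov}{`[m,b,e,j] = <mb|ej> = (me|bj)` — ring (direct)}
#'   \item{g_ovov_x}{`[m,b,j,e] = <mb|je> = (mj|be)` — ring (cross, oo x vv)}
#' }
#'
#' @param G_ovov pair matrix `(ia|jb)` with column-major ov pairs
#'   (occupied index fastest) on both axes.
#' @param G_vvvv pair matrix `(ae|bf)`, vv pairs both axes.
#' @param G_oooo pair matrix `(mi|nj)`, oo pairs both axes.
#' @param G_oovv pair matrix `(mj|be)`, oo pairs on rows, vv pairs on columns.
#' @param no,nv numbers of active occupied / virtual orbitals.
#' @return an object of class `integral_blocks` (list of dense arrays).
#' @export
integral_blocks <- function(G_ovov, G_vvvv, G_oooo, G_oovv, no, nv) {
  ## (ia|jb)[(ia),(jb)] -> array [i,a,j,b] -> g_oovv[i,j,a,b]
  g_oovv <- aperm(array(G_ovov, c(no, nv, no, nv)), c(1, 3, 2, 4))
  ## (ae|bf) -> [a,e,b,f] -> g_vvvv[a,b,e,f]
  g_vvvv <- aperm(array(G_vvvv, c(nv, nv, nv, nv)), c(1, 3, 2, 4))
  ## (mi|nj) -> [m,i,n,j] -> g_oooo[m,n,i,j]
  g_oooo <- aperm(array(G_oooo, c(no, no, no, no)), c(1, 3, 2, 4))
  ## (me|bj) -> [m,e,j,b] -> g_ovov[m,b,e,j]
  g_ovov <- aperm(array(G_ovov, c(no, nv, no, nv)), c(1, 4, 2, 3))
  ## (mj|be) -> [m,j,b,e] -> g_ovov_x[m,b,j,e]
  g_ovov_x <- aperm(array(G_oovv, c(no, no, nv, nv)), c(1, 3, 2, 4))
  structure(list(g_oovv = g_oovv, g_vvvv = g_vvvv, g_oooo = g_oooo,
                 g_ovov = g_ovov, g_ovov_x = g_ovov_x, no = no, nv = nv),
            class = "integral_blocks")
}

#' @rdname integral_blocks
#' @param df a [df_tensors()] object; the density-fitted (exact within RI)
#'   pair matrices are formed as `B %*% t(B)` over flattened pairs.
#' @export
integral_blocks_from_df <- function(df) {
  validate_df_tensors(df)
  no <- dim(df$B_oo)[1]
  nv <- dim(df$B_vv)[1]
  Fov <- flatten_df(df$B_ov)
  Foo <- flatten_df(df$B_oo)
  Fvv <- flatten_df(df$B_vv)
  integral_blocks(
    G_ovov = Fov %*% t(Fov),
    G_vvvv = Fvv %*% t(Fvv),
    G_oooo = Foo %*% t(Foo),
    G_oovv = Foo %*% t(Fvv),
    no = no, nv = nv
  )
}

## Orbital-energy denominator D[i,j,a,b] = eps_i + eps_j - eps_a - eps_b.
energy_denominator <- function(system) {
  occ <- system$eps[seq_len(system$n_occ_active)]
  vir <- system$eps[system$n_occ_active + seq_len(system$n_vir)]
  no <- length(occ); nv <- length(vir)
  D <- outer(outer(occ, occ, `+`), outer(vir, vir, `+`), `-`)
  dim(D) <- c(no, no, nv, nv)
  D
}

#' First-order doubles amplitudes
#'
#' Canonical first-order amplitudes
#' `t[i,j,a,b] = g_oovv[i,j,a,b] / (eps_i + eps_j - eps_a - eps_b)`.
#' Singles vanish identically for a canonical reference and are never stored.
#'
#' @param system an [orbital_system()].
#' @param g_oovv dense `<ij|ab>` array.
#' @param tol_denom degeneracy guard: any `|denominator|` below this (Hartree)
#'   is an error, not a regularization.
#' @return amplitude array with the same shape as `g_oovv`.
#' @export
first_order_amplitudes <- function(system, g_oovv, tol_denom = 1e-8) {
  D <- energy_denominator(system)
  if (!identical(dim(D), dim(g_oovv)))
    stop("first_order_amplitudes: g_oovv shape does not match the system")
  small <- abs(D) < tol_denom
  if (any(small)) {
    idx <- which(small, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "first_order_amplitudes: near-degenerate denominator at (i=%d, j=%d, a=%d, b=%d)",
      idx[1], idx[2], idx[3], idx[4]))
  }
  g_oovv / D
}

#' MP2 correlation-energy components
#'
#' Closed-shell opposite-spin decomposition:
#' `E_C = 2 * sum(t[i,j,a,b] * g[i,j,a,b])`,
#' `E_X = -sum(t[j,i,a,b] * g[i,j,a,b])`.
#' The conventional spin components follow as `E_OS = E_C / 2` and
#' `E_SS = E_C / 2 + E_X` (derived, never stored).
#'
#' @param t doubles amplitudes `[i,j,a,b]`.
#' @param g_oovv integrals `<ij|ab>`.
#' @return named numeric `c(E_C, E_X)` in Hartree.
#' @export
mp2_components <- function(t, g_oovv) {
  if (!identical(dim(t), dim(g_oovv)))
    stop("mp2_components: shape mismatch between t and g_oovv")
  c(E_C = 2 * sum(t * g_oovv),
    E_X = -sum(aperm(t, c(2, 1, 3, 4)) * g_oovv))
}

#' The ten MP3 diagram components
#'
#' Computes the ten third-order contractions of the closed-shell correlation
#' energy in fixed printed-term order: the particle-particle ladder pair
#' (prefactors +2, -1 against `g_vvvv`), the hole-hole ladder pair
#' (+2, -1 against `g_oooo`), and the six ring terms
#' (+8, -4, -4, +2, -8, +4 against the two ring blocks). Each component is
#' one Goldstone diagram (E9/E10 each the sum of two Hermitian-conjugate
#' diagrams).
#'
#' @param t doubles amplitudes `[i,j,a,b]`.
#' @param blocks an [integral_blocks()] object.
#' @return numeric vector `E1 ... E10` in Hartree.
#' @export
mp3_components <- function(t, blocks) {
  no <- blocks$no; nv <- blocks$nv
  if (!identical(dim(t), c(no, no, nv, nv)))
    stop("mp3_components: amplitude shape does not match blocks")
  tT <- aperm(t, c(2, 1, 3, 4))              # t[j,i,a,b]

  ## ladder terms via (ij) x (ab) matricization
  M  <- matrix(t,  no * no, nv * nv)         # rows (ij), cols (ab)
  Mt <- matrix(tT, no * no, nv * nv)
  Gv <- matrix(blocks$g_vvvv, nv * nv, nv * nv)   # [(ab),(ef)] = <ab|ef>
  Go <- matrix(blocks$g_oooo, no * no, no * no)   # [(mn),(ij)] = <mn|ij>
  E1 <- 2 * sum((M %*% Gv) * M)
  E2 <- -sum((Mt %*% Gv) * M)
  MMt  <- M %*% t(M)                         # [(ij),(mn)]
  MtMt <- Mt %*% t(M)
  E3 <- 2 * sum(MMt * t(Go))
  E4 <- -sum(MtMt * t(Go))

  ## ring terms via (ia) x (jb) matricization
  A  <- matrix(aperm(t,  c(1, 3, 2, 4)), no * nv, no * nv)  # [(ia),(jb)] = t[i,j,a,b]
  At <- matrix(aperm(tT, c(1, 3, 2, 4)), no * nv, no * nv)  # [(ia),(jb)] = t[j,i,a,b]
  RJ <- matrix(aperm(blocks$g_ovov,   c(4, 2, 1, 3)), no * nv, no * nv) # [(jb),(me)] = <mb|ej>
  RK <- matrix(aperm(blocks$g_ovov_x, c(3, 2, 1, 4)), no * nv, no * nv) # [(jb),(me)] = <mb|je>
  AA  <- crossprod(A)        # [(jb),(me)] = sum_ia t[i,j,a,b] t[i,m,a,e]
  AtAt <- crossprod(At)
  AAt <- crossprod(A, At)    # [(jb),(me)] = sum_ia t[i,j,a,b] t[m,i,a,e]
  E5  <-  8 * sum(AA * RJ)
  E6  <- -4 * sum(AA * RK)
  E7  <- -4 * sum(AtAt * RK)
  E8  <-  2 * sum(AtAt * RJ)
  E9  <- -8 * sum(AAt * RJ)
  E10 <-  4 * sum(AAt * RK)

  stats::setNames(c(E1, E2, E3, E4, E5, E6, E7, E8, E9, E10),
                  paste0("E", 1:10))
}

#' Energy breakdown container
#'
#' Bundles the SCF reference, the MP2 components `E_C`/`E_X` and (for
#' MP3-bearing variants) the ten MP3 diagram components of one variant:
#' `canonical` (density-fitted reference), `mp2a` (THC integrals only),
#' `mp2b` (THC integrals and amplitudes) or `mp3b` (THC throughout).
#'
#' @param species_id species label.
#' @param variant one of `"canonical"`, `"mp2a"`, `"mp2b"`, `"mp3b"`.
#' @param e_scf,e_c,e_x energies in Hartree.
#' @param components numeric vector `E1...E10` (length 10), or `NULL` for
#'   MP2-only variants.
#' @return an object of class `energy_breakdown`.
#' @export
energy_breakdown <- function(species_id, variant, e_scf, e_c, e_x,
                             components = NULL) {
  variant <- match.arg(variant, c("canonical", "mp2a", "mp2b", "mp3b"))
  if (!is.null(components)) {
    if (length(components) != 10L || !all(is.finite(components)))
      stop("energy_breakdown: components must be 10 finite values")
    components <- stats::setNames(as.numeric(components), paste0("E", 1:10))
  }
  structure(
    list(species_id = species_id, variant = variant,
         e_scf = unname(as.numeric(e_scf)), e_c = unname(as.numeric(e_c)),
         e_x = unname(as.numeric(e_x)), components = components),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> %s [%s]: E_SCF %.8f, E_C %.8f, E_X %.8f",
              x$species_id, x$variant, x$e_scf, x$e_c, x$e_x))
  if (!is.null(x$components))
    cat(sprintf(", sum(E1..E10) %.8f", sum(x$components)))
  cat("\n")
  invisible(x)
}

#' Total and parameterized energies of a breakdown
#'
#' With all scaling coefficients equal to one, `total_energy()` returns
#' `E_SCF + E_C + E_X + sum(E_n)`. `parameterized_energy()` evaluates the
#' component-scaled energy: in the `absolute` basis
#' `E_SCF + E_C + E_X + sum(c_n * E_n)`; in the `delta` basis the correction
#' `sum(c'_n * E_n)` with `c'_n = c_n - 1`, so that
#' `parameterized(c, absolute) - total == parameterized(c - 1, delta)`
#' identically.
#'
#' @param bd an [energy_breakdown()] with MP3 components.
#' @param c numeric vector of 10 scaling coefficients.
#' @param basis `"absolute"` (coefficients `c_n`) or `"delta"`
#'   (difference coefficients `c'_n = c_n - 1`).
#' @return energy in Hartree.
#' @export
parameterized_energy <- function(bd, c, basis = c("absolute", "delta")) {
  basis <- match.arg(basis)
  if (is.null(bd$components))
    stop("parameterized_energy: breakdown variant '", bd$variant,
         "' carries no MP3 components")
  if (length(c) != 10L || !all(is.finite(c)))
    stop("parameterized_energy: c must be 10 finite coefficients")
  if (basis == "absolute")
    bd$e_scf + bd$e_c + bd$e_x + sum(c * bd$components)
  else
    sum(c * bd$components)
}

#' @rdname parameterized_energy
#' @export
total_energy <- function(bd) {
  bd$e_scf + bd$e_c + bd$e_x +
    if (is.null(bd$components)) 0 else sum(bd$components)
}

#' MP2-level correlation total of a breakdown
#' @rdname parameterized_energy
#' @export
mp2_energy <- function(bd) bd$e_scf + bd$e_c + bd$e_x

#' Serialize energy breakdowns to a data frame / CSV
#'
#' One row per breakdown: `species_id, variant, E_SCF, E_C, E_X, E1...E10`
#' (Hartree; missing components are `NA` for MP2-only variants).
#'
#' @param breakdowns list of [energy_breakdown()] objects.
#' @return a `data.frame`.
#' @export
breakdown_table <- function(breakdowns) {
  rows <- lapply(breakdowns, function(bd) {
    comp <- bd$components %||% stats::setNames(rep(NA_real_, 10), paste0("E", 1:10))
    cbind(data.frame(species_id = bd$species_id, variant = bd$variant,
                     E_SCF = bd$e_scf, E_C = bd$e_c, E_X = bd$e_x,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(comp)))
  })
  do.call(rbind, rows)
}

#' @rdname breakdown_table
#' @param tab a data frame in `breakdown_table()` layout.
#' @return list of [energy_breakdown()] objects.
#' @export
breakdowns_from_table <- function(tab) {
  lapply(seq_len(nrow(tab)), function(r) {
    comp <- as.numeric(tab[r, paste0("E", 1:10)])
    energy_breakdown(tab$species_id[r], tab$variant[r],
                     tab$E_SCF[r], tab$E_C[r], tab$E_X[r],
                     components = if (!anyNA(comp)) comp)
  })
}
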