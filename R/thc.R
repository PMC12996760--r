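## Least-squares tensor hypercontraction (LS-THC).
##
## A four-index integral block in chemists' pair form, g[(pq),(rs)], is
## factorized through grid collocation matrices X and a small core matrix V:
##   g[(pq),(rs)] ~ sum_PQ X_left[p,P] X_right[q,P] V[P,Q] X_left[r,Q] X_right[s,Q]
## The core is the least-squares minimizer of the Frobenius reconstruction
## residual, obtained from the grid metric S and the density-fitted factors.

#' Grid metric of a collocation
#'
#' `S[P,Q] = sum_pq X_left[p,P] X_right[q,P] X_left[p,Q] X_right[q,Q]`, the
#' Gram matrix of the grid's orbital-pair products; equal to the elementwise
#' (Hadamard) product of the left and right orbital Gram matrices. Symmetric
#' positive semidefinite by construction.
#'
#' @param coll a [collocation()].
#' @return `n_grid x n_grid` metric matrix.
#' @export
fit_metric <- function(coll) {
  crossprod(coll$X_left) * crossprod(coll$X_right)
}

#' Prune a parent grid by pivoted Cholesky factorization
#'
#' Runs a greedy pivoted Cholesky factorization of the parent grid metric,
#' selecting points in pivot order (largest residual diagonal first, lowest
#' index on exact ties) while the current pivot diagonal stays at or above
#' `10^-delta` times the largest initial diagonal. Smaller `delta` keeps
#' fewer points: a cheaper, less accurate THC factorization.
#'
#' @param parent a parent-grid [collocation()].
#' @param delta positive pruning tolerance exponent.
#' @return the sub-collocation of the selected points, with attributes
#'   `selected` (parent indices in pivot order) and `parent_n_grid`.
#' @export
prune_grid <- function(parent, delta) {
  stopifnot(delta > 0)
  S <- fit_metric(parent)
  n <- nrow(S)
  d <- diag(S)
  dmax0 <- max(d)
  if (dmax0 <= 0)
    stop("prune_grid: all metric diagonals vanish; no grid point can be selected")
  thresh <- 10^(-delta) * dmax0
  L <- matrix(0, n, n)
  selected <- integer(0)
  for (k in seq_len(n)) {
    avail <- setdiff(seq_len(n), selected)
    p <- avail[which.max(d[avail])]     # which.max takes the lowest index on ties
    if (d[p] < thresh) break
    lk <- S[, p] - if (k > 1) L[, seq_len(k - 1), drop = FALSE] %*% L[p, seq_len(k - 1)] else 0
    lk <- as.numeric(lk) / sqrt(d[p])
    L[, k] <- lk
    d <- pmax(d - lk^2, 0)
    selected <- c(selected, p)
  }
  if (length(selected) == 0L)
    stop("prune_grid: selection is empty; adjust delta or the parent grid")
  out <- subset_grid(parent, selected)
  attr(out, "selected") <- selected
  attr(out, "parent_n_grid") <- n
  out
}

#' Least-squares THC core matrix
#'
#' Fits the core `V` of one integral block pairing by projecting each
#' density-fitting factor onto the grid and solving the normal equations
#' with pseudo-inverted metrics:
#' `V = pinv(S_bra) %*% (P_bra' B_bra) %*% (P_ket' B_ket)' %*% pinv(S_ket)`,
#' where `P` is the grid pair-product basis. This is the minimizer of
#' `|| g - P_bra V P_ket' ||_F` over the density-fitted block
#' `g = B_bra %*% t(B_ket)` (flattened pairs).
#'
#' @param bra,ket (pruned) [collocation()]s for the two pair blocks.
#' @param B_bra,B_ket three-index DF factors of the two blocks.
#' @param rtol relative eigenvalue cutoff of the metric pseudo-inverse.
#' @return core matrix `V` (`n_grid_bra x n_grid_ket`), with attribute
#'   `ranks = c(bra, ket)` holding the metric pseudo-inverse ranks.
#' @export
fit_core_v <- function(bra, ket, B_bra, B_ket, rtol = 1e-10) {
  Pb <- pair_basis(bra)
  Pk <- pair_basis(ket)
  Fb <- flatten_df(B_bra)
  Fk <- flatten_df(B_ket)
  sb <- psd_pinv(fit_metric(bra), rtol)
  sk <- psd_pinv(fit_metric(ket), rtol)
  solve1 <- function(G) sb$pinv %*% crossprod(Pb, G) %*% Pk %*% sk$pinv
  G <- Fb %*% t(Fk)
  V <- solve1(G)
  ## iterative refinement against metric ill-conditioning (see fit_core_t1)
  for (it in 1:2) V <- V + solve1(G - Pb %*% V %*% t(Pk))
  attr(V, "ranks") <- c(bra = sb$rank, ket = sk$rank)
  V
}

#' Reconstruct a dense integral block from THC factors
#'
#' `g_THC[(pq),(rs)] = P_bra %*% V %*% t(P_ket)` with `P` the pair-product
#' bases; rows/columns are column-major orbital pairs (left index fastest),
#' the layout [integral_blocks()] consumes.
#'
#' @param bra,ket [collocation()]s.
#' @param V core matrix.
#' @return dense pair matrix.
#' @export
reconstruct_integrals <- function(bra, ket, V) {
  Pb <- pair_basis(bra)
  Pk <- pair_basis(ket)
  if (!identical(dim(V), c(ncol(Pb), ncol(Pk))))
    stop("reconstruct_integrals: core shape does not match the grids")
  Pb %*% V %*% t(Pk)
}

#' Least-squares THC core for the first-order amplitudes
#'
#' Fits the amplitude core `T1` so that the THC reconstruction approximates
#' the denominator-weighted THC integrals
#' `t~[i,j,a,b] = g_THC[i,j,a,b] / (eps_i + eps_j - eps_a - eps_b)` in the
#' same least-squares normal-equation form as the integral core, on the
#' occupied-virtual grid. The fit is performed densely.
#'
#' @param ov (pruned) occupied-virtual [collocation()].
#' @param g_thc_oovv dense THC-approximated `<ij|ab>` array.
#' @param system an [orbital_system()].
#' @param rtol metric pseudo-inverse cutoff.
#' @param tol_denom degeneracy guard for the denominators.
#' @return core matrix `T1` (`n_grid x n_grid`).
#' @export
fit_core_t1 <- function(ov, g_thc_oovv, system, rtol = 1e-10, tol_denom = 1e-8) {
  t_target <- first_order_amplitudes(system, g_thc_oovv, tol_denom = tol_denom)
  no <- system$n_occ_active; nv <- system$n_vir
  Tm <- matrix(aperm(t_target, c(1, 3, 2, 4)), no * nv, no * nv)  # [(ia),(jb)]
  P <- pair_basis(ov)
  sp <- psd_pinv(fit_metric(ov), rtol)
  solve1 <- function(R) sp$pinv %*% crossprod(P, R) %*% P %*% sp$pinv
  T1 <- solve1(Tm)
  ## two steps of iterative refinement: the metric can be ill-conditioned
  ## near the complete-grid limit, and refinement restores the least-squares
  ## residual to working precision
  for (it in 1:2) T1 <- T1 + solve1(Tm - P %*% T1 %*% t(P))
  T1
}

#' Reconstruct amplitudes from the THC amplitude core
#'
#' @param ov [collocation()] used for the fit.
#' @param T1 amplitude core.
#' @param no,nv occupied/virtual dimensions.
#' @return dense amplitude array `[i,j,a,b]`.
#' @export
reconstruct_amplitudes <- function(ov, T1, no, nv) {
  P <- pair_basis(ov)
  Tm <- P %*% T1 %*% t(P)                      # [(ia),(jb)]
  aperm(array(Tm, c(no, nv, no, nv)), c(1, 3, 2, 4))
}

## Projection of a DF factor onto the THC grid basis (for goodness-of-fit):
## each auxiliary column of the flattened B is replaced by its least-squares
## representation in the span of the grid pair products.
project_df_on_grid <- function(B, coll, rtol = 1e-10) {
  P <- pair_basis(coll)
  sp <- psd_pinv(fit_metric(coll), rtol)
  Bf <- flatten_df(B)
  proj <- P %*% (sp$pinv %*% crossprod(P, Bf))
  array(proj, dim(B))
}

#' THC energy suite for one system
#'
#' Runs the full LS-THC pipeline on one archived system at a given pruning
#' tolerance and returns the canonical density-fitted breakdown together
#' with the three THC variants:
#' \describe{
#'   \item{canonical}{DF integrals, exact amplitudes — the reference.}
#'   \item{mp2a}{integrals THC-approximated; amplitudes by exact division
#'     of the THC integrals (approximation of the integrals only).}
#'   \item{mp2b}{integrals and amplitudes both THC-approximated.}
#'   \item{mp3b}{as mp2b, plus the ten THC-MP3 diagram components.}
#' }
#' Distinct pruned grids are used for the oo, ov and vv pair types. A
#' fit-quality sidecar reports per pair type the goodness of fit
#' `f = 1 - ||B - B_THC||_F / ||B||_F` and the parent/pruned grid sizes.
#'
#' @param sys_data list with `system`, `df`, `grids` (as returned by
#'   [read_system_archive()] or [generate_system()]).
#' @param delta pruning tolerance exponent (`10^-delta` threshold).
#' @param rtol metric pseudo-inverse cutoff.
#' @return an object of class `thc_suite`: list with `breakdowns`
#'   (named list canonical/mp2a/mp2b/mp3b of [energy_breakdown()]),
#'   `fits` (data frame: species_id, pair_type, f, n_grid_parent,
#'   n_grid_pruned), and `norms` (Frobenius and max-abs norms of the
#'   density-fitted `g_oovv` and amplitudes).
#' @export
thc_energy_suite <- function(sys_data, delta, rtol = 1e-10) {
  system <- sys_data$system; df <- sys_data$df; grids <- sys_data$grids
  validate_orbital_system(system)
  no <- system$n_occ_active; nv <- system$n_vir
  sid <- system$species_id

  ## canonical DF reference
  blocks_df <- integral_blocks_from_df(df)
  t_df <- first_order_amplitudes(system, blocks_df$g_oovv)
  mp2_df <- mp2_components(t_df, blocks_df$g_oovv)
  e3_df <- mp3_components(t_df, blocks_df)
  canonical <- energy_breakdown(sid, "canonical", system$e_scf,
                                mp2_df["E_C"], mp2_df["E_X"], e3_df)

  ## prune grids per pair type, fit cores
  pruned <- lapply(c(oo = "oo", ov = "ov", vv = "vv"),
                   function(pt) prune_grid(grids[[pt]], delta))
  V_ovov <- fit_core_v(pruned$ov, pruned$ov, df$B_ov, df$B_ov, rtol)
  V_vvvv <- fit_core_v(pruned$vv, pruned$vv, df$B_vv, df$B_vv, rtol)
  V_oooo <- fit_core_v(pruned$oo, pruned$oo, df$B_oo, df$B_oo, rtol)
  V_oovv <- fit_core_v(pruned$oo, pruned$vv, df$B_oo, df$B_vv, rtol)

  blocks_thc <- integral_blocks(
    G_ovov = reconstruct_integrals(pruned$ov, pruned$ov, V_ovov),
    G_vvvv = reconstruct_integrals(pruned$vv, pruned$vv, V_vvvv),
    G_oooo = reconstruct_integrals(pruned$oo, pruned$oo, V_oooo),
    G_oovv = reconstruct_integrals(pruned$oo, pruned$vv, V_oovv),
    no = no, nv = nv
  )

  ## mp2a: exact division of the THC integrals
  t_a <- first_order_amplitudes(system, blocks_thc$g_oovv)
  mp2a_c <- mp2_components(t_a, blocks_thc$g_oovv)
  mp2a <- energy_breakdown(sid, "mp2a", system$e_scf, mp2a_c["E_C"], mp2a_c["E_X"])

  ## mp2b / mp3b: amplitudes THC-reconstructed from the fitted core
  T1 <- fit_core_t1(pruned$ov, blocks_thc$g_oovv, system, rtol)
  t_b <- reconstruct_amplitudes(pruned$ov, T1, no, nv)
  mp2b_c <- mp2_components(t_b, blocks_thc$g_oovv)
  mp2b <- energy_breakdown(sid, "mp2b", system$e_scf, mp2b_c["E_C"], mp2b_c["E_X"])
  e3_b <- mp3_components(t_b, blocks_thc)
  mp3b <- energy_breakdown(sid, "mp3b", system$e_scf, mp2b_c["E_C"], mp2b_c["E_X"], e3_b)

  gof <- function(B, pt) goodness_of_fit(B, project_df_on_grid(B, pruned[[pt]], rtol))
  fits <- data.frame(
    species_id = sid,
    pair_type = c("oo", "ov", "vv"),
    f = c(gof(df$B_oo, "oo"), gof(df$B_ov, "ov"), gof(df$B_vv, "vv")),
    n_grid_parent = vapply(c("oo", "ov", "vv"), function(pt) grids[[pt]]$n_grid, 0L),
    n_grid_pruned = vapply(c("oo", "ov", "vv"), function(pt) pruned[[pt]]$n_grid, 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )

  norms <- list(
    norm_g_F = sqrt(sum(blocks_df$g_oovv^2)),
    norm_t_F = sqrt(sum(t_df^2)),
    norm_g_inf = max(abs(blocks_df$g_oovv)),
    norm_t_inf = max(abs(t_df))
  )

  structure(
    list(species_id = sid, delta = delta, system = system,
         breakdowns = list(canonical = canonical, mp2a = mp2a,
                           mp2b = mp2b, mp3b = mp3b),
         fits = fits, norms = norms,
         pruned = pruned, cores = list(ovov = V_ovov, vvvv = V_vvvv,
                                       oooo = V_oooo, oovv = V_oovv, T1 = T1)),
    class = "thc_suite"
  )
}

#' @export
print.thc_suite <- function(x, ...) {
  cat(sprintf("<thc_suite> %s at delta = %g\n", x$species_id, x$delta))
  cat(sprintf("  E_MP3 (canonical) = %.8f Eh, E_MP3b = %.8f Eh, error = %.3e Eh\n",
              total_energy(x$breakdowns$canonical),
              total_energy(x$breakdowns$mp3b),
              total_energy(x$breakdowns$canonical) - total_energy(x$breakdowns$mp3b)))
  invisible(x)
}
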