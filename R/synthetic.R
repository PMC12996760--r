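## Seeded synthetic generators: closed-shell model systems with
## density-fitting factors and parent collocation grids, reaction schemes,
## and planted regression datasets. A corpus is a structural *family*: one
## master template (orbital-energy ladder, collocation template, auxiliary
## mixing pool) drawn from the corpus seed, with each species a truncation
## plus small perturbation of it. This emulates a benchmark set of related
## main-group molecules computed with one basis-set/parent-grid protocol —
## the regime where THC errors are systematic across species — not real
## chemistry.

#' Generator configuration
#'
#' @param seed global integer seed. The corpus-level master template derives
#'   from counter 0, each species from its own counter, so a corpus can be
#'   extended without reshuffling existing species.
#' @param n_occ_range,n_vir_range,n_aux_range inclusive integer ranges for
#'   the per-species active occupied, virtual and auxiliary dimensions.
#' @param grid_mult parent grid points per orbital (each pair type's parent
#'   grid has `grid_mult * (n_left + n_right)` points).
#' @param gap_min minimum HOMO-LUMO gap (Hartree), enforced by shifting the
#'   virtual block when a perturbation closes the gap.
#' @param orb_decay stretched-exponential decay exponent of the collocation
#'   template's orbital weights, `w_r = exp(-orb_decay * sqrt(r - 1))`:
#'   controls how steeply the pair-metric spectrum falls, hence how the
#'   pruned grid and the THC error respond to `delta`.
#' @param orb_floor lower floor on the orbital weights; keeps the complete
#'   grid's metric comfortably above the pseudo-inverse cutoff so the
#'   exact-grid limit is numerically exact.
#' @param df_scale root-mean-square magnitude of the DF factors; sets the
#'   correlation-energy scale (default gives MP2 energies of a few
#'   hundredths of a Hartree at the default sizes).
#' @param df_decay optional geometric damping (per metric direction, in
#'   (0, 1]) of the DF factors' content along the higher pair-metric
#'   directions; 1 = undamped.
#' @param family_spread magnitude of per-species perturbations: orbital
#'   energies are jittered by `0.1 * family_spread` Hartree and the SCF
#'   energy by `family_spread` Hartree around its size trend.
#' @param c_true,bump_amplitude,bump_bandwidth,noise_sd planted-regression
#'   parameters: linear coefficients, Gaussian-bump amplitude and length
#'   scale, and label noise.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_occ_range = c(2L, 4L),
                             n_vir_range = c(4L, 8L),
                             n_aux_range = c(20L, 40L),
                             grid_mult = 3L,
                             gap_min = 0.3,
                             orb_decay = 2.5,
                             orb_floor = 0.03,
                             df_scale = 0.025,
                             df_decay = 1.0,
                             family_spread = 0.1,
                             c_true = NULL,
                             bump_amplitude = 0,
                             bump_bandwidth = 1,
                             noise_sd = 0) {
  stopifnot(gap_min > 0, df_decay > 0, df_decay <= 1, noise_sd >= 0,
            n_occ_range[1] >= 1, n_vir_range[1] >= 1, n_aux_range[1] >= 1,
            grid_mult >= 1, orb_decay > 0, orb_floor > 0, family_spread >= 0)
  structure(list(seed = as.integer(seed),
                 n_occ_range = as.integer(n_occ_range),
                 n_vir_range = as.integer(n_vir_range),
                 n_aux_range = as.integer(n_aux_range),
                 grid_mult = as.integer(grid_mult),
                 gap_min = gap_min, orb_decay = orb_decay,
                 orb_floor = orb_floor,
                 df_scale = df_scale, df_decay = df_decay,
                 family_spread = family_spread,
                 c_true = c_true,
                 bump_amplitude = bump_amplitude,
                 bump_bandwidth = bump_bandwidth, noise_sd = noise_sd),
            class = "generator_config")
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)

## Corpus-level master template: orbital-energy ladders at the maximum
## dimensions, one collocation template per occupancy block (orthogonal
## mixing of stretched-exponentially weighted rows), and a Gaussian pool for
## the auxiliary mixing. Every species is derived from this.
family_master <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, 0L))
  no_max <- cfg$n_occ_range[2]
  nv_max <- cfg$n_vir_range[2]
  naux_max <- cfg$n_aux_range[2]
  ng_max <- cfg$grid_mult * (no_max + nv_max) * 2L
  template <- function(n) {
    w <- pmax(exp(-cfg$orb_decay * sqrt(seq_len(n) - 1)), cfg$orb_floor)
    U <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
    U %*% (w * matrix(stats::rnorm(n * ng_max), n, ng_max))
  }
  list(
    occ_ladder = sort(stats::runif(no_max, -1.4, -0.5)),
    vir_ladder = sort(stats::runif(nv_max, -0.05, 1.8)),
    X_occ = template(no_max),
    X_vir = template(nv_max),
    aux_pool = matrix(stats::rnorm(naux_max^2 * 4), 2L * naux_max, 2L * naux_max)
  )
}

#' Generate one synthetic system
#'
#' Draws one closed-shell model species of the corpus family: active
#' dimensions sampled from the configured ranges; orbital energies taken
#' from the master ladders (occupied around -1.4..-0.5 Hartree, virtuals up
#' to ~1.8) with a small per-species jitter and a positive gap of at least
#' `gap_min`; per-pair-type parent collocation grids cut from the shared
#' master template; and an SCF reference energy following a size trend.
#'
#' The three-index DF factors are built spectrally aligned with the parent
#' grid's pair metric — `B = P Q_k diag(d) Omega`, with `P` the grid pair
#' products, `Q/lambda` the metric eigensystem, `d` an optional damping and
#' `Omega` a semi-orthogonal auxiliary mixing drawn from the master pool —
#' the way real orbital-product densities live in the span of orbital
#' products at grid points. The integral pair matrix `B B'` is therefore
#' positive semidefinite by construction, exactly representable on the
#' complete grid, and its pruning residual is a systematic spectral tail,
#' so THC errors behave consistently across the corpus (as they do for real
#' molecules computed with one grid protocol) rather than as idiosyncratic
#' noise. Deterministic in `(cfg$seed, index)`.
#'
#' @param cfg a [generator_config()].
#' @param index species counter within the corpus (>= 1).
#' @param master optional precomputed corpus master template (an
#'   optimization used by [generate_corpus()]); derived from `cfg` when
#'   missing.
#' @return list with `system`, `df`, `grids` (archive contents).
#' @export
generate_system <- function(cfg, index, master = NULL) {
  if (is.null(master)) master <- family_master(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, index))

  no <- sample_range(cfg$n_occ_range)
  nv <- sample_range(cfg$n_vir_range)
  naux <- sample_range(cfg$n_aux_range)
  eps_jit <- 0.1 * cfg$family_spread

  occ <- sort(master$occ_ladder[seq_len(no)] + eps_jit * stats::rnorm(no))
  vir <- sort(master$vir_ladder[seq_len(nv)] + eps_jit * stats::rnorm(nv))
  if (max(occ) + cfg$gap_min > min(vir))
    vir <- vir + (max(occ) + cfg$gap_min - min(vir))
  e_scf <- -(5 + 2 * (no + nv) + cfg$family_spread * stats::rnorm(1))
  sys <- orbital_system(sprintf("syn%04d", index), c(occ, vir), no, nv,
                        n_frozen = sample(0:2, 1), e_scf = e_scf)

  mk_grid <- function(pt, nl, nr) {
    ng <- cfg$grid_mult * (nl + nr)
    Xl <- master[[if (pt == "vv") "X_vir" else "X_occ"]][seq_len(nl), seq_len(ng), drop = FALSE]
    if (pt == "ov") {
      Xr <- master$X_vir[seq_len(nr), seq_len(ng), drop = FALSE]
      collocation("ov", Xl, Xr)
    } else {
      collocation(pt, Xl)
    }
  }
  grids <- list(oo = mk_grid("oo", no, no),
                ov = mk_grid("ov", no, nv),
                vv = mk_grid("vv", nv, nv))

  grid_df <- function(coll, pool_row) {
    P <- pair_basis(coll)
    ee <- eigen(crossprod(P), symmetric = TRUE)
    k <- min(naux, sum(ee$values > 1e-8 * max(ee$values)))
    damp <- cfg$df_decay^(seq_len(k) - 1)
    Om <- t(qr.Q(qr(master$aux_pool[pool_row + seq_len(naux), seq_len(k), drop = FALSE])))
    Bf <- P %*% ee$vectors[, seq_len(k), drop = FALSE] %*% (damp * Om)
    Bf <- Bf * (cfg$df_scale / sqrt(mean(Bf^2)))
    array(Bf, c(nrow(coll$X_left), nrow(coll$X_right), naux))
  }
  B_oo <- grid_df(grids$oo, 0L)
  B_vv <- grid_df(grids$vv, cfg$n_aux_range[2])
  B_ov <- grid_df(grids$ov, 2L * cfg$n_aux_range[2] - naux)
  ## symmetrize same-occupancy blocks (P rows are already symmetric pairs;
  ## this only removes roundoff asymmetry)
  B_oo <- (B_oo + aperm(B_oo, c(2, 1, 3))) / 2
  B_vv <- (B_vv + aperm(B_vv, c(2, 1, 3))) / 2
  df <- df_tensors(B_oo, B_ov, B_vv)
  list(system = sys, df = df, grids = grids)
}

#' Generate a synthetic corpus
#'
#' @param cfg a [generator_config()].
#' @param n number of species.
#' @return list of system archives (contents of [generate_system()]).
#' @export
generate_corpus <- function(cfg, n) {
  master <- family_master(cfg)
  lapply(seq_len(n), function(i) generate_system(cfg, i, master))
}

#' Generate random reaction schemes
#'
#' Each scheme has 2-5 distinct member species with stoichiometric numbers
#' in `{-2, -1, 1, 2}` and at least one reactant and one product.
#' Deterministic under the seed.
#'
#' @param species_ids available species ids (at least 2).
#' @param n_rxn number of schemes.
#' @param seed integer seed.
#' @return list of [reaction_scheme()]s.
#' @export
generate_reactions <- function(species_ids, n_rxn, seed) {
  if (length(species_ids) < 2L)
    stop("generate_reactions: need at least 2 species")
  if (n_rxn == 0L) return(list())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 999983L))
  lapply(seq_len(n_rxn), function(r) {
    m_max <- min(5L, length(species_ids))
    m <- if (m_max == 2L) 2L else sample(seq(2L, m_max), 1)
    ids <- sample(species_ids, m)
    signs <- c(-1L, 1L, sample(c(-1L, 1L), m - 2L, replace = TRUE))
    nu <- signs * sample(1:2, m, replace = TRUE)
    reaction_scheme(sprintf("rxn%04d", r), ids, nu)
  })
}

#' Generate a planted regression dataset
#'
#' `y = X c_true + A exp(-||x - x0||^2 / (2 l^2)) + eps`,
#' `eps ~ N(0, sigma^2)`: a linear signal with an optional localized
#' Gaussian bump (the nonlinearity a kernel model can exploit and a linear
#' model cannot).
#'
#' @param cfg a [generator_config()]; uses `c_true`, `bump_amplitude`,
#'   `bump_bandwidth`, `noise_sd`, `seed`.
#' @param N,K rows and feature count.
#' @return list `X`, `y`, `truth` (the planted parameters).
#' @export
generate_planted_regression <- function(cfg, N, K) {
  stopifnot(N >= 1, K >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, 424243L))
  c_true <- cfg$c_true %||% stats::runif(K, -2, 2)
  if (length(c_true) != K) stop("generate_planted_regression: c_true must have length K")
  X <- matrix(stats::rnorm(N * K), N, K,
              dimnames = list(NULL, paste0("x", seq_len(K))))
  x0 <- stats::rnorm(K)
  d2 <- rowSums(sweep(X, 2, x0)^2)
  bump <- cfg$bump_amplitude * exp(-d2 / (2 * cfg$bump_bandwidth^2))
  y <- as.numeric(X %*% c_true) + bump + stats::rnorm(N, 0, cfg$noise_sd)
  list(X = X, y = y,
       truth = list(c_true = c_true, amplitude = cfg$bump_amplitude,
                    bandwidth = cfg$bump_bandwidth, x0 = x0,
                    sigma = cfg$noise_sd))
}
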