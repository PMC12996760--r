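## Independent oracles used across the suite. These deliberately use slow,
## index-by-index loops (or direct dense linear algebra) so they share no
## code path with the package's matricized implementations.

## MP2 components by quadruple loop.
oracle_mp2 <- function(t, g) {
  d <- dim(t); no <- d[1]; nv <- d[3]
  ec <- 0; ex <- 0
  for (i in 1:no) for (j in 1:no) for (a in 1:nv) for (b in 1:nv) {
    ec <- ec + 2 * t[i, j, a, b] * g[i, j, a, b]
    ex <- ex - t[j, i, a, b] * g[i, j, a, b]
  }
  c(E_C = ec, E_X = ex)
}

## The ten MP3 components by nested loops, term by printed term.
oracle_mp3 <- function(t, blocks) {
  no <- blocks$no; nv <- blocks$nv
  gv <- blocks$g_vvvv; go <- blocks$g_oooo
  gj <- blocks$g_ovov; gk <- blocks$g_ovov_x
  E <- numeric(10)
  for (i in 1:no) for (j in 1:no) for (a in 1:nv) for (b in 1:nv) {
    for (e in 1:nv) for (f in 1:nv) {
      E[1] <- E[1] + 2 * t[i, j, a, b] * gv[a, b, e, f] * t[i, j, e, f]
      E[2] <- E[2] -     t[j, i, a, b] * gv[a, b, e, f] * t[i, j, e, f]
    }
    for (m in 1:no) for (n in 1:no) {
      E[3] <- E[3] + 2 * t[i, j, a, b] * go[m, n, i, j] * t[m, n, a, b]
      E[4] <- E[4] -     t[j, i, a, b] * go[m, n, i, j] * t[m, n, a, b]
    }
    for (e in 1:nv) for (m in 1:no) {
      E[5]  <- E[5]  + 8 * t[i, j, a, b] * gj[m, b, e, j] * t[i, m, a, e]
      E[6]  <- E[6]  - 4 * t[i, j, a, b] * gk[m, b, j, e] * t[i, m, a, e]
      E[7]  <- E[7]  - 4 * t[j, i, a, b] * gk[m, b, j, e] * t[m, i, a, e]
      E[8]  <- E[8]  + 2 * t[j, i, a, b] * gj[m, b, e, j] * t[m, i, a, e]
      E[9]  <- E[9]  - 8 * t[i, j, a, b] * gj[m, b, e, j] * t[m, i, a, e]
      E[10] <- E[10] + 4 * t[i, j, a, b] * gk[m, b, j, e] * t[m, i, a, e]
    }
  }
  E
}

## Monolithic MP2+MP3 correlation oracle: one loop nest per diagram class
## with all ring terms merged into a single expression.
oracle_correlation_total <- function(t, g, blocks) {
  no <- blocks$no; nv <- blocks$nv
  gv <- blocks$g_vvvv; go <- blocks$g_oooo
  gj <- blocks$g_ovov; gk <- blocks$g_ovov_x
  tot <- 0
  for (i in 1:no) for (j in 1:no) for (a in 1:nv) for (b in 1:nv) {
    tot <- tot + (2 * t[i, j, a, b] - t[j, i, a, b]) * g[i, j, a, b]
    for (e in 1:nv) for (f in 1:nv)
      tot <- tot + (2 * t[i, j, a, b] - t[j, i, a, b]) * gv[a, b, e, f] * t[i, j, e, f]
    for (m in 1:no) for (n in 1:no)
      tot <- tot + (2 * t[i, j, a, b] - t[j, i, a, b]) * go[m, n, i, j] * t[m, n, a, b]
    for (e in 1:nv) for (m in 1:no)
      tot <- tot +
        gj[m, b, e, j] * (8 * t[i, j, a, b] * t[i, m, a, e] +
                          2 * t[j, i, a, b] * t[m, i, a, e] -
                          8 * t[i, j, a, b] * t[m, i, a, e]) +
        gk[m, b, j, e] * (-4 * t[i, j, a, b] * t[i, m, a, e] -
                           4 * t[j, i, a, b] * t[m, i, a, e] +
                           4 * t[i, j, a, b] * t[m, i, a, e])
  }
  tot
}

## Greedy pivoted-Cholesky oracle: argmax of the explicit Schur-complement
## residual diagonal at each step.
oracle_pivot_order <- function(S, delta) {
  n <- nrow(S)
  thresh <- 10^(-delta) * max(diag(S))
  sel <- integer(0)
  R <- S
  for (k in seq_len(n)) {
    d <- diag(R)
    d[sel] <- -Inf
    p <- which.max(d)
    if (d[p] < thresh) break
    sel <- c(sel, p)
    R <- R - outer(R[, p], R[, p]) / R[p, p]
  }
  sel
}

## Dense least-squares oracle for the THC core fit: pseudo-inverse of the
## pair bases applied to the target block.
oracle_lstsq_core <- function(Pb, Pk, G) {
  pinv <- function(M) {
    sv <- svd(M)
    keep <- sv$d > max(sv$d) * 1e-10
    sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  }
  pinv(Pb) %*% G %*% t(pinv(Pk))
}

## Small random-but-valid system built from random DF factors, so every
## integral block satisfies its permutational symmetry by construction.
random_sysdata <- function(seed, no = 2, nv = 3, naux = 8) {
  set.seed(seed)
  sym3 <- function(n) {
    B <- array(rnorm(n * n * naux, sd = 0.2), c(n, n, naux))
    (B + aperm(B, c(2, 1, 3))) / 2
  }
  df <- df_tensors(sym3(no),
                   array(rnorm(no * nv * naux, sd = 0.2), c(no, nv, naux)),
                   sym3(nv))
  occ <- sort(runif(no, -1.5, -0.5))
  vir <- sort(runif(nv, 0.3, 1.5))
  sys <- orbital_system(sprintf("rnd%03d", seed), c(occ, vir), no, nv,
                        e_scf = -10 - runif(1))
  list(system = sys, df = df)
}

## Random collocation of a given shape (independent of the generator module).
random_collocation <- function(seed, pair_type, nl, nr, ng) {
  set.seed(seed)
  Xl <- matrix(rnorm(nl * ng), nl, ng)
  if (pair_type == "ov")
    collocation("ov", Xl, matrix(rnorm(nr * ng), nr, ng))
  else
    collocation(pair_type, Xl)
}
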