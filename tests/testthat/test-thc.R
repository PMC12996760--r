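test_that("the grid metric matches its definition and is PSD", {
  ## identity collocation -> identity metric
  cid <- collocation("oo", diag(3))
  expect_equal(fit_metric(cid), diag(3))

  coll <- random_collocation(21, "ov", 2, 3, 5)
  S <- fit_metric(coll)
  ## quadruple-loop oracle
  S_or <- matrix(0, 5, 5)
  for (P in 1:5) for (Q in 1:5)
    for (p in 1:2) for (q in 1:3)
      S_or[P, Q] <- S_or[P, Q] +
        coll$X_left[p, P] * coll$X_right[q, P] * coll$X_left[p, Q] * coll$X_right[q, Q]
  expect_equal(S, S_or, tolerance = 1e-13)
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("pivoted-Cholesky pruning reproduces the greedy oracle pivot order", {
  for (s in 1:8) {
    coll <- random_collocation(30 + s, "ov", 2, 2, 5)
    for (delta in c(1, 2, 6)) {
      pruned <- prune_grid(coll, delta)
      expect_equal(attr(pruned, "selected"),
                   oracle_pivot_order(fit_metric(coll), delta))
    }
  }
})

test_that("pruning keeps a full-rank grid at loose thresholds and deduplicates points", {
  ## 6-point full-rank metric, delta = 12 -> all 6 kept
  coll <- random_collocation(41, "vv", 3, 3, 6)
  expect_equal(sort(attr(prune_grid(coll, 12), "selected")), 1:6)

  ## an exactly duplicated grid point is never selected twice
  X <- matrix(rnorm(12), 3, 4)
  X <- cbind(X, X[, 2])            # column 5 duplicates column 2
  dup <- collocation("vv", X)
  sel <- attr(prune_grid(dup, 12), "selected")
  expect_false(all(c(2, 5) %in% sel))
  expect_equal(length(sel), length(unique(sel)))
})

test_that("THC core fit is the dense least-squares solution", {
  sd <- random_sysdata(51, no = 2, nv = 3, naux = 6)
  ## rectangular case: grid smaller than the pair dimension
  bra <- random_collocation(52, "ov", 2, 3, 4)
  ket <- random_collocation(53, "ov", 2, 3, 4)
  V <- fit_core_v(bra, ket, sd$df$B_ov, sd$df$B_ov)
  G <- thccorrect:::flatten_df(sd$df$B_ov) %*% t(thccorrect:::flatten_df(sd$df$B_ov))
  Pb <- thccorrect:::pair_basis(bra)
  Pk <- thccorrect:::pair_basis(ket)
  V_or <- oracle_lstsq_core(Pb, Pk, G)
  expect_equal(Pb %*% V %*% t(Pk), Pb %*% V_or %*% t(Pk), tolerance = 1e-10)

  ## zero DF factor -> zero core
  expect_equal(max(abs(fit_core_v(bra, ket, array(0, dim(sd$df$B_ov)),
                                  sd$df$B_ov))), 0)

  ## square invertible case reconstructs the DF block exactly
  brx <- random_collocation(54, "ov", 2, 3, 6)   # n_grid = n_pairs = 6
  Vx <- fit_core_v(brx, brx, sd$df$B_ov, sd$df$B_ov)
  expect_equal(reconstruct_integrals(brx, brx, Vx), G, tolerance = 1e-10)
})

test_that("least-squares optimality: perturbing the core never reduces the residual", {
  sd <- random_sysdata(55, no = 2, nv = 3, naux = 6)
  bra <- random_collocation(56, "ov", 2, 3, 4)
  V <- fit_core_v(bra, bra, sd$df$B_ov, sd$df$B_ov)
  G <- thccorrect:::flatten_df(sd$df$B_ov) %*% t(thccorrect:::flatten_df(sd$df$B_ov))
  res0 <- norm(G - reconstruct_integrals(bra, bra, V), "F")
  set.seed(57)
  for (i in 1:10) {
    Vp <- V + matrix(sample(c(-1e-4, 1e-4), length(V), TRUE), nrow(V))
    expect_gte(norm(G - reconstruct_integrals(bra, bra, Vp), "F"), res0)
  }
})

test_that("integral reconstruction matches the six-factor loop oracle and keeps symmetry", {
  bra <- random_collocation(61, "ov", 2, 2, 3)
  set.seed(62)
  V <- crossprod(matrix(rnorm(9), 3))   # symmetric core
  G <- reconstruct_integrals(bra, bra, V)
  ## loop oracle over all indices
  or <- matrix(0, 4, 4)
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    acc <- 0
    for (P in 1:3) for (Q in 1:3)
      acc <- acc + bra$X_left[p, P] * bra$X_right[q, P] * V[P, Q] *
        bra$X_left[r, Q] * bra$X_right[s, Q]
    or[p + 2 * (q - 1), r + 2 * (s - 1)] <- acc
  }
  expect_equal(G, or, tolerance = 1e-12)
  ## zero core -> zero block; symmetric setup -> (pq)<->(rs) symmetric block
  expect_equal(max(abs(reconstruct_integrals(bra, bra, matrix(0, 3, 3)))), 0)
  expect_equal(G, t(G), tolerance = 1e-12)
})

test_that("amplitude core fit matches the dense least-squares oracle and the exact limit", {
  cfg <- generator_config(seed = 71)
  sd <- generate_system(cfg, 1)
  no <- sd$system$n_occ_active; nv <- sd$system$n_vir
  blocks <- integral_blocks_from_df(sd$df)

  ## exact limit: complete grid reproduces the target amplitudes elementwise
  full <- prune_grid(sd$grids$ov, 12)
  T1 <- fit_core_t1(full, blocks$g_oovv, sd$system)
  t_target <- first_order_amplitudes(sd$system, blocks$g_oovv)
  expect_equal(reconstruct_amplitudes(full, T1, no, nv), t_target,
               tolerance = 1e-8)

  ## zero integrals -> zero core
  expect_equal(max(abs(fit_core_t1(full, array(0, dim(blocks$g_oovv)),
                                   sd$system))), 0)

  ## rectangular case: matches the vectorized least-squares oracle
  sub <- prune_grid(sd$grids$ov, 1)
  T1r <- fit_core_t1(sub, blocks$g_oovv, sd$system)
  P <- thccorrect:::pair_basis(sub)
  Tm <- matrix(aperm(t_target, c(1, 3, 2, 4)), no * nv, no * nv)
  T_or <- oracle_lstsq_core(P, P, Tm)
  expect_equal(P %*% T1r %*% t(P), P %*% T_or %*% t(P), tolerance = 1e-10)
})

test_that("every THC variant collapses onto its DF counterpart on the complete grid", {
  cfg <- generator_config(seed = 81)
  for (i in 1:5) {
    sd <- generate_system(cfg, i)
    st <- thc_energy_suite(sd, delta = 12)
    can <- st$breakdowns$canonical
    for (v in c("mp2a", "mp2b", "mp3b")) {
      expect_lt(abs(st$breakdowns[[v]]$e_c - can$e_c), 1e-8)
      expect_lt(abs(st$breakdowns[[v]]$e_x - can$e_x), 1e-8)
    }
    expect_lt(max(abs(st$breakdowns$mp3b$components - can$components)), 1e-8)
    expect_lt(abs(total_energy(st$breakdowns$mp3b) - total_energy(can)), 1e-8)
    ## perfect fit quality in the exact limit
    expect_true(all(st$fits$f > 1 - 1e-7))
  }
})

test_that("the mp2a pipeline equals composing reconstruction with the MP2 operations", {
  cfg <- generator_config(seed = 82)
  sd <- generate_system(cfg, 2)
  st <- thc_energy_suite(sd, delta = 1.5)
  ## composed route: rebuild THC integrals independently from the suite's
  ## pruned grids/cores and push them through the mp_theory operations
  pr <- st$pruned
  G_ovov <- reconstruct_integrals(pr$ov, pr$ov, st$cores$ovov)
  no <- sd$system$n_occ_active; nv <- sd$system$n_vir
  g_thc <- aperm(array(G_ovov, c(no, nv, no, nv)), c(1, 3, 2, 4))
  t_a <- first_order_amplitudes(sd$system, g_thc)
  m2 <- mp2_components(t_a, g_thc)
  expect_equal(unname(st$breakdowns$mp2a$e_c), unname(m2["E_C"]), tolerance = 1e-12)
  expect_equal(unname(st$breakdowns$mp2a$e_x), unname(m2["E_X"]), tolerance = 1e-12)
})

test_that("ensemble THC error is non-increasing in delta", {
  cfg <- generator_config(seed = 83)
  corpus <- generate_corpus(cfg, 20)
  mean_err <- sapply(c(1, 1.5, 2), function(d)
    mean(sapply(corpus, function(sd) {
      st <- thc_energy_suite(sd, d)
      abs(total_energy(st$breakdowns$mp3b) - total_energy(st$breakdowns$canonical))
    })))
  expect_true(all(diff(mean_err) <= 1e-15))
})
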