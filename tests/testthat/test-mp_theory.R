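test_that("first-order amplitudes follow the orbital-energy denominator rule", {
  ## hand-forced single-element check: t = g / (eps_i + eps_j - eps_a - eps_b)
  sys1 <- orbital_system("one", c(-0.5, 0.5), 1, 1, e_scf = -1)
  g1 <- array(0.2, c(1, 1, 1, 1))
  expect_equal(as.numeric(first_order_amplitudes(sys1, g1)), -0.1)  # 0.2 / -2.0

  ## zero map
  sd <- random_sysdata(1)
  blocks <- integral_blocks_from_df(sd$df)
  expect_equal(first_order_amplitudes(sd$system, array(0, dim(blocks$g_oovv))),
               array(0, dim(blocks$g_oovv)))

  ## elementwise division against the explicit denominator
  D <- thccorrect:::energy_denominator(sd$system)
  t <- first_order_amplitudes(sd$system, blocks$g_oovv)
  for (idx in list(c(1, 2, 1, 3), c(2, 1, 3, 2))) {
    expect_equal(t[idx[1], idx[2], idx[3], idx[4]],
                 blocks$g_oovv[idx[1], idx[2], idx[3], idx[4]] /
                   D[idx[1], idx[2], idx[3], idx[4]], tolerance = 1e-14)
  }

  ## a positive gap bounds |denominator| >= 2*gap from below, so exact
  ## degeneracy cannot be constructed; the guard is exercised via tol_denom
  ## (the smallest |D| here is 2 * 0.8 = 1.6) and must name the indices
  sys_deg <- orbital_system("deg", c(-0.6, -0.4, 0.4, 0.6), 2, 2, e_scf = -1)
  expect_error(first_order_amplitudes(sys_deg, array(1, c(2, 2, 2, 2)),
                                      tol_denom = 1.7),
               "degenerate.*i=2, j=2, a=1, b=1")
})

test_that("MP2 components match the loop oracle and have the physical sign", {
  sd <- random_sysdata(2)
  blocks <- integral_blocks_from_df(sd$df)
  t <- first_order_amplitudes(sd$system, blocks$g_oovv)
  expect_equal(mp2_components(t, blocks$g_oovv), oracle_mp2(t, blocks$g_oovv),
               tolerance = 1e-13)
  ## t = 0 -> (0, 0)
  expect_equal(unname(mp2_components(array(0, dim(t)), blocks$g_oovv)), c(0, 0))
  ## E_C < 0 for canonical amplitudes over an ensemble of seeded systems
  for (s in 1:50) {
    sd2 <- random_sysdata(100 + s)
    b2 <- integral_blocks_from_df(sd2$df)
    t2 <- first_order_amplitudes(sd2$system, b2$g_oovv)
    expect_lt(mp2_components(t2, b2$g_oovv)["E_C"], 0)
  }
})

test_that("the ten MP3 components match the loop oracle term by term", {
  for (s in 1:5) {
    sd <- random_sysdata(10 + s, no = 2 + s %% 2, nv = 3)
    blocks <- integral_blocks_from_df(sd$df)
    t <- first_order_amplitudes(sd$system, blocks$g_oovv)
    expect_equal(unname(mp3_components(t, blocks)), oracle_mp3(t, blocks),
                 tolerance = 1e-12)
  }
})

test_that("MP3 term support follows the diagram structure", {
  sd <- random_sysdata(3)
  blocks <- integral_blocks_from_df(sd$df)
  t <- first_order_amplitudes(sd$system, blocks$g_oovv)
  ## t = 0 -> all ten zero
  expect_equal(unname(mp3_components(array(0, dim(t)), blocks)), rep(0, 10))
  ## no hole-hole / ring integrals -> only the particle-particle ladder survives
  b0 <- blocks
  b0$g_oooo[] <- 0; b0$g_ovov[] <- 0; b0$g_ovov_x[] <- 0
  e <- mp3_components(t, b0)
  expect_true(all(abs(e[3:10]) < 1e-14))
  expect_true(abs(e[1]) > 0 && abs(e[2]) > 0)
})

test_that("component sums equal the monolithic correlation oracle over seeded systems", {
  for (s in 1:50) {
    sd <- random_sysdata(200 + s)
    blocks <- integral_blocks_from_df(sd$df)
    t <- first_order_amplitudes(sd$system, blocks$g_oovv)
    m2 <- mp2_components(t, blocks$g_oovv)
    e3 <- mp3_components(t, blocks)
    expect_equal(unname(m2["E_C"] + m2["E_X"] + sum(e3)),
                 oracle_correlation_total(t, blocks$g_oovv, blocks),
                 tolerance = 1e-11)
  }
})

test_that("parameterized energies obey the absolute/delta identity", {
  sd <- random_sysdata(4)
  blocks <- integral_blocks_from_df(sd$df)
  t <- first_order_amplitudes(sd$system, blocks$g_oovv)
  m2 <- mp2_components(t, blocks$g_oovv)
  bd <- energy_breakdown("x", "canonical", sd$system$e_scf, m2["E_C"], m2["E_X"],
                         mp3_components(t, blocks))
  expect_equal(parameterized_energy(bd, rep(1, 10)), total_energy(bd),
               tolerance = 1e-14)
  expect_equal(parameterized_energy(bd, rep(0, 10), basis = "delta"), 0)
  set.seed(7)
  for (i in 1:5) {
    cc <- runif(10, -2, 2)
    expect_equal(parameterized_energy(bd, cc) - parameterized_energy(bd, rep(1, 10)),
                 parameterized_energy(bd, cc - 1, basis = "delta"),
                 tolerance = 1e-13)
  }
  ## MP2-only breakdowns refuse component scaling
  bd2 <- energy_breakdown("x", "mp2a", 0, -0.1, 0.02)
  expect_error(parameterized_energy(bd2, rep(1, 10)), "components")
})

test_that("breakdown tables round-trip through their CSV layout", {
  sd <- random_sysdata(5)
  blocks <- integral_blocks_from_df(sd$df)
  t <- first_order_amplitudes(sd$system, blocks$g_oovv)
  m2 <- mp2_components(t, blocks$g_oovv)
  bds <- list(
    energy_breakdown("a", "canonical", -10, m2["E_C"], m2["E_X"],
                     mp3_components(t, blocks)),
    energy_breakdown("a", "mp2a", -10, -0.1, 0.01)
  )
  tab <- breakdown_table(bds)
  expect_equal(names(tab)[1:5], c("species_id", "variant", "E_SCF", "E_C", "E_X"))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- breakdowns_from_table(utils::read.csv(path, stringsAsFactors = FALSE))
  expect_equal(back[[1]]$components, bds[[1]]$components, tolerance = 1e-14)
  expect_null(back[[2]]$components)
  unlink(path)
})
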