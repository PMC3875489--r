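table4_sets <- function() pft_params()

test_that("osmotic pressure implements photosynthesis-driven adjustment", {
  subs <- pft_params("SUBS")
  # direct evaluation: 1.87 * (1 + 9.9 * 6.5/(319.8 + 6.5))
  expect_equal(osmotic_pressure(subs, a_n = 6.5), 2.2387849, tolerance = 1e-6)
  # gain off -> baseline for any assimilation
  p0 <- demo_params(xi = 0)
  expect_equal(osmotic_pressure(p0, a_n = c(-2, 0, 5, 30)), rep(1.8, 4))
  # zero assimilation -> baseline
  expect_equal(osmotic_pressure(subs, a_n = 0), 1.87)
  # respiration gives no negative adjustment
  expect_equal(osmotic_pressure(subs, a_n = -3), 1.87)
  # the CO2 ratio scales the adjustment term only
  pi_lo_ci <- osmotic_pressure(subs, a_n = 6.5, c_i = 185)
  expect_equal(pi_lo_ci - 1.87, 2 * (2.2387849 - 1.87), tolerance = 1e-6)
  expect_error(osmotic_pressure(demo_params(k_i = 2), a_n = -2), "positive")
})

test_that("hydraulic conductance is hyperbolic with an efficiency-safety tradeoff", {
  p <- stomatal_params("x", 0.5, 0.01906, 3.13, 1.8, 300, 20)
  expect_equal(hydraulic_conductance(p, 0), 0.01906)
  # analytic half-loss point of the hyperbola
  half_psi <- -1 / (3.13 * 0.01906)
  expect_equal(hydraulic_conductance(p, half_psi), 0.01906 / 2, tolerance = 1e-12)
  # strictly decreasing with tension
  ks <- hydraulic_conductance(p, seq(0, -20, by = -0.5))
  expect_true(all(diff(ks) < 0))
  # doubling g_p at fixed c_lambda lowers the fractional conductance
  p2 <- stomatal_params("y", 0.5, 2 * 0.01906, 3.13, 1.8, 300, 20)
  frac1 <- hydraulic_conductance(p, -5) / p$g_p
  frac2 <- hydraulic_conductance(p2, -5) / p2$g_p
  expect_lt(frac2, frac1)
  expect_error(hydraulic_conductance(p, 0.1), "tension")
})

test_that("solve_leaf satisfies the coupled turgor / mass-balance system", {
  subs <- pft_params("SUBS")
  st <- solve_leaf(subs, psi_soil = -0.033, d = 0.0035, a_n = 6.5)

  # independent root check: uniroot on the mass balance written out here
  f <- function(px) {
    gs <- subs$k_psi * max(subs$pi_0 * (1 + subs$xi * 6.5 / (subs$k_i + 6.5)) + px, 0)
    K <- subs$g_p / (1 + subs$c_lambda * subs$g_p * abs(px))
    gs * 0.0035 - K * (-0.033 - px)
  }
  px_oracle <- stats::uniroot(f, c(-2.2387, -0.033), tol = 1e-12)$root
  expect_equal(st$psi_x, px_oracle, tolerance = 1e-8)
  expect_equal(st$g_s, subs$k_psi * (st$pi + px_oracle), tolerance = 1e-8)
  expect_true(abs(st$psi_x - (-1.08)) < 0.02)

  # no demand: xylem equilibrates with the soil
  st0 <- solve_leaf(subs, psi_soil = -0.5, d = 0, a_n = 6.5)
  expect_equal(st0$psi_x, -0.5)
  expect_equal(st0$E, 0)
  expect_equal(st0$g_s, subs$k_psi * (st0$pi - 0.5))

  # soil drier than the osmotic pressure: closed stomata
  stc <- solve_leaf(subs, psi_soil = -2.5, d = 0.0035, a_n = 6.5)
  expect_equal(stc$g_s, 0)
  expect_equal(stc$psi_x, -2.5)
  expect_error(solve_leaf(subs, psi_soil = 0.5, d = 0.01, a_n = 6.5), "<= 0")
})

test_that("closed form and bisection agree and satisfy the balance on a grid", {
  grid <- tidyr::expand_grid(
    psi = seq(-3, -0.05, length.out = 10),
    d = seq(0.001, 0.06, length.out = 10),
    an = seq(0, 15, length.out = 5)
  )
  for (g in seq_len(nrow(pft_params()))) {
    p <- pft_params()[g, ]
    closed <- solve_leaf(p, grid$psi, grid$d, grid$an)
    bis <- solve_leaf(p, grid$psi, grid$d, grid$an, method = "bisect")
    expect_lt(max(abs(closed$psi_x - bis$psi_x)), 1e-8)
    resid <- closed$g_s * grid$d -
      hydraulic_conductance(p, closed$psi_x) * (grid$psi - closed$psi_x)
    expect_lt(max(abs(resid)), 1e-10)
    # state invariants
    expect_true(all(closed$K > 0 & closed$K <= p$g_p + 1e-12))
    expect_true(all(closed$E >= 0))
    expect_true(all(closed$g_s >= 0))
    # open stomata sit between full turgor loss and the soil potential;
    # closed stomata equilibrate with the soil (psi_x = psi_soil)
    open <- closed$g_s > 0
    expect_true(all(closed$psi_x[open] >= -closed$pi[open] - 1e-9 &
                    closed$psi_x[open] <= grid$psi[open] + 1e-9))
    expect_true(all(closed$psi_x[!open] == grid$psi[!open]))
  }
})

test_that("conductance responds monotonically to soil drying and demand", {
  psi <- seq(-0.05, -4, length.out = 60)
  d <- seq(0.001, 0.08, length.out = 60)
  for (g in seq_len(nrow(pft_params()))) {
    p <- pft_params()[g, ]
    gs_psi <- solve_leaf(p, psi, d = 0.01, a_n = 6.5)$g_s
    expect_true(all(diff(gs_psi) <= 1e-10))
    gs_d <- solve_leaf(p, psi_soil = -0.5, d = d, a_n = 6.5)$g_s
    expect_true(all(diff(gs_d) <= 1e-10))
    # closure is exact: zero iff soil at or beyond -pi
    pi_adj <- osmotic_pressure(p, 6.5)
    gs <- solve_leaf(p, c(-pi_adj - 0.01, -pi_adj + 0.01), 0.01, 6.5)$g_s
    expect_equal(gs[1], 0)
    expect_gt(gs[2], 0)
  }
})

test_that("vanishing cavitation recovers the linear supply model", {
  p <- demo_params(c_lambda = 1e-9)
  psi <- -1.2; d <- 0.03; an <- 6.5
  st <- solve_leaf(p, psi, d, an)
  pi_adj <- osmotic_pressure(p, an)
  # linear model: k_psi*D*(pi + psi_x) = g_p*(psi - psi_x), solved exactly
  a <- p$k_psi * d
  px_lin <- (p$g_p * psi - a * pi_adj) / (p$g_p + a)
  expect_equal(st$psi_x, px_lin, tolerance = 1e-6)
  expect_equal(st$g_s, p$k_psi * (pi_adj + px_lin), tolerance = 1e-6)
})

test_that("transpiration is conductance times demand", {
  expect_equal(transpiration(1.7, 0.0035), 0.00595)
  expect_equal(transpiration(0, 0.05), 0)
  expect_equal(transpiration(0.23, 0.05), 0.0115)
})

test_that("batch prediction aligns parameters and day potentials to records", {
  p <- demo_params("A")
  rec <- make_records(n = 3, params = p, psi = -0.7)
  out <- predict_gs(rec, p, psi = psi_table(psi = -0.7))
  expect_equal(out$gs_pred, rec$gs_mol, tolerance = 1e-12)
  # mismatched day table is an explicit error
  expect_error(predict_gs(rec, p, psi = psi_table(date = "1999-01-01")),
               "missing soil water potential")
})
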