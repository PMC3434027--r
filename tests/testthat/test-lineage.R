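# Lineage response fields, the velocity closure and ablation.

test_that("replication probability is monotone in Wnt and BMP", {
  lp <- lineage_params()
  W <- seq(0, 3, length.out = 50)
  m_lowB <- morphogen_state(W, bmp = rep(0.05, 50))
  m_highB <- morphogen_state(W, bmp = rep(0.5, 50))
  p_low <- replication_probability(m_lowB, lp)$p0
  p_high <- replication_probability(m_highB, lp)$p0
  expect_true(all(diff(p_low) > 0))          # increasing in Wnt
  expect_true(all(p_high < p_low | W == 0))  # decreasing in BMP
  expect_equal(p_low[1], 0)                  # zero without Wnt
  expect_true(all(p_low <= lp$p0_max))
})

test_that("velocity closure satisfies its defining equation", {
  lp <- lineage_params()
  g <- crypt_grid(64L, L = 0.22)
  C0 <- 0.4 + 0.3 * cos(2 * pi * 2 * g$xi)
  cells <- lineage_state(C0)
  d1 <- death_rate_field(g, cells, lp)
  vel <- compute_velocity(cells, d1, lp, g)
  src <- lp$v0 * cells$C0 - d1 * cells$C1
  # dV/ds equals the fluctuating part of the source; the mean drives growth
  dVds <- spectral_derivative(vel$V, 1L, g$L)
  expect_lt(max(abs(dVds - (src - mean(src)))), 1e-9)
  expect_lt(abs(mean(vel$V)), 1e-12)
  expect_equal(vel$net_growth_rate, trapezoid_periodic(src, g$L),
               tolerance = 1e-12)
})

test_that("the transport term conserves total progenitor mass", {
  lp <- lineage_params()
  g <- crypt_grid(64L, L = 0.2)
  C0 <- 0.4 + 0.25 * cos(2 * pi * 3 * g$xi)
  cells <- lineage_state(C0)
  V <- 0.01 * sin(2 * pi * 2 * g$xi)
  transport <- -spectral_derivative(V * C0, 1L, g$L)
  expect_lt(abs(trapezoid_periodic(transport, g$L)), 1e-12)
})

test_that("ablation replaces progenitors and keeps the total density at one", {
  g <- crypt_grid(64L, L = 0.2)
  C0 <- 0.4 + 0.3 * cos(2 * pi * 2 * g$xi)
  cells <- lineage_state(C0)
  ab <- ablate_progenitors(cells, list(from = 0.2, to = 0.3), 0.5, g)
  idx <- g$xi >= 0.2 & g$xi <= 0.3
  expect_equal(ab$C0[idx], 0.5 * C0[idx])
  expect_equal(ab$C0[!idx], C0[!idx])
  expect_equal(max(abs(ab$C0 + ab$C1 - 1)), 0)
  full <- ablate_progenitors(cells, list(from = 0.9, to = 0.1), 1, g)
  wrap <- g$xi >= 0.9 | g$xi <= 0.1
  expect_equal(max(full$C0[wrap]), 0)
  expect_error(ablate_progenitors(cells, list(from = 0.2, to = 0.3), 1.5, g))
})

test_that("the apex-localized death profile spares crypt bases", {
  lp <- lineage_params(d1_profile = list(name = "apex_localized",
                                         floor_frac = 0.2,
                                         width_frac = 0.1))
  g <- crypt_grid(64L, L = 0.2)
  C0 <- pmax(0, 0.5 * cos(2 * pi * (g$xi - 0.5)))   # single peak at 0.5
  cells <- lineage_state(C0)
  d1 <- death_rate_field(g, cells, lp)
  peak <- which.min(cryptdyn:::xi_distance(g$xi, 0.5))
  far <- which.min(cryptdyn:::xi_distance(g$xi, 0.0))
  expect_lt(d1[peak], 0.35 * lp$d1_max)
  expect_gt(d1[far], 0.9 * lp$d1_max)
  expect_true(all(d1 > 0 & d1 <= lp$d1_max + 1e-12))
})
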