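# Morphogen kinetics and the quasi-steady solver against analytic
# solutions and the independently written adaptive integrator.

test_that("quasi-steady solve reproduces analytic uniform solutions", {
  p <- morphogen_params()
  g <- crypt_grid(32L, L = 0.2)
  num <- numerics_params(n_points = 32L)

  # no cells anywhere: Wnt and inhibitor decay to zero, BMP to mu1/d_B
  cells <- lineage_state(rep(0, 32))
  init <- morphogen_state(rep(0.05, 32), rep(0.01, 32))
  m <- solve_quasi_steady(cells, p, g, init, num, relax_first = 500L)
  expect_lt(max(m$wnt), 1e-7)
  expect_lt(max(m$inhibitor), 1e-6)
  expect_equal(m$bmp, rep(p$mu1 / p$d_B, 32), tolerance = 1e-10)

  # uniform cells: the solver must preserve the homogeneous fixed point
  cells <- lineage_state(rep(0.5, 32))
  hss <- homogeneous_fixed_point(0.5, 0.5, p)
  row <- hss[hss$selected, ]
  init <- morphogen_state(rep(row$W, 32), rep(row$I, 32))
  m <- solve_quasi_steady(cells, p, g, init, num)
  expect_lt(max(abs(m$wnt - row$W)), 1e-9)
  expect_lt(max(abs(m$inhibitor - row$I)), 1e-9)
})

test_that("the quasi-steady state agrees with long-time parabolic relaxation", {
  # independent oracle: integrate the time-dependent morphogen PDE with
  # independently coded kinetics to large time; its attractor must match
  # the stationary solve from the same neighbourhood
  p <- morphogen_params()
  n <- 64L
  g <- crypt_grid(n, L = 0.2)
  num <- numerics_params(n_points = n)
  c0 <- rep(0.5, n)
  hss <- homogeneous_fixed_point(0.5, 0.5, p)
  row <- hss[hss$selected, ]
  pert <- 0.05 * cos(2 * pi * 2 * g$xi)
  W0 <- row$W + pert
  I0 <- rep(row$I, n)

  sol <- mol_integrate_morphogens(W0, I0, 0.5, p, g$L,
                                  times = c(0, 40000), rtol = 1e-9)
  Wt <- unname(sol[nrow(sol), 2:(n + 1)])
  It <- unname(sol[nrow(sol), (n + 2):(2 * n + 1)])

  cells <- lineage_state(c0)
  m <- solve_quasi_steady(cells, p, g, morphogen_state(W0, I0), num,
                          relax_first = 2000L)
  expect_lt(max(abs(m$wnt - Wt)), 1e-3 * max(Wt))
  expect_lt(max(abs(m$inhibitor - It)), 1e-3 * max(It))
  # and the certified residual of the stationary solve holds
  r <- cryptdyn:::qss_residual(m$wnt, m$inhibitor, c0, p, g, 0)
  expect_lt(max(abs(c(r$rW, r$rI))), num$qss_tol)
})

test_that("BMP solve matches the analytic single-mode solution", {
  p <- morphogen_params()
  n <- 64L
  g <- crypt_grid(n, L = 0.3)
  k <- 2 * pi * 3 / g$L
  C1 <- 1 + 0.4 * cos(k * g$xi * g$L)
  B <- cryptdyn:::solve_bmp(C1, p, g)
  B_exact <- p$mu1 / p$d_B + p$mu1 * 0.4 * cos(k * g$xi * g$L) /
    (p$d_B + p$D_B * k^2)
  expect_lt(max(abs(B - B_exact)), 1e-12)
})

test_that("homogeneous fixed points are genuine roots and unique here", {
  p <- morphogen_params()
  for (c0 in c(0.1, 0.5, 0.9)) {
    hss <- homogeneous_fixed_point(c0, 1 - c0, p)
    expect_lt(max(hss$residual), 1e-10)
    expect_equal(nrow(hss), 1L)      # calibrated monostability
    expect_true(hss$stable[1])
    r <- oracle_reaction(hss$W[1], hss$I[1], c0, p)
    expect_lt(abs(r$rW), 1e-10)
    expect_lt(abs(r$rI), 1e-10)
  }
})

test_that("an exogenous source lifts Wnt inside its window", {
  p <- morphogen_params()
  n <- 64L
  g <- crypt_grid(n, L = 0.2)
  num <- numerics_params(n_points = n)
  cells <- lineage_state(rep(0.5, n))
  hss <- homogeneous_fixed_point(0.5, 0.5, p)
  row <- hss[hss$selected, ]
  init <- morphogen_state(rep(row$W, n), rep(row$I, n))
  src <- wnt_source(position_p = 0.25, width_omega = 0.1, rate_theta = 4e-4)
  m <- solve_quasi_steady(cells, p, g, init, num, src = src,
                          relax_first = 500L)
  inside <- cryptdyn:::xi_distance(g$xi, 0.25) <= 0.05
  expect_gt(min(m$wnt[inside]), row$W)
  expect_gt(mean(m$wnt[inside]), mean(m$wnt[!inside]))
})
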