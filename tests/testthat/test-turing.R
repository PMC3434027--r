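# Linear stability analysis against brute-force eigenvalues and known
# limits.

test_that("dispersion growth rates match direct eigenvalues of J - k^2 D", {
  p <- morphogen_params()
  hss <- homogeneous_fixed_point(0.5, 0.5, p)
  row <- hss[hss$selected, ]
  J <- kinetics_jacobian(row$W, row$I, 0.5, p)
  D <- c(p$D_W, p$D_I)
  dr <- dispersion_relation(J, D, L = 0.2, n_modes = 16L)
  for (j in c(0, 1, 2, 5, 16)) {
    k2 <- (2 * pi * j / 0.2)^2
    lam <- max(Re(eigen(J - k2 * diag(D), only.values = TRUE)$values))
    expect_equal(dr$growth_rates[j + 1], lam, tolerance = 1e-12)
  }
})

test_that("the default parameterisation is Turing-unstable with fastest mode 2", {
  p <- morphogen_params()
  pc <- predict_crypt_count(p, 0.5, 0.2)
  expect_false(pc$stable)
  expect_equal(pc$count, 2L)
  dr <- pc$dispersion
  expect_true(dr$turing_unstable)
  expect_true(dr$kinetics_stable)
  band <- dr$unstable_band
  expect_false(any(is.na(band)))
  # the fastest admissible wavenumber lies inside the continuum band
  kstar <- 2 * pi * dr$fastest_mode / 0.2
  expect_gt(kstar, band[1])
  expect_lt(kstar, band[2])
})

test_that("equal diffusivities cannot produce a Turing instability", {
  p <- morphogen_params(D_I = morphogen_params()$D_W)
  hss <- homogeneous_fixed_point(0.5, 0.5, p)
  row <- hss[hss$selected, ]
  J <- kinetics_jacobian(row$W, row$I, 0.5, p)
  dr <- dispersion_relation(J, c(p$D_W, p$D_I), L = 0.2)
  expect_false(dr$turing_unstable)
  expect_true(all(dr$growth_rates < 0))
})

test_that("kinetics_jacobian rejects non-fixed points and matches finite differences", {
  p <- morphogen_params()
  expect_error(kinetics_jacobian(0.3, 0.2, 0.5, p), "not a fixed point")
  hss <- homogeneous_fixed_point(0.5, 0.5, p)
  row <- hss[hss$selected, ]
  J <- kinetics_jacobian(row$W, row$I, 0.5, p)
  h <- 1e-7
  fd <- matrix(0, 2, 2)
  base <- oracle_reaction(row$W, row$I, 0.5, p)
  rW <- oracle_reaction(row$W + h, row$I, 0.5, p)
  rI <- oracle_reaction(row$W, row$I + h, 0.5, p)
  fd[, 1] <- c(rW$rW - base$rW, rW$rI - base$rI) / h
  fd[, 2] <- c(rI$rW - base$rW, rI$rI - base$rI) / h
  expect_equal(J, fd, tolerance = 1e-5)
})

test_that("the instability region grows with the diffusivity ratio", {
  p <- morphogen_params()
  m <- instability_map(c(1, 5, 25), c(1), p, c0 = 0.5)
  expect_false(m[1, 1])    # equal diffusivities: stable
  expect_true(m[3, 1])     # the default ratio 25 is inside the region
})
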