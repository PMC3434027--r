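# Crypt segmentation, the depth-embedding energy and the arclength.

synthetic_two_bump <- function(n = 128L, L = 0.2) {
  g <- crypt_grid(n, L)
  C0 <- pmax(0, 0.4 * cos(2 * pi * 2 * (g$xi - 0.125)))^1  # peaks at .125, .625
  list(grid = g, C0 = C0)
}

test_that("crypt segmentation finds contiguous arcs and merges the seam", {
  tb <- synthetic_two_bump()
  segs <- crypt_segments(tb$C0, tb$grid)
  expect_length(segs, 2L)
  peaks <- sort(vapply(segs, function(s) tb$grid$xi[s$peak_idx], numeric(1)))
  expect_equal(peaks, c(0.125, 0.625), tolerance = 1 / tb$grid$n)
  # a pattern straddling xi = 0 is one crypt, not two
  g <- crypt_grid(64L, 0.2)
  C0w <- pmax(0, 0.4 * cos(2 * pi * g$xi))
  segw <- crypt_segments(C0w, g)
  expect_length(segw, 1L)
  expect_true(segw[[1]]$wraps)
  expect_equal(g$xi[segw[[1]]$peak_idx], 0)
  # below-threshold or sub-resolution features are ignored
  expect_length(crypt_segments(rep(0, 64), g), 0L)
})

test_that("the embedding seam falls in the widest inter-crypt gap", {
  tb <- synthetic_two_bump()
  segs <- crypt_segments(tb$C0, tb$grid)
  xi0 <- cryptdyn:::seam_xi(segs)
  # both gaps are equal by symmetry here; the seam must be outside every arc
  for (s in segs) {
    inside <- if (s$xi_from <= s$xi_to) xi0 >= s$xi_from && xi0 <= s$xi_to
              else xi0 >= s$xi_from || xi0 <= s$xi_to
    expect_false(inside)
  }
})

test_that("the depth multiplier embeds exactly the requested arclength", {
  tb <- synthetic_two_bump()
  gp <- geometry_params()
  segs <- crypt_segments(tb$C0, tb$grid)
  centers <- cryptdyn:::segment_centers(segs, tb$grid, gp)
  curve <- flat_curve(tb$grid$n, gp)
  for (Lt in c(0.22, 0.3)) {
    m <- cryptdyn:::solve_depth_multiplier(segs, centers, curve, gp, Lt)
    expect_gt(m, 0)
    tg <- cryptdyn:::curve_target(curve$x, segs, centers, gp,
                                  depth_mult = m)$target
    arclen <- sum(sqrt(diff(curve$x)^2 + diff(tg)^2))
    expect_equal(arclen, Lt, tolerance = 1e-9)
  }
  # no excess length: stay flat
  expect_equal(cryptdyn:::solve_depth_multiplier(segs, centers, curve, gp,
                                                 0.2), 0)
})

test_that("gradient flow descends the energy monotonically to the target", {
  tb <- synthetic_two_bump()
  gp <- geometry_params()
  curve <- flat_curve(tb$grid$n, gp)
  # perturb the heights away from both the flat and the target profile
  set.seed(42)
  curve$y <- curve$y + 0.01 * sin(2 * pi * 3 * (0:tb$grid$n) / tb$grid$n)
  curve$y[1] <- gp$endpoint_a[2]; curve$y[tb$grid$n + 1] <- gp$endpoint_b[2]
  Lt <- 0.24
  E <- crypt_energy(curve, tb$C0, gp, tb$grid, L_target = Lt)$E
  energies <- E
  for (i in 1:30) {
    curve <- gradient_flow_step(curve, tb$C0, gp, dt = 0.002, tb$grid,
                                L_target = Lt)
    energies <- c(energies, crypt_energy(curve, tb$C0, gp, tb$grid,
                                         L_target = Lt)$E)
  }
  expect_true(all(diff(energies) <= 1e-14))
  expect_lt(energies[31], 1e-3 * energies[1])
  # endpoints stay pinned
  expect_equal(curve$y[1], gp$endpoint_a[2])
  expect_equal(curve$y[tb$grid$n + 1], gp$endpoint_b[2])
})

test_that("arclength quadratures agree and respect the chord lower bound", {
  gp <- geometry_params()
  cv <- flat_curve(128L, gp)
  expect_equal(domain_length(cv), 0.2, tolerance = 1e-12)
  # smooth sinusoidal graph: polyline vs spectral quadrature
  t <- (0:128) / 128
  y <- 0.01 * sin(pi * t)^2 * sin(2 * pi * 4 * t)
  cv2 <- crypt_curve(cv$x, y)
  expect_equal(domain_length(cv2, "polyline"),
               domain_length(cv2, "spectral"), tolerance = 1e-3)
  expect_gte(domain_length(cv2), 0.2)
})

test_that("crypt summaries report heights at the right horizontal windows", {
  tb <- synthetic_two_bump()
  gp <- geometry_params()
  curve <- flat_curve(tb$grid$n, gp)
  curve <- gradient_flow_step(curve, tb$C0, gp, dt = 1, tb$grid,
                              L_target = 0.24)
  sm <- summarize_crypts(curve, tb$C0, tb$grid, gp)
  expect_equal(sm$count, 2L)
  expect_length(sm$heights, 2L)
  expect_gt(min(sm$heights), 0)
  expect_equal(sm$heights[1], sm$heights[2], tolerance = 0.05)
  expect_equal(sort(sm$tip_positions), c(0.125, 0.625),
               tolerance = 1 / tb$grid$n)
})
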