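# Spectral primitives against analytic derivatives and quadrature.

test_that("spectral derivatives are exact for band-limited fields", {
  n <- 64; L <- 0.4
  s <- (0:(n - 1)) / n * L
  f <- 1.5 + sin(2 * pi * 3 * s / L) + 0.2 * cos(2 * pi * 7 * s / L)
  d1 <- (2 * pi * 3 / L) * cos(2 * pi * 3 * s / L) -
    0.2 * (2 * pi * 7 / L) * sin(2 * pi * 7 * s / L)
  d2 <- -(2 * pi * 3 / L)^2 * sin(2 * pi * 3 * s / L) -
    0.2 * (2 * pi * 7 / L)^2 * cos(2 * pi * 7 * s / L)
  expect_lt(max(abs(spectral_derivative(f, 1L, L) - d1)), 1e-9)
  expect_lt(max(abs(spectral_derivative(f, 2L, L) - d2)), 1e-7)
  expect_lt(max(abs(spectral_derivative(rep(3, n), 1L, L))), 1e-12)
})

test_that("periodic antiderivative inverts the derivative on zero-mean fields", {
  n <- 64; L <- 0.25
  s <- (0:(n - 1)) / n * L
  f <- sin(2 * pi * 2 * s / L) + 0.3 * cos(2 * pi * 5 * s / L)
  Fa <- cryptdyn:::periodic_antiderivative(f, L)
  expect_lt(abs(mean(Fa)), 1e-12)
  expect_lt(max(abs(spectral_derivative(Fa, 1L, L) - f)), 1e-9)
})

test_that("grid integral matches trapezoid quadrature on periodic data", {
  g <- crypt_grid(64L, L = 0.31)
  f <- 2 + cos(2 * pi * 4 * g$xi) + 0.1 * sin(2 * pi * g$xi)
  expect_equal(cryptdyn:::grid_integral(f, g),
               trapezoid_periodic(f, g$L), tolerance = 1e-12)
  expect_equal(cryptdyn:::grid_integral(rep(1, 64), g), g$L,
               tolerance = 1e-12)
})

test_that("dense derivative matrices reproduce the FFT operators", {
  n <- 32
  set.seed(7)
  f <- stats::rnorm(n)
  D2 <- cryptdyn:::second_derivative_matrix(n)
  expect_lt(max(abs(D2 %*% f - spectral_derivative(f, 2L, 1))), 1e-8)
  D1 <- cryptdyn:::first_derivative_matrix(n)
  fs <- cos(2 * pi * 3 * (0:(n - 1)) / n)   # band-limited, Nyquist-free
  expect_lt(max(abs(D1 %*% fs - spectral_derivative(fs, 1L, 1))), 1e-9)
})

test_that("the spectral filter leaves smooth fields essentially untouched", {
  n <- 64
  sig <- cryptdyn:::filter_sigma(n)
  expect_equal(sig[1], 1)
  f <- cos(2 * pi * 3 * (0:(n - 1)) / n)
  expect_lt(max(abs(cryptdyn:::apply_filter(f, sig) - f)), 1e-12)
})
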