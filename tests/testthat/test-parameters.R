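# Parameter validation and configuration round-trips.

test_that("constructors name the offending field", {
  expect_error(lineage_params(v0 = -1), "v0")
  expect_error(lineage_params(p0_max = 1.2), "p0_max")
  expect_error(morphogen_params(D_W = 0), "D_W")
  expect_error(numerics_params(length_drive = "nope"), "length_drive")
  expect_error(geometry_params(endpoint_a = c(0, 0), endpoint_b = c(0, 0)),
               "endpoint_b")
  expect_error(crypt_grid(33L), "even")
})

test_that("config save/load round-trips the parameter list", {
  params <- default_params()
  params$morphogen$d_W <- 0.004
  params$numerics$n_points <- 64L
  path <- tempfile(fileext = ".yaml")
  save_config(params, path)
  back <- load_config(path)
  expect_equal(back$morphogen$d_W, 0.004)
  expect_equal(back$numerics$n_points, 64L)
  expect_equal(unclass(back$lineage), unclass(params$lineage))
  unlink(path)
})

test_that("apply_overrides parses dotted paths and revalidates", {
  params <- default_params()
  out <- apply_overrides(params, c("morphogen.d_W=0.02",
                                   "numerics.n_points=32"))
  expect_equal(out$morphogen$d_W, 0.02)
  expect_equal(out$numerics$n_points, 32L)
  expect_error(apply_overrides(params, "morphogen.bogus=1"), "bogus")
  expect_error(apply_overrides(params, "numerics.dt=-1"), "dt")
})

test_that("the shipped configuration file loads to the package defaults", {
  path <- system.file("extdata", "default_config.yaml", package = "cryptdyn")
  expect_true(nzchar(path))
  cfg <- load_config(path)
  def <- default_params()
  for (f in names(def$morphogen))
    expect_equal(cfg$morphogen[[f]], def$morphogen[[f]], tolerance = 0,
                 label = paste("morphogen", f))
  expect_equal(cfg$numerics$dt, def$numerics$dt)
  expect_equal(cfg$numerics$n_points, def$numerics$n_points)
  expect_equal(cfg$numerics$length_drive, def$numerics$length_drive)
  expect_equal(cfg$lineage$gamma_W, def$lineage$gamma_W)
  expect_equal(cfg$scenario$name, "formation")
})
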