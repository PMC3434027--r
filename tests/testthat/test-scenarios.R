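# Outcome classification and run export (cheap, synthetic inputs).

synthetic_ts <- function(mass, max_C0, n_crypts) {
  t <- seq(0, 30, by = 1)
  data.frame(t = t, L = 0.2, L_curve = 0.2,
             n_crypts = n_crypts, max_C0 = max_C0,
             mass_C0 = mass, p0_peak = 0.6, net_growth = 0, energy = 0)
}

test_that("the outcome classifier labels the canonical histories", {
  t <- seq(0, 30, by = 1)
  ext <- synthetic_ts(mass = exp(-t), max_C0 = 1e-4 + exp(-t) * 0.5,
                      n_crypts = 0)
  expect_equal(classify_outcome(ext, 1)$label, "crypt_extinction")
  grow <- synthetic_ts(mass = 0.01 * exp(t / 5), max_C0 = 0.9, n_crypts = 2)
  expect_equal(classify_outcome(grow, 2)$label, "unstable_progenitor_pool")
  stab <- synthetic_ts(mass = 0.03, max_C0 = 0.4, n_crypts = 2)
  expect_equal(classify_outcome(stab, 2)$label, "stable_crypt_number")
  mult <- synthetic_ts(mass = 0.05, max_C0 = 0.4, n_crypts = 4)
  oc <- classify_outcome(mult, 2)
  expect_equal(oc$label, "crypt_multiplication")
  expect_true(oc$confident)
})

test_that("export_run writes a readable, restartable bundle", {
  params <- default_params()
  params$numerics <- numerics_params(n_points = 64L, t_end = 0.2,
                                     qss_recheck_every = 0L)
  run <- run_simulation(params)
  dir <- tempfile("export")
  export_run(run, dir)
  prof <- utils::read.csv(file.path(dir, "profiles.csv"))
  expect_equal(nrow(prof), 64L)
  expect_lt(max(abs(prof$C0 + prof$C1 - 1)), 1e-12)
  ts <- utils::read.csv(file.path(dir, "timeseries.csv"))
  expect_true(all(c("t", "L", "n_crypts", "energy") %in% names(ts)))
  cfg <- load_config(file.path(dir, "config.yaml"))
  expect_equal(cfg$numerics$n_points, 64L)
  st <- readRDS(file.path(dir, "state.rds"))
  expect_s3_class(st, "crypt_state")
  # restart continues from the stored state
  run2 <- run_simulation(params, init = st, t_end = st$t + 0.01)
  expect_equal(run2$state$t, st$t + 0.01, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})

test_that("scenario plumbing validates names and restart requirements", {
  expect_error(run_scenario("not_a_scenario"), "unknown scenario")
  expect_error(run_scenario("regeneration_full", default_params()),
               "steady state")
})
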