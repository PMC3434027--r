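# Shared fixtures and independent reference implementations used across
# the test files. The oracles re-derive model pieces from their documented
# definitions (adaptive method-of-lines time integration, independently
# written kinetics, quadrature) rather than calling the engine's own
# stepping code.

fixture_env <- new.env(parent = emptyenv())

# Homeostatic two-crypt reference state of the default parameterisation.
# t = 200 puts the state within ~3e-5 (max-norm of C0) of the fixed point:
# the slow mode decays with time constant ~30 and the density rate crosses
# 1e-6 per unit time near t = 200. Computed once and shared.
steady_reference_run <- function() {
  if (is.null(fixture_env$ref_run)) {
    params <- default_params()
    params$numerics$t_end <- 200
    fixture_env$ref_run <- run_simulation(params, record_every = 25)
  }
  fixture_env$ref_run
}

steady_reference <- function() steady_reference_run()$state

# ---------------------------------------------------------------------
# Independent adaptive method-of-lines integrator for the cell-lineage
# system on a fixed domain: C0 is integrated by deSolve::lsoda with tight
# tolerances, with the morphogen quasi-steady state re-solved inside the
# right-hand side. Time integration (adaptive, high order) is fully
# independent of the engine's fixed-step first-order splitting.
mol_integrate_cells <- function(state, params, t_end,
                                rtol = 1e-10, atol = 1e-12) {
  grid <- state$grid
  lp <- params$lineage; mp <- params$morphogen; num <- params$numerics
  env <- new.env(parent = emptyenv())
  env$m <- state$morphogens
  rhs <- function(t, y, parms) {
    cells <- lineage_state(pmin(pmax(y, 0), 1))
    m <- solve_quasi_steady(cells, mp, grid, env$m, num)
    env$m <- m
    p0 <- replication_probability(m, lp)
    d1 <- death_rate_field(grid, cells, lp)
    vel <- compute_velocity(cells, d1, lp, grid)
    gbar <- vel$net_growth_rate / grid$L
    list(lineage_rhs(cells, p0, d1, vel$V, lp, grid) - gbar * cells$C0)
  }
  sol <- deSolve::ode(y = state$cells$C0, times = c(0, t_end), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  unname(sol[nrow(sol), -1])
}

# ---------------------------------------------------------------------
# Independently written morphogen kinetics (from the documented reciprocal
# Hill forms) and an adaptive integrator for the parabolic Wnt/inhibitor
# pair with frozen cells. Used to cross-check the stationary solver and
# the linear dispersion relation.
oracle_hill_up <- function(x, beta, n) {
  t <- (beta * pmax(x, 0))^n
  ifelse(x <= 0, 0, t / (1 + t))
}

oracle_hill_down <- function(x, beta, m) 1 / (1 + (beta * pmax(x, 0))^m)

oracle_reaction <- function(W, I, c0, p) {
  list(rW = p$mu0 * c0 +
         p$alpha_W * oracle_hill_up(W, p$beta_W, p$n_W) *
           oracle_hill_down(I, p$beta_I, p$m_W) - p$d_W * W,
       rI = p$alpha_I * oracle_hill_up(W, p$beta_W_inh, p$n_I) - p$d_I * I)
}

mol_integrate_morphogens <- function(W0, I0, c0, p, L, times,
                                     rtol = 1e-10, atol = 1e-13) {
  n <- length(W0)
  rhs <- function(t, y, parms) {
    W <- y[1:n]; I <- y[(n + 1):(2 * n)]
    r <- oracle_reaction(W, I, c0, p)
    list(c(p$D_W * spectral_derivative(W, 2L, L) + r$rW,
           p$D_I * spectral_derivative(I, 2L, L) + r$rI))
  }
  deSolve::ode(y = c(W0, I0), times = times, func = rhs, parms = NULL,
               method = "lsoda", rtol = rtol, atol = atol)
}

# amplitude of Fourier mode j of a real field
mode_amplitude <- function(f, j) {
  2 * Mod(stats::fft(f)[j + 1]) / length(f)
}

# trapezoid quadrature on the periodic grid (independent of grid_integral's
# rectangle rule; identical for periodic data, which is itself a check)
trapezoid_periodic <- function(f, L) {
  n <- length(f)
  h <- L / n
  sum((f + c(f[-1], f[1])) / 2) * h
}
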