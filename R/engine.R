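# Master time loop: semi-implicit Fourier-spectral stepping of the cell
# field, molecular quasi-steady solves each step, growing-domain dilution,
# and quasi-static curve relaxation.
#
# Splitting order per step (first order, documented):
#   (i)   molecules <- quasi-steady state given current cells
#   (ii)  replication probability, death-rate field, velocity closure
#   (iii) progenitor transport-reaction, explicit in time; the high-order
#         spectral dissipation (36th-order exponential filter on the top
#         third of modes) is applied as the implicitly treated stiff part
#   (iv)  dilution -(Ldot/L) C0 from the growing-domain mapping
#   (v)   curve advanced by the energy gradient flow
#   (vi)  domain length updated (production- or geometry-driven; see the
#         methods vignette)

#' Full simulation state
#'
#' @param grid [crypt_grid()].
#' @param cells [lineage_state()].
#' @param morphogens [morphogen_state()].
#' @param curve [crypt_curve()].
#' @param t current time.
#' @export
crypt_state <- function(grid, cells, morphogens, curve, t = 0) {
  stopifnot(length(cells$C0) == grid$n, length(morphogens$wnt) == grid$n,
            curve$n == grid$n)
  st <- list(grid = grid, cells = cells, morphogens = morphogens,
             curve = curve, t = t)
  class(st) <- "crypt_state"
  st
}

#' @export
print.crypt_state <- function(x, ...) {
  cat(sprintf("crypt state at t = %.4g, L = %.5g\n", x$t, x$grid$L))
  print(x$cells); print(x$morphogens)
  invisible(x)
}

#' Rescale the domain metric
#'
#' Fields are carried on the fixed computational coordinate, so a length
#' change leaves the samples untouched and only updates the metric: total
#' amounts `int f ds` change exactly by `L_new / L_old`; the density
#' effect of growth is the dilution term applied in [imex_step()].
#'
#' @param state [crypt_state()].
#' @param L_new new domain length.
#' @export
remap_fields <- function(state, L_new) {
  stopifnot(L_new > 0)
  state$grid$L <- L_new
  state$grid$h <- L_new / state$grid$n
  state
}

#' One coupled semi-implicit step
#'
#' Advances cells, molecules, curve and domain length by `dt`. Throws on
#' quasi-steady failure or non-finite fields; warns when the advective
#' CFL number exceeds `num$cfl_max` or the progenitor density dips below
#' -1e-8.
#'
#' @param state [crypt_state()].
#' @param params full parameter list as from [default_params()].
#' @param dt time step.
#' @param src optional [wnt_source()].
#' @param cache internal per-run environment (filter masks, morphogen
#'   warm starts); created on the fly when NULL.
#' @return updated [crypt_state()] with attributes `net_growth_rate` and
#'   `cfl`.
#' @export
imex_step <- function(state, params, dt, src = NULL, cache = NULL) {
  lp <- params$lineage; mp <- params$morphogen
  gp <- params$geometry; num <- params$numerics
  grid <- state$grid
  n <- grid$n
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$sigma)) cache$sigma <- filter_sigma(n)

  # (i) molecular quasi-steady state
  relax_first <- if (isTRUE(cache$fresh)) num$qss_relax_max else 0L
  cache$fresh <- FALSE
  m <- solve_quasi_steady(state$cells, mp, grid, state$morphogens, num,
                          src = src, relax_first = relax_first,
                          velocity = cache$V, cache = cache)

  # periodic stability kick: perturb the tracked quasi-steady branch with
  # a tiny seeded band-limited field and let it relax; stable branches
  # return, unstable ones escape to the physical attractor
  cache$step_count <- (cache$step_count %||% 0L) + 1L
  if (num$qss_recheck_every > 0L &&
      cache$step_count %% num$qss_recheck_every == 0L) {
    kick <- kick_field(n, num$seed, cache$step_count)
    kicked <- morphogen_state(pmax(m$wnt * (1 + 1e-3 * kick), 0),
                              m$inhibitor, m$bmp)
    # the relax budget must allow the slow linear growth of an unstable
    # direction to amplify the 1e-3 kick to O(1); a stable branch decays
    # quickly and exits early, so the large cap is cheap in the common case
    m <- solve_quasi_steady(state$cells, mp, grid, kicked, num, src = src,
                            relax_first = num$qss_relax_max,
                            velocity = cache$V, cache = cache)
  }

  # (ii) lineage response fields
  p0 <- replication_probability(m, lp)
  d1 <- death_rate_field(grid, state$cells, lp)
  vel <- compute_velocity(state$cells, d1, lp, grid)
  cache$V <- vel$V
  gbar <- vel$net_growth_rate / grid$L   # mean growth rate = Ldot/L target

  cfl <- max(abs(vel$V)) * dt / grid$h
  if (cfl > num$cfl_max)
    warning(sprintf("advective CFL %.2f exceeds %.2f at t = %.4g",
                    cfl, num$cfl_max, state$t), call. = FALSE)

  # (iii) transport-reaction, explicit; (iv) dilution
  rhs <- lineage_rhs(state$cells, p0, d1, vel$V, lp, grid) -
    gbar * state$cells$C0
  C0 <- apply_filter(state$cells$C0 + dt * rhs, cache$sigma)
  if (any(!is.finite(C0)))
    stop(sprintf("non-finite progenitor density at t = %.4g", state$t))
  # sub-grid Gibbs undershoots at sharp fronts are clipped; warn once per
  # run (per cache) so a persistent undershoot does not flood the caller
  if (min(C0) < -1e-8 && !isTRUE(cache$c0_neg_warned)) {
    warning(sprintf(paste0(
      "progenitor density %.3g below zero at t = %.4g (clipped; ",
      "further undershoots in this run will not warn again)"),
      min(C0), state$t), call. = FALSE)
    cache$c0_neg_warned <- TRUE
  }
  cells <- lineage_state(pmin(pmax(C0, 0), 1))

  # (v) curve relaxation, quasi-static: the crypt depth scale embeds the
  # produced tissue length, so the relaxed arclength tracks production
  L_prod <- grid$L + dt * vel$net_growth_rate
  L_embed <- if (num$length_drive == "fixed") grid$L else L_prod
  curve <- gradient_flow_step(state$curve, cells$C0, gp, dt, grid,
                              L_target = L_embed)

  # (vi) domain length
  L_new <- switch(num$length_drive,
                  production = L_prod,
                  fixed = grid$L,
                  geometry = domain_length(curve))
  if (!is.finite(L_new) || L_new <= 0)
    stop(sprintf("domain length became %.3g at t = %.4g", L_new, state$t))

  out <- crypt_state(crypt_grid(n, L_new), cells, m, curve, state$t + dt)
  attr(out, "net_growth_rate") <- vel$net_growth_rate
  attr(out, "cfl") <- cfl
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic band-limited kick derived from the run seed and step count
kick_field <- function(n, seed, counter) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((as.integer(seed) * 7919L + as.integer(counter)) %% 2147483587L)
  band_limited_noise(n, 16L)
}

#' Run a full simulation
#'
#' Builds the initial state (unless one is supplied), then steps the
#' coupled system to `t_end` or until steady-state detection fires:
#' steady is declared when the max-norm change of the progenitor density
#' per unit time stays below `num$steady_tol` across a sliding window of
#' `num$steady_window` time units.
#'
#' @param params full parameter list (see [default_params()]).
#' @param init optional [crypt_state()] to restart from.
#' @param src optional [wnt_source()], active for the whole run (see
#'   [apply_exogenous_wnt()] for timed sources).
#' @param t_end overrides `params$numerics$t_end`.
#' @param dt overrides `params$numerics$dt`.
#' @param record_every time interval between time-series records.
#' @param keep_snapshots record full field snapshots every
#'   `num$snapshot_every` time units.
#' @param src_until deactivate `src` after this time (NULL: never).
#' @param quiet suppress progress messages.
#' @return object of class `crypt_run`: final `state`, `timeseries`
#'   data.frame (t, L, L_curve, n_crypts, max_C0, mass_C0, p0_max,
#'   net_growth, energy), `snapshots` list, `steady_time` (NA when not
#'   detected), and the effective parameters.
#' @export
run_simulation <- function(params, init = NULL, src = NULL,
                           t_end = NULL, dt = NULL,
                           record_every = 0.5, keep_snapshots = FALSE,
                           src_until = NULL, quiet = TRUE) {
  num <- params$numerics
  if (!is.null(t_end)) num$t_end <- t_end
  if (!is.null(dt)) num$dt <- dt
  params$numerics <- num

  if (is.null(init)) {
    grid <- crypt_grid(num$n_points, L = chord_length(params$geometry))
    sc <- params$scenario$init %||% list(kind = "uniform_noisy_wnt")
    ini <- make_initial_state(sc$kind %||% "uniform_noisy_wnt", grid,
                              options = sc, seed = num$seed)
    state <- crypt_state(grid, ini$cells, ini$morphogens,
                         flat_curve(grid$n, params$geometry), t = 0)
  } else {
    state <- init
  }

  cache <- new.env(parent = emptyenv())
  cache$fresh <- TRUE
  # guard the step count against floating-point excess (e.g. 5 + 1e-16)
  n_steps <- ceiling((num$t_end - state$t) / num$dt - 1e-9)
  rec_stride <- max(1L, round(record_every / num$dt))
  snap_stride <- max(1L, round(num$snapshot_every / num$dt))
  win_steps <- max(1L, round(num$steady_window / num$dt))

  ts <- list(); snaps <- list()
  steady_time <- NA_real_
  C0_window <- state$cells$C0
  record <- function(state, g) {
    summ <- summarize_crypts(state$curve, state$cells$C0, state$grid,
                             params$geometry)
    en <- crypt_energy(state$curve, state$cells$C0, params$geometry,
                       state$grid)
    data.frame(t = state$t, L = state$grid$L,
               L_curve = domain_length(state$curve),
               n_crypts = summ$count,
               max_C0 = max(state$cells$C0),
               mass_C0 = grid_integral(state$cells$C0, state$grid),
               p0_peak = max(replication_probability(state$morphogens,
                                                     params$lineage)$p0),
               net_growth = g, energy = en$E)
  }

  g0 <- NA_real_
  ts[[1]] <- record(state, 0)
  if (keep_snapshots) snaps[[1]] <- state

  for (i in seq_len(n_steps)) {
    state <- imex_step(state, params, num$dt, src = src, cache = cache)
    if (!is.null(src_until) && state$t >= src_until) src <- NULL
    g0 <- attr(state, "net_growth_rate")
    if (i %% rec_stride == 0L) ts[[length(ts) + 1L]] <- record(state, g0)
    if (keep_snapshots && i %% snap_stride == 0L)
      snaps[[length(snaps) + 1L]] <- state
    if (i %% win_steps == 0L) {
      rate <- max(abs(state$cells$C0 - C0_window)) / num$steady_window
      if (is.na(steady_time) && rate < num$steady_tol && state$t > 1) {
        steady_time <- state$t
        if (!quiet) message(sprintf("steady state detected at t = %.4g",
                                    state$t))
        break
      }
      C0_window <- state$cells$C0
    }
  }
  ts[[length(ts) + 1L]] <- record(state, g0)

  out <- list(state = state, timeseries = do.call(rbind, ts),
              snapshots = snaps, steady_time = steady_time,
              params = params)
  class(out) <- "crypt_run"
  out
}

chord_length <- function(gp) {
  sqrt(sum((gp$endpoint_b - gp$endpoint_a)^2))
}

#' @export
print.crypt_run <- function(x, ...) {
  last <- x$timeseries[nrow(x$timeseries), ]
  cat(sprintf(
    "crypt run: t = %.4g, L = %.5g, %d crypt(s), max C0 = %.4g%s\n",
    last$t, last$L, last$n_crypts, last$max_C0,
    if (is.na(x$steady_time)) "" else
      sprintf(" (steady at t = %.4g)", x$steady_time)))
  invisible(x)
}
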