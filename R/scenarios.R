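# Scenario runners reproducing the study protocols, the outcome
# classifier, and the feedback-strength phase diagram.

#' Classify the long-run outcome of a crypt simulation
#'
#' Labels, in order of precedence:
#' * `crypt_extinction` — final progenitor maximum below `eps_ext`;
#' * `unstable_progenitor_pool` — total progenitor mass still growing
#'   (positive fitted slope over the last third of the run) and more than
#'   three times its value at the run's midpoint;
#' * `stable_crypt_number` / `crypt_multiplication` — final crypt count
#'   equal to / above the number of initially seeded progenitor spots.
#'
#' An oscillating crypt count over the last third lowers the confidence
#' flag instead of changing the label.
#'
#' @param timeseries data.frame from a `crypt_run`.
#' @param initial_spot_count number of initially localized progenitor
#'   spots (1 for a uniform start pattern comparison).
#' @param eps_ext extinction threshold on max C0.
#' @return list of class `outcome_label`: `label`, `confident`, `evidence`.
#' @export
classify_outcome <- function(timeseries, initial_spot_count,
                             eps_ext = 1e-3) {
  ts <- timeseries
  nr <- nrow(ts)
  last3 <- ts[ts$t >= ts$t[nr] * 2 / 3, , drop = FALSE]
  mid <- ts$mass_C0[which.min(abs(ts$t - ts$t[nr] / 2))]
  slope <- if (nrow(last3) >= 3)
    unname(stats::coef(stats::lm(mass_C0 ~ t, data = last3))[2]) else 0
  final_max <- ts$max_C0[nr]
  final_count <- ts$n_crypts[nr]
  oscillating <- length(unique(last3$n_crypts)) > 2

  label <- if (final_max < eps_ext) {
    "crypt_extinction"
  } else if (slope > 0 && ts$mass_C0[nr] > 3 * mid) {
    "unstable_progenitor_pool"
  } else if (final_count > initial_spot_count) {
    "crypt_multiplication"
  } else {
    "stable_crypt_number"
  }
  out <- list(label = label, confident = !oscillating,
              evidence = list(final_max_C0 = final_max,
                              final_count = final_count,
                              initial_spot_count = initial_spot_count,
                              mass_slope = slope,
                              mass_final_over_mid = ts$mass_C0[nr] /
                                max(mid, .Machine$double.eps)))
  class(out) <- "outcome_label"
  out
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(sprintf("outcome: %s%s (max C0 %.3g, %d crypt(s), mass slope %.3g)\n",
              x$label, if (x$confident) "" else " [low confidence]",
              x$evidence$final_max_C0, x$evidence$final_count,
              x$evidence$mass_slope))
  invisible(x)
}

#' Run a named scenario protocol
#'
#' Each runner wires up the protocol of one study figure: de-novo
#' formation from uniform cells with fluctuating Wnt; removal-rate scans;
#' ablation/regeneration from a steady state; BMP knockout; localized
#' progenitor seeding; exogenous Wnt sources; and the feedback-strength
#' phase diagram.
#'
#' Scenario options are read from `params$scenario` and may be overridden
#' via `...` (e.g. `values =` for scans, `fraction`, `theta`,
#' `remove_at`). Intervention scenarios (`regeneration_*`, `bmp_knockout`,
#' `exogenous_wnt`) start from a steady state: pass one as `init`, or a
#' snapshot path in `params$scenario$restart`.
#'
#' @param name scenario name (see `scenario_names` in the package source).
#' @param params full parameter list.
#' @param seed integer; overrides `params$numerics$seed`.
#' @param init optional restart [crypt_state()].
#' @param outdir optional directory: time series, profiles, effective
#'   config, seed and the machine-readable summary are written there.
#' @param ... scenario option overrides.
#' @return list of class `scenario_result`: `name`, `run` (or `runs` /
#'   `table` for scans), `summary`, and `outcome` where applicable.
#' @export
run_scenario <- function(name, params = default_params(), seed = NULL,
                         init = NULL, outdir = NULL, ...) {
  if (!name %in% scenario_names)
    stop("unknown scenario name '", name, "'")
  if (!is.null(seed)) params$numerics$seed <- as.integer(seed)
  opts <- utils::modifyList(params$scenario %||% list(), list(...))
  params$scenario$name <- name

  need_restart <- function() {
    if (!is.null(init)) return(init)
    if (!is.null(opts$restart) && file.exists(opts$restart))
      return(readRDS(opts$restart))
    stop("scenario '", name, "' starts from a steady state: supply `init` ",
         "or a snapshot path in scenario$restart", call. = FALSE)
  }

  res <- switch(
    name,
    formation = {
      params$scenario$init <- opts$init %||%
        list(kind = "uniform_noisy_wnt", c0 = opts$c0 %||% 0.5,
             wnt_mean = opts$wnt_mean %||% 0.1,
             noise_amplitude = opts$noise_amplitude %||% 0.05)
      run <- run_simulation(params)
      summ <- summarize_crypts(run$state$curve, run$state$cells$C0,
                               run$state$grid, params$geometry)
      list(run = run, summary = summ,
           outcome = classify_outcome(run$timeseries, summ$count))
    },
    localized_seed = {
      params$scenario$init <- list(kind = "localized_spots",
                                   level = opts$level %||% 0.1,
                                   width_frac = opts$width_frac %||% 0.1,
                                   centers = opts$centers %||% 0.5)
      run <- run_simulation(params)
      summ <- summarize_crypts(run$state$curve, run$state$cells$C0,
                               run$state$grid, params$geometry)
      list(run = run, summary = summ,
           outcome = classify_outcome(run$timeseries,
                                      length(params$scenario$init$centers)))
    },
    dW_scan = ,
    dB_scan = ,
    d1_scan = {
      values <- opts$values %||% switch(name,
        dW_scan = c(0.002, 0.0045, 0.008, 0.0125, 0.018),
        dB_scan = c(1.1e-3, 1.4e-3, 1.75e-3),
        d1_scan = c(0.02, 0.05, 0.1, 0.2))
      runs <- list()
      rows <- list()
      for (v in values) {
        pv <- params
        if (name == "dW_scan") {
          # Wnt removal-rate sweep at fixed production-to-removal ratios:
          # the whole Wnt/inhibitor kinetic block is scaled together, which
          # changes the block's time unit only. The quasi-steady fixed
          # point is invariant, the instability band scales as k^2 ~ d_W,
          # and the selected crypt count as sqrt(d_W).
          sigma <- v / params$morphogen$d_W
          for (f in c("d_W", "d_I", "mu0", "alpha_W", "alpha_I"))
            pv$morphogen[[f]] <- params$morphogen[[f]] * sigma
          # the instability band scales as k^2 ~ d_W, so front widths
          # shrink as 1/sqrt(sigma); scale the grid to keep resolving them
          pv$numerics$n_points <- max(pv$numerics$n_points,
                                      2L * ceiling(sqrt(sigma) *
                                                   pv$numerics$n_points / 2))
        } else if (name == "dB_scan") {
          pv$morphogen$d_B <- v
        } else {
          pv$lineage$d1_max <- v
        }
        run <- run_simulation(pv)
        summ <- summarize_crypts(run$state$curve, run$state$cells$C0,
                                 run$state$grid, pv$geometry)
        predicted <- if (name == "dW_scan")
          predict_crypt_count(pv$morphogen, params$scenario$init$c0 %||% 0.5,
                              run$state$grid$L)$count else NA_integer_
        runs[[as.character(v)]] <- run
        rows[[as.character(v)]] <- data.frame(
          value = v, n_crypts = summ$count, predicted = predicted,
          max_C0 = max(run$state$cells$C0),
          mass_C0 = grid_integral(run$state$cells$C0, run$state$grid),
          height = if (summ$count) max(summ$heights) else 0,
          L = run$state$grid$L)
      }
      list(runs = runs, table = do.call(rbind, rows))
    },
    regeneration_partial = ,
    regeneration_full = {
      base <- need_restart()
      fraction <- opts$fraction %||%
        if (name == "regeneration_full") 1 else 0.5
      segs <- crypt_segments(base$cells$C0, base$grid)
      if (length(segs) < 1) stop("restart state has no crypt to ablate")
      target <- segs[[opts$crypt_index %||% 1L]]
      ablated <- ablate_progenitors(base$cells, target, fraction, base$grid)
      st <- crypt_state(base$grid, ablated, base$morphogens, base$curve,
                        t = 0)
      # the tissue is held at its homeostatic length during regeneration:
      # on the closed periodic domain a production-driven length would
      # contract while the ablated crypt's production is missing (an
      # artifact of the closed-system idealization — in an ablation
      # experiment the surrounding tissue holds the domain), and the
      # shrunken domain stabilises the wrong, crypt-deficient state
      pv <- params
      pv$numerics$length_drive <- "fixed"
      run <- run_simulation(pv, init = st)
      err <- max(abs(run$state$cells$C0 - base$cells$C0))
      list(run = run, reference = base,
           summary = list(recovery_error = err, fraction = fraction),
           outcome = classify_outcome(run$timeseries, length(segs)))
    },
    bmp_knockout = {
      base <- need_restart()
      n0 <- length(crypt_segments(base$cells$C0, base$grid))
      params$lineage$gamma_B <- 0
      st <- crypt_state(base$grid, base$cells, base$morphogens,
                        base$curve, t = 0)
      run <- run_simulation(params, init = st)
      summ <- summarize_crypts(run$state$curve, run$state$cells$C0,
                               run$state$grid, params$geometry)
      list(run = run, summary = summ,
           outcome = classify_outcome(run$timeseries, n0))
    },
    exogenous_wnt = {
      base <- need_restart()
      src <- wnt_source(position_p = opts$position_p %||% 0.75,
                        width_omega = opts$width_omega %||% 0.05,
                        rate_theta = opts$theta %||% 4e-4)
      st <- crypt_state(base$grid, base$cells, base$morphogens,
                        base$curve, t = 0)
      run <- run_simulation(params, init = st, src = src,
                            src_until = opts$remove_at %||% NULL)
      summ <- summarize_crypts(run$state$curve, run$state$cells$C0,
                               run$state$grid, params$geometry)
      list(run = run, summary = summ, source = src,
           outcome = classify_outcome(run$timeseries, 1L))
    },
    phase_diagram = {
      pd <- run_phase_diagram(opts$gammaW_grid %||% c(0.1, 0.7, 2, 6),
                              opts$gammaB_grid %||% c(0, 5, 20),
                              params, seed = params$numerics$seed,
                              spot = opts$spot %||% NULL)
      list(table = pd$table, labels = pd$labels, runs = NULL)
    })

  res$name <- name
  class(res) <- "scenario_result"
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$run)) export_run(res$run, outdir)
    if (!is.null(res$table))
      utils::write.csv(res$table, file.path(outdir, "scan.csv"),
                       row.names = FALSE)
    writeLines(yaml::as.yaml(list(
      scenario = name, seed = params$numerics$seed,
      outcome = if (!is.null(res$outcome)) res$outcome$label else NULL,
      summary = res$summary %||% NULL)),
      file.path(outdir, "summary.yaml"))
  }
  res
}

#' Feedback-strength phase diagram
#'
#' Runs the localized-seed protocol on every `(gamma_W, gamma_B)` grid
#' cell — the same seeded initial distribution of progenitor cells is
#' reused everywhere — and classifies each outcome. Individual failures
#' are recorded as `"error"` and the scan continues.
#'
#' @param gammaW_grid,gammaB_grid feedback-strength grids.
#' @param params base parameter list.
#' @param seed run seed (one seed, one shared initial state).
#' @param spot optional localized-spot options (level, width_frac,
#'   centers).
#' @return list with `labels` (character matrix gamma_B x gamma_W) and
#'   `table` (long-format data.frame with evidence columns).
#' @export
run_phase_diagram <- function(gammaW_grid, gammaB_grid,
                              params = default_params(), seed = 1L,
                              spot = NULL) {
  spot <- spot %||% list(level = 0.1, width_frac = 0.1, centers = 0.5)
  params$numerics$seed <- as.integer(seed)
  labels <- matrix(NA_character_, length(gammaB_grid), length(gammaW_grid),
                   dimnames = list(signif(gammaB_grid, 4),
                                   signif(gammaW_grid, 4)))
  rows <- list()
  for (ib in seq_along(gammaB_grid)) {
    for (iw in seq_along(gammaW_grid)) {
      pv <- params
      pv$lineage$gamma_W <- gammaW_grid[iw]
      pv$lineage$gamma_B <- gammaB_grid[ib]
      pv$scenario$init <- c(list(kind = "localized_spots"), spot)
      res <- tryCatch({
        run <- run_simulation(pv)
        oc <- classify_outcome(run$timeseries, length(spot$centers))
        data.frame(gamma_W = gammaW_grid[iw], gamma_B = gammaB_grid[ib],
                   label = oc$label, confident = oc$confident,
                   final_max_C0 = oc$evidence$final_max_C0,
                   final_count = oc$evidence$final_count,
                   mass_slope = oc$evidence$mass_slope)
      }, error = function(e)
        data.frame(gamma_W = gammaW_grid[iw], gamma_B = gammaB_grid[ib],
                   label = "error", confident = FALSE,
                   final_max_C0 = NA, final_count = NA, mass_slope = NA))
      labels[ib, iw] <- res$label
      rows[[length(rows) + 1L]] <- res
    }
  }
  list(labels = labels, table = do.call(rbind, rows))
}

#' Add (and optionally later remove) an exogenous Wnt source to a run
#'
#' Thin wrapper over [run_simulation()]: the source is active from the
#' start of the continued run and deactivated at `remove_at` when given.
#'
#' @param base steady [crypt_state()] to continue from.
#' @param params parameter list.
#' @param source [wnt_source()].
#' @param remove_at time at which the source is switched off (NULL: kept).
#' @param ... passed to [run_simulation()].
#' @export
apply_exogenous_wnt <- function(base, params, source, remove_at = NULL,
                                ...) {
  st <- crypt_state(base$grid, base$cells, base$morphogens, base$curve,
                    t = 0)
  run_simulation(params, init = st, src = source, src_until = remove_at,
                 ...)
}
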