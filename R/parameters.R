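# Parameter containers. Each constructor validates its fields and names the
# offending field in the error, so config loading can surface precise
# messages. Defaults form the package's reference parameterisation: values
# printed in the source figures are used as-is; the remaining values are
# calibrated so that the Wnt/inhibitor pair is Turing-unstable (see
# `dispersion_relation`) and the de-novo scenario settles into a two-crypt
# steady state on the default domain. Calibrated values are flagged in the
# shipped config file.

check_positive <- function(value, field, strict = TRUE) {
  if (length(value) != 1L || !is.finite(value) ||
      (strict && value <= 0) || (!strict && value < 0))
    stop("parameter '", field, "' must be a ",
         if (strict) "positive" else "non-negative", " number, got ",
         paste(format(value), collapse = ","), call. = FALSE)
  as.numeric(value)
}

#' Cell-lineage parameters
#'
#' @param v0 reciprocal of the cell-cycle length scaled by ln 2; sets the
#'   cellular time unit (default 1: time is measured in cell cycles / ln 2).
#' @param p0_max maximal replication probability of progenitor cells, in
#'   (0, 1].
#' @param gamma_W,gamma_B reciprocal EC50s of the Wnt and BMP response in
#'   the replication probability (1/uM).
#' @param n,m Hill exponents of the Wnt and BMP response.
#' @param d1_max maximal removal rate of terminally differentiated cells
#'   (1/time).
#' @param d1_profile named spatial-regulation profile for the TD-cell death
#'   rate: a list with `name` ("constant" or "apex_localized") and, for the
#'   localized profile, `floor_frac` (death-rate floor as a fraction of
#'   `d1_max`, default 0.1) and `width_frac` (kernel width as a fraction of
#'   the domain, default 0.08).
#' @return object of class `lineage_params`.
#' @export
lineage_params <- function(v0 = 1, p0_max = 0.95,
                           gamma_W = 1.2, n = 2,
                           gamma_B = 5, m = 2,
                           d1_max = 0.15,
                           d1_profile = list(name = "constant")) {
  p <- list(
    v0      = check_positive(v0, "v0"),
    p0_max  = check_positive(p0_max, "p0_max"),
    gamma_W = check_positive(gamma_W, "gamma_W"),
    n       = check_positive(n, "n"),
    gamma_B = check_positive(gamma_B, "gamma_B", strict = FALSE),
    m       = check_positive(m, "m"),
    d1_max  = check_positive(d1_max, "d1_max"),
    d1_profile = validate_d1_profile(d1_profile)
  )
  if (p$p0_max > 1) stop("parameter 'p0_max' must be <= 1", call. = FALSE)
  class(p) <- "lineage_params"
  p
}

validate_d1_profile <- function(prof) {
  if (is.character(prof)) prof <- list(name = prof)
  if (is.null(prof$name)) stop("d1_profile needs a 'name'", call. = FALSE)
  known <- c("constant", "apex_localized")
  if (!prof$name %in% known)
    stop("unknown d1_profile '", prof$name, "'; known: ",
         paste(known, collapse = ", "), call. = FALSE)
  if (prof$name == "apex_localized") {
    if (is.null(prof$floor_frac)) prof$floor_frac <- 0.1
    if (is.null(prof$width_frac)) prof$width_frac <- 0.08
    check_positive(prof$floor_frac, "d1_profile$floor_frac")
    check_positive(prof$width_frac, "d1_profile$width_frac")
    if (prof$floor_frac > 1)
      stop("d1_profile$floor_frac must be <= 1", call. = FALSE)
  }
  prof
}

#' Morphogen (Wnt / Wnt-inhibitor / BMP) parameters
#'
#' Rates carry the molecular time unit (per second in the reference
#' parameterisation); because the molecules are always solved at quasi-steady
#' state, only ratios of molecular rates matter to the coupled model, and
#' the quasi-steady solution is invariant under a common rescaling of all
#' production, removal and diffusion constants.
#'
#' The default kinetics are calibrated so that the uniform Wnt/inhibitor
#' fixed point is unique and linearly stable at every progenitor density
#' (no trapping low-Wnt state) and Turing-unstable near the homogeneous
#' start `C0 = 1/2`, with fastest mode 2 on the default domain — two
#' crypts form de novo. Because only rate ratios matter at quasi-steady
#' state, a physically meaningful removal-rate sweep co-scales the whole
#' Wnt/inhibitor kinetic block (see the `dW_scan` scenario), which moves
#' the instability band as `k^2` proportional to `d_W` and the selected
#' crypt count as `sqrt(d_W)`.
#'
#' @param D_W,D_I,D_B diffusion coefficients (length^2/time).
#' @param mu0 Wnt production rate per unit progenitor density (uM/time).
#' @param mu1 BMP production rate per unit TD-cell density (uM/time).
#' @param alpha_W self-enhanced Wnt activation rate (uM/time).
#' @param alpha_I Wnt-inhibitor synthesis rate (uM/time).
#' @param beta_W,beta_I,beta_W_inh reciprocal EC50s: Wnt self-activation,
#'   inhibitor repression of Wnt, and Wnt activation of the inhibitor
#'   (1/uM).
#' @param n_W,m_W,n_I Hill coefficients of the three responses.
#' @param d_W,d_I,d_B linear removal rates (1/time).
#' @return object of class `morphogen_params`. The derived non-dimensional
#'   ratios `d_I/d_W` and `D_I/D_W` are available via [morphogen_ratios()].
#' @export
morphogen_params <- function(D_W = 6e-8, D_I = 1.5e-6, D_B = 2e-5,
                             mu0 = 1.6e-3, mu1 = 2.5e-4,
                             alpha_W = 6e-3, alpha_I = 8e-3,
                             beta_W = 1, beta_I = 0.7, beta_W_inh = 1,
                             n_W = 4, m_W = 2, n_I = 2,
                             d_W = 2e-3, d_I = 2e-3, d_B = 1.4e-3) {
  fields <- list(D_W = D_W, D_I = D_I, D_B = D_B, mu0 = mu0, mu1 = mu1,
                 alpha_W = alpha_W, alpha_I = alpha_I, beta_W = beta_W,
                 beta_I = beta_I, beta_W_inh = beta_W_inh, n_W = n_W,
                 m_W = m_W, n_I = n_I, d_W = d_W, d_I = d_I, d_B = d_B)
  nonneg <- c("mu0", "mu1")      # basal production may be switched off
  p <- mapply(function(v, f) check_positive(v, f, strict = !(f %in% nonneg)),
              fields, names(fields), SIMPLIFY = FALSE)
  class(p) <- "morphogen_params"
  p
}

#' Non-dimensional removal-rate and diffusivity ratios of the Turing pair
#' @param p a `morphogen_params` object
#' @return named vector with `d_ratio` = d_I/d_W and `D_ratio` = D_I/D_W.
#' @export
morphogen_ratios <- function(p) {
  c(d_ratio = p$d_I / p$d_W, D_ratio = p$D_I / p$D_W)
}

#' Crypt-geometry parameters
#'
#' @param epsilon0 sharpness of the crypt shape in the energy functional
#'   (length).
#' @param baseline_b vertical offset of the crypt baseline (length).
#' @param endpoint_a,endpoint_b fixed 2D endpoints of the tissue curve.
#' @param flow_rate relaxation coefficient of the gradient flow (1/time);
#'   large values keep the curve quasi-statically slaved to the cell
#'   pattern.
#' @param energy_kind identifier of the energy functional; "tanh_wells" is
#'   the built-in per-crypt depression energy. A function (curve, C0, grid,
#'   gp) -> list(E, grad_x, grad_y) may be supplied for custom functionals.
#' @param count_threshold_frac crypt-counting threshold as a fraction of the
#'   global progenitor maximum.
#' @export
geometry_params <- function(epsilon0 = 0.005, baseline_b = 0,
                            endpoint_a = c(-0.1, 0), endpoint_b = c(0.1, 0),
                            flow_rate = 50, energy_kind = "tanh_wells",
                            count_threshold_frac = 0.1) {
  check_positive(epsilon0, "epsilon0")
  check_positive(flow_rate, "flow_rate")
  check_positive(count_threshold_frac, "count_threshold_frac")
  if (length(endpoint_a) != 2L || length(endpoint_b) != 2L)
    stop("endpoints must be length-2 coordinate vectors", call. = FALSE)
  if (all(endpoint_a == endpoint_b))
    stop("parameter 'endpoint_b' must differ from endpoint_a", call. = FALSE)
  p <- list(epsilon0 = epsilon0, baseline_b = baseline_b,
            endpoint_a = as.numeric(endpoint_a),
            endpoint_b = as.numeric(endpoint_b),
            flow_rate = flow_rate, energy_kind = energy_kind,
            count_threshold_frac = count_threshold_frac)
  class(p) <- "geometry_params"
  p
}

#' Exogenous Wnt source
#'
#' A constant-rate Wnt source confined to the arc
#' `[position_p - width_omega/2, position_p + width_omega/2]`, wrapped
#' periodically; positions are fractions of the current domain length.
#'
#' @param position_p centre of the source region (fraction of L).
#' @param width_omega width of the region (fraction of L).
#' @param rate_theta production rate inside the region (uM/time).
#' @export
wnt_source <- function(position_p = 0.75, width_omega = 0.05,
                       rate_theta = 4e-4) {
  check_positive(width_omega, "width_omega")
  check_positive(rate_theta, "rate_theta", strict = FALSE)
  s <- list(position_p = position_p %% 1, width_omega = width_omega,
            rate_theta = rate_theta)
  class(s) <- "wnt_source"
  s
}

# indicator (0/1) of the source window on the xi grid
source_window <- function(src, grid) {
  if (is.null(src)) return(rep(0, grid$n))
  as.numeric(xi_distance(grid$xi, src$position_p) <= src$width_omega / 2)
}

#' Numerical settings
#'
#' @param dt time-step of the cell-scale integrator (cell time units).
#'   The default resolves the O(0.1-1) cellular rates with relative
#'   first-order error below a percent; halve it to confirm convergence.
#' @param t_end final time.
#' @param n_points spatial grid points (even).
#' @param qss_tol residual tolerance of the molecular quasi-steady solve.
#' @param qss_tol_soft fallback tolerance accepted (with a one-time
#'   warning) when the stationary Jacobian passes near a fold of the
#'   quasi-steady branch during a transient and the strict tolerance is
#'   uncertifiable; the solve hard-fails above this value. The default is
#'   several orders of magnitude below the reaction scale.
#' @param qss_max_iter Newton iteration cap per solve.
#' @param qss_relax_max cap on pseudo-time relaxation sweeps.
#' @param qss_recheck_every re-test the tracked quasi-steady branch for
#'   dynamic stability every this many steps (0 disables): a tiny seeded
#'   band-limited kick is applied and relaxed; a stable branch returns, an
#'   unstable one escapes to the physical attractor.
#' @param seed random seed used for every stochastic ingredient of a run.
#' @param snapshot_every record a full field snapshot every this many time
#'   units.
#' @param steady_tol steady-state detection threshold: max-norm change of
#'   progenitor density per unit time.
#' @param steady_window sliding-window length (time units) for detection.
#' @param length_drive "production" (domain length integrates net cell
#'   production; exact mass balance), "geometry" (length follows the
#'   relaxed curve's arclength) or "fixed" (length held constant; net
#'   production is shed uniformly — used by fixed-domain verification
#'   protocols). See the methods vignette.
#' @param cfl_max warn when |V| dt / h exceeds this.
#' @param qss_include_advection retain the molecular convection term in the
#'   quasi-steady solve (sensitivity switch; default drops it).
#' @param strict_negative error on quasi-steady iterates below -1e-12
#'   instead of clipping.
#' @export
numerics_params <- function(dt = 2e-3, t_end = 100, n_points = 128L,
                            qss_tol = 1e-9, qss_tol_soft = 1e-5,
                            qss_max_iter = 40L,
                            qss_relax_max = 4000L, qss_recheck_every = 200L,
                            seed = 1L, snapshot_every = 10,
                            steady_tol = 1e-6, steady_window = 1,
                            length_drive = "production",
                            cfl_max = 0.5,
                            qss_include_advection = FALSE,
                            strict_negative = FALSE) {
  check_positive(dt, "dt")
  check_positive(t_end, "t_end")
  check_positive(qss_tol, "qss_tol")
  check_positive(qss_tol_soft, "qss_tol_soft")
  if (!length_drive %in% c("production", "geometry", "fixed"))
    stop("length_drive must be 'production', 'geometry' or 'fixed'",
         call. = FALSE)
  p <- list(dt = dt, t_end = t_end, n_points = as.integer(n_points),
            qss_tol = qss_tol, qss_tol_soft = qss_tol_soft,
            qss_max_iter = as.integer(qss_max_iter),
            qss_relax_max = as.integer(qss_relax_max),
            qss_recheck_every = as.integer(qss_recheck_every),
            seed = as.integer(seed), snapshot_every = snapshot_every,
            steady_tol = steady_tol, steady_window = steady_window,
            length_drive = length_drive, cfl_max = cfl_max,
            qss_include_advection = isTRUE(qss_include_advection),
            strict_negative = isTRUE(strict_negative))
  class(p) <- "numerics_params"
  p
}

#' Full default parameterisation
#'
#' @return list with components `lineage`, `morphogen`, `geometry`,
#'   `numerics` and `scenario` (a free-form list holding the scenario name
#'   and its options).
#' @export
default_params <- function() {
  list(lineage = lineage_params(), morphogen = morphogen_params(),
       geometry = geometry_params(), numerics = numerics_params(),
       scenario = list(name = "formation",
                       init = list(kind = "uniform_noisy_wnt",
                                   c0 = 0.5, wnt_mean = 0.1,
                                   noise_amplitude = 0.05, n_modes = 16L)))
}
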