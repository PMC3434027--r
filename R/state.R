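# State containers: cell densities, morphogen concentrations, the embedded
# tissue curve, and seeded initial-condition generation.

#' Cell-lineage state
#'
#' Progenitor density `C0` and TD-cell density `C1` on the periodic grid.
#' Total density is one everywhere by construction: `C1` is stored as
#' `1 - C0`, which makes the normalization a structural identity rather
#' than a numerical one.
#'
#' @param C0 progenitor density per grid point (in `[0, 1]`).
#' @export
lineage_state <- function(C0) {
  if (any(!is.finite(C0))) stop("non-finite progenitor density")
  if (any(C0 < -1e-10) || any(C0 > 1 + 1e-10))
    stop("progenitor density outside [0, 1]")
  C0 <- pmin(pmax(C0, 0), 1)
  s <- list(C0 = C0, C1 = 1 - C0)
  class(s) <- "lineage_state"
  s
}

#' @export
print.lineage_state <- function(x, ...) {
  cat(sprintf("lineage state: %d points, C0 in [%.4g, %.4g], mean %.4g\n",
              length(x$C0), min(x$C0), max(x$C0), mean(x$C0)))
  invisible(x)
}

#' Morphogen state
#'
#' Wnt, Wnt-inhibitor and BMP concentration fields (uM) on the grid.
#' @param wnt,inhibitor,bmp non-negative concentration vectors of equal
#'   length.
#' @export
morphogen_state <- function(wnt, inhibitor = rep(0, length(wnt)),
                            bmp = rep(0, length(wnt))) {
  n <- length(wnt)
  if (length(inhibitor) != n || length(bmp) != n)
    stop("morphogen fields must share the grid length")
  for (f in list(wnt, inhibitor, bmp))
    if (any(!is.finite(f)) || any(f < -1e-10))
      stop("morphogen concentrations must be finite and >= 0")
  m <- list(wnt = pmax(wnt, 0), inhibitor = pmax(inhibitor, 0),
            bmp = pmax(bmp, 0))
  class(m) <- "morphogen_state"
  m
}

#' @export
print.morphogen_state <- function(x, ...) {
  cat(sprintf(
    "morphogens: max Wnt %.4g, max inhibitor %.4g, max BMP %.4g uM\n",
    max(x$wnt), max(x$inhibitor), max(x$bmp)))
  invisible(x)
}

#' Tissue curve in the plane
#'
#' `n + 1` nodes: node `j` sits at computational coordinate `xi = j/n`;
#' node 0 and node n are the two pinned endpoints (the field coordinate is
#' periodic, the embedding is an open curve between distinct anchor
#' points).
#'
#' @param x,y coordinate vectors of length `n + 1`.
#' @export
crypt_curve <- function(x, y) {
  if (length(x) != length(y) || length(x) < 9L)
    stop("curve needs matching x/y of length n + 1 >= 9")
  cv <- list(x = as.numeric(x), y = as.numeric(y), n = length(x) - 1L)
  class(cv) <- "crypt_curve"
  cv
}

#' Flat initial curve between the pinned endpoints
#' @param n number of field grid points (curve has `n + 1` nodes).
#' @param gp geometry parameters (supplies the endpoints and baseline).
#' @export
flat_curve <- function(n, gp = geometry_params()) {
  t <- (0:n) / n
  crypt_curve(x = gp$endpoint_a[1] + t * (gp$endpoint_b[1] - gp$endpoint_a[1]),
              y = gp$endpoint_a[2] + t * (gp$endpoint_b[2] - gp$endpoint_a[2]))
}

#' @export
print.crypt_curve <- function(x, ...) {
  cat(sprintf("tissue curve: %d nodes, arclength %.5g, depth range [%.4g, %.4g]\n",
              x$n + 1L, domain_length(x), min(x$y), max(x$y)))
  invisible(x)
}

# band-limited periodic noise: sum of the first `n_modes` Fourier modes
# with seeded uniform amplitudes/phases, normalized to unit max amplitude
band_limited_noise <- function(n, n_modes = 16L) {
  xi <- (0:(n - 1)) / n
  z <- rep(0, n)
  for (j in seq_len(n_modes)) {
    amp <- stats::runif(1, -1, 1)
    ph  <- stats::runif(1, 0, 2 * pi)
    z <- z + amp * cos(2 * pi * j * xi + ph)
  }
  if (max(abs(z)) > 0) z <- z / max(abs(z))
  z
}

#' Seeded initial conditions
#'
#' Generates the study's initial states: `uniform_noisy_wnt` (uniform cells
#' with a low, fluctuating Wnt field and no inhibitor or BMP — the de-novo
#' formation start), `random_wnt_field` (band-limited random Wnt of larger
#' amplitude, used to probe multi-stability of the pattern),
#' `localized_spots` (progenitor cells placed in one or more arcs of the
#' domain, zero elsewhere) and `from_snapshot` (restart from a stored
#' state).
#'
#' Identical seeds produce bit-identical states. Noise is applied to Wnt
#' only; optional progenitor noise is a separate switch (`c0_noise`).
#'
#' @param kind one of "uniform_noisy_wnt", "random_wnt_field",
#'   "localized_spots", "from_snapshot".
#' @param grid a [crypt_grid()].
#' @param options list of kind-specific options: `c0`, `wnt_mean`,
#'   `noise_amplitude`, `n_modes`, `c0_noise` (noisy kinds); `level`,
#'   `width_frac`, `centers` (localized spots); `path` or `state`
#'   (snapshot restart).
#' @param seed integer seed.
#' @return list with components `cells` ([lineage_state()]) and
#'   `morphogens` ([morphogen_state()]).
#' @export
make_initial_state <- function(kind = c("uniform_noisy_wnt",
                                        "random_wnt_field",
                                        "localized_spots",
                                        "from_snapshot"),
                               grid, options = list(), seed = 1L) {
  kind <- match.arg(kind)
  n <- grid$n
  opt <- function(name, default) {
    if (!is.null(options[[name]])) options[[name]] else default
  }
  set.seed(as.integer(seed))

  if (kind == "from_snapshot") {
    st <- options$state
    if (is.null(st) && !is.null(options$path)) st <- readRDS(options$path)
    if (is.null(st)) stop("from_snapshot needs options$state or options$path")
    return(list(cells = st$cells, morphogens = st$morphogens))
  }

  if (kind == "localized_spots") {
    level <- opt("level", 0.1)
    if (level < 0 || level > 1) stop("spot level must lie in [0, 1]")
    width <- opt("width_frac", 0.1)
    if (width <= 0 || width > 1)
      stop("spot width_frac must lie in (0, 1] of the domain")
    centers <- opt("centers", 0.5)
    if (length(centers) * width > 1)
      stop("total spot width exceeds the domain")
    C0 <- rep(0, n)
    for (ctr in centers)
      C0[xi_distance(grid$xi, ctr) <= width / 2] <- level
    wnt <- opt("wnt_mean", 0.1) +
      opt("noise_amplitude", 0.05) * band_limited_noise(n, opt("n_modes", 16L))
    return(list(cells = lineage_state(C0),
                morphogens = morphogen_state(pmax(wnt, 0))))
  }

  # noisy uniform kinds
  c0 <- opt("c0", 0.5)
  amp <- opt("noise_amplitude", if (kind == "uniform_noisy_wnt") 0.05 else 0.5)
  wnt_mean <- opt("wnt_mean", if (kind == "uniform_noisy_wnt") 0.1 else 0.5)
  n_modes <- opt("n_modes", 16L)
  wnt <- wnt_mean + amp * band_limited_noise(n, n_modes)
  C0 <- rep(c0, n)
  c0_noise <- opt("c0_noise", 0)
  if (c0_noise > 0)
    C0 <- pmin(pmax(C0 + c0_noise * band_limited_noise(n, n_modes), 0), 1)
  list(cells = lineage_state(C0), morphogens = morphogen_state(pmax(wnt, 0)))
}
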