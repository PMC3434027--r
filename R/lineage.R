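# Cell-lineage dynamics: replication probability, spatially regulated
# TD-cell removal, the velocity closure, the progenitor transport-reaction
# right-hand side, and ablation interventions.

#' Replication probability of progenitor cells
#'
#' Hill response combining Wnt activation and BMP repression:
#' `p0 = p0_max * x / (1 + x + y)` with `x = (gamma_W [Wnt])^n` and
#' `y = (gamma_B [BMP])^m`. Strictly increasing in Wnt, strictly
#' decreasing in BMP; zero where Wnt vanishes. A division yields two
#' progenitors with probability `p0` and two TD cells otherwise, so the
#' progenitor pool expands locally when `p0 > 1/2`.
#'
#' @param m [morphogen_state()].
#' @param lp [lineage_params()].
#' @return list of class `replication_field` with component `p0`.
#' @export
replication_probability <- function(m, lp) {
  if (any(m$wnt < 0) || any(m$bmp < 0)) stop("negative concentration input")
  x <- (lp$gamma_W * m$wnt)^lp$n
  y <- (lp$gamma_B * m$bmp)^lp$m
  p0 <- lp$p0_max * x / (1 + x + y)
  p0[m$wnt == 0] <- 0
  big <- !is.finite(x)
  if (any(big)) p0[big] <- lp$p0_max / (1 + ifelse(is.finite(y[big]), 0, 1))
  out <- list(p0 = p0)
  class(out) <- "replication_field"
  out
}

#' Spatially regulated TD-cell removal rate
#'
#' The "constant" profile removes TD cells uniformly at `d1_max`. The
#' "apex_localized" profile concentrates removal away from progenitor
#' peaks (shedding at the luminal surface): a smooth Gaussian kernel of
#' the periodic distance to the nearest progenitor maximum suppresses the
#' rate near crypt bases down to a floor `floor_frac * d1_max`.
#'
#' @param grid [crypt_grid()].
#' @param cells [lineage_state()].
#' @param lp [lineage_params()].
#' @return removal-rate vector, `0 < d1 <= d1_max` pointwise.
#' @export
death_rate_field <- function(grid, cells, lp) {
  prof <- lp$d1_profile
  if (prof$name == "constant") return(rep(lp$d1_max, grid$n))
  # apex_localized
  segs <- crypt_segments(cells$C0, grid, threshold = 0.1 * max(cells$C0, 0))
  if (length(segs) == 0) return(rep(lp$d1_max, grid$n))
  peaks <- vapply(segs, function(s) grid$xi[s$peak_idx], numeric(1))
  w <- prof$width_frac
  near <- rep(0, grid$n)
  for (pk in peaks)
    near <- pmax(near, exp(-(xi_distance(grid$xi, pk) / w)^2))
  lp$d1_max * (prof$floor_frac + (1 - prof$floor_frac) * (1 - near))
}

#' Cell velocity from the incompressibility closure
#'
#' With total density pinned at one, the divergence of the cell velocity
#' equals net local production: `dV/ds = v0 C0 - d1 C1`. On the periodic
#' domain the mean of the source is absorbed into uniform domain growth,
#' and `V` is the zero-mean periodic antiderivative of the fluctuating
#' part (any constant shift of `V` is a relabelling of the periodic
#' coordinate).
#'
#' @param cells [lineage_state()].
#' @param d1 removal-rate field (from [death_rate_field()]).
#' @param lp [lineage_params()].
#' @param grid [crypt_grid()].
#' @return list with `V` (zero-mean periodic velocity) and
#'   `net_growth_rate` (the integral of the source over the domain, which
#'   drives domain-length change).
#' @export
compute_velocity <- function(cells, d1, lp, grid) {
  if (max(abs(cells$C0 + cells$C1 - 1)) > 1e-8)
    stop("total cell density is not normalized")
  g <- lp$v0 * cells$C0 - d1 * cells$C1
  V <- periodic_antiderivative(g, grid$L) # zero-mean by construction
  list(V = V, net_growth_rate = grid_integral(g, grid))
}

#' Progenitor transport-reaction right-hand side
#'
#' `dC0/dt = v0 (2 p0 - 1) C0 - d(V C0)/ds`, evaluated spectrally. The
#' growing-domain dilution term is applied by the time stepper, and the
#' TD density is never integrated independently: `C1 = 1 - C0` holds by
#' construction, which is algebraically consistent with the TD equation
#' under the velocity closure.
#'
#' @param cells [lineage_state()].
#' @param p0 [replication_probability()] output.
#' @param d1 removal-rate field (kept for signature symmetry; enters via
#'   the velocity).
#' @param V zero-mean periodic velocity.
#' @param lp [lineage_params()].
#' @param grid [crypt_grid()].
#' @export
lineage_rhs <- function(cells, p0, d1, V, lp, grid) {
  lp$v0 * (2 * p0$p0 - 1) * cells$C0 -
    spectral_derivative(V * cells$C0, 1L, grid$L)
}

#' Replace progenitor cells by TD cells in an arc
#'
#' Inside the region, `C0 <- (1 - fraction) * C0` and `C1` complements it,
#' so the total density stays one everywhere (the ablated progenitors are
#' replaced, not removed).
#'
#' @param cells [lineage_state()].
#' @param region either a list `list(from =, to =)` of xi coordinates
#'   (wrapped periodically) or a crypt segment as returned by
#'   [crypt_segments()].
#' @param fraction fraction of progenitors replaced, in `[0, 1]`.
#' @param grid [crypt_grid()].
#' @export
ablate_progenitors <- function(cells, region, fraction, grid) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (!is.null(region$idx)) {
    idx <- region$idx
  } else {
    from <- region$from %% 1; to <- region$to %% 1
    xi <- grid$xi
    idx <- if (from <= to) which(xi >= from & xi <= to)
           else which(xi >= from | xi <= to)
  }
  if (length(idx) == 0) stop("empty ablation region")
  C0 <- cells$C0
  C0[idx] <- (1 - fraction) * C0[idx]
  lineage_state(C0)
}
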