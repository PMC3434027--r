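# Crypt geometry: segmentation of the progenitor pattern, the per-crypt
# depression energy, its gradient flow, arclength, and summary observables.

#' Contiguous crypt arcs of the progenitor pattern
#'
#' Maximal contiguous arcs where `C0 > threshold`, merged across the
#' periodic seam; arcs narrower than two grid cells are discarded. Each
#' arc carries its index set, its peak location and value, and its
#' progenitor mass (integral of C0 over the arc).
#'
#' @param C0 progenitor density vector.
#' @param grid [crypt_grid()].
#' @param threshold density threshold; the default is a fixed fraction of
#'   the global maximum (see [geometry_params()]).
#' @return list of segments (possibly empty); each has `idx`, `peak_idx`,
#'   `peak_value`, `mass`, `xi_from`, `xi_to`.
#' @export
crypt_segments <- function(C0, grid, threshold = 0.1 * max(C0, 0)) {
  n <- grid$n
  above <- C0 > threshold
  if (!any(above)) return(list())
  if (all(above)) {
    return(list(list(idx = seq_len(n), peak_idx = which.max(C0),
                     peak_value = max(C0), mass = grid_integral(C0, grid),
                     xi_from = 0, xi_to = 1 - 1 / n, wraps = TRUE)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  runs <- Map(function(s, e, v) if (v) s:e else NULL, starts, ends, r$values)
  runs <- Filter(Negate(is.null), runs)
  # merge across the seam
  if (above[1] && above[n] && length(runs) > 1) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  runs <- Filter(function(ix) length(ix) >= 2L, runs)
  lapply(runs, function(ix) {
    pk <- ix[which.max(C0[ix])]
    list(idx = ix, peak_idx = pk, peak_value = C0[pk],
         mass = sum(C0[ix]) * grid$L / n,
         xi_from = grid$xi[ix[1]], xi_to = grid$xi[ix[length(ix)]],
         wraps = ix[1] > ix[length(ix)])
  })
}

# xi coordinate of the embedding seam: the midpoint of the widest gap
# between consecutive crypt segments. The periodic field is cut there
# before being laid out between the pinned endpoints, so no crypt
# depression straddles an endpoint (a well containing a pinned node can
# never be dug, which would silently lose arclength).
seam_xi <- function(segments) {
  if (length(segments) == 0) return(0)
  from <- vapply(segments, function(s) s$xi_from, numeric(1))
  to <- vapply(segments, function(s) s$xi_to, numeric(1))
  o <- order(from)
  from <- from[o]; to <- to[o]
  gap_start <- to
  gap_width <- (c(from[-1], from[1]) - to) %% 1
  i <- which.max(gap_width)
  (gap_start[i] + gap_width[i] / 2) %% 1
}

# horizontal chord positions of the crypt centres under the seam cut
segment_centers <- function(segments, grid, gp, xi0 = seam_xi(segments)) {
  ax <- gp$endpoint_a[1]; bx <- gp$endpoint_b[1]
  vapply(segments, function(s) {
    u <- (grid$xi[s$peak_idx] - xi0) %% 1
    ax + u * (bx - ax)
  }, numeric(1))
}

# Per-segment target depth profile in the horizontal coordinate x:
# each crypt contributes a tanh-smoothed depression of half-width
# d(C0) = mass / max(C0) (an effective crypt diameter) centred at
# `centers[k]`; depressions of different crypts superpose. Relative
# depths are proportional to the peak progenitor density; the absolute
# scale `depth_mult` (length per unit density) is solved separately so
# the folded curve embeds the produced tissue length (see
# solve_depth_multiplier).
curve_target <- function(x_nodes, segments, centers, gp, depth_mult = 1) {
  tgt <- rep(gp$baseline_b, length(x_nodes))
  dtgt <- rep(0, length(x_nodes))
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    M <- depth_mult * seg$peak_value
    if (M <= 0) next
    xstar <- centers[k]
    d <- seg$mass / seg$peak_value   # physical half-width, scale-free
    u <- (d - abs(x_nodes - xstar)) / gp$epsilon0
    H <- (tanh(u) + 1) / 2
    tgt <- tgt - M * H
    Hp <- (1 - tanh(u)^2) / 2
    dtgt <- dtgt + M * Hp * sign(x_nodes - xstar) / gp$epsilon0
  }
  list(target = tgt, dtarget = dtgt)
}

# Scalar depth multiplier m such that the target profile with crypt
# depths m * peak_value has polyline arclength equal to `L_target`
# (the produced tissue length): the curve between the pinned endpoints
# must fold the excess length into the crypt depressions. Returns 0 when
# there is nothing to fold (no crypts, or no excess length). The
# arclength of the target profile is strictly increasing in m, so
# bisection via uniroot is safe.
solve_depth_multiplier <- function(segments, centers, curve, gp, L_target,
                                   m_prev = NULL) {
  chord <- sum(sqrt(diff(curve$x)^2))
  if (length(segments) == 0 || L_target <= chord + 1e-12) return(0)
  arclen_at <- function(m) {
    tg <- curve_target(curve$x, segments, centers, gp, depth_mult = m)$target
    sum(sqrt(diff(curve$x)^2 + diff(tg)^2))
  }
  f <- function(m) arclen_at(m) - L_target
  # warm start: along a run the multiplier changes little per step, so a
  # narrow bracket around the previous value usually contains the root
  if (!is.null(m_prev) && is.finite(m_prev) && m_prev > 0) {
    lo <- 0.7 * m_prev; hi_w <- 1.4 * m_prev
    flo <- f(lo); fhi <- f(hi_w)
    if (flo < 0 && fhi > 0)
      return(stats::uniroot(f, c(lo, hi_w), f.lower = flo, f.upper = fhi,
                            tol = 1e-12)$root)
  }
  hi <- (L_target - chord) / max(1e-12, sum(vapply(segments, function(s)
    2 * s$peak_value, numeric(1))))
  while (f(hi) < 0 && hi < 1e6) {
    hi <- 2 * hi
    # a depression spanning the whole chord only shifts the profile and
    # never adds arclength (e.g. the near-uniform pattern before crypts
    # individuate); nothing can be folded yet, keep the curve flat
    if (arclen_at(hi) - arclen_at(0) < 1e-3 * (L_target - chord)) return(0)
  }
  if (f(hi) < 0) return(0)
  stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}

#' Crypt-shape energy
#'
#' Discrete energy `E = mean_j (y_j + sum_k M_k H_k(x_j) - b)^2` over the
#' curve nodes, where each crypt segment `k` contributes a smoothed
#' depression of half-width `d_k = mass_k / peak_k` centred at the
#' horizontal position of its progenitor peak. Depths `M_k` are
#' proportional to the peak progenitor density; the proportionality
#' constant (a length per unit density) is solved so that the target
#' curve's arclength equals the domain length `L_target` — the folded
#' epithelium embeds exactly the tissue length produced by the lineage.
#' `E = 0` exactly when the curve matches the target profile; with no
#' crypts the integrand reduces to `(y - b)^2`, minimised by the flat
#' baseline.
#'
#' @param curve [crypt_curve()].
#' @param C0 progenitor density (length `n`).
#' @param gp [geometry_params()].
#' @param grid [crypt_grid()].
#' @param L_target tissue length the folded curve must embed; defaults to
#'   the current domain length `grid$L`.
#' @return list with `E` (scalar), `integrand` (per node), `target`
#'   (the zero-energy curve height per node), `dtarget`, `depth_mult`
#'   and `segments`.
#' @export
crypt_energy <- function(curve, C0, gp, grid, L_target = grid$L) {
  if (is.function(gp$energy_kind))
    return(gp$energy_kind(curve, C0, grid, gp))
  n <- curve$n
  if (length(C0) != n) stop("curve and C0 do not share a grid")
  segs <- crypt_segments(C0, grid, gp$count_threshold_frac * max(C0, 0))
  centers <- segment_centers(segs, grid, gp)
  m <- solve_depth_multiplier(segs, centers, curve, gp, L_target,
                              m_prev = attr(curve, "depth_mult"))
  ct <- curve_target(curve$x, segs, centers, gp, depth_mult = m)
  integrand <- (curve$y - ct$target)^2
  list(E = mean(integrand), integrand = integrand, target = ct$target,
       dtarget = ct$dtarget, depth_mult = m, segments = segs,
       centers = centers)
}

#' One gradient-flow step of the tissue curve
#'
#' Explicit descent on the node heights against the gradient of
#' [crypt_energy()], sub-stepped for stability and backtracked so that the
#' energy never increases across the call; endpoints are re-pinned after
#' every substep. The horizontal node positions stay fixed at the uniform
#' chord parametrization: the constrained flow is still a monotone
#' descent of the same energy, and the graph representation keeps the
#' discrete arclength bookkeeping consistent with the depth solve (free
#' horizontal motion has zero gradient once the heights match the target,
#' so it only de-calibrates the parametrization without lowering the
#' energy further).
#'
#' @param curve [crypt_curve()].
#' @param C0 progenitor density.
#' @param gp [geometry_params()].
#' @param dt time interval to advance (cell time units).
#' @param grid [crypt_grid()].
#' @param L_target tissue length the folded curve must embed (sets the
#'   crypt depth scale); defaults to the current domain length.
#' @return updated [crypt_curve()].
#' @export
gradient_flow_step <- function(curve, C0, gp, dt, grid, L_target = grid$L) {
  n <- curve$n
  en <- crypt_energy(curve, C0, gp, grid, L_target)
  remaining <- gp$flow_rate * dt      # total pseudo-time to advance
  max_sub <- 0.2                      # stable for the quadratic y-dynamics
  E <- en$E
  ct <- en
  while (remaining > 1e-12) {
    h <- min(max_sub, remaining)
    gy <- 2 * (curve$y - ct$target)
    tries <- 0
    repeat {
      yn <- curve$y - h * gy
      yn[1] <- gp$endpoint_a[2]
      yn[n + 1] <- gp$endpoint_b[2]
      En <- mean((yn - ct$target)^2)
      if (En <= E + 1e-15) break
      h <- h / 2; tries <- tries + 1
      if (tries > 30) stop("gradient flow backtracking failed")
    }
    curve <- crypt_curve(curve$x, yn)
    E <- En
    remaining <- remaining - h
  }
  # carry the solved depth scale so the next call can warm-start its
  # embedding solve
  attr(curve, "depth_mult") <- en$depth_mult
  curve
}

#' Arclength of the tissue curve
#'
#' Integral of `sqrt(x'^2 + y'^2)` over the curve parameter. The default
#' "polyline" quadrature (sum of chord lengths) is robust for curves with
#' steep crypt walls; "spectral" detrends `x` by the endpoint chord,
#' differentiates spectrally and applies the trapezoid rule, which is
#' more accurate for smooth, well-resolved curves. The result is never
#' less than the straight-line distance between the pinned endpoints.
#'
#' @param curve [crypt_curve()].
#' @param method "polyline" or "spectral".
#' @export
domain_length <- function(curve, method = c("polyline", "spectral")) {
  method <- match.arg(method)
  n <- curve$n
  if (method == "polyline") {
    return(sum(sqrt(diff(curve$x)^2 + diff(curve$y)^2)))
  }
  chord <- curve$x[n + 1] - curve$x[1]
  xt <- curve$x[1:n] - (curve$x[1] + chord * (0:(n - 1)) / n)
  dx <- chord + spectral_derivative(xt, 1L, 1)
  dy <- spectral_derivative(curve$y[1:n], 1L, 1)
  mean(sqrt(dx^2 + dy^2))
}

#' Summary observables of the crypt pattern
#'
#' Crypt count, per-crypt height (baseline minus the deepest curve node in
#' the crypt's horizontal window), tip positions and tip densities.
#'
#' @param curve [crypt_curve()].
#' @param C0 progenitor density.
#' @param grid [crypt_grid()].
#' @param gp [geometry_params()].
#' @return list of class `crypt_summary`: `count`, `heights`,
#'   `tip_positions` (xi of each progenitor peak), `tip_densities`.
#' @export
summarize_crypts <- function(curve, C0, grid, gp = geometry_params()) {
  segs <- crypt_segments(C0, grid, gp$count_threshold_frac * max(C0, 0))
  centers <- segment_centers(segs, grid, gp)
  heights <- numeric(0); tips <- numeric(0); dens <- numeric(0)
  for (k in seq_along(segs)) {
    seg <- segs[[k]]
    xstar <- centers[k]
    d <- seg$mass / seg$peak_value
    win <- abs(curve$x - xstar) <= d + 2 * gp$epsilon0
    nodes <- unique(c(seg$idx, which(win)))
    heights <- c(heights, max(0, gp$baseline_b - min(curve$y[nodes])))
    tips <- c(tips, grid$xi[seg$peak_idx])
    dens <- c(dens, seg$peak_value)
  }
  out <- list(count = length(segs), heights = heights,
              tip_positions = tips, tip_densities = dens)
  class(out) <- "crypt_summary"
  out
}

#' @export
print.crypt_summary <- function(x, ...) {
  cat(sprintf("%d crypt(s)", x$count))
  if (x$count > 0)
    cat(sprintf(": heights %s; tip C0 %s",
                paste(signif(x$heights, 3), collapse = ", "),
                paste(signif(x$tip_densities, 3), collapse = ", ")))
  cat("\n")
  invisible(x)
}
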