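# Linear stability analysis of the Wnt / Wnt-inhibitor pair about
# homogeneous steady states: kinetics Jacobian, dispersion relation,
# instability maps in the (D_I/D_W, d_I/d_W) plane, and the predicted
# fastest-growing mode count. The cell field (hence basal Wnt production)
# is frozen at its homogeneous value: cells vary on the slow time scale.

#' Kinetics Jacobian of the Wnt/inhibitor pair at a fixed point
#'
#' Analytic partial derivatives of the two reaction terms with respect to
#' (Wnt, inhibitor), with the progenitor density entering as a frozen
#' parameter. The inhibitor's self-derivative is always `-d_I` (linear
#' removal), and on the `W* = 0` branch the Hill activations vanish so the
#' Jacobian is `diag(-d_W, -d_I)`.
#'
#' @param W_star,I_star homogeneous fixed point (checked: the uniform
#'   reaction rates must vanish to `tol`).
#' @param c0 frozen progenitor density.
#' @param p [morphogen_params()].
#' @param tol fixed-point residual tolerance.
#' @return 2x2 matrix, rows = (Wnt, inhibitor) equations.
#' @export
kinetics_jacobian <- function(W_star, I_star, c0, p, tol = 1e-8) {
  resW <- wnt_production(W_star, I_star, c0, p) - p$d_W * W_star
  resI <- inhibitor_production(W_star, p) - p$d_I * I_star
  if (max(abs(resW), abs(resI)) > tol)
    stop(sprintf("(%g, %g) is not a fixed point (residual %.3g)",
                 W_star, I_star, max(abs(resW), abs(resI))))
  pd <- reaction_partials(W_star, I_star, p)
  matrix(c(pd$dW_dW, pd$dI_dW, pd$dW_dI, pd$dI_dI), 2, 2)
}

#' Dispersion relation of the linearised reaction-diffusion pair
#'
#' For each admissible wavenumber `k_j = 2 pi j / L` the growth rate is
#' the largest real part of the eigenvalues of `J - k^2 diag(D)`. The
#' system is classified Turing-unstable when the homogeneous kinetics are
#' stable (`growth(0) < 0`) but some `k > 0` grows. The continuum
#' instability band (independent of the domain quantisation) is the root
#' interval of `det(J - k^2 D) = 0` in `k^2`.
#'
#' @param J 2x2 kinetics Jacobian.
#' @param D length-2 diffusion pair `(D_W, D_I)`.
#' @param L domain length (quantises the admissible modes).
#' @param n_modes highest mode index evaluated.
#' @return object of class `dispersion_result` with `wavenumbers`,
#'   `growth_rates`, `modes`, `unstable_band` (continuum, in k),
#'   `fastest_mode`, `turing_unstable`.
#' @export
dispersion_relation <- function(J, D, L, n_modes = 128L) {
  stopifnot(length(D) == 2, L > 0)
  growth <- function(k2) {
    M <- J - k2 * diag(D)
    max(Re(eigen(M, only.values = TRUE)$values))
  }
  j <- 0:n_modes
  k <- 2 * pi * j / L
  g <- vapply(k^2, growth, numeric(1))
  g0_stable <- g[1] < 0

  # continuum band: det(J - k2 D) = DW DI k2^2 - (a DI + d DW) k2 + det J
  a <- J[1, 1]; d <- J[2, 2]; detJ <- det(J)
  A <- D[1] * D[2]; B <- a * D[2] + d * D[1]
  disc <- B^2 - 4 * A * detJ
  band <- c(NA_real_, NA_real_)
  if (disc > 0 && B > 0) {
    k2r <- sort((B + c(-1, 1) * sqrt(disc)) / (2 * A))
    if (k2r[2] > 0) band <- sqrt(pmax(k2r, 0))
  }
  unstable_j <- j[g > 0 & j > 0]
  fastest <- if (length(unstable_j)) {
    cand <- which(j %in% unstable_j)
    j[cand[which.max(g[cand])]]
  } else 0L
  out <- list(wavenumbers = k, modes = j, growth_rates = g,
              unstable_band = band,
              fastest_mode = as.integer(fastest),
              turing_unstable = g0_stable && any(g[-1] > 0),
              kinetics_stable = g0_stable)
  class(out) <- "dispersion_result"
  out
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("dispersion: kinetics %s, %s",
              if (x$kinetics_stable) "stable" else "unstable",
              if (x$turing_unstable)
                sprintf("Turing-unstable; fastest mode j = %d (growth %.3g); band k in [%.3g, %.3g]",
                        x$fastest_mode, max(x$growth_rates),
                        x$unstable_band[1], x$unstable_band[2])
              else "no diffusion-driven instability"), "\n")
  invisible(x)
}

#' Turing-instability map over removal-rate and diffusivity ratios
#'
#' Classifies each cell of a `(D_I/D_W, d_I/d_W)` grid: the base
#' parameters are rescaled to the cell's ratios, the homogeneous steady
#' state is recomputed (it depends on `d_I`), and the continuum dispersion
#' relation decides instability. Cells with no homogeneous steady state
#' are marked `NA`.
#'
#' @param ratio_grid_D vector of `D_I/D_W` ratios.
#' @param ratio_grid_d vector of `d_I/d_W` ratios.
#' @param base [morphogen_params()] supplying everything else.
#' @param c0 frozen progenitor density.
#' @return logical matrix, rows = `ratio_grid_D`, columns = `ratio_grid_d`,
#'   with the grids attached as dimnames.
#' @export
instability_map <- function(ratio_grid_D, ratio_grid_d, base, c0 = 0.5) {
  stopifnot(all(ratio_grid_D > 0), all(ratio_grid_d > 0))
  out <- matrix(NA, length(ratio_grid_D), length(ratio_grid_d),
                dimnames = list(signif(ratio_grid_D, 4),
                                signif(ratio_grid_d, 4)))
  for (i in seq_along(ratio_grid_D)) {
    for (jj in seq_along(ratio_grid_d)) {
      p <- base
      p$D_I <- base$D_W * ratio_grid_D[i]
      p$d_I <- base$d_W * ratio_grid_d[jj]
      hss <- tryCatch(homogeneous_fixed_point(c0, 1 - c0, p),
                      error = function(e) NULL)
      if (is.null(hss)) next
      row <- hss[hss$selected, ]
      J <- kinetics_jacobian(row$W, row$I, c0, p, tol = 1e-6)
      dr <- dispersion_relation(J, c(p$D_W, p$D_I), L = 1, n_modes = 0L)
      # continuum criterion: kinetics stable and band non-empty
      out[i, jj] <- dr$kinetics_stable && !any(is.na(dr$unstable_band)) &&
        dr$unstable_band[2] > 0
    }
  }
  out
}

#' Predicted crypt count from the fastest-growing mode
#'
#' The fastest-growing admissible wavenumber on a periodic domain of
#' length `L` predicts the number of Wnt peaks, hence the crypt count,
#' emerging from small perturbations of the homogeneous state.
#'
#' @param p [morphogen_params()].
#' @param c0 frozen progenitor density.
#' @param L domain length.
#' @param n_modes highest mode evaluated.
#' @return list with `count` (0 when the state is not Turing-unstable),
#'   `stable` flag, and the underlying `dispersion` result.
#' @export
predict_crypt_count <- function(p, c0, L, n_modes = 128L) {
  hss <- homogeneous_fixed_point(c0, 1 - c0, p)
  row <- hss[hss$selected, ]
  J <- kinetics_jacobian(row$W, row$I, c0, p, tol = 1e-6)
  dr <- dispersion_relation(J, c(p$D_W, p$D_I), L, n_modes)
  if (!dr$turing_unstable)
    return(list(count = 0L, stable = TRUE, dispersion = dr))
  list(count = dr$fastest_mode, stable = FALSE, dispersion = dr)
}
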