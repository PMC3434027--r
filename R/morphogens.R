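# Morphogen kinetics and the quasi-steady-state solver.
#
# Reaction terms (per grid point, transport excluded):
#   Wnt:       mu0*C0 + alpha_W * H+(W; beta_W, n_W) * H-(I; beta_I, m_W)
#              - d_W*W  (+ theta inside an exogenous source window)
#   inhibitor: alpha_I * H+(W; beta_W_inh, n_I) - d_I*I
#   BMP:       mu1*C1 - d_B*B
# with H+(x) = (beta x)^n / (1 + (beta x)^n) and H-(x) = 1 / (1 + (beta x)^m).
# H+ at x = 0 is 0 (the limit of the reciprocal-power form), so the zero
# state is a kinetic fixed point when basal production vanishes.

# Negative arguments are clamped to zero (constant extension): transient
# solver iterates may carry tiny negative lobes near sharp fronts, and the
# extension keeps the kinetics defined, continuous and monotone there.
hill_up <- function(x, beta, n) {
  x <- pmax(x, 0)
  t <- (beta * x)^n
  out <- t / (1 + t)
  out[!is.finite(t)] <- 1
  out[x == 0] <- 0
  out
}

hill_up_deriv <- function(x, beta, n) {
  x <- pmax(x, 0)
  t <- (beta * x)^n
  d <- n * t / (x * (1 + t)^2)
  d[!is.finite(t)] <- 0
  zero <- x == 0
  if (any(zero)) d[zero] <- if (n > 1) 0 else if (n == 1) beta else Inf
  d
}

hill_down <- function(x, beta, m) {
  x <- pmax(x, 0)
  t <- (beta * x)^m
  out <- 1 / (1 + t)
  out[!is.finite(t)] <- 0
  out
}

hill_down_deriv <- function(x, beta, m) {
  x <- pmax(x, 0)
  t <- (beta * x)^m
  d <- -m * t / (x * (1 + t)^2)
  d[!is.finite(t)] <- 0
  zero <- x == 0
  if (any(zero)) d[zero] <- if (m > 1) 0 else if (m == 1) -beta else -Inf
  d
}

# Pointwise production terms and their partial derivatives.
wnt_production <- function(W, I, C0, p, theta_field = 0) {
  p$mu0 * C0 +
    p$alpha_W * hill_up(W, p$beta_W, p$n_W) * hill_down(I, p$beta_I, p$m_W) +
    theta_field
}

inhibitor_production <- function(W, p) {
  p$alpha_I * hill_up(W, p$beta_W_inh, p$n_I)
}

#' Local net reaction rates of the morphogen system
#'
#' Production minus linear removal for Wnt, Wnt inhibitor and BMP at each
#' grid point, excluding transport. When an exogenous source is supplied,
#' its rate is added to the Wnt term inside the (periodically wrapped)
#' source window.
#'
#' @param m a [morphogen_state()].
#' @param cells a [lineage_state()] on the same grid.
#' @param p [morphogen_params()].
#' @param src optional [wnt_source()].
#' @param grid the [crypt_grid()] (required when `src` is given, to place
#'   the window).
#' @return list of class `reaction_rates` with `r_wnt`, `r_inh`, `r_bmp`.
#' @export
reaction_rates <- function(m, cells, p, src = NULL, grid = NULL) {
  n <- length(m$wnt)
  if (length(cells$C0) != n) stop("states do not share a grid")
  if (any(m$wnt < 0) || any(m$inhibitor < 0) || any(m$bmp < 0))
    stop("negative concentration input")
  theta <- 0
  if (!is.null(src)) {
    if (is.null(grid)) stop("grid needed to place the exogenous source")
    theta <- src$rate_theta * source_window(src, grid)
  }
  out <- list(
    r_wnt = wnt_production(m$wnt, m$inhibitor, cells$C0, p, theta) -
      p$d_W * m$wnt,
    r_inh = inhibitor_production(m$wnt, p) - p$d_I * m$inhibitor,
    r_bmp = p$mu1 * cells$C1 - p$d_B * m$bmp)
  class(out) <- "reaction_rates"
  out
}

# Pointwise Jacobian entries of the (Wnt, inhibitor) reaction pair.
reaction_partials <- function(W, I, p) {
  huW  <- hill_up(W, p$beta_W, p$n_W)
  hdI  <- hill_down(I, p$beta_I, p$m_W)
  list(
    dW_dW = p$alpha_W * hill_up_deriv(W, p$beta_W, p$n_W) * hdI - p$d_W,
    dW_dI = p$alpha_W * huW * hill_down_deriv(I, p$beta_I, p$m_W),
    dI_dW = p$alpha_I * hill_up_deriv(W, p$beta_W_inh, p$n_I),
    dI_dI = rep(-p$d_I, length(W)))
}

# Fourier solve of the linear BMP balance (d_B - D_B d^2/ds^2) B = mu1 C1.
solve_bmp <- function(C1, p, grid) {
  n <- grid$n
  k2 <- (2 * pi * fourier_modes(n) / grid$L)^2
  Bh <- stats::fft(p$mu1 * C1) / (p$d_B + p$D_B * k2)
  pmax(Re(stats::fft(Bh, inverse = TRUE)) / n, 0)
}

qss_residual <- function(W, I, C0, p, grid, theta_field, V = NULL) {
  L <- grid$L
  rW <- p$D_W * spectral_derivative(W, 2L, L) +
    wnt_production(W, I, C0, p, theta_field) - p$d_W * W
  rI <- p$D_I * spectral_derivative(I, 2L, L) +
    inhibitor_production(W, p) - p$d_I * I
  if (!is.null(V)) {
    rW <- rW - spectral_derivative(V * W, 1L, L)
    rI <- rI - spectral_derivative(V * I, 1L, L)
  }
  list(rW = rW, rI = rI)
}

# One semi-implicit pseudo-time sweep (diffusion + removal implicit,
# production explicit), diagonal in Fourier space.
relax_sweep <- function(W, I, C0, p, grid, theta_field, tau, V = NULL) {
  n <- grid$n
  k2 <- (2 * pi * fourier_modes(n) / grid$L)^2
  pw <- wnt_production(W, I, C0, p, theta_field)
  pi_ <- inhibitor_production(W, p)
  if (!is.null(V)) {
    pw <- pw - spectral_derivative(V * W, 1L, grid$L)
    pi_ <- pi_ - spectral_derivative(V * I, 1L, grid$L)
  }
  Wn <- Re(stats::fft((stats::fft(W) + tau * stats::fft(pw)) /
                        (1 + tau * (p$d_W + p$D_W * k2)), inverse = TRUE)) / n
  In <- Re(stats::fft((stats::fft(I) + tau * stats::fft(pi_)) /
                        (1 + tau * (p$d_I + p$D_I * k2)), inverse = TRUE)) / n
  list(W = pmax(Wn, 0), I = pmax(In, 0))
}

relax_tau <- function(p) {
  lip <- p$alpha_W * p$n_W * p$beta_W + p$alpha_I * p$n_I * p$beta_W_inh
  0.8 / (lip + p$d_W)
}

#' Quasi-steady state of the morphogen system
#'
#' Solves `0 = D f'' + reaction(f)` for all three species on the current
#' domain, holding the cell fields fixed. BMP is linear and solved directly
#' in Fourier space. The coupled (Wnt, inhibitor) pair is solved by damped
#' Newton iteration on the spectrally discretised stationary system,
#' warm-started from `init`; when Newton stalls (or when `relax_first`
#' sweeps are requested, e.g. at the start of a run so the physically
#' stable patterned branch is selected from a noisy field), a semi-implicit
#' pseudo-time relaxation of the parabolic system is interleaved.
#'
#' The molecular convection term is dropped by default (molecule transport
#' by cell flow is slow compared to diffusion and decay on the molecular
#' time scale); set `num$qss_include_advection = TRUE` and pass `velocity`
#' to retain it.
#'
#' @param cells [lineage_state()].
#' @param p [morphogen_params()].
#' @param grid [crypt_grid()].
#' @param init warm-start [morphogen_state()].
#' @param num [numerics_params()] (tolerances, iteration caps, negativity
#'   policy).
#' @param src optional [wnt_source()].
#' @param relax_first pseudo-time sweeps to run before the first Newton
#'   attempt.
#' @param velocity cell velocity field, used only when
#'   `num$qss_include_advection` is TRUE.
#' @param cache optional environment persisting across calls (as kept by
#'   [imex_step()]): stores the factorised Jacobian so consecutive solves
#'   along a run reuse it (chord Newton); convergence is always verified
#'   against the residual tolerance, never assumed from the cache.
#' @return a [morphogen_state()] whose residual
#'   `max |diffusion + reaction|` is at most `num$qss_tol` per species.
#' @export
solve_quasi_steady <- function(cells, p, grid, init, num = numerics_params(),
                               src = NULL, relax_first = 0L,
                               velocity = NULL, cache = NULL) {
  if (any(init$wnt < 0) || any(init$inhibitor < 0))
    stop("initial morphogen state must be non-negative")
  C0 <- cells$C0
  theta <- if (is.null(src)) 0 else src$rate_theta * source_window(src, grid)
  V <- if (num$qss_include_advection) velocity else NULL

  W <- init$wnt; I <- init$inhibitor
  tau <- relax_tau(p)
  resnorm <- function(W, I) {
    r <- qss_residual(W, I, C0, p, grid, theta, V)
    max(max(abs(r$rW)), max(abs(r$rI)))
  }

  if (relax_first > 0L) {
    # relax only until Newton's basin is reached (1e3 * tol); the final
    # polish is Newton's job. Exit requires the residual to be small AND
    # non-increasing: a slowly growing unstable direction keeps the
    # residual rising between checks, so relaxation cannot stop while it
    # is still escaping an unstable branch.
    prev <- Inf
    for (i in seq_len(relax_first)) {
      st <- relax_sweep(W, I, C0, p, grid, theta, tau, V)
      W <- st$W; I <- st$I
      if (i %% 25L == 0L) {
        rn <- resnorm(W, I)
        if (rn <= 1e3 * num$qss_tol && rn <= prev) break
        prev <- rn
      }
    }
  }

  # Explicit inverse of the 2n x 2n stationary Jacobian at (W, I). The
  # iteration below is chord Newton: the inverse is cached across time
  # steps (the fields drift slowly along a run) so the per-step cost is a
  # few matrix-vector products instead of an LU factorisation; convergence
  # is still certified by the residual-norm contract, and the inverse is
  # rebuilt at the current iterate whenever the contraction degrades.
  jacobian_inverse <- function(W, I) {
    n <- grid$n
    D2 <- second_derivative_matrix(n) / grid$L^2
    pd <- reaction_partials(W, I, p)
    A11 <- p$D_W * D2; diag(A11) <- diag(A11) + pd$dW_dW
    A22 <- p$D_I * D2; diag(A22) <- diag(A22) + pd$dI_dI
    if (!is.null(V)) {
      Adv <- (first_derivative_matrix(n) / grid$L) %*% diag(V)
      A11 <- A11 - Adv; A22 <- A22 - Adv
    }
    J <- rbind(cbind(A11, diag(pd$dW_dI, n)),
               cbind(diag(pd$dI_dW, n), A22))
    tryCatch(solve(J), error = function(e) NULL)
  }

  newton_phase <- function(W, I) {
    n <- grid$n
    Jinv <- if (!is.null(cache)) cache$qss_Jinv else NULL
    if (!is.null(Jinv) && nrow(Jinv) != 2L * n) Jinv <- NULL
    fresh <- FALSE
    if (is.null(Jinv)) {
      Jinv <- jacobian_inverse(W, I)
      fresh <- TRUE
      if (is.null(Jinv)) return(list(W = W, I = I, ok = FALSE,
                                     res = resnorm(W, I)))
    }
    rn <- resnorm(W, I)
    for (it in seq_len(num$qss_max_iter)) {
      if (rn <= num$qss_tol) break
      r <- qss_residual(W, I, C0, p, grid, theta, V)
      delta <- -as.vector(Jinv %*% c(r$rW, r$rI))
      if (any(!is.finite(delta))) return(list(W = W, I = I, ok = FALSE, res = rn))
      step <- 1
      improved <- FALSE
      rn_prev <- rn
      repeat {
        Wn <- W + step * delta[1:n]; In <- I + step * delta[(n + 1):(2 * n)]
        neg <- min(min(Wn), min(In))
        # tiny negative lobes near sharp fronts are tolerated during the
        # iteration (the kinetics extend continuously; the converged state
        # is clipped and checked by the caller); only substantial
        # negativity rejects the step
        if (neg < -1e-6 * max(1, max(W))) {
          if (num$strict_negative && step < 1 / 64)
            stop("quasi-steady iterate went negative (strict mode)")
        } else {
          rnn <- resnorm(Wn, In)
          if (rnn < rn || step < 1 / 64) {
            improved <- rnn < rn
            W <- Wn; I <- In; rn <- rnn
            break
          }
        }
        step <- step / 2
        if (step < 1 / 256) break
      }
      if (improved) fresh <- FALSE   # iterate moved off the build point
      stalled <- !improved || (rn > num$qss_tol && rn > 0.5 * rn_prev)
      if (stalled) {
        if (fresh) {
          # a Jacobian built at this very iterate could not improve:
          # hand back to the relaxation fallback
          return(list(W = W, I = I, ok = rn <= num$qss_tol, res = rn))
        }
        Jinv <- jacobian_inverse(W, I)
        fresh <- TRUE
        if (is.null(Jinv)) return(list(W = W, I = I, ok = FALSE, res = rn))
      }
    }
    if (!is.null(cache)) cache$qss_Jinv <- Jinv
    list(W = W, I = I, ok = rn <= num$qss_tol, res = rn)
  }

  np <- newton_phase(W, I)
  if (!np$ok) {
    # pseudo-time damping fallback, then a final Newton polish; the
    # relaxation stops early when it stagnates (less than 1% progress
    # per check), since further sweeps cannot help Newton then
    W <- np$W; I <- np$I
    prev <- Inf
    for (i in seq_len(num$qss_relax_max)) {
      st <- relax_sweep(W, I, C0, p, grid, theta, tau, V)
      W <- st$W; I <- st$I
      if (i %% 25L == 0L) {
        rn <- resnorm(W, I)
        if (rn <= 1e3 * num$qss_tol || rn > 0.99 * prev) break
        prev <- rn
      }
    }
    np <- newton_phase(W, I)
    if (!np$ok) {
      # near a fold of the quasi-steady branch (stationary Jacobian close
      # to singular during a transient) the strict tolerance is not
      # certifiable by any iteration; accept a residual still orders of
      # magnitude below the reaction scale, fail hard above it
      if (np$res <= num$qss_tol_soft) {
        if (is.null(cache) || !isTRUE(cache$qss_soft_warned)) {
          warning(sprintf(paste0(
            "quasi-steady solve stalled near a fold; accepted residual ",
            "%.3g (soft tolerance %.3g); further soft accepts in this ",
            "run will not warn again"), np$res, num$qss_tol_soft))
          if (!is.null(cache)) cache$qss_soft_warned <- TRUE
        }
      } else {
        stop(sprintf(
          "quasi-steady solve did not converge (residual %.3g > tol %.3g)",
          np$res, num$qss_tol_soft))
      }
    }
  }
  W <- np$W; I <- np$I

  B <- solve_bmp(cells$C1, p, grid)
  if (num$strict_negative && (min(W) < -1e-12 || min(I) < -1e-12))
    stop("negative quasi-steady concentration")
  # sub-grid Gibbs lobes at sharp fronts are clipped silently below the
  # tolerance admitted by the Newton line search; anything larger warns
  if (min(W) < -1e-6 * max(1, max(W)) || min(I) < -1e-6 * max(1, max(I)))
    warning("clipped negative quasi-steady concentrations")
  morphogen_state(pmax(W, 0), pmax(I, 0), B)
}

#' Homogeneous fixed points of the morphogen kinetics
#'
#' Roots of the spatially uniform reaction system at given cell densities.
#' BMP is closed-form (`B* = mu1 c1 / d_B`); the inhibitor is eliminated
#' (`I*(W) = alpha_I H+(W) / d_I`) and the remaining scalar Wnt balance is
#' bracketed on a fine scan and polished with `uniroot`.
#'
#' @param c0,c1 uniform progenitor / TD-cell densities (>= 0).
#' @param p [morphogen_params()].
#' @param n_scan scan resolution for bracketing.
#' @return data.frame with one row per root: `W`, `I`, `B`, `residual`,
#'   `stable` (linear stability of the uniform kinetics) and `selected`
#'   (largest-W stable root, falling back to the largest-W root).
#' @export
homogeneous_fixed_point <- function(c0, c1, p, n_scan = 800L) {
  if (c0 < 0 || c1 < 0) stop("cell densities must be >= 0")
  Bstar <- p$mu1 * c1 / p$d_B
  Istar <- function(W) p$alpha_I * hill_up(W, p$beta_W_inh, p$n_I) / p$d_I
  FW <- function(W) wnt_production(W, Istar(W), c0, p) - p$d_W * W

  Wmax <- 1.1 * (p$mu0 * c0 + p$alpha_W) / p$d_W + 1e-12
  ws <- c(0, Wmax * exp(seq(log(1e-9), 0, length.out = n_scan)))
  fv <- vapply(ws, FW, numeric(1))
  roots <- numeric(0)
  if (abs(fv[1]) <= 1e-14) roots <- c(roots, 0)
  for (i in seq_len(length(ws) - 1)) {
    if (is.finite(fv[i]) && is.finite(fv[i + 1]) &&
        fv[i] * fv[i + 1] < 0) {
      r <- stats::uniroot(FW, c(ws[i], ws[i + 1]), tol = 1e-15)$root
      roots <- c(roots, r)
    } else if (i > 1 && fv[i + 1] == 0) {
      roots <- c(roots, ws[i + 1])
    }
  }
  if (length(roots) == 0)
    stop("no homogeneous fixed point found in the search bracket")
  roots <- sort(unique(roots))
  # drop near-duplicates
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-10 * max(1, Wmax))]

  rows <- lapply(roots, function(W) {
    I <- Istar(W)
    res <- abs(FW(W))
    pd <- reaction_partials(W, I, p)
    J <- matrix(c(pd$dW_dW, pd$dI_dW, pd$dW_dI, pd$dI_dI), 2, 2)
    stable <- max(Re(eigen(J, only.values = TRUE)$values)) < 0
    data.frame(W = W, I = I, B = Bstar, residual = res, stable = stable)
  })
  out <- do.call(rbind, rows)
  sel <- which(out$stable)
  pick <- if (length(sel)) sel[which.max(out$W[sel])] else which.max(out$W)
  out$selected <- seq_len(nrow(out)) == pick
  out
}

# first-derivative circulant matrix (unit domain), cached
first_derivative_matrix <- function(n) {
  key <- paste0("d1_", n)
  if (!is.null(.spectral_cache[[key]])) return(.spectral_cache[[key]])
  k <- 2 * pi * fourier_modes(n)
  k[n / 2L + 1L] <- 0
  gen <- Re(stats::fft(1i * k, inverse = TRUE)) / n
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  D1 <- matrix(gen[idx], n, n)
  .spectral_cache[[key]] <- D1
  D1
}
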