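# Fourier wavenumber index vector for an even-length periodic grid.
# Layout follows stats::fft: 0, 1, ..., n/2, -(n/2-1), ..., -1.
fourier_modes <- function(n) {
  if (n %% 2L != 0L) stop("periodic grid length must be even, got ", n)
  c(0:(n / 2L), -((n / 2L - 1L):1L))
}

#' Spectral derivative of a periodic field
#'
#' Differentiates a real field sampled on a uniform periodic grid of length
#' `L` using the discrete Fourier transform. Exact for band-limited input;
#' the derivative of a constant is zero to machine precision. For odd
#' derivative orders the Nyquist mode is zeroed (standard convention for a
#' real, antisymmetric symbol).
#'
#' @param f numeric vector, samples of a periodic field (even length).
#' @param order derivative order, 1 or 2.
#' @param L domain length; the grid spacing is `L / length(f)`.
#' @return numeric vector of the same length as `f`.
#' @export
spectral_derivative <- function(f, order = 1L, L = 1) {
  n <- length(f)
  if (n %% 2L != 0L) stop("spectral_derivative needs an even number of points")
  if (!all(is.finite(f))) stop("non-finite values in field")
  if (!(order %in% c(1L, 2L))) stop("order must be 1 or 2")
  k <- 2 * pi * fourier_modes(n) / L
  if (order == 1L) {
    k[n / 2L + 1L] <- 0          # Nyquist
    sym <- 1i * k
  } else {
    sym <- -k^2
  }
  Re(stats::fft(sym * stats::fft(f), inverse = TRUE)) / n
}

# Zero-mean periodic antiderivative of the fluctuating part of f.
# Solves F' = f - mean(f) with mean(F) = 0 on a domain of length L.
periodic_antiderivative <- function(f, L = 1) {
  n <- length(f)
  k <- 2 * pi * fourier_modes(n) / L
  fh <- stats::fft(f)
  Fh <- complex(n)
  nz <- k != 0
  Fh[nz] <- fh[nz] / (1i * k[nz])
  Fh[n / 2L + 1L] <- 0           # Nyquist has no odd antiderivative
  Re(stats::fft(Fh, inverse = TRUE)) / n
}

# Exponential spectral filter (36th order) acting on the upper third of the
# spectrum; used as the implicitly-treated high-order dissipation that
# stabilises advection of sharp fronts. sigma(0) = 1 exactly.
filter_sigma <- function(n, p = 36, alpha = 36, cutoff = 2 / 3) {
  j <- abs(fourier_modes(n))
  eta <- j / (n / 2)
  sig <- rep(1, n)
  hi <- eta > cutoff
  sig[hi] <- exp(-alpha * ((eta[hi] - cutoff) / (1 - cutoff))^p)
  sig
}

apply_filter <- function(f, sigma) {
  Re(stats::fft(sigma * stats::fft(f), inverse = TRUE)) / length(f)
}

# Dense second-derivative matrix on the unit periodic grid (n points).
# Built once per n via FFT of the canonical basis and cached; the physical
# operator on a domain of length L is D2 / L^2.
.spectral_cache <- new.env(parent = emptyenv())

second_derivative_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.spectral_cache[[key]])) return(.spectral_cache[[key]])
  k2 <- -(2 * pi * fourier_modes(n))^2
  # columns: ifft(k2 * fft(e_j)); fft(e_j) is a complex exponential, so the
  # whole matrix is a circulant generated by ifft(k2)
  gen <- Re(stats::fft(k2, inverse = TRUE)) / n
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  D2 <- matrix(gen[idx], n, n)
  .spectral_cache[[key]] <- D2
  D2
}
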