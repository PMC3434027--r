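#' Periodic collocation grid
#'
#' The tissue coordinate is arclength-like, periodic on `[0, L)`. Fields are
#' carried on the fixed computational coordinate `xi` in `[0, 1)`; the
#' physical coordinate is `s = xi * L`, so a growing domain only changes the
#' metric `L`, never the samples.
#'
#' @param n_points number of collocation points; even, at least 8.
#' @param L current domain length (> 0).
#' @return object of class `crypt_grid`.
#' @export
crypt_grid <- function(n_points = 256L, L = 0.2) {
  n_points <- as.integer(n_points)
  if (n_points < 8L || n_points %% 2L != 0L)
    stop("n_points must be an even integer >= 8, got ", n_points)
  if (!is.finite(L) || L <= 0) stop("domain length L must be > 0")
  g <- list(n = n_points, L = L, xi = (0:(n_points - 1L)) / n_points,
            h = L / n_points)
  class(g) <- "crypt_grid"
  g
}

#' @export
print.crypt_grid <- function(x, ...) {
  cat(sprintf("periodic grid: %d points, L = %.6g (h = %.3g)\n",
              x$n, x$L, x$h))
  invisible(x)
}

# physical coordinates of the grid points
grid_s <- function(grid) grid$xi * grid$L

# integral of a field over the physical domain (spectral/rectangle rule,
# exact for trigonometric polynomials)
grid_integral <- function(f, grid) sum(f) * grid$L / grid$n

# wrapped distance between xi coordinates on the unit circle
xi_distance <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}
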