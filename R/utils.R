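# Small numerical helpers shared across the solvers. All grids in this package
# are uniform, so the trapezoid primitives take a spacing rather than an x vector.

# trapezoid integral on a uniform grid
trapz_u <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}

# cumulative trapezoid on a uniform grid; first element is 0
cumtrapz_u <- function(y, dx) {
  dx * (cumsum(y) - (y + y[1L]) / 2)
}

# numerically safe log(cosh(x)) for large |x|
logcosh <- function(x) {
  ax <- abs(x)
  ifelse(ax > 20, ax + log1p(exp(-2 * ax)) - log(2), log(cosh(ax)))
}

#' Linear interpolation on a periodic grid
#'
#' `y` is sampled at `x = (0:(M-1))*dx` with period `T = M*dx`; `xout` is
#' arbitrary and wrapped into `[0, T)`. Used to evaluate periodic cycle
#' quantities (activity, mPRC, interaction functions) at off-grid phases.
#'
#' @param y sampled values.
#' @param dx sample spacing.
#' @param xout evaluation points.
#' @return interpolated values at `xout`.
#' @export
interp_periodic <- function(y, dx, xout) {
  M <- length(y)
  T_per <- M * dx
  x <- (xout %% T_per) / dx
  i0 <- floor(x)
  w <- x - i0
  i0 <- as.integer(i0 %% M)
  i1 <- (i0 + 1L) %% M
  (1 - w) * y[i0 + 1L] + w * y[i1 + 1L]
}

# centered periodic finite difference in time along the rows of a matrix
# (or of a vector); sample spacing dx
periodic_diff <- function(y, dx) {
  if (is.matrix(y)) {
    M <- nrow(y)
    (y[c(2:M, 1L), , drop = FALSE] - y[c(M, 1:(M - 1L)), , drop = FALSE]) / (2 * dx)
  } else {
    M <- length(y)
    (y[c(2:M, 1L)] - y[c(M, 1:(M - 1L))]) / (2 * dx)
  }
}

# Gaussian kernel smoothing of a regularly sampled series (edge-renormalised)
gauss_smooth <- function(x, sigma_steps) {
  if (sigma_steps <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma_steps))
  k <- stats::dnorm(seq(-half, half), sd = sigma_steps)
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric(num[(half + 1L):(half + n)] / den[(half + 1L):(half + n)])
}

# times of upward crossings of `x` through `level`, sub-sample accuracy by
# linear interpolation; `t` is the (uniform) sample time vector
upward_crossings <- function(x, level, t) {
  n <- length(x)
  below <- x[-n] < level & x[-1L] >= level
  idx <- which(below)
  if (length(idx) == 0L) return(numeric(0))
  frac <- (level - x[idx]) / (x[idx + 1L] - x[idx])
  t[idx] + frac * (t[idx + 1L] - t[idx])
}

# circular mean and circular SD (in radians)
circ_mean <- function(theta) {
  Arg(mean(exp(1i * theta)))
}

circ_sd <- function(theta) {
  R <- Mod(mean(exp(1i * theta)))
  sqrt(-2 * log(max(R, .Machine$double.eps)))
}

# wrap a time difference into (-T/2, T/2]
wrap_half <- function(x, T_per) {
  y <- x %% T_per
  ifelse(y > T_per / 2, y - T_per, y)
}

# composite Simpson on a uniform grid (n odd number of points preferred; a
# trailing trapezoid panel is used when the interval count is odd)
simpson_u <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  if (n == 2L) return(dx * (y[1L] + y[2L]) / 2)
  m <- if ((n - 1L) %% 2L == 0L) n else n - 1L
  i <- seq_len(m)
  w <- rep(c(4, 2), length.out = m - 2L)
  s <- dx / 3 * (y[1L] + sum(w * y[2:(m - 1L)]) + y[m])
  if (m < n) s <- s + dx * (y[n - 1L] + y[n]) / 2
  s
}
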