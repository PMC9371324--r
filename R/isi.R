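#' Interspike-interval density of a hazard model
#'
#' The ISI density of a renewal neuron with hazard `S` at fixed input `h` is
#' `ISI(h, r) = S(h, r) exp(-int_0^r S(h, s) ds)`: survive without firing up to
#' age `r`, then fire. The cumulative hazard is computed by the cumulative
#' trapezoid rule on the (uniform) age grid, so the density integrates to
#' `1 - exp(-int_0^rmax S)` on the truncated grid.
#'
#' @param model a [hazard_model()].
#' @param h input level (mV) at which to tabulate.
#' @param r_grid uniform age grid starting at 0 (ms).
#' @return an object of class `isi_density`: list with `r`, `density`, `h`.
#' @export
hazard_to_isi <- function(model, h, r_grid) {
  stopifnot(inherits(model, "hazard_model"))
  dr <- r_grid[2L] - r_grid[1L]
  if (abs(r_grid[1L]) > 1e-12) stop("r_grid must start at 0")
  if (max(abs(diff(r_grid) - dr)) > 1e-9 * dr) stop("r_grid must be uniform")
  S <- model$S(h, r_grid)
  ch <- cumtrapz_u(S, dr)
  structure(list(r = r_grid, density = S * exp(-ch), h = h),
            class = "isi_density")
}

#' Reconstruct the hazard rate from an ISI density
#'
#' Inverts the ISI/hazard relation through the quotient
#' `S(r) = ISI(r) / (1 - int_0^r ISI)`. The denominator (the survivor
#' function) decays to zero, which makes the quotient numerically fragile at
#' large ages: once the survivor function falls below `floor`, the hazard is
#' held at its last reliable value and the truncation age is reported in the
#' `"truncation_age"` attribute of the result.
#'
#' @param isi an `isi_density` (or a list with uniform `r` and `density`).
#' @param floor survivor-function floor below which the quotient is not
#'   evaluated (default `1e-8`).
#' @return a tabulated [hazard_model()] carrying the reconstructed `S(r)`.
#' @export
isi_to_hazard <- function(isi, floor = 1e-8) {
  r <- isi$r
  dens <- isi$density
  if (any(dens < 0)) stop("ISI density must be nonnegative")
  dr <- r[2L] - r[1L]
  cumI <- cumtrapz_u(dens, dr)
  if (cumI[length(cumI)] > 1 + 1e-4) stop("ISI density integrates to more than 1")
  surv <- pmax(1 - cumI, 0)
  ok <- surv >= floor
  S <- numeric(length(r))
  S[ok] <- dens[ok] / surv[ok]
  S[dens == 0 & ok] <- 0
  trunc_age <- NA_real_
  if (any(!ok)) {
    i_tr <- which(!ok)[1L]
    trunc_age <- r[i_tr]
    last <- if (i_tr > 1L) S[i_tr - 1L] else 0
    S[!ok] <- last
  }
  out <- hazard_model("tabulated", r = r, S = S)
  attr(out, "truncation_age") <- trunc_age
  out
}

#' Input derivative of the hazard rate from an ISI family
#'
#' Evaluates `dS/dh` from a family of ISI densities parametrised by the input
#' `h`, through the quotient formula
#' \deqn{\partial_h S = \frac{\partial_h ISI\,(1-\int ISI) +
#'   ISI \int \partial_h ISI}{(1-\int ISI)^2}.}
#' The `h`-derivative of the density is taken analytically when `d_isi_dh` is
#' supplied, otherwise by a central finite difference with step `delta`. The
#' same survivor-function floor as [isi_to_hazard()] applies (for heavy-tailed
#' families such as the gamma the quotient is numerically unstable at large
#' ages).
#'
#' @param isi_fun function `(h, r_grid) -> density values` defining the family.
#' @param h input level at which to differentiate.
#' @param r_grid uniform age grid starting at 0.
#' @param d_isi_dh optional function `(h, r_grid) -> d(density)/dh`.
#' @param delta finite-difference step (mV), default `1e-4`.
#' @param floor survivor-function floor.
#' @return numeric vector of `dS/dh` on `r_grid`, with attribute
#'   `"truncation_age"`.
#' @export
dS_dh_from_isi <- function(isi_fun, h, r_grid, d_isi_dh = NULL, delta = 1e-4,
                           floor = 1e-8) {
  dr <- r_grid[2L] - r_grid[1L]
  dens <- isi_fun(h, r_grid)
  dI <- if (is.null(d_isi_dh)) {
    (isi_fun(h + delta, r_grid) - isi_fun(h - delta, r_grid)) / (2 * delta)
  } else {
    d_isi_dh(h, r_grid)
  }
  cumI <- cumtrapz_u(dens, dr)
  cumdI <- cumtrapz_u(dI, dr)
  surv <- 1 - cumI
  ok <- surv >= floor
  out <- numeric(length(r_grid))
  out[ok] <- (dI[ok] * surv[ok] + dens[ok] * cumdI[ok]) / surv[ok]^2
  out[dens == 0 & ok] <- 0
  trunc_age <- NA_real_
  if (any(!ok)) {
    i_tr <- which(!ok)[1L]
    trunc_age <- r_grid[i_tr]
    out[!ok] <- if (i_tr > 1L) out[i_tr - 1L] else 0
  }
  attr(out, "truncation_age") <- trunc_age
  out
}

#' Read/write a tabulated ISI density as two-column CSV
#'
#' Column convention: `age_ms`, `density_per_ms`.
#' @param path file path.
#' @param isi an `isi_density` object (for writing).
#' @return for `read_isi_csv`, an `isi_density` (with `h = NA`).
#' @export
read_isi_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(r = d$age_ms, density = d$density_per_ms, h = NA_real_),
            class = "isi_density")
}

#' @rdname read_isi_csv
#' @export
write_isi_csv <- function(isi, path) {
  utils::write.csv(data.frame(age_ms = isi$r, density_per_ms = isi$density),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.isi_density <- function(x, ...) {
  dr <- x$r[2L] - x$r[1L]
  cat("ISI density on [0, ", max(x$r), "] ms (", length(x$r), " points), h = ",
      x$h, " mV\n", sep = "")
  cat("  integral =", format(trapz_u(x$density, dr), digits = 6), "\n")
  invisible(x)
}

#' @export
plot.isi_density <- function(x, ...) {
  graphics::plot(x$r, x$density, type = "l", xlab = "interspike interval (ms)",
                 ylab = "density (1/ms)", ...)
  invisible(x)
}
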