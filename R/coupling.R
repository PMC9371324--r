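# Weakly-coupled-oscillator analysis of two delayed, symmetrically coupled
# oscillatory circuits. The phase lag theta between the circuits obeys
# d(theta)/dt = G(theta) with G(theta) = H(theta - d) - H(-theta - d), where
# d is the conduction delay and H is the interaction function
#   H(theta) = (eps Gs / T) * int_0^T Z_I(s) A(s - theta) ds,
# computed from one period of the activity and the mPRC. Zeros of G with
# negative slope are stable phase lags.

#' Interaction function H of two weakly coupled circuits
#'
#' Circular cross-correlation of the mPRC with one period of the activity,
#' `H(theta) = (eps Gs / T) int Z_I(s) A(s - theta) ds`, evaluated on the
#' common periodic grid with periodic wraparound of `A`.
#'
#' @param mprc a `prc_curve` (the adjoint mPRC) sampled on the cycle grid.
#' @param activity one period of the collective activity `A` on the same
#'   grid (1/ms); resampled with a warning if the lengths differ.
#' @param T_period oscillation period (ms).
#' @param epsGs cross-circuit coupling strength, the product eps*Gs (mV ms).
#' @return object of class `interaction_fn` with `theta` (time units, ms),
#'   `H`, `T`, `epsGs`.
#' @export
interaction_H <- function(mprc, activity, T_period, epsGs) {
  Z <- mprc$response
  M <- length(Z)
  if (length(activity) != M) {
    warning("activity and mPRC grids differ (", length(activity), " vs ", M,
            " samples); resampling the activity")
    dx_a <- T_period / length(activity)
    activity <- interp_periodic(activity, dx_a, (0:(M - 1)) * T_period / M)
  }
  dtc <- T_period / M
  # H[k] = (epsGs/T) * sum_s Z[s] A[s - k] dtc, periodic in k
  idx <- seq_len(M)
  H <- vapply(0:(M - 1L), function(k) {
    sum(Z * activity[((idx - 1L - k) %% M) + 1L])
  }, numeric(1)) * dtc * epsGs / T_period
  structure(list(theta = (0:(M - 1L)) * dtc, H = H, T = T_period,
                 epsGs = epsGs),
            class = "interaction_fn")
}

#' @export
print.interaction_fn <- function(x, ...) {
  cat("Interaction function H on [0,", format(x$T, digits = 5), ") ms, ",
      length(x$H), " samples, epsGs = ", x$epsGs, " mV ms\n", sep = "")
  invisible(x)
}

#' G-function and phase-locking fixed points for a given delay
#'
#' `G(theta) = H(theta - d) - H(-theta - d)` (periodic evaluation by linear
#' interpolation). Fixed points are the sign changes of `G`, located by
#' linear interpolation; a negative slope at the crossing means a stable
#' phase lag. Zeros closer than two grid steps are merged (flagged in the
#' `merged` column).
#'
#' @param H an [interaction_H()] result.
#' @param d conduction delay (ms, in `[0, T)`).
#' @return object of class `phase_interaction`: `theta` (ms), `theta_rad`,
#'   `G`, `d`, and `fixed_points` (data.frame with `theta`, `theta_rad`,
#'   `stability`, `slope`, `merged`).
#' @export
g_function <- function(H, d) {
  stopifnot(inherits(H, "interaction_fn"))
  M <- length(H$H); dtc <- H$T / M
  th <- H$theta
  G <- interp_periodic(H$H, dtc, th - d) - interp_periodic(H$H, dtc, -th - d)
  # circular sign changes
  Gn <- c(G, G[1L])
  fp_th <- numeric(0); fp_sl <- numeric(0)
  for (k in seq_len(M)) {
    g1 <- Gn[k]; g2 <- Gn[k + 1L]
    if (g1 == 0 || (g1 < 0) != (g2 < 0)) {
      frac <- if (g1 == g2) 0 else g1 / (g1 - g2)
      fp_th <- c(fp_th, (k - 1L + frac) * dtc)
      fp_sl <- c(fp_sl, (g2 - g1) / dtc)
    }
  }
  merged <- rep(FALSE, length(fp_th))
  if (length(fp_th) > 1L) {
    keep <- rep(TRUE, length(fp_th))
    for (k in seq_along(fp_th)[-1L]) {
      if (fp_th[k] - fp_th[k - 1L] < 2 * dtc && keep[k - 1L]) {
        keep[k] <- FALSE; merged[k - 1L] <- TRUE
      }
    }
    fp_th <- fp_th[keep]; fp_sl <- fp_sl[keep]; merged <- merged[keep]
  }
  fixed_points <- data.frame(
    theta = fp_th, theta_rad = 2 * pi * fp_th / H$T,
    stability = ifelse(fp_sl < 0, "stable", "unstable"),
    slope = fp_sl, merged = merged)
  structure(list(theta = th, theta_rad = 2 * pi * th / H$T, G = G, d = d,
                 T = H$T, fixed_points = fixed_points),
            class = "phase_interaction")
}

#' @export
print.phase_interaction <- function(x, ...) {
  cat("G-function at delay d =", x$d, "ms (period", format(x$T, digits = 5),
      "ms)\n")
  if (nrow(x$fixed_points)) {
    print(x$fixed_points[, c("theta", "theta_rad", "stability")],
          row.names = FALSE, digits = 4)
  } else cat("  no fixed points\n")
  invisible(x)
}

#' @export
plot.phase_interaction <- function(x, ...) {
  graphics::plot(x$theta, x$G, type = "l", xlab = "phase lag (ms)",
                 ylab = "G", ...)
  graphics::abline(h = 0, lty = 3)
  fp <- x$fixed_points
  if (nrow(fp))
    graphics::points(fp$theta, rep(0, nrow(fp)),
                     pch = ifelse(fp$stability == "stable", 19, 1))
  invisible(x)
}

#' Locking-mode bifurcation diagram over the conduction delay
#'
#' Sweeps the delay, collecting the fixed points of the G-function and
#' their stability.
#'
#' @param H an [interaction_H()] result.
#' @param d_values delays to scan (ms, within `[0, T)`).
#' @return object of class `delay_bifurcation`: data.frame with `d`,
#'   `theta`, `theta_rad`, `stability`.
#' @export
delay_bifurcation <- function(H, d_values) {
  rows <- lapply(d_values, function(d) {
    fp <- g_function(H, d)$fixed_points
    if (nrow(fp) == 0L) return(NULL)
    cbind(d = d, fp[, c("theta", "theta_rad", "stability")])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("delay_bifurcation", "data.frame")
  out
}

#' @export
print.delay_bifurcation <- function(x, ...) {
  cat("Delay bifurcation diagram:", length(unique(x$d)), "delays,",
      nrow(x), "fixed points\n")
  print.data.frame(utils::head(as.data.frame(x), 8), digits = 4)
  invisible(x)
}

#' @export
plot.delay_bifurcation <- function(x, ...) {
  graphics::plot(x$d, x$theta, pch = ifelse(x$stability == "stable", 19, 1),
                 xlab = "delay d (ms)", ylab = "phase lag (ms)", ...)
  invisible(x)
}
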