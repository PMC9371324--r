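#' Escape-rate (hazard) models for renewal spiking neurons
#'
#' Constructs a hazard model `S(h, r)`: the instantaneous firing rate of a
#' neuron receiving total input `h` (mV) at age `r` (ms since its last spike).
#' All refractory forms are zero below the refractory time `T_ref` and carry
#' the input multiplicatively through `exp(h)` (so `h` enters dimensionlessly).
#' Units: time in ms, rates in 1/ms, `h` in mV.
#'
#' Available forms (Heaviside `H` with the convention `H(0) = 1`, and
#' `u = r - T_ref`):
#' \describe{
#'   \item{`exp_relax`}{`exp(h) H(u) (1 - exp(-u/tau))`; `tau = 0` degenerates
#'     to the hard-threshold hazard `exp(h) H(u)`. `tau` acts as an effective
#'     noise level (threshold softness).}
#'   \item{`ramp`}{`exp(h) H(u) * eps * u`, a linearly growing hazard.}
#'   \item{`tanh`}{`exp(h) H(u) tanh(exp(h) u)`; note `h` also enters through
#'     the tanh argument, so `dS/dh != S`.}
#'   \item{`tanh_cos`}{the `tanh` form modulated by `(1 + eps*cos(omega r))`,
#'     clamped at zero where the modulation factor is negative (a hazard rate
#'     cannot be negative).}
#'   \item{`gamma_isi`}{the hazard of a gamma interspike-interval density with
#'     shape `alpha` and rate `exp(h)` (so `alpha = 1` is a Poisson neuron).}
#'   \item{`tabulated`}{an age-dependent hazard given on a grid (input
#'     independent); see [isi_to_hazard()].}
#' }
#'
#' @param form one of `"exp_relax"`, `"ramp"`, `"tanh"`, `"tanh_cos"`,
#'   `"gamma_isi"`, `"tabulated"`.
#' @param T_ref absolute refractory time (ms, >= 0).
#' @param tau threshold-softness time constant (ms, >= 0; `exp_relax` only).
#' @param eps form-specific gain (`ramp` slope, `tanh_cos` modulation depth).
#' @param omega modulation angular frequency (1/ms, `tanh_cos` only).
#' @param alpha gamma shape parameter (`gamma_isi` only, > 0).
#' @param r,S,dS age grid, hazard values and optional `dS/dh` values for the
#'   `tabulated` form.
#'
#' @return an object of class `hazard_model` with vectorised functions
#'   `S(h, r)` and `dS_dh(h, r)`, and (where a closed form exists) the
#'   cumulative hazard `cumhaz(h, r)`.
#' @examples
#' hz <- hazard_model("exp_relax", T_ref = 10, tau = 5)
#' hz$S(0, 15)          # 1 - exp(-1)
#' hz$S(2, 8)           # 0: refractory
#' @export
hazard_model <- function(form = c("exp_relax", "ramp", "tanh", "tanh_cos",
                                  "gamma_isi", "tabulated"),
                         T_ref = 0, tau = 0, eps = NULL, omega = NULL,
                         alpha = NULL, r = NULL, S = NULL, dS = NULL) {
  form <- match.arg(form)
  if (T_ref < 0) stop("T_ref must be >= 0")
  if (tau < 0) stop("tau must be >= 0")

  m <- list(form = form, T_ref = T_ref, tau = tau, eps = eps, omega = omega,
            alpha = alpha)

  if (form == "exp_relax") {
    base <- if (tau > 0) {
      function(r) {
        u <- r - T_ref
        ifelse(u >= 0, 1 - exp(-u / tau), 0)
      }
    } else {
      function(r) as.numeric(r >= T_ref)
    }
    m$separable <- TRUE
    m$base <- base
    m$S <- function(h, r) exp(h) * base(r)
    m$dS_dh <- m$S
    m$cumhaz <- if (tau > 0) {
      function(h, r) {
        u <- pmax(r - T_ref, 0)
        exp(h) * (u - tau * (1 - exp(-u / tau)))
      }
    } else {
      function(h, r) exp(h) * pmax(r - T_ref, 0)
    }
  } else if (form == "ramp") {
    if (is.null(eps)) stop("ramp form requires eps")
    base <- function(r) {
      u <- r - T_ref
      ifelse(u >= 0, eps * u, 0)
    }
    m$separable <- TRUE
    m$base <- base
    m$S <- function(h, r) exp(h) * base(r)
    m$dS_dh <- m$S
    m$cumhaz <- function(h, r) exp(h) * eps * pmax(r - T_ref, 0)^2 / 2
  } else if (form == "tanh") {
    m$separable <- FALSE
    m$S <- function(h, r) {
      u <- r - T_ref
      ifelse(u >= 0, exp(h) * tanh(exp(h) * u), 0)
    }
    m$dS_dh <- function(h, r) {
      u <- r - T_ref
      x <- exp(h) * pmax(u, 0)
      sech2 <- (1 / cosh(x))^2
      ifelse(u >= 0, exp(h) * tanh(x) + exp(h) * x * sech2, 0)
    }
    m$cumhaz <- function(h, r) {
      u <- pmax(r - T_ref, 0)
      logcosh(exp(h) * u)
    }
  } else if (form == "tanh_cos") {
    if (is.null(eps) || is.null(omega)) stop("tanh_cos form requires eps and omega")
    m$separable <- FALSE
    mod <- function(r) 1 + eps * cos(omega * r)
    m$S <- function(h, r) {
      u <- r - T_ref
      raw <- ifelse(u >= 0, exp(h) * tanh(exp(h) * pmax(u, 0)) * mod(r), 0)
      pmax(raw, 0)
    }
    m$dS_dh <- function(h, r) {
      u <- r - T_ref
      x <- exp(h) * pmax(u, 0)
      sech2 <- (1 / cosh(x))^2
      g <- mod(r)
      raw <- ifelse(u >= 0, exp(h) * tanh(x) * g, 0)
      ifelse(u >= 0 & raw > 0, (exp(h) * tanh(x) + exp(h) * x * sech2) * g, 0)
    }
    m$cumhaz <- NULL # clamping leaves no closed form
  } else if (form == "gamma_isi") {
    if (is.null(alpha) || alpha <= 0) stop("gamma_isi form requires alpha > 0")
    m$separable <- FALSE
    m$T_ref <- 0
    # hazard of Gamma(shape = alpha, rate = exp(h)); log-gamma normalisation
    # inside dgamma keeps large alpha overflow-free
    m$S <- function(h, r) {
      rate <- exp(h)
      out <- exp(stats::dgamma(r, shape = alpha, rate = rate, log = TRUE) -
                   stats::pgamma(r, shape = alpha, rate = rate,
                                 lower.tail = FALSE, log.p = TRUE))
      out[r <= 0 & alpha > 1] <- 0
      if (alpha == 1) out[r <= 0] <- rate
      out
    }
    m$dS_dh <- function(h, r) {
      rate <- exp(h)
      s <- m$S(h, r)
      s * (alpha - rate * r) + r * s^2
    }
    m$cumhaz <- function(h, r) {
      -stats::pgamma(r, shape = alpha, rate = exp(h), lower.tail = FALSE,
                     log.p = TRUE)
    }
  } else { # tabulated
    if (is.null(r) || is.null(S)) stop("tabulated form requires r and S")
    if (any(S < 0)) stop("tabulated hazard must be nonnegative")
    Sfun <- stats::approxfun(r, S, rule = 2)
    m$separable <- FALSE
    m$table <- list(r = r, S = S, dS = dS)
    zero_lead <- which(S > 0)
    m$T_ref <- if (length(zero_lead) && zero_lead[1L] > 1L) r[zero_lead[1L] - 1L] else 0
    m$S <- function(h, rr) Sfun(rr)
    m$dS_dh <- if (is.null(dS)) {
      function(h, rr) rep(0, length(rr))
    } else {
      dfun <- stats::approxfun(r, dS, rule = 2)
      function(h, rr) dfun(rr)
    }
    m$cumhaz <- NULL
  }

  class(m) <- "hazard_model"
  m
}

# cumulative hazard on a uniform grid starting at 0: closed form when the
# model has one, cumulative trapezoid otherwise
cumhaz_grid <- function(model, h, r_grid) {
  if (!is.null(model$cumhaz)) {
    model$cumhaz(h, r_grid)
  } else {
    cumtrapz_u(model$S(h, r_grid), r_grid[2L] - r_grid[1L])
  }
}

#' @export
print.hazard_model <- function(x, ...) {
  cat("Hazard model:", x$form, "\n")
  cat("  T_ref =", x$T_ref, "ms")
  if (x$form == "exp_relax") cat(", tau =", x$tau, "ms")
  if (!is.null(x$eps)) cat(", eps =", x$eps)
  if (!is.null(x$omega)) cat(", omega =", x$omega, "/ms")
  if (!is.null(x$alpha)) cat(", alpha =", x$alpha)
  cat("\n")
  invisible(x)
}
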