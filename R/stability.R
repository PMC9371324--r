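# Linear stability of the asynchronous state.
#
# Linearising the refractory-density equation around (A_inf, q_inf) and
# looking for modes ~ exp(lambda t) yields a characteristic equation
# C(lambda) = 0 whose roots are the eigenvalues of the linearised operator.
# C always has the structural root lambda = 0 (mass conservation); the
# asynchronous state loses stability when a complex-conjugate pair crosses
# the imaginary axis (Hopf), which happens along the curve C(i w) = 0 in the
# (I_ext, J_s) plane.

#' Characteristic problem of the linearised mean-field operator
#'
#' Bundles the asynchronous steady state with the synaptic parameters and the
#' Laplace transform of the synaptic filter, `kappa_hat(lambda) =
#' 1/(1 + lambda tau_s)` (so `kappa_hat(0) = 1`).
#'
#' @inheritParams integrate_meanfield
#' @param steady optionally, a precomputed [steady_state()].
#' @return object of class `characteristic_problem`.
#' @export
characteristic_problem <- function(hazard, I_ext, J_s, tau_s, steady = NULL) {
  if (is.null(steady)) steady <- steady_state(hazard, I_ext, J_s)
  structure(list(hazard = hazard, I_ext = I_ext, J_s = J_s, tau_s = tau_s,
                 steady = steady,
                 kappa_hat = function(lambda) 1 / (1 + lambda * tau_s)),
            class = "characteristic_problem")
}

#' Characteristic function, general quadrature form
#'
#' Evaluates the (dimensionless) characteristic function of the linearised
#' operator for an arbitrary hazard model:
#' \deqn{C(\lambda) = 1 - J_s\hat\kappa(\lambda)\int \partial_h S\, q_\infty\,dr
#'  - \int S_\infty e^{-\int_0^r (S_\infty+\lambda)}\,dr
#'  + J_s\hat\kappa(\lambda)\int S_\infty(r)\int_0^r \partial_h S\,
#'    q_\infty(x)\, e^{-\int_x^r (S_\infty+\lambda)}\,dx\,dr.}
#' Using `q_inf(x) = A_inf exp(-cumhaz(x))` the inner integrand collapses to
#' `A_inf dS/dh(x) exp(lambda x)`, which keeps the nested quadrature
#' overflow-free. Integrals are restricted to `r >= T_ref` (the integrands
#' vanish below) so the hazard's jump at `T_ref` never crosses a quadrature
#' panel; trapezoid rule with step `dr` on the smooth part.
#'
#' `C(0) = 0` structurally. For the hard-threshold hazard (`exp_relax`,
#' `tau = 0`) this form relates to the closed form of
#' [characteristic_tau0()] by `C_tau0(lambda) = (exp(h_inf) + lambda) *
#' C_general(lambda)` — same zeros, different normalisation.
#'
#' @param problem a [characteristic_problem()].
#' @param lambda complex value(s) at which to evaluate.
#' @param dr quadrature step (ms).
#' @return complex vector `C(lambda)`.
#' @export
characteristic_general <- function(problem, lambda, dr = 2e-5) {
  st <- problem$steady
  hz <- problem$hazard
  h_inf <- st$h_inf
  Tr <- hz$T_ref

  # smooth integration range: survivor decayed below ~1e-13
  r_end <- Tr + 10
  while (utils::tail(cumhaz_grid(hz, h_inf, seq(0, r_end, length.out = 4097L)), 1L) < 30 &&
         r_end < Tr + 1e4)
    r_end <- Tr + (r_end - Tr) * 2
  rg <- seq(Tr, r_end, by = dr)
  if (is.null(hz$cumhaz)) {
    full <- seq(0, r_end, by = dr)
    ch <- utils::tail(cumtrapz_u(hz$S(h_inf, full), dr), length(rg))
    ch <- ch - ch[1L]
  } else {
    ch <- hz$cumhaz(h_inf, rg) - hz$cumhaz(h_inf, Tr)
  }
  S <- hz$S(h_inf, rg)
  dS <- hz$dS_dh(h_inf, rg)
  A_inf <- st$A_inf
  q_inf <- A_inf * exp(-ch)

  T2 <- trapz_u(dS * q_inf, dr)
  vapply(lambda, function(lam) {
    kap <- problem$kappa_hat(lam)
    decay <- exp(-ch - lam * rg)
    T3 <- trapz_u(S * decay, dr)
    inner <- cumtrapz_u(dS * exp(lam * rg), dr)
    T4 <- A_inf * trapz_u(S * decay * inner, dr)
    1 - problem$J_s * kap * T2 - T3 + problem$J_s * kap * T4
  }, complex(1))
}

#' Characteristic function, closed form for the hard-threshold hazard
#'
#' For `S = exp(h) H(r - T_ref)` (the `exp_relax` form with `tau = 0`) the
#' characteristic equation reduces to
#' \deqn{C(\lambda) = \lambda - J_s \lambda \hat\kappa(\lambda) A_\infty
#'   + e^{h_\infty} - e^{h_\infty - \lambda T_{ref}}.}
#'
#' @inheritParams characteristic_general
#' @param deriv if `TRUE`, also return the analytic derivative `dC/dlambda`
#'   (used by the Newton root finders).
#' @return complex vector `C(lambda)` (or a list with `C` and `dC`).
#' @export
characteristic_tau0 <- function(problem, lambda, deriv = FALSE) {
  hz <- problem$hazard
  if (hz$form != "exp_relax" || hz$tau != 0)
    stop("characteristic_tau0 requires the exp_relax hazard with tau = 0")
  st <- problem$steady
  A <- st$A_inf; h <- st$h_inf
  Js <- problem$J_s; ts <- problem$tau_s; Tr <- hz$T_ref
  kap <- 1 / (1 + lambda * ts)
  C <- lambda - Js * lambda * kap * A + exp(h) - exp(h - lambda * Tr)
  if (!deriv) return(C)
  dkap_l <- kap - lambda * ts * kap^2          # d(lambda*kappa)/dlambda
  dC <- 1 - Js * A * dkap_l + Tr * exp(h - lambda * Tr)
  list(C = C, dC = dC)
}

# damped complex Newton on the closed-form characteristic function
newton_root_tau0 <- function(problem, lambda0, tol = 1e-12, max_iter = 60L) {
  lam <- lambda0
  f <- characteristic_tau0(problem, lam, deriv = TRUE)
  for (k in seq_len(max_iter)) {
    if (abs(f$dC) < 1e-14) return(NULL)
    step <- f$C / f$dC
    damp <- 1
    repeat {
      lam_new <- lam - damp * step
      f_new <- characteristic_tau0(problem, lam_new, deriv = TRUE)
      if (abs(f_new$C) < abs(f$C) || damp < 1 / 64) break
      damp <- damp / 2
    }
    lam <- lam_new; f <- f_new
    if (abs(f$C) < tol) return(lam)
  }
  if (abs(f$C) < 1e-8) lam else NULL
}

#' Rightmost eigenvalue of the asynchronous state (hard-threshold hazard)
#'
#' Multi-start damped Newton search on the closed-form characteristic
#' function over a grid of starting points `sigma + i omega`,
#' `sigma` in `sigma_range`, `omega` in `(0, 3 * 2 pi / T_ref]`. The
#' structural root at `lambda = 0` (|lambda| < `omega_min`) is excluded.
#' The returned value is the rightmost root *found*; with finitely many
#' starts this is a heuristic (no argument-principle root counting).
#'
#' @inheritParams characteristic_general
#' @param sigma_range real-part range of Newton starting points (1/ms).
#' @param n_sigma,n_omega starting-grid resolution.
#' @param omega_min roots with `|lambda|` below this are treated as the
#'   structural zero mode and discarded (1/ms).
#' @return list with `rightmost` (complex), `roots` (all distinct roots
#'   found) and `oscillatory` (`TRUE` if `Re(rightmost) > 0`).
#' @export
rightmost_eigenvalue <- function(problem, sigma_range = c(-0.5, 0.5),
                                 n_sigma = 7L, n_omega = 12L,
                                 omega_min = 1e-3) {
  Tr <- problem$hazard$T_ref
  om_max <- 3 * 2 * pi / max(Tr, 1)
  starts <- as.vector(outer(seq(sigma_range[1L], sigma_range[2L],
                                length.out = n_sigma),
                            seq(om_max / n_omega, om_max,
                                length.out = n_omega) * 1i, `+`))
  roots <- complex(0)
  for (s in starts) {
    r <- newton_root_tau0(problem, s)
    if (is.null(r)) next
    if (Mod(r) < omega_min) next
    r <- complex(real = Re(r), imaginary = abs(Im(r)))
    if (!length(roots) || min(Mod(roots - r)) > 1e-6) roots <- c(roots, r)
  }
  if (!length(roots)) stop("no nonzero characteristic roots found")
  rm_ <- roots[which.max(Re(roots))]
  list(rightmost = rm_, roots = roots, oscillatory = Re(rm_) > 0)
}

# 2D damped Newton with finite-difference Jacobian for the Hopf system
# F(J_s, omega) = (Re C(i omega), Im C(i omega)) with the steady state
# recomputed self-consistently at each (I_ext, J_s)
hopf_F <- function(hazard, I_ext, tau_s, Js, omega, dr = 1e-3) {
  st <- steady_state(hazard, I_ext, Js, dr = dr)
  pr <- characteristic_problem(hazard, I_ext, Js, tau_s, steady = st)
  C <- characteristic_tau0(pr, 1i * omega)
  c(Re(C), Im(C))
}

hopf_solve_point <- function(hazard, I_ext, tau_s, x0, tol = 1e-10,
                             max_iter = 40L) {
  x <- x0
  Fx <- hopf_F(hazard, I_ext, tau_s, x[1L], x[2L])
  for (k in seq_len(max_iter)) {
    if (max(abs(Fx)) < tol) return(x)
    hstep <- pmax(1e-6, 1e-6 * abs(x))
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + hstep[j]
      Jm[, j] <- (hopf_F(hazard, I_ext, tau_s, xp[1L], xp[2L]) - Fx) / hstep[j]
    }
    step <- tryCatch(solve(Jm, Fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    damp <- 1
    repeat {
      xn <- x - damp * step
      if (xn[1L] > 0 && xn[2L] > 1e-3) {
        Fn <- hopf_F(hazard, I_ext, tau_s, xn[1L], xn[2L])
        if (sum(Fn^2) < sum(Fx^2)) break
      }
      damp <- damp / 2
      if (damp < 1 / 256) return(NULL)
    }
    x <- xn; Fx <- Fn
  }
  if (max(abs(Fx)) < 1e-6) x else NULL
}

#' Trace the Hopf bifurcation line in the (I_ext, J_s) plane
#'
#' For each external current in `I_ext`, solves the two-real-equation system
#' `Re C(i omega) = Im C(i omega) = 0` in `(J_s, omega)` (with `omega > 0`,
#' excluding the structural zero root, and the steady state recomputed
#' self-consistently since `h_inf` depends on `J_s`). The first point is
#' located from a coarse scan, later points by continuation with warm starts
#' and step halving on failure; points where the solver fails leave a gap
#' (`NA`) in the curve.
#'
#' Only available for the hard-threshold hazard (`exp_relax`, `tau = 0`),
#' for which the characteristic equation has a closed form.
#'
#' @param hazard a tau = 0 `exp_relax` [hazard_model()].
#' @param tau_s synaptic decay (ms).
#' @param I_ext increasing vector of external currents (mV).
#' @return object of class `hopf_boundary`: data.frame with columns
#'   `I_ext`, `J_s`, `omega`.
#' @export
hopf_boundary <- function(hazard, tau_s, I_ext) {
  if (hazard$form != "exp_relax" || hazard$tau != 0)
    stop("hopf_boundary requires the exp_relax hazard with tau = 0 ",
         "(no closed-form characteristic equation otherwise)")
  Tr <- hazard$T_ref
  out <- data.frame(I_ext = I_ext, J_s = NA_real_, omega = NA_real_)
  warm <- NULL
  for (i in seq_along(I_ext)) {
    x0s <- if (!is.null(warm)) list(warm) else {
      # coarse scan in (J_s, omega), restricted to the fundamental mode
      # (omega near 2 pi / T_ref); higher resonance branches also satisfy
      # C(i omega) = 0 but bifurcate later
      Js_grid <- seq(1, 60, by = 1)
      om_grid <- 2 * pi / Tr * seq(0.5, 1.4, length.out = 31L)
      best <- NULL; best_v <- Inf
      for (Js in Js_grid) {
        st <- steady_state(hazard, I_ext[i], Js)
        pr <- characteristic_problem(hazard, I_ext[i], Js, tau_s, steady = st)
        v <- Mod(characteristic_tau0(pr, 1i * om_grid))
        if (min(v) < best_v) { best_v <- min(v); best <- c(Js, om_grid[which.min(v)]) }
      }
      list(best)
    }
    sol <- NULL
    for (x0 in x0s) {
      sol <- hopf_solve_point(hazard, I_ext[i], tau_s, x0)
      if (!is.null(sol)) break
    }
    if (is.null(sol) && !is.null(warm)) {
      # retry from a perturbed warm start before declaring a gap
      sol <- hopf_solve_point(hazard, I_ext[i], tau_s, warm * c(1.1, 1))
    }
    if (!is.null(sol)) {
      out$J_s[i] <- sol[1L]; out$omega[i] <- sol[2L]
      warm <- sol
    }
  }
  class(out) <- c("hopf_boundary", "data.frame")
  out
}

#' @export
print.hopf_boundary <- function(x, ...) {
  cat("Hopf bifurcation line:", sum(!is.na(x$J_s)), "of", nrow(x),
      "points traced\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}
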