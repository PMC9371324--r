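# Adjoint of the linearised refractory-density dynamics around a limit cycle.
#
# The pair (Z_q(t, r), Z_Is(t)) solves
#   -dZq/dt - dZq/dr = -S(h, r) [Zq - Zq(t, 0) - (Js/tau_s) Z_Is]
#   -dZ_Is/dt = -Z_Is/tau_s - int [Zq - Zq(t,0) - (Js/tau_s) Z_Is] dS/dh q dr
# with T-periodic coefficients taken from the limit cycle. The adjoint has
# the opposite stability of the forward dynamics, so it is integrated
# backward in time along characteristics, cycling over the periodic
# coefficients. The periodic adjoint is the eigenvector of the (linear)
# backward-period map with unit eigenvalue; because the secondary Floquet
# multipliers of these networks sit very close to the unit circle (weakly
# damped resonance modes), plain repetition of backward periods contracts
# too slowly, and the eigenvector is instead extracted by a small Arnoldi
# (Krylov) eigensolve whose matrix-vector product is one backward period.
# After normalising the pairing  int Zq dq/dt dr + Z_Is dIs/dt = 2 pi / T,
# Z_Is is the macroscopic phase-resetting curve (phase shift in radians per
# mV of instantaneous synaptic-current displacement).

#' Solve the adjoint system backward along characteristics
#'
#' First-order backward scheme: for each step (coefficients at cycle sample
#' `n`, producing sample `n-1`)
#' `Zq_{j-1}^{n-1} = Zq_j^n - dt S_j^n [Zq_j^n - Zq_1^n - Js Z_Is^n / tau_s]`,
#' the missing value at the oldest age filled by extrapolation, and
#' `Z_Is^{n-1} = Z_Is^n - dt (Z_Is^n/tau_s + int dS/dh [.] q dr)` with the
#' age integral computed by the trapezoid rule. One backward pass over the
#' period is a linear map of the section state `(Zq, Z_Is)`; the periodic
#' adjoint is its fixed point (unit-eigenvalue eigenvector), computed by
#' Arnoldi iteration with restarts until a full backward period reproduces
#' the section state to within `tol` (relative sup norm). The arbitrary
#' starting state (`Zq = 0`, `Z_Is = 1`) only seeds the Krylov space.
#'
#' Two backward steps are available. `scheme = "transpose"` (default) is the
#' discrete adjoint: the exact transpose of the forward scheme's linearised
#' step, under which the pairing with the cycle's own discrete tangent is
#' conserved to near machine precision (so the normalisation bracket is flat
#' even where the oscillation develops a near-singular activity volley).
#' `scheme = "characteristics"` is the direct first-order discretisation of
#' the continuous adjoint equations sketched above (backward transport with
#' nearest-node extrapolation at the oldest age and a trapezoid age
#' integral); it differs from the transpose by one index shift and the
#' top-boundary closure, i.e. at O(dt). Both converge to the same mPRC.
#'
#' @param cycle a [find_limit_cycle()] result.
#' @param n_cycles maximum total number of backward passes over the period.
#' @param tol relative convergence tolerance of the periodic section state.
#' @param krylov_dim Krylov subspace dimension per Arnoldi restart.
#' @param scheme `"transpose"` (discrete adjoint) or `"characteristics"`
#'   (direct discretisation of the continuous adjoint).
#' @param extrapolation fill rule for the oldest-age boundary cell:
#'   `"copy"` (nearest node) or `"linear"` (two-point extrapolation).
#' @return object of class `adjoint_solution` with `Z_q` (`M x J`), `Z_Is`
#'   (`M`), `T`, `residuals` (per-pass convergence history) and
#'   `normalized = FALSE`.
#' @export
solve_adjoint <- function(cycle, n_cycles = 400L, tol = 1e-6,
                          extrapolation = c("copy", "linear"),
                          krylov_dim = 30L,
                          scheme = c("transpose", "characteristics")) {
  stopifnot(inherits(cycle, "limit_cycle"))
  extrapolation <- match.arg(extrapolation)
  scheme <- match.arg(scheme)
  M <- cycle$M; J <- length(cycle$r)
  dt <- cycle$dt_cycle
  r <- cycle$r
  hz <- cycle$hazard
  Js <- cycle$J_s; ts <- cycle$tau_s

  hbar <- cycle$I_ext + cycle$I_s
  sep <- isTRUE(hz$separable)
  # coefficients stored as (J x M): one time sample per column, matching the
  # compiled kernel's access pattern
  if (sep) {
    # dS/dh = S for purely exp(h)-prefactor hazards
    S_mat <- hz$base(r) %o% exp(hbar)
    dS_mat <- S_mat
  } else {
    S_mat <- vapply(seq_len(M), function(n) hz$S(hbar[n], r), numeric(J))
    dS_mat <- vapply(seq_len(M), function(n) hz$dS_dh(hbar[n], r),
                     numeric(J))
  }
  q_t <- t(cycle$q)
  scheme_i <- if (scheme == "transpose") 0L else 1L
  extrap_i <- if (extrapolation == "copy") 0L else 1L

  # one backward period: section state s = c(Zq, Z_Is) -> B s; optionally
  # records the whole period. For the transpose (discrete-adjoint) scheme
  # the coefficients of forward step n -> n+1 act at row n and the shifted
  # adjoint value beyond r_max is 0 (mass leaving the grid is lost); the
  # characteristics scheme follows the backward transport discretisation
  # with an extrapolated top cell. Compiled kernel in src/kernels.cpp.
  backward_pass <- function(s, record = FALSE) {
    out <- adjoint_pass(S_mat, dS_mat, q_t, dt, Js, ts, s, scheme_i,
                        extrap_i, record)
    if (record) out else out$s
  }

  # The adjoint system always admits the trivial periodic solution
  # Zq = const, Z_Is = 0 (the conserved-mass functional: perturbations that
  # enter through the input carry zero net mass, so constants pair to zero
  # with them and cancel inside `br`). It is an exact unit eigenvector of
  # the backward map and sits on top of the phase dual's eigenvalue; it is
  # deflated by orthogonal projection, after which the phase dual is the
  # dominant eigenvector of the deflated map.
  e0 <- c(rep(1 / sqrt(J), J), 0)
  deflate <- function(s) s - sum(s * e0) * e0
  passes <- 0L
  B_defl <- function(s) {
    passes <<- passes + 1L
    deflate(backward_pass(deflate(s)))
  }

  # direction (shape) residual: the discrete dual eigenvalue deviates from 1
  # by the O(dt) scheme error, so raw successive-period differences never
  # vanish; convergence is measured modulo a uniform scale factor
  shape_defect <- function(s, s2) {
    cc <- sum(s2 * s) / sum(s * s)
    max(abs(s2 / cc - s)) / max(abs(s))
  }

  s <- B_defl(c(numeric(J), 1))
  resid <- numeric(0)
  mu <- NA_real_
  degenerate <- FALSE
  repeat {
    # Arnoldi factorisation of the deflated map, seeded at the current state
    K <- krylov_dim
    V <- matrix(0, J + 1L, K + 1L)
    H <- matrix(0, K + 1L, K)
    V[, 1L] <- s / sqrt(sum(s^2))
    k_used <- K
    for (k in seq_len(K)) {
      wv <- B_defl(V[, k])
      for (j in seq_len(k)) {
        H[j, k] <- sum(V[, j] * wv)
        wv <- wv - H[j, k] * V[, j]
      }
      H[k + 1L, k] <- sqrt(sum(wv^2))
      if (H[k + 1L, k] < 1e-12) { k_used <- k; break }
      V[, k + 1L] <- wv / H[k + 1L, k]
    }
    Hk <- H[seq_len(k_used), seq_len(k_used), drop = FALSE]
    eg <- eigen(Hk)
    cand <- which(Mod(eg$values - 1) < 0.1)
    if (!length(cand)) {
      # no near-unit mode beyond the deflated constants: the input-coupling
      # term dS/dh q is (numerically) absent and the only periodic adjoint
      # solutions are the constants
      degenerate <- TRUE
      break
    }
    # among near-unit Ritz pairs take the one best aligned with the current
    # estimate (the seed is basis vector 1); "nearest to 1" alone can grab a
    # spurious Ritz value once the seed is almost invariant
    pick <- cand[which.max(Mod(eg$vectors[1L, cand]))]
    mu <- eg$values[pick]
    y <- eg$vectors[, pick]
    y <- if (is.complex(y)) Re(y * exp(-1i * Arg(y[which.max(Mod(y))]))) else y
    s_new <- as.numeric(V[, seq_len(k_used), drop = FALSE] %*% y)
    if (abs(s_new[J + 1L]) < 1e-9 * max(abs(s_new))) {
      # near-unit mode with no synaptic component: the age transport alone
      # retains its (mass-dual) mode, but nothing couples to the input
      degenerate <- TRUE
      break
    }
    dd <- shape_defect(s_new, B_defl(s_new))
    if (length(resid) && dd > utils::tail(resid, 1L)) {
      # restart made things worse (noise-dominated Krylov basis): keep the
      # previous estimate and refine it by plain deflated power passes
      s <- B_defl(s)
      dd <- shape_defect(s, B_defl(s))
    } else {
      s <- s_new
    }
    resid <- c(resid, dd)
    if (dd < tol) break
    if (passes >= n_cycles)
      stop("adjoint iteration did not converge within ", n_cycles,
           " backward passes; residual history: ",
           paste(format(resid, digits = 3), collapse = ", "),
           " (is the limit cycle accurate enough?)")
    s <- B_defl(s)
  }

  if (degenerate) {
    warning("adjoint system has no input-coupled periodic mode ",
            "(dS/dh vanishes on the cycle); returning the trivial solution")
    Z_q <- matrix(0, M, J); Z_Is <- numeric(M)
    out <- list(Z_q = Z_q, Z_Is = Z_Is)
    resid <- 0
  } else {
    out <- backward_pass(s, record = TRUE)
    # the discrete dual eigenvalue mu = 1 + O(dt) tilts the recorded trace
    # by mu^(t/T) across the period; divide it out (Floquet correction)
    fac <- Re(mu)^(-(M - seq_len(M) + 1L) / M)
    out$Z_q <- out$Z_q * fac
    out$Z_Is <- out$Z_Is * fac
  }

  structure(list(Z_q = out$Z_q, Z_Is = out$Z_Is, T = cycle$T, M = M, r = r,
                 dt_cycle = dt, normalized = FALSE, residuals = resid,
                 passes = passes, eigenvalue = Re(mu), scheme = scheme,
                 periodic_defect = utils::tail(resid, 1L)),
            class = "adjoint_solution")
}

#' Impose the 2*pi/T normalisation on an adjoint solution
#'
#' Computes the pairing `bracket(t) = int Zq dq/dt dr + Z_Is dIs/dt` on the
#' cycle grid and rescales both components by `(2 pi / T) / mean(bracket)`.
#' The discrete time derivative of the cycle is matched to the adjoint
#' scheme: for the `"transpose"` (discrete-adjoint) scheme the forward
#' secant `(x^{n+1} - x^n)/dt` with the scheme's rectangle age weights (the
#' pairing that the transpose conserves exactly); for `"characteristics"`
#' centred periodic differences with trapezoid weights. For an exact adjoint
#' the bracket is constant in `t`; its maximum relative deviation from the
#' mean is reported as a quality metric and an error is raised when it
#' changes sign or deviates by more than 10% (the adjoint or the cycle is
#' then insufficiently converged).
#'
#' @param adjoint an unnormalised [solve_adjoint()] result.
#' @param cycle the generating [find_limit_cycle()].
#' @return the adjoint with `Z_q`, `Z_Is` rescaled, `normalized = TRUE`,
#'   plus fields `bracket` and `bracket_deviation`.
#' @export
normalize_adjoint <- function(adjoint, cycle) {
  stopifnot(inherits(adjoint, "adjoint_solution"))
  M <- adjoint$M; dt <- adjoint$dt_cycle
  J <- ncol(cycle$q)
  if (identical(adjoint$scheme, "characteristics")) {
    dq_dt <- periodic_diff(cycle$q, dt)
    dIs_dt <- periodic_diff(cycle$I_s, dt)
    w <- rep(dt, J); w[1L] <- dt / 2; w[J] <- dt / 2
  } else {
    # forward secant: the discrete tangent whose pairing the transpose
    # scheme conserves, with the scheme's own rectangle weights
    nxt <- c(2:M, 1L)
    dq_dt <- (cycle$q[nxt, , drop = FALSE] - cycle$q) / dt
    dIs_dt <- (cycle$I_s[nxt] - cycle$I_s) / dt
    w <- rep(dt, J)
  }
  bracket <- as.numeric((adjoint$Z_q * dq_dt) %*% w) + adjoint$Z_Is * dIs_dt
  m <- mean(bracket)
  dev <- max(abs(bracket - m)) / abs(m)
  if (any(sign(bracket) != sign(m)))
    stop("normalisation bracket changes sign across the period; ",
         "adjoint or cycle insufficiently converged")
  if (dev > 0.10)
    stop("normalisation bracket deviates by ", format(dev, digits = 3),
         " from constancy (> 10%); adjoint or cycle insufficiently converged")
  scale <- (2 * pi / adjoint$T) / m
  adjoint$Z_q <- adjoint$Z_q * scale
  adjoint$Z_Is <- adjoint$Z_Is * scale
  adjoint$bracket <- bracket * scale
  adjoint$bracket_deviation <- dev
  adjoint$normalized <- TRUE
  adjoint
}

#' Extract the macroscopic PRC from a normalised adjoint
#'
#' Since network perturbations arrive through the synapses, the synaptic
#' component `Z_Is` of the normalised adjoint is the macroscopic PRC: the
#' asymptotic phase shift (radians) per mV of instantaneous displacement of
#' the synaptic current, as a function of the phase `theta = 2 pi t / T`
#' anchored at the cycle's Poincare crossing.
#'
#' @param adjoint a normalised [normalize_adjoint()] result.
#' @return object of class `prc_curve` with `theta` (rad) and `response`
#'   (rad/mV).
#' @export
mprc <- function(adjoint) {
  stopifnot(inherits(adjoint, "adjoint_solution"))
  if (!isTRUE(adjoint$normalized))
    stop("mprc requires a normalised adjoint; call normalize_adjoint() first")
  structure(list(theta = 2 * pi * (0:(adjoint$M - 1L)) / adjoint$M,
                 response = adjoint$Z_Is, sem = NULL, T = adjoint$T,
                 stimulus = NULL, kind = "adjoint"),
            class = "prc_curve")
}

#' @export
print.adjoint_solution <- function(x, ...) {
  cat("Adjoint solution over one period (T =", format(x$T, digits = 6),
      "ms,", x$M, "samples)\n")
  cat("  normalised:", x$normalized, "; backward passes:",
      length(x$residuals) + 1L, "; final residual:",
      format(x$periodic_defect, digits = 3), "\n")
  if (!is.null(x$bracket_deviation))
    cat("  bracket deviation from 2*pi/T:",
        format(x$bracket_deviation, digits = 3), "\n")
  invisible(x)
}

#' @export
print.prc_curve <- function(x, ...) {
  cat("PRC curve (", x$kind, "), ", length(x$theta), " phases, T = ",
      format(x$T, digits = 6), " ms\n", sep = "")
  cat("  response range [", format(min(x$response), digits = 4), ",",
      format(max(x$response), digits = 4), "] rad/mV\n")
  invisible(x)
}

#' @export
plot.prc_curve <- function(x, ...) {
  graphics::plot(x$theta, x$response, type = if (is.null(x$sem)) "l" else "p",
                 xlab = "phase (rad)", ylab = "phase response (rad/mV)", ...)
  if (!is.null(x$sem))
    graphics::arrows(x$theta, x$response - x$sem, x$theta, x$response + x$sem,
                     angle = 90, code = 3, length = 0.02)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
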