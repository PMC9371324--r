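# Refractory-density mean-field solver.
#
# The population density q(t, r) of neuron ages obeys the age-structured
# transport equation dq/dt + dq/dr = -S(h, r) q with reflux boundary
# q(t, 0) = A(t) = int S q dr and synaptic feedback
# tau_s dIs/dt = -Is + Js A, h = I_ext + Is.
#
# Discretisation: ages r_j = j*dt (j = 1..J, cell-centred view, no r = 0
# node), time step equal to the age step so the scheme advects exactly one
# cell per step along characteristics, with first-order decay (1 - dt*S).
# Activity and density mass use plain rectangle sums dt*sum(.). The boundary
# cell receives exactly the mass fired during the step,
# q_1^{n+1} = A^n = dt * sum(S^n q^n), which makes the scheme conserve the
# rectangle mass to machine precision (minus the tracked leak past r_max);
# evaluating the activity sum at the new time instead books the influx one
# step ahead of the outflux and lets the mass wobble by O(dt * A) within an
# oscillation cycle.

# --- internal stepping core -------------------------------------------------
# Advances n_steps from state (q, I_s) at time t0. Records per-step series
# (including the initial state as sample 1). `pulse` is a square pulse:
# list(onset, duration, amplitude, route = "iext" | "synaptic").
mf_core <- function(model, I_ext, J_s, tau_s, dt, r, q, I_s, n_steps, t0 = 0,
                    pulse = NULL, record_q = FALSE) {
  Iext_fun <- if (is.function(I_ext)) I_ext else function(t) I_ext
  J <- length(r)
  sep <- isTRUE(model$separable)
  base <- if (sep) model$base(r) else NULL
  S_of <- if (sep) function(h) exp(h) * base else function(h) model$S(h, r)

  p_on <- !is.null(pulse)
  if (p_on) {
    p_route <- match.arg(pulse$route %||% "iext", c("iext", "synaptic"))
    p_t0 <- pulse$onset; p_t1 <- pulse$onset + pulse$duration
    p_amp <- pulse$amplitude
  }

  # compiled fast path: separable hazard, constant external current
  if (sep && !is.function(I_ext)) {
    out <- mf_steps_sep(base, I_ext, J_s, tau_s, dt, q, I_s, n_steps, t0,
                        if (!p_on) 0L else if (p_route == "iext") 1L else 2L,
                        if (p_on) p_t0 else 0, if (p_on) p_t1 else 0,
                        if (p_on) p_amp else 0, record_q)
    out$time <- t0 + (0:n_steps) * dt
    out$t_final <- t0 + n_steps * dt
    return(out)
  }

  iext_pulse <- function(t) {
    if (p_on && p_route == "iext" && t >= p_t0 && t < p_t1) p_amp else 0
  }

  h <- Iext_fun(t0) + I_s + if (p_on) iext_pulse(t0) else 0
  S <- S_of(h)
  A <- dt * sum(S * q)

  ns <- n_steps + 1L
  act <- numeric(ns); is_tr <- numeric(ns); h_tr <- numeric(ns)
  mass <- numeric(ns); leak <- 0
  act[1L] <- A; is_tr[1L] <- I_s; h_tr[1L] <- h; mass[1L] <- dt * sum(q)
  qrec <- if (record_q) matrix(0, ns, J) else NULL
  if (record_q) qrec[1L, ] <- q

  jj <- seq_len(J - 1L)
  warned_neg <- FALSE
  for (i in seq_len(n_steps)) {
    smax <- dt * max(S)
    if (smax >= 2)
      stop("time step too large for this hazard: |1 - dt*S| >= 1 on the grid ",
           "(the characteristics scheme is unstable); reduce dt")
    if (smax >= 1 && !warned_neg) {
      warning("dt*S exceeds 1 on part of the grid; the decay factor 1 - dt*S ",
              "goes negative (still contractive, but accuracy degrades)")
      warned_neg <- TRUE
    }
    t_now <- t0 + (i - 1L) * dt
    t_next <- t0 + i * dt

    leak <- leak + q[J] * (1 - dt * S[J]) * dt
    qn <- c(A, q[jj] * (1 - dt * S[jj]))

    I_s <- I_s + dt * (-I_s + J_s * A) / tau_s
    if (p_on && p_route == "synaptic" && t_now >= p_t0 && t_now < p_t1)
      I_s <- I_s + dt * p_amp

    h <- Iext_fun(t_next) + I_s + if (p_on) iext_pulse(t_next) else 0
    S <- S_of(h)
    q <- qn
    A <- dt * sum(S * q)

    act[i + 1L] <- A; is_tr[i + 1L] <- I_s; h_tr[i + 1L] <- h
    mass[i + 1L] <- dt * sum(q)
    if (record_q) qrec[i + 1L, ] <- q
  }

  list(time = t0 + (0:n_steps) * dt, activity = act, I_s = is_tr, h = h_tr,
       mass = mass, leak = leak, q = qrec, q_final = q, I_s_final = I_s,
       t_final = t0 + n_steps * dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default initial density: truncated Gaussian age profile, normalised under
# the scheme's rectangle quadrature
mf_init_density <- function(model, r, dt, init_mean = NULL, init_sd = NULL) {
  Tr <- model$T_ref
  m0 <- init_mean %||% if (Tr > 0) Tr / 2 else max(r) / 4
  s0 <- init_sd %||% if (Tr > 0) Tr / 6 else max(r) / 12
  q0 <- stats::dnorm(r, m0, s0)
  q0 / (dt * sum(q0))
}

#' Integrate the refractory-density mean-field equation
#'
#' First-order method-of-characteristics integration of the age-structured
#' population equation with escape-rate loss, reflux boundary
#' `q(t,0) = A(t)` and exponentially filtered synaptic feedback.
#'
#' @param hazard a [hazard_model()].
#' @param I_ext external current (mV), scalar or `function(t)`.
#' @param J_s recurrent synaptic efficiency (mV ms).
#' @param tau_s synaptic decay time (ms).
#' @param duration integration time (ms).
#' @param dt time step = age step (ms).
#' @param r_max age-grid truncation (ms); default `1.25 * T_ref` (the age by
#'   which essentially the whole population has fired). Mass leaking past
#'   `r_max` is accumulated in the `leak` field.
#' @param q0 initial density on the grid `r_j = j dt` (default: truncated
#'   Gaussian profile, mean `T_ref/2`, sd `T_ref/6`).
#' @param I_s0 initial synaptic current (mV).
#' @param pulse optional square perturbation:
#'   `list(onset, duration, amplitude, route)` with `route = "iext"` (added to
#'   the external current, mV) or `"synaptic"` (added to `dIs/dt`, mV/ms).
#' @param record_q if `TRUE`, keep every density snapshot (memory `M x J`).
#' @param init_mean,init_sd initial Gaussian age profile parameters (ms).
#' @return object of class `meanfield_sim` with per-step `time`, `activity`,
#'   `I_s`, `h`, `mass`, the accumulated `leak`, the final state and (if
#'   requested) the density history `q`.
#' @examples
#' hz <- hazard_model("exp_relax", T_ref = 10, tau = 5)
#' sim <- integrate_meanfield(hz, I_ext = 2, J_s = 15, tau_s = 10,
#'                            duration = 200, dt = 0.05)
#' range(sim$mass - 1)
#' @export
integrate_meanfield <- function(hazard, I_ext, J_s, tau_s, duration,
                                dt = 0.05, r_max = NULL, q0 = NULL, I_s0 = 0,
                                pulse = NULL, record_q = FALSE,
                                init_mean = NULL, init_sd = NULL) {
  stopifnot(inherits(hazard, "hazard_model"), duration >= dt, dt > 0,
            tau_s > 0)
  r_max <- r_max %||% (1.25 * hazard$T_ref)
  if (r_max <= dt) stop("r_max must exceed dt (is T_ref set?)")
  J <- round(r_max / dt)
  r <- (1:J) * dt
  if (is.null(q0)) q0 <- mf_init_density(hazard, r, dt, init_mean, init_sd)
  n_steps <- round(duration / dt)
  out <- mf_core(hazard, I_ext, J_s, tau_s, dt, r, q0, I_s0, n_steps,
                 pulse = pulse, record_q = record_q)
  out$r <- r; out$dt <- dt
  out$params <- list(I_ext = I_ext, J_s = J_s, tau_s = tau_s, r_max = r_max)
  out$hazard <- hazard
  class(out) <- "meanfield_sim"
  out
}

#' @export
print.meanfield_sim <- function(x, ...) {
  cat("Mean-field integration:", length(x$time) - 1L, "steps of dt =", x$dt,
      "ms\n")
  cat("  final activity", format(x$activity[length(x$activity)], digits = 4),
      "/ms; mass error", format(max(abs(x$mass - x$mass[1L])), digits = 3),
      "; leaked mass", format(x$leak, digits = 3), "\n")
  invisible(x)
}

# --- asynchronous steady state ---------------------------------------------

# integral of the survivor function exp(-int_0^r S(h, s) ds) over r >= 0,
# i.e. the mean interspike interval at clamped input h. The survivor is
# identically 1 below T_ref (counted exactly) and smooth above, where a
# composite Simpson rule is used; the closed-form cumulative hazard is taken
# when the model has one.
survivor_integral <- function(model, h, dr = 1e-3, r_end = NULL) {
  Tr <- model$T_ref
  if (is.null(r_end)) {
    r_end <- Tr + 10
    repeat {
      tail_ch <- utils::tail(cumhaz_grid(model, h, seq(0, r_end, by = dr)), 1L)
      if (tail_ch > 30 || r_end > Tr + 1e4) break
      r_end <- Tr + (r_end - Tr) * 2
    }
  }
  grid <- seq(Tr, r_end, by = dr)
  ch_full <- cumhaz_grid(model, h, if (Tr > 0) c(seq(0, Tr - dr, by = dr), grid)
                         else grid)
  ch <- utils::tail(ch_full, length(grid))
  Tr + simpson_u(exp(-(ch - ch[1L])), dr) * exp(-ch[1L])
}

#' Asynchronous steady state of the mean-field network
#'
#' Solves the self-consistency condition of the time-independent solution:
#' the stationary rate satisfies `1/A_inf = int_0^inf exp(-int_0^r S(h_inf,s)
#' ds) dr` (the mean ISI at the stationary input) with
#' `h_inf = I_ext + J_s A_inf`. The root in `A_inf` is found by bracketed
#' root finding on the residual `A * meanISI(h(A)) - 1`, starting from
#' `A = 0`; if several roots exist the one reached from below is returned
#' with a warning.
#'
#' @inheritParams integrate_meanfield
#' @param dr quadrature step for the survivor integral (ms).
#' @param tol root-finder tolerance on `A_inf`.
#' @return object of class `steady_state`: `A_inf` (1/ms), `h_inf` (mV),
#'   `r`/`q_inf` (stationary density profile), and the residual of the
#'   self-consistency equation at the returned root.
#' @examples
#' hz <- hazard_model("exp_relax", T_ref = 8, tau = 0)
#' st <- steady_state(hz, I_ext = 2, J_s = 0)
#' all.equal(st$A_inf, 1 / (8 + exp(-2)), tolerance = 1e-9)
#' @export
steady_state <- function(hazard, I_ext, J_s, dr = 1e-3, tol = 1e-13) {
  stopifnot(inherits(hazard, "hazard_model"))
  resid <- function(A) A * survivor_integral(hazard, I_ext + J_s * A, dr) - 1
  lo <- 1e-12
  hi <- 1 / max(hazard$T_ref, 10 * dr)
  k <- 0L
  while (resid(hi) < 0 && k < 60L) { hi <- hi * 2; k <- k + 1L }
  if (resid(hi) < 0) stop("steady_state: could not bracket a root; last residual ",
                          format(resid(hi)))
  root <- stats::uniroot(resid, c(lo, hi), tol = tol, maxiter = 1000L)
  A_inf <- root$root
  h_inf <- I_ext + J_s * A_inf
  # flag additional roots above the one reached from A = 0
  probe <- A_inf * c(1.5, 3, 6)
  rs <- vapply(probe, resid, numeric(1))
  if (any(diff(sign(rs)) != 0))
    warning("steady_state: residual changes sign again above the returned root; ",
            "multiple steady states may exist")
  r_end <- hazard$T_ref + 10
  while (utils::tail(cumhaz_grid(hazard, h_inf, seq(0, r_end, by = dr)), 1L) < 30 &&
         r_end < hazard$T_ref + 1e4)
    r_end <- hazard$T_ref + (r_end - hazard$T_ref) * 2
  rg <- seq(0, r_end, by = dr)
  q_inf <- A_inf * exp(-cumhaz_grid(hazard, h_inf, rg))
  structure(list(A_inf = A_inf, h_inf = h_inf, r = rg, q_inf = q_inf,
                 residual = resid(A_inf), hazard = hazard,
                 I_ext = I_ext, J_s = J_s, dr = dr),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Asynchronous steady state\n")
  cat("  A_inf =", format(x$A_inf, digits = 8), "/ms  (h_inf =",
      format(x$h_inf, digits = 6), "mV)\n")
  cat("  self-consistency residual:", format(x$residual, digits = 3), "\n")
  invisible(x)
}

# --- limit cycle ------------------------------------------------------------

#' Extract the oscillatory limit cycle of the mean-field equation
#'
#' Integrates past a transient, detects the collective oscillation from
#' upward crossings of the synaptic current through its mean (the Poincare
#' section anchoring phase zero), estimates the period as the mean crossing
#' interval, and stores one period of the density and synaptic current
#' resampled onto exactly `M = round(T/dt)` samples by linear interpolation
#' in time.
#'
#' @inheritParams integrate_meanfield
#' @param t_transient time discarded before measuring (ms).
#' @param t_measure measurement window for the period estimate (ms).
#' @param cycle_tol maximum tolerated relative periodicity defect
#'   `||x(t) - x(t+T)|| / ||x||` of the stored cycle.
#' @param drift_tol maximum tolerated relative drift of the period estimate
#'   between the two halves of the measurement window.
#' @return object of class `limit_cycle`: period `T`, sample count `M`,
#'   cycle sample spacing `dt_cycle = T/M`, density matrix `q` (`M x J`),
#'   synaptic current `I_s`, activity `A = q[, 1]`, age grid `r`, Poincare
#'   `level`, periodicity `defect`, and the generating parameters.
#' @export
find_limit_cycle <- function(hazard, I_ext, J_s, tau_s, dt = 0.05,
                             r_max = NULL, t_transient = 500, t_measure = 300,
                             cycle_tol = 0.02, drift_tol = 2e-3,
                             q0 = NULL, I_s0 = 0) {
  stopifnot(inherits(hazard, "hazard_model"))
  r_max <- r_max %||% (1.25 * hazard$T_ref)
  J <- round(r_max / dt)
  r <- (1:J) * dt
  if (is.null(q0)) q0 <- mf_init_density(hazard, r, dt)

  tr <- mf_core(hazard, I_ext, J_s, tau_s, dt, r, q0, I_s0,
                round(t_transient / dt))
  me <- mf_core(hazard, I_ext, J_s, tau_s, dt, r, tr$q_final, tr$I_s_final,
                round(t_measure / dt), t0 = tr$t_final)

  is_tr <- me$I_s
  level <- mean(is_tr)
  amp <- diff(range(is_tr))
  if (amp < max(1e-8, 1e-3 * abs(level)))
    stop("no oscillation detected (synaptic current is flat)")
  # transient ringing of a stable focus decays; a limit cycle does not
  third <- floor(length(is_tr) / 3)
  amp1 <- diff(range(is_tr[seq_len(third)]))
  amp3 <- diff(range(is_tr[(2L * third + 1L):length(is_tr)]))
  if (amp3 < 0.9 * amp1)
    stop("oscillation amplitude is decaying (asynchronous regime, or ",
         "increase t_transient)")
  cross <- upward_crossings(is_tr, level, me$time)
  if (length(cross) < 4L)
    stop("no oscillation detected (fewer than 4 Poincare crossings)")
  intervals <- diff(cross)
  T_per <- mean(intervals)
  half <- floor(length(intervals) / 2)
  drift <- abs(mean(intervals[seq_len(half)]) -
                 mean(intervals[(half + 1):length(intervals)])) / T_per
  if (drift > drift_tol)
    stop("period estimate drifts by ", format(drift, digits = 3),
         " relative; increase t_transient")

  # record a little over one period starting at the next section crossing
  state_q <- me$q_final; state_is <- me$I_s_final; t_now <- me$t_final
  probe <- mf_core(hazard, I_ext, J_s, tau_s, dt, r, state_q, state_is,
                   ceiling(1.5 * T_per / dt), t0 = t_now)
  pc <- upward_crossings(probe$I_s, level, probe$time)
  pc <- pc[pc > t_now + dt]
  if (length(pc) == 0L) stop("no oscillation detected in the recording window")
  t_c <- pc[1L]
  n_pre <- max(floor((t_c - t_now) / dt) - 1L, 0L)
  pre <- mf_core(hazard, I_ext, J_s, tau_s, dt, r, state_q, state_is, n_pre,
                 t0 = t_now)
  M <- round(T_per / dt)
  rec <- mf_core(hazard, I_ext, J_s, tau_s, dt, r, pre$q_final, pre$I_s_final,
                 M + 4L, t0 = pre$t_final, record_q = TRUE)

  dtc <- T_per / M
  tt <- t_c + (0:(M - 1)) * dtc
  pos <- (tt - rec$time[1L]) / dt
  i0 <- pmin(floor(pos), M + 3L)
  w <- pos - i0
  qbar <- (1 - w) * rec$q[i0 + 1L, , drop = FALSE] +
    w * rec$q[i0 + 2L, , drop = FALSE]
  isbar <- (1 - w) * rec$I_s[i0 + 1L] + w * rec$I_s[i0 + 2L]

  # periodicity defect: state at t_c vs t_c + T
  posT <- (t_c + T_per - rec$time[1L]) / dt
  iT <- floor(posT); wT <- posT - iT
  qT <- (1 - wT) * rec$q[iT + 1L, ] + wT * rec$q[iT + 2L, ]
  isT <- (1 - wT) * rec$I_s[iT + 1L] + wT * rec$I_s[iT + 2L]
  s1 <- c(qbar[1L, ], isbar[1L]); s2 <- c(qT, isT)
  defect <- sqrt(sum((s1 - s2)^2) / sum(s1^2))
  if (defect > cycle_tol)
    stop("cycle periodicity defect ", format(defect, digits = 3),
         " exceeds cycle_tol; increase t_transient")
  # periodise: distribute the (small) residual gap between the two ends of
  # the stored period linearly across the samples, so the cycle wraps
  # exactly and periodic finite differences see no seam jump
  ramp <- (0:(M - 1)) / M
  qbar <- qbar + outer(ramp, qbar[1L, ] - qT)
  isbar <- isbar + ramp * (isbar[1L] - isT)

  structure(list(T = T_per, M = M, dt_cycle = dtc, dt = dt, r = r,
                 q = qbar, I_s = isbar, A = qbar[, 1L], level = level,
                 defect = defect, hazard = hazard,
                 I_ext = I_ext, J_s = J_s, tau_s = tau_s, r_max = r_max),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat("Mean-field limit cycle\n")
  cat("  period T =", format(x$T, digits = 6), "ms (", x$M, "samples of",
      format(x$dt_cycle, digits = 4), "ms )\n")
  cat("  activity range [", format(min(x$A), digits = 4), ",",
      format(max(x$A), digits = 4), "] /ms; periodicity defect",
      format(x$defect, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.limit_cycle <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  tt <- (0:(x$M - 1)) * x$dt_cycle
  graphics::plot(tt, x$I_s, type = "l", xlab = "time in cycle (ms)",
                 ylab = "I_s (mV)", ...)
  graphics::plot(tt, x$A, type = "l", xlab = "time in cycle (ms)",
                 ylab = "activity (1/ms)", ...)
  invisible(x)
}
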