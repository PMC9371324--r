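# Direct-perturbation measurement of the macroscopic PRC, on the
# deterministic mean-field and on the stochastic spiking network. These
# provide the validation surface for the adjoint result.
#
# Routes for the mean-field pulse:
#  * "synaptic": the pulse p(t) is added to the synaptic equation,
#    tau_s dIs/dt = -Is + Js A + tau_s p(t), so a charge integral(p) dt = c
#    displaces I_s by c mV. In the infinitesimal limit the phase shift per
#    unit charge converges to Z_Is itself -- this is the protocol that
#    validates the adjoint mPRC, and it mirrors how input from another
#    circuit enters (through the synaptic drive).
#  * "iext": the pulse is added to the external current (so to h directly,
#    unfiltered). The adjoint pairing shows the corresponding sensitivity is
#    Z_h(t) = Z_Is/tau_s - dZ_Is/dt, not Z_Is.

#' Phase shift of the mean-field oscillation after a square pulse
#'
#' Runs two mean-field trajectories from the same on-cycle state (the
#' Poincare anchor, phase 0), one receiving a square pulse starting at the
#' requested phase. After a settling time the asymptotic time shift is read
#' from the difference of Poincare-crossing times and converted to radians
#' via `2 pi / T`. Positive shift = phase advance (earlier crossings).
#'
#' @param cycle a [find_limit_cycle()] result.
#' @param phase stimulus onset phase in `[0, 2 pi)`.
#' @param amplitude pulse amplitude (mV for `route = "iext"`; mV/ms for
#'   `route = "synaptic"`, so `amplitude * duration` is the displacement of
#'   `I_s` in mV).
#' @param duration pulse duration (ms).
#' @param route where the pulse enters (see Details above).
#' @param n_periods total run length in periods (>= `settle_periods + 3`).
#' @param settle_periods periods to discard before reading the shift.
#' @param reference optional precomputed unperturbed run (as returned in the
#'   `reference` field), reused across phases.
#' @return list with `shift_rad`, `shift_ms`, `response` (shift per unit
#'   charge) and `reference` for reuse.
#' @export
perturb_meanfield <- function(cycle, phase, amplitude, duration,
                              route = c("synaptic", "iext"),
                              n_periods = 12L, settle_periods = 6L,
                              reference = NULL) {
  stopifnot(inherits(cycle, "limit_cycle"))
  route <- match.arg(route)
  T_per <- cycle$T
  dt <- cycle$dt
  horizon <- n_periods * T_per
  n_steps <- round(horizon / dt)
  q0 <- cycle$q[1L, ]; I0 <- cycle$I_s[1L]

  run <- function(pulse) {
    mf_core(cycle$hazard, cycle$I_ext, cycle$J_s, cycle$tau_s, dt, cycle$r,
            q0, I0, n_steps, pulse = pulse)
  }
  if (is.null(reference)) reference <- run(NULL)
  cr_ref <- upward_crossings(reference$I_s, cycle$level, reference$time)
  if (amplitude == 0)
    return(list(shift_rad = 0, shift_ms = 0, response = 0,
                reference = reference))

  pulse <- list(onset = phase / (2 * pi) * T_per, duration = duration,
                amplitude = amplitude, route = route)
  pert <- run(pulse)
  cr_p <- upward_crossings(pert$I_s, cycle$level, pert$time)
  if (length(cr_p) < settle_periods + 2L)
    stop("perturbed trajectory lost the oscillation (no late crossings)")

  late <- cr_ref[cr_ref > settle_periods * T_per]
  late <- utils::tail(late, 3L)
  shifts <- vapply(late, function(tu) {
    wrap_half(tu - cr_p[which.min(abs(cr_p - tu))], T_per)
  }, numeric(1))
  shift_ms <- mean(shifts)
  list(shift_rad = 2 * pi * shift_ms / T_per, shift_ms = shift_ms,
       response = 2 * pi * shift_ms / T_per / (amplitude * duration),
       reference = reference)
}

#' Direct mean-field PRC over a sweep of phases
#'
#' @inheritParams perturb_meanfield
#' @param n_phases number of equally spaced stimulus phases.
#' @return a `prc_curve` with `response` in radians per unit pulse charge
#'   (rad/mV for the synaptic route).
#' @export
prc_direct_meanfield <- function(cycle, n_phases = 16L, amplitude = 0.2,
                                 duration = 2, route = c("synaptic", "iext"),
                                 n_periods = 12L, settle_periods = 6L) {
  route <- match.arg(route)
  theta <- 2 * pi * (0:(n_phases - 1L)) / n_phases
  ref <- NULL
  resp <- numeric(n_phases)
  for (i in seq_along(theta)) {
    out <- perturb_meanfield(cycle, theta[i], amplitude, duration,
                             route = route, n_periods = n_periods,
                             settle_periods = settle_periods, reference = ref)
    ref <- out$reference
    resp[i] <- out$response
  }
  structure(list(theta = theta, response = resp, sem = NULL, T = cycle$T,
                 stimulus = list(amplitude = amplitude, duration = duration,
                                 shape = "square", route = route),
                 kind = "direct_meanfield"),
            class = "prc_curve")
}

#' Phase shift of the spiking-network oscillation after a square pulse
#'
#' Per trial, a perturbed and an unperturbed network are simulated with a
#' common noise seed (identical trajectories until pulse onset). The
#' oscillation phase is read from peaks of the Gaussian-smoothed population
#' activity (sd `T/20`); the pulse is timed relative to an anchor peak of
#' the unperturbed run, and the shift is the circular mean of late
#' peak-time differences. Positive = phase advance.
#'
#' @param params a [network_params()] in the oscillatory regime.
#' @param T_period the collective oscillation period (ms), e.g. from the
#'   mean-field limit cycle.
#' @param phase stimulus onset phase in `[0, 2 pi)` relative to an activity
#'   peak.
#' @param amplitude pulse amplitude on `h` (mV).
#' @param duration pulse duration (ms).
#' @param n_trials number of paired trials.
#' @param seed base seed; trial `k` uses `seed + k`.
#' @param t_anchor anchor time (ms): the pulse is applied after the first
#'   unperturbed activity peak following this time.
#' @param horizon per-trial simulated duration (ms).
#' @return list with `shift_rad` (trial mean), `sem_rad`, `shifts_rad`.
#' @export
perturb_spiking <- function(params, T_period, phase, amplitude, duration,
                            n_trials = 20L, seed = 1L, t_anchor = NULL,
                            horizon = NULL) {
  stopifnot(inherits(params, "network_params"))
  dt <- params$dt
  horizon <- horizon %||% (t_anchor %||% (20 * T_period) + 12 * T_period)
  t_anchor <- t_anchor %||% (8 * T_period)
  sg <- T_period / 20 / dt
  shifts <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    ref <- simulate_network(params, horizon, seed = seed + k)
    sa <- gauss_smooth(ref$activity, sg)
    pk <- pracma::findpeaks(sa, minpeakdistance = round(0.6 * T_period / dt),
                            minpeakheight = mean(sa))
    if (is.null(pk) || nrow(pk) < 6L)
      stop("oscillation too noisy to anchor the stimulus; increase N")
    pk_t <- sort(pk[, 2L] * dt)
    anchor <- pk_t[pk_t > t_anchor][1L]
    if (is.na(anchor)) stop("no anchor peak found; increase horizon")
    onset <- anchor + phase / (2 * pi) * T_period
    pert <- simulate_network(params, horizon, seed = seed + k,
                             perturbation = list(onset = onset,
                                                 duration = duration,
                                                 amplitude = amplitude))
    sp <- gauss_smooth(pert$activity, sg)
    pkp <- pracma::findpeaks(sp, minpeakdistance = round(0.6 * T_period / dt),
                             minpeakheight = mean(sp))
    pkp_t <- sort(pkp[, 2L] * dt)
    late_ref <- pk_t[pk_t > onset + 3 * T_period]
    late_ref <- utils::tail(late_ref, 4L)
    if (length(late_ref) < 2L) stop("horizon too short after the pulse")
    dphi <- vapply(late_ref, function(tu) {
      wrap_half(tu - pkp_t[which.min(abs(pkp_t - tu))], T_period)
    }, numeric(1))
    shifts[k] <- circ_mean(2 * pi * dphi / T_period)
  }
  list(shift_rad = mean(shifts),
       sem_rad = stats::sd(shifts) / sqrt(n_trials), shifts_rad = shifts)
}

#' Direct spiking-network PRC over a sweep of phases
#'
#' @inheritParams perturb_spiking
#' @param n_phases number of equally spaced phases.
#' @return a `prc_curve` with trial-mean `response` (rad, raw shift per
#'   pulse) and `sem`.
#' @export
prc_direct_spiking <- function(params, T_period, n_phases = 8L,
                               amplitude = 3, duration = 5, n_trials = 20L,
                               seed = 1L, horizon = NULL) {
  theta <- 2 * pi * (0:(n_phases - 1L)) / n_phases
  res <- lapply(theta, function(th)
    perturb_spiking(params, T_period, th, amplitude, duration,
                    n_trials = n_trials, seed = seed, horizon = horizon))
  structure(list(theta = theta,
                 response = vapply(res, `[[`, numeric(1), "shift_rad"),
                 sem = vapply(res, `[[`, numeric(1), "sem_rad"),
                 T = T_period,
                 stimulus = list(amplitude = amplitude, duration = duration,
                                 shape = "square", route = "h"),
                 kind = "direct_spiking"),
            class = "prc_curve")
}
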