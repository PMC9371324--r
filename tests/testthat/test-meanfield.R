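# Mean-field refractory-density solver: transport, steady state, limit cycle.

test_that("with zero hazard a density bump advects at unit speed, conserving mass", {
  hz <- hazard_model("tabulated", r = c(0, 100), S = c(0, 0))
  dt <- 0.05
  r <- (1:400) * dt   # r_max = 20
  q0 <- stats::dnorm(r, 5, 0.5); q0 <- q0 / (dt * sum(q0))
  sim <- integrate_meanfield(hz, 0, 0, 10, duration = 5, dt = dt, r_max = 20,
                             q0 = q0)
  expect_equal(max(abs(sim$mass - 1)), 0, tolerance = 1e-12)
  # the bump's centre of mass moved by exactly the elapsed time
  com <- sum(r * sim$q_final) / sum(sim$q_final)
  expect_equal(com, 5 + 5, tolerance = 1e-6)
})

test_that("constant hazard relaxes to the truncated exponential profile", {
  s <- 0.8
  hz <- hazard_model("exp_relax", T_ref = 0, tau = 0)  # S = e^h, use h = log(s)
  dt <- 0.01; r_max <- 12
  sim <- integrate_meanfield(hz, log(s), 0, 10, duration = 120, dt = dt,
                             r_max = r_max)
  r <- sim$r
  A_trunc <- s / (1 - exp(-s * r_max))    # steady state of the leaky grid
  expect_equal(sim$q_final / sim$q_final[1L], exp(-s * (r - r[1L])),
               tolerance = 1e-2)
  expect_equal(sim$activity[length(sim$activity)], A_trunc, tolerance = 1e-2)
})

test_that("steady_state solves the printed fixed point for the hard threshold", {
  hz <- hazard_model("exp_relax", T_ref = 8, tau = 0)
  st0 <- steady_state(hz, I_ext = 2, J_s = 0)
  expect_equal(st0$A_inf, 1 / (8 + exp(-2)), tolerance = 1e-10)
  expect_lt(abs(st0$residual), 1e-10)
  # with feedback: A = (T_ref + exp(-I_ext - Js A))^-1 self-consistently
  st1 <- steady_state(hz, I_ext = 2, J_s = 1)
  expect_lt(abs(st1$A_inf - 1 / (8 + exp(-st1$h_inf))), 1e-10)
  expect_equal(st1$h_inf, 2 + st1$A_inf)
  # profile invariants: q(0) = A_inf, unit mass
  expect_equal(st1$q_inf[1L], st1$A_inf)
  expect_equal(trapz_u(st1$q_inf, st1$r[2L] - st1$r[1L]), 1, tolerance = 1e-6)
})

test_that("steady_state works for every hazard preset", {
  for (nm in c("fig3", "fig4a", "fig4b", "fig4c")) {
    cfg <- make_fixture(nm)
    st <- steady_state(cfg$hazard_model, cfg$network$I_ext, cfg$network$J_s)
    expect_gt(st$A_inf, 0)
    expect_lt(abs(st$residual), 1e-10)
  }
  hg <- hazard_model("gamma_isi", alpha = 2)
  stg <- steady_state(hg, 0.5, 0)
  # mean ISI of a gamma(2, e^h): 2 e^-h
  expect_equal(stg$A_inf, exp(0.5) / 2, tolerance = 1e-8)
})

test_that("asynchronous mean-field activity time-averages to A_inf", {
  hz <- hazard_model("exp_relax", T_ref = 8, tau = 0)
  st <- steady_state(hz, 2, 1)
  sim <- integrate_meanfield(hz, 2, 1, 10, duration = 800, dt = 0.01)
  n <- length(sim$activity)
  Abar <- mean(sim$activity[(n %/% 3):n])
  expect_lt(abs(Abar - st$A_inf) / st$A_inf, 0.01)
})

test_that("find_limit_cycle detects the oscillation and satisfies its contracts", {
  cyc <- test_cycle()
  expect_gt(cyc$T, 10); expect_lt(cyc$T, 11.5)
  expect_equal(nrow(cyc$q), cyc$M)
  expect_equal(cyc$A, cyc$q[, 1L])
  expect_lt(cyc$defect, 0.02)
  # the stored period wraps exactly (periodised seam)
  expect_equal(cyc$M, round(cyc$T / cyc$dt))
  # boundary condition: q(t, 0) equals the activity up to the one-step flux
  # convention (q[n, 1] is the mass fired in the preceding step)
  expect_equal(cyc$q[-1L, 1L], cyc$A[-cyc$M], tolerance = 0.15)
})

test_that("period estimate is insensitive to doubling the measurement window", {
  hz <- hz_soft()
  T1 <- suppressWarnings(find_limit_cycle(hz, 2, 15, 10, dt = 0.05,
                                          t_transient = 1500,
                                          t_measure = 200))$T
  T2 <- suppressWarnings(find_limit_cycle(hz, 2, 15, 10, dt = 0.05,
                                          t_transient = 1500,
                                          t_measure = 400))$T
  expect_lt(abs(T1 - T2) / T1, 1e-3)
})

test_that("period converges at first order in dt", {
  hz <- hz_soft()
  Ts <- vapply(c(0.08, 0.04, 0.02), function(dt)
    suppressWarnings(find_limit_cycle(hz, 2, 15, 10, dt = dt,
                                      t_transient = 1500,
                                      t_measure = 250))$T, numeric(1))
  e1 <- abs(Ts[1L] - Ts[3L]); e2 <- abs(Ts[2L] - Ts[3L])
  expect_gt(e1 / e2, 1.5)   # halving dt at least ~halves the error
  expect_lt(e1 / e2, 4)
})

test_that("the asynchronous regime raises a no-oscillation error", {
  hz <- hz_hard()
  expect_error(
    suppressWarnings(find_limit_cycle(hz, 2, 1, 10, dt = 0.05,
                                      t_transient = 1500, t_measure = 2400)),
    "decaying|no oscillation")
})

test_that("mass stays conserved through the fig3 oscillation", {
  hz <- hz_soft()
  sim <- suppressWarnings(integrate_meanfield(hz, 2, 15, 10, duration = 500,
                                              dt = 0.05))
  # |mass - 1| equals the tracked leak; both stay small
  expect_lt(max(abs(sim$mass - 1)), 1e-3)
  expect_equal(sim$mass[length(sim$mass)] + sim$leak, 1, tolerance = 1e-12)
})

test_that("too-large dt aborts with a stability message", {
  hz <- hz_hard()   # e^h jumps to ~e^4 on the E-point volley
  expect_error(
    suppressWarnings(integrate_meanfield(hz, 2, 15, 10, duration = 1500,
                                         dt = 0.1)),
    "unstable")
})
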