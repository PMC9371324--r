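# Characteristic equation and Hopf boundary of the asynchronous state.

problem_fig2 <- function(J_s = 1) cached(paste0("prob_fig2_", J_s),
  characteristic_problem(hz_hard(), I_ext = 2, J_s = J_s, tau_s = 10))

test_that("the conservation zero mode: C(0) = 0 for both evaluators", {
  pr <- problem_fig2()
  expect_equal(Mod(characteristic_tau0(pr, 0 + 0i)), 0)
  expect_lt(Mod(characteristic_general(pr, 0 + 0i)), 1e-8)
  # also for a soft-threshold (tau > 0) problem, general form only
  prs <- characteristic_problem(hz_soft(), 2, 1, 10)
  expect_lt(Mod(characteristic_general(prs, 0 + 0i)), 1e-8)
})

test_that("kappa_hat is the synaptic filter transform with kappa_hat(0) = 1", {
  pr <- problem_fig2()
  expect_equal(pr$kappa_hat(0), 1)
  expect_equal(pr$kappa_hat(0.3 + 0.1i), 1 / (1 + (0.3 + 0.1i) * 10))
})

test_that("closed form and general quadrature agree at random complex lambda", {
  pr <- problem_fig2()
  h_inf <- pr$steady$h_inf
  set.seed(42)
  lam <- complex(real = stats::runif(20, 0, 0.5),
                 imaginary = stats::runif(20, 0.01, 2))
  cg <- characteristic_general(pr, lam)
  cc <- characteristic_tau0(pr, lam)
  # exact relation: C_tau0 = (e^{h_inf} + lambda) * C_general
  expect_lt(max(Mod(cc - (exp(h_inf) + lam) * cg)), 1e-6)
})

test_that("characteristic function has real coefficients (conjugate symmetry)", {
  pr <- problem_fig2()
  lam <- c(0.2 + 0.9i, -0.1 + 0.4i)
  expect_equal(characteristic_general(pr, Conj(lam)),
               Conj(characteristic_general(pr, lam)))
  expect_equal(characteristic_tau0(pr, Conj(lam)),
               Conj(characteristic_tau0(pr, lam)))
})

test_that("degenerate case J_s = 0, T_ref = 0 reduces to C(lambda) = lambda", {
  hz <- hazard_model("exp_relax", T_ref = 0, tau = 0)
  pr <- characteristic_problem(hz, 1, 0, 10)
  lam <- c(0.3 + 0.2i, 1 + 1i)
  expect_equal(characteristic_tau0(pr, lam), lam, tolerance = 1e-12)
})

test_that("characteristic_tau0 refuses soft-threshold hazards", {
  pr <- characteristic_problem(hz_soft(), 2, 1, 10)
  expect_error(characteristic_tau0(pr, 0.1 + 0.1i), "tau = 0")
})

test_that("roots come in conjugate pairs and classify the fig2 regimes", {
  rD <- rightmost_eigenvalue(problem_fig2(1))
  rE <- rightmost_eigenvalue(problem_fig2(15))
  expect_false(rD$oscillatory)
  expect_true(rE$oscillatory)
  # every root satisfies C = 0 at its conjugate too
  pr <- problem_fig2(15)
  for (rt in rE$roots[seq_len(min(3, length(rE$roots)))])
    expect_lt(Mod(characteristic_tau0(pr, Conj(rt))), 1e-6)
})

test_that("the Hopf boundary decreases with I_ext and pins the fig2 points", {
  hb <- cached("hopf_fig2",
               hopf_boundary(hz_hard(), tau_s = 10,
                             I_ext = seq(0.5, 3, by = 0.25)))
  expect_true(all(!is.na(hb$J_s)))
  expect_true(all(diff(hb$J_s) < 0))          # monotone in I_ext
  expect_true(all(hb$omega > 0))
  # the boundary verifies C(i omega) = 0 self-consistently
  i2 <- which(hb$I_ext == 2)
  prb <- characteristic_problem(hz_hard(), 2, hb$J_s[i2], 10)
  expect_lt(Mod(characteristic_tau0(prb, 1i * hb$omega[i2])), 1e-6)
  # asynchronous point below, oscillatory point above
  expect_gt(hb$J_s[i2], 1)
  expect_lt(hb$J_s[i2], 15)
})

test_that("Hopf frequency matches the nascent limit-cycle frequency near onset", {
  hb <- cached("hopf_fig2",
               hopf_boundary(hz_hard(), tau_s = 10,
                             I_ext = seq(0.5, 3, by = 0.25)))
  i2 <- which(hb$I_ext == 2)
  Jb <- hb$J_s[i2]
  # just inside the unstable region
  cyc <- suppressWarnings(find_limit_cycle(hz_hard(), 2, Jb * 1.1, 10,
                                           dt = 0.01, t_transient = 2500,
                                           t_measure = 400))
  expect_lt(abs(2 * pi / cyc$T - hb$omega[i2]) / hb$omega[i2], 0.10)
})

test_that("root-sign classification agrees with oscillation detection across the boundary", {
  # parameter grid straddling the fig2-style boundary
  hz <- hz_hard()
  for (I_ext in c(1, 1.5, 2, 2.5, 3)) {
    pr_b <- cached("hopf_fig2",
                   hopf_boundary(hz, tau_s = 10,
                                 I_ext = seq(0.5, 3, by = 0.25)))
    Jb <- stats::approx(pr_b$I_ext, pr_b$J_s, I_ext)$y
    for (J_s in c(0.4 * Jb, 2.5 * Jb)) {
      rm_ <- rightmost_eigenvalue(characteristic_problem(hz, I_ext, J_s, 10))
      verdict_roots <- rm_$oscillatory
      # resolving decay (or its absence) needs to integrate for a fair
      # fraction of the predicted decay/growth time of the rightmost mode
      w <- min(12000, max(600, 0.6 / abs(Re(rm_$rightmost))))
      verdict_sim <- tryCatch({
        suppressWarnings(find_limit_cycle(hz, I_ext, J_s, 10, dt = 0.01,
                                          t_transient = 1500,
                                          t_measure = w))
        TRUE
      }, error = function(e) FALSE)
      expect_identical(verdict_roots, verdict_sim,
                       label = sprintf("I_ext=%g J_s=%g roots=%s", I_ext,
                                       J_s, verdict_roots))
    }
  }
})
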