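# Shared, lazily computed objects. Expensive pipeline stages (limit cycle,
# adjoint) are computed once per test run at a moderate grid (dt = 0.02) and
# reused across test files; the acceptance tests build their own
# finer-resolution objects.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

hz_soft <- function() hazard_model("exp_relax", T_ref = 10, tau = 5)
hz_hard <- function() hazard_model("exp_relax", T_ref = 8, tau = 0)

# oscillatory benchmark cycle at a coarse grid (fast, ~1 s)
test_cycle <- function() cached("cycle_dt02", suppressWarnings(
  find_limit_cycle(hz_soft(), I_ext = 2, J_s = 15, tau_s = 10, dt = 0.02,
                   t_transient = 1500, t_measure = 300)))

test_adjoint <- function() cached("adjoint_dt02", {
  cyc <- test_cycle()
  normalize_adjoint(solve_adjoint(cyc), cyc)
})

# gamma-family ISI density helper (analytic gamma density with rate e^h)
gamma_isi_fun <- function(alpha) {
  function(h, r) stats::dgamma(r, shape = alpha, rate = exp(h))
}

# fine-resolution benchmark pipeline (dt = 0.005) for the acceptance checks
fine_cycle <- function() cached("cycle_dt005", suppressWarnings(
  find_limit_cycle(hz_soft(), I_ext = 2, J_s = 15, tau_s = 10, dt = 0.005,
                   t_transient = 3000, t_measure = 300)))

fine_adjoint <- function() cached("adjoint_dt005", {
  cyc <- fine_cycle()
  normalize_adjoint(solve_adjoint(cyc), cyc)
})

# circular distance on a ring of circumference T
circ_dist <- function(a, b, T_per) {
  d <- abs(a - b) %% T_per
  pmin(d, T_per - d)
}
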