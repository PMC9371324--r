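# Hazard models and the hazard <-> ISI duality.

test_that("hazard presets evaluate the printed closed forms", {
  hz <- hazard_model("exp_relax", T_ref = 10, tau = 5)
  expect_equal(hz$S(0, 15), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(hz$S(2, 8), 0)            # refractory
  expect_equal(hz$S(2, 10), 0)           # H(0) = 1 but relaxation factor = 0
  # tau = 0 degenerates to the hard threshold with H(0) = 1
  hz0 <- hazard_model("exp_relax", T_ref = 10, tau = 0)
  expect_equal(hz0$S(0.5, 10), exp(0.5))
  expect_equal(hz0$S(0.5, 9.999), 0)
  # no refractoriness, tau -> 0: S = exp(h)
  hzp <- hazard_model("exp_relax", T_ref = 0, tau = 0)
  expect_equal(hzp$S(0, 3.7), 1)
  # ramp form
  hr <- hazard_model("ramp", T_ref = 6, eps = 3)
  expect_equal(hr$S(1, 8), exp(1) * 3 * 2)
  # gamma hazard, alpha = 2, h = 0: S(r) = r / (1 + r)
  hg <- hazard_model("gamma_isi", alpha = 2)
  r <- c(0.5, 1, 2, 5)
  expect_equal(hg$S(0, r), r / (1 + r), tolerance = 1e-10)
  expect_error(hazard_model("exp_relax", T_ref = -1), "T_ref")
  expect_error(hazard_model("exp_relax", T_ref = 1, tau = -2), "tau")
})

test_that("hazards are nonnegative, refractory and increasing in h", {
  presets <- list(
    hazard_model("exp_relax", T_ref = 10, tau = 5),
    hazard_model("exp_relax", T_ref = 8, tau = 0),
    hazard_model("ramp", T_ref = 6, eps = 3),
    hazard_model("tanh", T_ref = 5),
    hazard_model("tanh_cos", T_ref = 10, eps = 3, omega = 1))
  r <- seq(0, 20, by = 0.05)
  for (hz in presets) {
    for (h in c(0, 1, 2.5)) {
      S <- hz$S(h, r)
      expect_true(all(S >= 0))
      expect_true(all(S[r < hz$T_ref] == 0))
      expect_true(all(hz$S(h + 0.5, r) >= S))
    }
  }
})

test_that("dS_dh equals S for exp(h)-prefactor forms and follows the chain rule for tanh", {
  for (hz in list(hazard_model("exp_relax", T_ref = 10, tau = 5),
                  hazard_model("ramp", T_ref = 6, eps = 3))) {
    r <- seq(0, 15, by = 0.1)
    expect_equal(hz$dS_dh(1.3, r), hz$S(1.3, r))
  }
  # tanh forms: verify against a central difference
  for (hz in list(hazard_model("tanh", T_ref = 5),
                  hazard_model("tanh_cos", T_ref = 10, eps = 3, omega = 1),
                  hazard_model("gamma_isi", alpha = 2))) {
    r <- seq(0.1, 12, by = 0.37)
    h <- 1.1; d <- 1e-5
    fd <- (hz$S(h + d, r) - hz$S(h - d, r)) / (2 * d)
    expect_equal(hz$dS_dh(h, r), fd, tolerance = 1e-6)
  }
})

test_that("analytic cumulative hazards match numerical integration", {
  r <- seq(0, 14, by = 0.001)
  for (hz in list(hazard_model("exp_relax", T_ref = 10, tau = 5),
                  hazard_model("exp_relax", T_ref = 8, tau = 0),
                  hazard_model("ramp", T_ref = 6, eps = 3),
                  hazard_model("tanh", T_ref = 5),
                  hazard_model("gamma_isi", alpha = 2))) {
    ch_num <- cumtrapz_u(hz$S(1.5, r), 0.001)
    expect_equal(hz$cumhaz(1.5, r), ch_num, tolerance = 2e-4)
  }
})

test_that("hazard_to_isi reproduces closed-form ISI densities", {
  # constant hazard s: exponential density s e^{-s r}
  hzp <- hazard_model("exp_relax", T_ref = 0, tau = 0)
  r <- seq(0, 10, by = 0.01)
  isi <- hazard_to_isi(hzp, h = log(2), r)   # s = 2
  expect_equal(isi$density, 2 * exp(-2 * r), tolerance = 1e-4)
  # gamma alpha = 1 is the exponential with rate e^h
  hg1 <- hazard_model("gamma_isi", alpha = 1)
  isi1 <- hazard_to_isi(hg1, h = 0, r)
  expect_equal(isi1$density, exp(-r), tolerance = 1e-4)
  # integral identity: integral of ISI = 1 - exp(-total cumulated hazard)
  hz <- hazard_model("exp_relax", T_ref = 10, tau = 5)
  rg <- seq(0, 14, by = 0.002)
  isi3 <- hazard_to_isi(hz, h = 2, rg)
  ch <- cumtrapz_u(hz$S(2, rg), 0.002)
  expect_equal(trapz_u(isi3$density, 0.002), 1 - exp(-ch[length(ch)]),
               tolerance = 1e-6)
})

test_that("fig4-style ISI densities vanish below T_ref and have one interior mode", {
  cfg <- make_fixture("fig4a")
  rg <- seq(0, 12, by = 0.01)
  isi <- hazard_to_isi(cfg$hazard_model, h = cfg$network$I_ext, rg)
  expect_true(all(isi$density[rg < 6] == 0))
  i_max <- which.max(isi$density)
  expect_gt(rg[i_max], 6)      # interior mode above the refractory time
  expect_lt(rg[i_max], 10)
  expect_lt(isi$density[length(rg)], max(isi$density) * 1e-3) # decayed tail
})

test_that("isi_to_hazard inverts hazard_to_isi and handles the survivor floor", {
  # exponential: recover the constant hazard (quadrature error in the
  # survivor quotient grows as 1/survivor, so compare where it is benign)
  r <- seq(0, 8, by = 0.001)
  isi <- structure(list(r = r, density = 1.7 * exp(-1.7 * r), h = 0),
                   class = "isi_density")
  tab <- isi_to_hazard(isi)
  keep <- r < 4
  expect_equal(tab$S(0, r[keep]), rep(1.7, sum(keep)), tolerance = 1e-3)
  # gamma alpha = 2: S(r) = r/(1+r)
  isig <- structure(list(r = r, density = stats::dgamma(r, 2, 1), h = 0),
                    class = "isi_density")
  tabg <- isi_to_hazard(isig)
  expect_equal(tabg$S(0, r[keep]), (r / (1 + r))[keep], tolerance = 1e-3)
  # round trip on a smooth refractory hazard: pointwise recovery to 1e-5
  # wherever the survivor exceeds 1e-4 (needs a fine grid: the error is the
  # cumulative-quadrature error amplified by 1/survivor)
  hz <- hazard_model("exp_relax", T_ref = 2, tau = 1)
  rg <- seq(0, 8, by = 2e-5)
  isi2 <- hazard_to_isi(hz, h = 1, rg)
  tab2 <- isi_to_hazard(isi2)
  surv <- 1 - cumtrapz_u(isi2$density, 2e-5)
  keep2 <- surv > 1e-4
  expect_lt(max(abs(tab2$S(0, rg[keep2]) - hz$S(1, rg[keep2]))), 1e-5)
  # survivor floor: truncation age is reported and the tail is held flat
  rl <- seq(0, 30, by = 0.01)
  isil <- structure(list(r = rl, density = 2 * exp(-2 * rl), h = 0),
                    class = "isi_density")
  tabl <- isi_to_hazard(isil, floor = 1e-6)
  expect_false(is.na(attr(tabl, "truncation_age")))
  expect_equal(tabl$S(0, 29), tabl$S(0, attr(tabl, "truncation_age")),
               tolerance = 1e-10)
  expect_error(isi_to_hazard(structure(list(r = r, density = rep(1, length(r)),
                                            h = 0), class = "isi_density")),
               "more than 1")
})

test_that("dS_dh_from_isi matches the analytic derivative for the gamma family", {
  rg <- seq(0, 6, by = 0.002)
  hg <- hazard_model("gamma_isi", alpha = 2)
  ok <- rg <= 4   # tail quotient degrades as the survivor shrinks
  # central-difference route through the quotient formula; spot value at r=1
  fd <- dS_dh_from_isi(gamma_isi_fun(2), h = 0, rg)
  expect_equal(fd[ok], hg$dS_dh(0, rg)[ok], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_lt(abs(fd[rg == 1] - hg$dS_dh(0, 1)), 1e-4)
  # analytic d(ISI)/dh route: dISI/dh = ISI * (alpha - r e^h)
  an <- dS_dh_from_isi(gamma_isi_fun(2), h = 0, rg,
                       d_isi_dh = function(h, r)
                         stats::dgamma(r, 2, exp(h)) * (2 - r * exp(h)))
  expect_equal(an[ok], hg$dS_dh(0, rg)[ok], tolerance = 1e-4,
               ignore_attr = TRUE)
  # zero-density region (below a refractory time) gives derivative 0
  hz <- hazard_model("exp_relax", T_ref = 2, tau = 1)
  isif <- function(h, r) hazard_to_isi(hz, h, r)$density
  dd <- dS_dh_from_isi(isif, h = 1, seq(0, 6, by = 0.002))
  expect_true(all(dd[seq(0, 6, by = 0.002) < 2] == 0))
})

test_that("ISI densities round trip through CSV", {
  hz <- hazard_model("exp_relax", T_ref = 2, tau = 1)
  isi <- hazard_to_isi(hz, 1, seq(0, 8, by = 0.01))
  path <- tempfile(fileext = ".csv")
  write_isi_csv(isi, path)
  back <- read_isi_csv(path)
  expect_equal(back$r, isi$r)
  expect_equal(back$density, isi$density)
})
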