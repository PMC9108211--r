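consts <- physical_constants()

test_that("GHK current vanishes at the Nernst potential and is monotone in V", {
  Ca_i <- 0.05; Ca_e <- 1500
  ## independent Nernst evaluation with Table-style constants
  Vn <- 1e3 * 8.314 * 300 / (2 * 9.648e4) * log(Ca_e / Ca_i)
  expect_equal(Vn, 133.25, tolerance = 1e-3)
  expect_equal(nernst_potential(Ca_i, Ca_e), Vn)
  expect_lt(abs(ghk_flux(Vn, Ca_i, Ca_e)), 1e-30)
  ## inward (negative) below the reversal, outward above
  expect_lt(ghk_flux(Vn - 20, Ca_i, Ca_e), 0)
  expect_gt(ghk_flux(Vn + 20, Ca_i, Ca_e), 0)
  V <- seq(-120, 250, by = 1)
  expect_true(all(diff(ghk_flux(V, Ca_i, Ca_e)) > 0))
})

test_that("GHK series branch matches the analytic V -> 0 limit", {
  ch <- channel_params()
  lim <- consts$z * consts$F_faraday * ch$p_x * (0.05 - 1500) / 1e21
  expect_equal(ghk_flux(0, 0.05, 1500, ch), lim)
  ## continuity across the branch switch
  expect_equal(ghk_flux(1e-6, 0.05, 1500, ch),
               ghk_flux(2e-5, 0.05, 1500, ch), tolerance = 1e-4)
})

test_that("gating curves have the sigmoid midpoint, saturation and tau floor", {
  g <- gate_params(V_half = -21, z_g = 3.4, gamma = 0.8, alpha0 = 800,
                   tau0 = 2e-3)
  expect_equal(gating_curves(-21, g)$x_inf, 0.5)
  expect_gt(gating_curves(150, g)$x_inf, 0.999)
  expect_lt(gating_curves(-150, g)$x_inf, 1e-3)
  V <- seq(-150, 150, by = 5)
  gc <- gating_curves(V, g)
  expect_true(all(gc$x_inf > 0 & gc$x_inf < 1))
  expect_true(all(gc$tau >= g$tau0))
  ## inactivation gate: falling sigmoid
  h <- gate_params(V_half = -40, z_g = -2, gamma = 0.5, alpha0 = 40,
                   tau0 = 75e-3)
  expect_true(all(diff(gating_curves(V, h)$x_inf) < 0))
})

test_that("exponential gating update has the exact closed-form behavior", {
  ch <- channel_params()
  st <- gating_state(ch, -70)
  expect_identical(step_gating(st, -70, 0, ch), st)
  ## relaxation limit
  far <- step_gating(st, 10, 5, ch)
  gc_m <- gating_curves(10, ch$gates$m)
  expect_equal(unname(far["m"]), gc_m$x_inf, tolerance = 1e-9)
  ## one time constant from 0 toward x_inf covers 1 - exp(-1)
  gc <- gating_curves(0, ch$gates$m)
  x0 <- c(m = 0, h = 0.5)
  x1 <- step_gating(x0, 0, gc$tau, ch)
  expect_equal(unname(x1["m"]), gc$x_inf * (1 - exp(-1)), tolerance = 1e-12)
})

test_that("exponential gating equals a high-accuracy ODE solve under piecewise-constant V", {
  skip_if_not_installed("deSolve")
  ch <- channel_params()
  segs <- data.frame(V = c(-70, 15, -30, -70), dur = c(1e-3, 8e-4, 5e-4, 2e-3))
  x <- gating_state(ch, -70)
  for (s in seq_len(nrow(segs)))
    x <- step_gating(x, segs$V[s], segs$dur[s], ch)
  ode_one <- function(gate, x0) {
    for (s in seq_len(nrow(segs))) {
      gc <- gating_curves(segs$V[s], gate)
      sol <- deSolve::lsoda(
        c(x = unname(x0)), c(0, segs$dur[s]),
        function(t, y, p) list((gc$x_inf - y) / gc$tau),
        rtol = 1e-12, atol = 1e-14)
      x0 <- sol[nrow(sol), 2]
    }
    unname(x0)
  }
  expect_equal(unname(x["m"]),
               ode_one(ch$gates$m, gating_state(ch, -70)[["m"]]),
               tolerance = 1e-8)
  expect_equal(unname(x["h"]),
               ode_one(ch$gates$h, gating_state(ch, -70)[["h"]]),
               tolerance = 1e-8)
})

test_that("gated current is the gating power law times the GHK flux", {
  ch <- channel_params(a = 2, b = 1)
  raw <- ghk_flux(-30, 0.05, 1500, ch)
  expect_equal(vgcc_current(-30, c(m = 1, h = 1), 0.05, 1500, ch), raw)
  expect_identical(vgcc_current(-30, c(m = 0, h = 1), 0.05, 1500, ch), 0)
  expect_equal(vgcc_current(-30, c(m = 0.5, h = 1), 0.05, 1500, ch),
               0.25 * raw)
})

test_that("pump fluxes follow Hill kinetics with saturation", {
  pp <- pump_params()
  expect_equal(pmca_flux(0.06, pp), 4e-24)      # half-saturation
  expect_identical(pmca_flux(0, pp), 0)
  expect_equal(pmca_flux(0.12, pp), 0.8 * 8e-24) # direct Hill evaluation
  expect_equal(ncx_flux(1.8, pp), 1.25e-21)
  expect_identical(ncx_flux(0, pp), 0)
  expect_equal(ncx_flux(1e6, pp), 2.5e-21, tolerance = 1e-5)
  ca <- seq(0, 10, by = 0.05)
  expect_true(all(diff(pmca_flux(ca, pp)) >= 0))
  expect_true(all(diff(ncx_flux(ca, pp)) >= 0))
  expect_true(all(pmca_flux(ca, pp) <= pp$I_p))
  expect_true(all(ncx_flux(ca, pp) <= pp$I_x))
})

test_that("a pump turnover of 8e-24 mol/s is 8e-3 uM*um^3/s", {
  ## unit conversion check via the composite flux: one PMCA per um^2,
  ## saturated, no channels, no NCX, no leak
  kin <- kinetic_params()
  pp <- pump_params(rho_pmca = 1, rho_ncx = 0)
  st <- c(m = 0, h = 0)
  f <- total_membrane_flux(-70, st, 1e6, kin, channel_params(), pp,
                           rho_vgcc = 0)
  expect_equal(f, -8e-3, tolerance = 1e-6)
})

test_that("membrane flux is linear in the channel density", {
  kin <- kinetic_params()
  ch <- channel_params()
  pp <- pump_params(rho_pmca = 0, rho_ncx = 0)
  st <- gating_state(ch, -20)
  f1 <- total_membrane_flux(-20, st, 0.05, kin, ch, pp, rho_vgcc = 100)
  f2 <- total_membrane_flux(-20, st, 0.05, kin, ch, pp, rho_vgcc = 200)
  expect_equal(f2, 2 * f1)
})

test_that("leak calibration zeroes the resting flux exactly", {
  kin <- kinetic_params()
  ch <- channel_params()
  pp <- calibrate_leak(kin, ch, pump_params(), rho_vgcc = 2297.1,
                       V_rest = -70)
  st <- gating_state(ch, -70)
  expect_equal(total_membrane_flux(-70, st, kin$Ca_V0, kin, ch, pp,
                                   2297.1), 0, tolerance = 1e-12)
  ## nothing to balance without pumps and channels
  pp0 <- calibrate_leak(kin, ch, pump_params(rho_pmca = 0, rho_ncx = 0),
                        rho_vgcc = 0, V_rest = -70)
  expect_equal(pp0$leak_flux, 0)
})

test_that("calibrated leak equals the brute-force sum of the resting terms", {
  kin <- kinetic_params()
  ch <- channel_params()
  rho <- 2297.1
  pp <- calibrate_leak(kin, ch,
                       pump_params(rho_pmca = 75000, rho_ncx = 2500),
                       rho_vgcc = rho, V_rest = -70)
  ## independent summation of the composite flux terms at rest
  st <- gating_state(ch, -70)
  G <- unname(st["m"]^2 * st["h"])
  vgcc_in <- rho * G * (-ghk_flux(-70, kin$Ca_V0, kin$Ca_e, ch)) /
    (2 * 9.648e4) * 1e21
  pmca <- 75000 * 8e-24 * kin$Ca_V0^2 / (0.06^2 + kin$Ca_V0^2) * 1e21
  ncx <- 2500 * 2.5e-21 * kin$Ca_V0 / (1.8 + kin$Ca_V0) * 1e21
  expect_equal(pp$leak_flux, pmca + ncx - vgcc_in, tolerance = 1e-10)
})

test_that("NCX denominator exponent is configurable", {
  pp_alt <- pump_params(n_x = 1, n_x_den = 2)
  expect_equal(ncx_flux(1.8, pp_alt),
               2.5e-21 * 1.8 / (1.8^2 + 1.8^2))
})

test_that("action-potential trains are periodic, continuous and rest between spikes", {
  tr <- ap_train(frequency = 40, duration = 0.1)
  expect_equal(ap_voltage(0, tr), tr$V_rest)
  ## rest between spikes
  expect_equal(ap_voltage(0.02, tr), -70)
  expect_equal(ap_voltage(tr$support + 1e-9, tr), -70)
  ## periodicity: second spike repeats the first
  s <- seq(0, 6e-3, by = 1e-5)
  expect_equal(ap_voltage(s, tr), ap_voltage(s + 1 / 40, tr),
               tolerance = 1e-9)
  ## peaks at V_peak
  expect_equal(max(ap_voltage(seq(0, 8e-3, by = 1e-6), tr)), tr$V_peak,
               tolerance = 1e-5)
  ## continuous at the end of the support
  expect_lt(abs(ap_voltage(tr$support - 1e-9, tr) - tr$V_rest), 1e-3)
  ## 100 Hz and 20 Hz onset alignment: fifth 100 Hz spike starts with
  ## the second half of the 20 Hz train (40 ms vs 50 ms onsets)
  t100 <- ap_train(frequency = 100, duration = 0.1)
  expect_equal(ap_voltage(0.04 + s, t100), ap_voltage(s, t100),
               tolerance = 1e-9)
})

test_that("a measured CSV waveform overrides the analytic spike template", {
  tt <- seq(0, 5e-3, by = 1e-4)
  wf <- data.frame(time = tt,
                   voltage = -70 + 85 * sin(pi * tt / 5e-3)^2)
  path <- file.path(tempdir(), "waveform.csv")
  utils::write.csv(wf, path, row.names = FALSE)
  tr <- ap_train(frequency = 40, duration = 0.05, waveform = path)
  expect_equal(tr$support, 5e-3)
  ## interpolates the measured template within the support
  expect_equal(ap_voltage(2.5e-3, tr), -70 + 85, tolerance = 1e-6)
  expect_equal(ap_voltage(1.25e-3 + 1 / 40, tr), -70 + 85 / 2,
               tolerance = 1e-3)
  ## rest outside the support
  expect_equal(ap_voltage(6e-3, tr), -70)
})
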