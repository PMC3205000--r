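test_that("sigmoid steady-state curve: midpoint, closed form, sign convention", {
  expect_equal(sigmoid_inf(-40, mu = -40, s = 5), 0.5)
  # frozen closed-form values: 1/(1 + exp(-1)) and its mirror
  expect_equal(sigmoid_inf(-35, mu = -40, s = 5), 0.7310585786300049,
               tolerance = 1e-12)
  expect_equal(sigmoid_inf(-35, mu = -40, s = -5), 0.2689414213699951,
               tolerance = 1e-12)
  expect_equal(sigmoid_inf(-35, mu = -40, s = -5),
               1 - sigmoid_inf(-35, mu = -40, s = 5))
  # symmetry about the midpoint
  d <- seq(-30, 30, by = 2.5)
  expect_equal(sigmoid_inf(-50 + d, -50, 7) + sigmoid_inf(-50 - d, -50, 7),
               rep(1, length(d)))
  # monotonic, direction set by the slope sign
  V <- seq(-90, 10, by = 1)
  expect_true(all(diff(sigmoid_inf(V, -40, 9)) > 0))
  expect_true(all(diff(sigmoid_inf(V, -60, -7)) < 0))
  expect_error(sigmoid_inf(-40, -40, 0), "nonzero")
  expect_error(sigmoid_inf(Inf, -40, 5), "finite")
})

test_that("gating update: fixed point, hand-computed step, clamping", {
  expect_equal(gating_step(0.3, x_inf = 0.3, tau = 5, dt = 0.1), 0.3)
  expect_equal(gating_step(0, x_inf = 1, tau = 10, dt = 0.1), 0.01)
  # overshoot when dt > tau is clamped, not extrapolated to -1
  expect_equal(gating_step(1, x_inf = 0, tau = 0.05, dt = 0.1), 0)
  expect_error(gating_step(0.5, 0.5, tau = -1, dt = 0.1), "tau")
  expect_error(gating_step(0.5, 0.5, tau = 1, dt = 0), "dt")
  expect_error(gating_step(1.2, 0.5, tau = 1, dt = 0.1), "\\[0, 1\\]")
})

test_that("implicit voltage update matches the closed form and is convex", {
  p <- hh_parameters()
  # no conductances at all: voltage cannot move
  p0 <- hh_parameters(gNa_max = 0, gK_max = 0, gL = 0)
  expect_equal(voltage_step(-12.3, 0, 0, 0, p0, dt = 0.1), -12.3)
  expect_equal(voltage_step(-12.3, 0, 0, 0, p0, dt = 50), -12.3)
  # leak only, enormous step: lands on the leak reversal
  expect_equal(voltage_step(-65, 0, 0, 0, p, dt = 1e12), p$E_L,
               tolerance = 1e-9)
  # frozen hand evaluation: (C_m*V/dt + gL*E_L + I) / (C_m/dt + gL)
  expect_equal(voltage_step(-65, 0, 0, 10, p, dt = 0.1),
               -63.72038834951456, tolerance = 1e-12)
  # convex combination: output between V and the shifted reversal potential
  for (dt in c(0.01, 0.1, 1, 10, 100)) {
    out <- voltage_step(-65, gNa = 30, gK = 10, I = 0, p, dt = dt)
    expect_gte(out, min(p$E_Na, p$E_K, p$E_L, -65))
    expect_lte(out, max(p$E_Na, p$E_K, p$E_L, -65))
  }
  expect_error(voltage_step(-65, 1, 1, 0, p, dt = 0), "dt")
  expect_error(voltage_step(-65, -1, 0, 0, p, dt = 0.1), ">= 0")
})

test_that("passive membrane follows the closed-form RC step response", {
  p <- hh_parameters(gNa_max = 0, gK_max = 0)
  proto <- stimulus_protocol()
  rc <- function(t) {
    V <- rep(p$E_L, length(t))
    on <- t >= proto$t_on & t < proto$t_off
    V[on] <- p$E_L + proto$I_amp / p$gL *
      (1 - exp(-(t[on] - proto$t_on) * p$gL / p$C_m))
    V_off <- p$E_L + proto$I_amp / p$gL *
      (1 - exp(-(proto$t_off - proto$t_on) * p$gL / p$C_m))
    off <- t >= proto$t_off
    V[off] <- p$E_L + (V_off - p$E_L) * exp(-(t[off] - proto$t_off) * p$gL / p$C_m)
    V
  }
  err <- function(dt) {
    pr <- proto; pr$dt <- dt
    tr <- hh_simulate(p, pr, V0 = p$E_L)
    max(abs(tr$V - rc(tr$t)))
  }
  # relaxes monotonically toward E_L + I/gL during the stimulus
  tr <- hh_simulate(p, proto, V0 = p$E_L)
  on <- tr$t >= proto$t_on & tr$t < proto$t_off
  expect_true(all(diff(tr$V[on]) >= 0))  # monotone rise, saturating at plateau
  expect_lt(max(tr$V[on]), p$E_L + proto$I_amp / p$gL + 1e-9)
  # within 1% of the plateau excursion after one step halving
  excursion <- proto$I_amp / p$gL
  expect_lt(err(0.05), 0.01 * excursion)
  # and halving dt roughly halves the first-order error
  expect_lt(err(0.05), 0.75 * err(0.1))
})

test_that("a conductance-free resting model is a fixed point of the integrator", {
  p <- hh_parameters(gNa_max = 0, gK_max = 0)
  proto <- stimulus_protocol(I_amp = 0)
  tr <- hh_simulate(p, proto, V0 = p$E_L)
  expect_equal(tr$V, rep(p$E_L, length(tr$t)))
  expect_length(detect_spikes(tr), 0)
  expect_equal(length(tr$t), floor(proto$duration / proto$dt) + 1)
  expect_equal(tr$t[1], 0)
  expect_true(all(diff(tr$t) > 0))
})

test_that("spike detection reports upward threshold crossings at the sample", {
  p <- hh_parameters(gNa_max = 0, gK_max = 0)
  proto <- stimulus_protocol(duration = 10, I_amp = 0, t_on = 0, t_off = 0)
  tr <- hh_simulate(p, proto, V0 = p$E_L)
  expect_identical(detect_spikes(tr), numeric(0))
  # synthetic triangle wave crossing 0 mV upward exactly twice
  tri <- tr
  tri$t <- 0:9
  tri$V <- c(-10, -5, 5, 10, 5, -5, -10, 5, 10, -5)
  expect_equal(detect_spikes(tri), c(2, 7))
  expect_equal(detect_spikes(tri, threshold = 6), c(3, 8))
})

test_that("gating variables stay in [0,1] without clamping when dt <= min(tau)", {
  set.seed(42)
  for (k in 1:12) {
    p <- hh_parameters(
      tau_m = runif(1, 0.2, 2), tau_h = runif(1, 1, 20),
      tau_n = runif(1, 1, 20),
      mu_m = runif(1, -60, -20), mu_h = runif(1, -80, -40),
      mu_n = runif(1, -70, -30),
      s_m = runif(1, 2, 15), s_h = -runif(1, 2, 15), s_n = runif(1, 2, 15),
      gNa_max = runif(1, 0, 200), gK_max = runif(1, 0, 80))
    proto <- stimulus_protocol(dt = min(p$tau_m, p$tau_h, p$tau_n, 0.1),
                               duration = 80, t_on = 20, t_off = 70,
                               I_amp = runif(1, 0, 20))
    tr <- hh_simulate(p, proto)
    expect_identical(tr$clamp_hits, 0L)
    expect_true(all(tr$m >= 0 & tr$m <= 1))
    expect_true(all(tr$h >= 0 & tr$h <= 1))
    expect_true(all(tr$n >= 0 & tr$n <= 1))
  }
  # dt beyond a time constant engages the clamp but must not crash
  p <- hh_parameters(tau_m = 0.05)
  tr <- hh_simulate(p, stimulus_protocol(dt = 0.1))
  expect_gt(tr$clamp_hits, 0)
  expect_true(all(tr$m >= 0 & tr$m <= 1))
})

test_that("without stimulus the voltage stays between the reversal potentials", {
  p <- hh_parameters()
  lo <- min(p$E_Na, p$E_K, p$E_L); hi <- max(p$E_Na, p$E_K, p$E_L)
  for (V0 in c(-76, -65, -20, 40)) {
    tr <- hh_simulate(p, stimulus_protocol(I_amp = 0, duration = 100,
                                           t_on = 0, t_off = 0), V0 = V0)
    expect_true(all(tr$V >= lo & tr$V <= hi))
  }
})

test_that("fixed-step solution converges under step halving", {
  p <- hh_parameters(gNa_max = 25)  # subthreshold: smooth trajectory
  errs <- sapply(c(0.1, 0.05, 0.025), function(dt) {
    pr <- stimulus_protocol(dt = dt, duration = 150, t_off = 140)
    pr2 <- stimulus_protocol(dt = dt / 2, duration = 150, t_off = 140)
    a <- hh_simulate(p, pr); b <- hh_simulate(p, pr2)
    idx <- seq(1, length(b$t), by = 2)
    max(abs(a$V - b$V[idx]))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("implicit voltage update survives a 10 ms step where explicit blows up", {
  p <- hh_parameters()  # stiff: gNa_max * dt / C_m >> 1
  proto <- stimulus_protocol(dt = 10)
  tr <- hh_simulate(p, proto, voltage_method = "implicit")
  expect_true(all(is.finite(tr$V)))
  expect_true(all(tr$V >= min(p$E_Na, p$E_K, p$E_L) &
                  tr$V <= max(p$E_Na, p$E_K, p$E_L)))
  diverged <- tryCatch({
    tr2 <- hh_simulate(p, proto, voltage_method = "explicit")
    max(abs(tr2$V)) > 1e6
  }, hhtune_nonfinite = function(e) TRUE)
  expect_true(diverged)
})

test_that("simulation is deterministic: identical inputs, bit-identical traces", {
  p <- hh_parameters()
  proto <- stimulus_protocol()
  a <- hh_simulate(p, proto)
  b <- hh_simulate(p, proto)
  expect_identical(a$V, b$V)
  expect_identical(a$m, b$m)
  expect_identical(a$spike_times, b$spike_times)
})

test_that("fixed-step trace tracks the adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  # subthreshold ringing: whole 50 ms post-onset window within 0.5 mV
  pre <- hh_preset("subthreshold_oscillations")
  proto <- pre$protocol
  proto$dt <- 0.001; proto$duration <- 100; proto$t_off <- 100
  tr <- hh_simulate(pre$parameters, proto)
  sol <- oracle_solve(pre$parameters, proto, V0 = tr$V0, out_dt = 0.1)
  grid <- seq(0, 100, by = 0.1)
  Vt <- tr$V[match(round(grid, 6), round(tr$t, 6))]
  Vo <- sol$V[match(round(grid, 6), round(sol$time, 6))]
  expect_true(all(is.finite(Vt)) && all(is.finite(Vo)))
  expect_lt(max(abs(Vt - Vo)), 0.5)

  # spiking regime: spike times within 1 ms of the oracle's
  reg <- hh_preset("regular_spiking")
  proto <- reg$protocol
  proto$dt <- 0.001; proto$duration <- 100; proto$t_off <- 100
  tr <- hh_simulate(reg$parameters, proto)
  sol <- oracle_solve(reg$parameters, proto, V0 = tr$V0, out_dt = 0.01)
  st <- detect_spikes(tr)
  so <- oracle_spikes(sol)
  expect_equal(length(st), length(so))
  expect_lt(max(abs(st - so)), 1)
})

test_that("lookup-table sigmoid stays within 1e-4 of direct evaluation", {
  lut <- sigmoid_lut(mu = -40, s = 9)
  expect_equal(lut$fun(-40), 0.5, tolerance = 1e-4)
  dense <- seq(-100, 50, by = 0.01)
  expect_lt(max(abs(lut$fun(dense) - sigmoid_inf(dense, -40, 9))), 1e-4)
  # steep inactivation curve too
  lut2 <- sigmoid_lut(mu = -62, s = -3)
  expect_lt(max(abs(lut2$fun(dense) - sigmoid_inf(dense, -62, -3))), 1e-4)
  # clamps outside the tabulated range
  expect_equal(lut$fun(-150), lut$fun(-100))
  expect_equal(lut$fun(80), lut$fun(50))
  expect_error(sigmoid_lut(-40, 9, n_points = 1), "n_points")
  expect_error(sigmoid_lut(-40, 9, V_range = c(0, 0)), "interval")
  # simulation with table lookup stays close to the exact-sigmoid run
  p <- hh_parameters()
  proto <- stimulus_protocol(duration = 100, t_off = 100)
  a <- hh_simulate(p, proto)
  b <- hh_simulate(p, proto, use_lut = TRUE)
  expect_lt(max(abs(a$V - b$V)), 0.5)
  expect_equal(length(a$spike_times), length(b$spike_times))
})

test_that("trace CSV + sidecar round-trips through the readers", {
  p <- hh_parameters()
  proto <- stimulus_protocol(duration = 50, t_on = 10, t_off = 40)
  tr <- hh_simulate(p, proto)
  path <- file.path(tempdir(), "trace.csv")
  write_trace(tr, path)
  expect_identical(readLines(path, n = 1), "t_ms,V_mV,m,h,n")
  back <- read_trace(path)
  expect_equal(back$V, tr$V, tolerance = 1e-12)
  expect_equal(back$parameters, tr$parameters)
  expect_equal(back$protocol, tr$protocol)
  expect_equal(back$spike_times, tr$spike_times)
})

test_that("parameter/protocol config round-trips through YAML", {
  p <- hh_parameters(gNa_max = 77.5, mu_h = -61.25)
  proto <- stimulus_protocol(I_amp = 12.5)
  path <- file.path(tempdir(), "params.yaml")
  write_hh_config(p, proto, path)
  cfg <- read_hh_config(path)
  expect_equal(cfg$parameters, p)
  expect_equal(cfg$protocol, proto)
  writeLines("bogus_key: 1", path)
  expect_error(read_hh_config(path), "unknown config key")
})

test_that("degenerate protocols and parameters are rejected up front", {
  expect_error(stimulus_protocol(dt = 0), "dt")
  expect_error(stimulus_protocol(dt = 400), "dt")
  expect_error(stimulus_protocol(t_on = 200, t_off = 100), "t_on")
  expect_error(hh_parameters(tau_m = 0), "tau")
  expect_error(hh_parameters(s_h = 0), "slope")
  expect_error(hh_parameters(C_m = -1), "C_m")
  expect_error(hh_parameters(gK_max = -5), "conductances")
})
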