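test_that("RC charging closed form reproduces the reference values", {
  tr <- rc_charge(ref_rc(), seq(0, 5, by = 0.001))
  at <- function(t, col) tr[[col]][match(t, tr$t_ms)]
  # t = 0: uncharged capacitor, full supply across the resistor
  expect_equal(at(0, "V_C_mV"), 0)
  expect_equal(at(0, "V_leak_mV"), 100)
  expect_equal(at(0, "I_uA"), 100)
  # t = tau: 63.21 / 36.79 mV
  expect_equal(at(1, "V_C_mV"), 100 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(round(at(1, "V_C_mV")), 63)
  expect_equal(round(at(1, "V_leak_mV")), 37)
  # t = 5 tau
  expect_equal(at(5, "V_C_mV"), 100 * (1 - exp(-5)), tolerance = 1e-12)
})

test_that("RC discharge closed form follows V_C0 e^(-t/tau)", {
  circ <- ref_rc(V_C0 = 100)
  tr <- rc_discharge(circ, seq(0, 10, by = 0.001))
  expect_equal(tr$V_C_mV[1], 100)
  expect_equal(tr$V_C_mV[match(1, tr$t_ms)], 100 * exp(-1), tolerance = 1e-12)
  # Q(t) = Q0 e^(-t/tau)
  expect_equal(tr$Q_C, 1e-6 * 0.1 * exp(-tr$t_ms), tolerance = 1e-12)
  # discharge current is negative (Eq. of the loop current)
  expect_true(all(tr$I_uA <= 0))
})

test_that("trace invariants hold: KVL, Q = C V_C, power balance", {
  ch <- rc_charge(ref_rc(), seq(0, 5, by = 0.01))
  expect_lt(max(abs(ch$V_C_mV + ch$V_leak_mV - 100)) / 100, 1e-12)
  expect_equal(ch$Q_C, 1e-6 * ch$V_C_mV * 1e-3, tolerance = 1e-12)
  expect_equal(ch$P_E_W, ch$P_C_W + ch$P_leak_W, tolerance = 1e-12)
  # P_E(0) = E^2/R = 1e-5 W
  expect_equal(ch$P_E_W[1], 1e-5)
  expect_equal(ch$P_C_W[1], 0)
  dis <- rc_discharge(ref_rc(V_C0 = 100), seq(0, 5, by = 0.01))
  expect_lt(max(abs(dis$V_C_mV + dis$V_leak_mV)), 1e-12)
  # capacitor sources what the leak dissipates
  expect_equal(dis$P_C_W + dis$P_leak_W, rep(0, nrow(dis)), tolerance = 1e-15)
  expect_true(all(dis$P_leak_W >= 0))
})

test_that("energy dissipated in the leak over a full discharge is CV0^2/2", {
  circ <- ref_rc(V_C0 = 100)
  tr <- rc_discharge(circ, seq(0, 12, by = 0.001))   # 12 tau
  E_leak <- trapz_int(tr$t_ms * 1e-3, tr$P_leak_W)   # ms -> s
  expect_equal(E_leak, 0.5 * 1e-6 * 0.1^2, tolerance = 1e-4)
})

test_that("frozen-M MC transients are the RC forms with R replaced by M", {
  mc <- mc_low()
  expect_equal(mc$tau_ms, 0.1)    # M = 100 ohm, C = 1e-6 F
  t <- seq(0, 0.6, by = 1e-4)
  ch <- mc_charge(mc, t)
  expect_equal(ch$V_C_mV, 100 * (1 - exp(-t / 0.1)), tolerance = 1e-12)
  # reaches 63.2% of E at t = 0.1 ms
  expect_equal(crossing_time(ch, 63.2), 0.1, tolerance = 1e-3)
  dis <- mc_discharge(mc_low(V_C0 = 100), t)
  # falls to e^-5 of V_C0 by 0.5 ms: full discharge in about 0.5 ms
  expect_equal(crossing_time(dis, 100 * exp(-5)), 0.5, tolerance = 1e-6)
  # frozen at the high-resistance state: tau = 20 ms
  slow <- series_circuit(memristor = memristor_params(), phi0 = -1)
  expect_equal(slow$tau_ms, 20)
})

test_that("full_charge_time implements tau ln(1/(1-threshold))", {
  expect_equal(full_charge_time(ref_rc()), 5)            # 5 tau criterion
  expect_equal(full_charge_time(mc_low()), 0.5)
  expect_equal(full_charge_time(ref_rc(), 0.5), log(2))
  expect_error(full_charge_time(ref_rc(), 1), "threshold")
  expect_error(full_charge_time(ref_rc(), 0), "threshold")
})

test_that("forward Euler: first step, convergence order, stability guard", {
  circ <- ref_rc()
  # one step from V_C = 0 gives E dt / tau
  e1 <- euler_transient(circ, dt = 0.001, T = 0.002)
  expect_equal(e1$V_C_mV[2], 100 * 0.001 / 1)
  # error halves when dt halves (first-order convergence)
  err <- function(dt) {
    tr <- euler_transient(circ, dt, T = 5)
    max(abs(tr$V_C_mV - 100 * (1 - exp(-tr$t_ms))))
  }
  ratio <- err(1 / 100) / err(1 / 200)
  expect_gt(ratio, 2 * 0.8)
  expect_lt(ratio, 2 * 1.2)
  # discharge convergence against Eq.-(21)-form closed solution
  errd <- function(dt) {
    tr <- euler_transient(ref_rc(V_C0 = 100), dt, T = 5, "discharge")
    max(abs(tr$V_C_mV - 100 * exp(-tr$t_ms)))
  }
  ratiod <- errd(1 / 100) / errd(1 / 200)
  expect_gt(ratiod, 2 * 0.8)
  expect_lt(ratiod, 2 * 1.2)
  # sup-norm error < 1% of E at dt = tau/1000
  expect_lt(err(1e-3), 1)
  expect_error(euler_transient(circ, dt = 2, T = 10), "unstable")
  expect_warning(euler_transient(circ, dt = 0.2, T = 1), "tau/10")
})

test_that("the sign-flipped textbook recurrence diverges from the supply", {
  tr <- euler_transient(ref_rc(), dt = 0.001, T = 2,
                        verbatim_recurrence = TRUE)
  expect_lt(tr$V_C_mV[nrow(tr)], 0)   # runs away from E instead of toward it
})

test_that("coupled memristor discharge is dissipative and monotone", {
  circ <- series_circuit(memristor = memristor_params(), phi0 = 0,
                         V_C0 = 100)
  # discharging flux runs negative, so M grows toward M_off (tau -> 20 ms)
  tr <- euler_transient(circ, dt = 2e-3, T = 120, "discharge")
  expect_true(all(diff(tr$V_C_mV) <= 1e-12))
  expect_lt(tr$V_C_mV[nrow(tr)], 1)
  # KVL along the coupled trace
  expect_lt(max(abs(tr$V_C_mV + tr$V_leak_mV)), 1e-12)
})

test_that("coupled MC charging is at least as fast as RC at the same M(0)", {
  mc <- series_circuit(memristor = memristor_params(), phi0 = 0)
  mc_tr <- euler_transient(mc, dt = 1e-3, T = 15)
  rc_tr <- euler_transient(series_circuit(R = 1e4), dt = 1e-3, T = 15)
  t_mc <- crossing_time(mc_tr, 100 * (1 - exp(-1)))
  t_rc <- crossing_time(rc_tr, 100 * (1 - exp(-1)))
  expect_lte(t_mc, t_rc)
})
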