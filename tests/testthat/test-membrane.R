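test_that("zero drive from rest stays quiescent", {
  tr <- integrate_membrane(membrane_circuit(),
                           stimulus("none", duration = 50))
  expect_true(all(tr$V_mV == 0))
  expect_identical(as.character(classify_response(tr)), "quiescent")
})

test_that("step response matches the closed-form charge toward I R", {
  circ <- membrane_circuit()   # R = 1e4, C = 1e-6, tau = 10 ms
  sp <- stimulus("step", amplitude = 10, onset = 3, width = 300,
                 duration = 300)
  tr <- integrate_membrane(circ, sp, dt = 0.01)
  # closed-form oracle: V(t) = I R (1 - exp(-(t-onset)/tau))
  after <- tr$t_ms >= 3
  oracle <- 100 * (1 - exp(-(tr$t_ms[after] - 3) / 10))
  expect_lt(max(abs(tr$V_mV[after] - oracle)) / 100, 0.005)
  # steady state approaches I R = 100 mV
  expect_equal(tr$V_mV[nrow(tr)], 100, tolerance = 1e-6)
  # monotone toward the fixed point: no overshoot in a first-order system
  expect_true(all(tr$V_mV <= 100 + 1e-9))
  expect_true(all(diff(tr$V_mV[after]) >= -1e-12))
})

test_that("RK4 and Euler agree and RK4 is far more accurate", {
  circ <- membrane_circuit()
  sp <- stimulus("step", amplitude = 10, onset = 0, width = 100,
                 duration = 100)
  oracle <- function(t) 100 * (1 - exp(-t / 10))
  eu <- integrate_membrane(circ, sp, dt = 0.05, method = "euler")
  rk <- integrate_membrane(circ, sp, dt = 0.05, method = "rk4")
  expect_lt(max(abs(rk$V_mV - oracle(rk$t_ms))),
            max(abs(eu$V_mV - oracle(eu$t_ms))) / 100)
})

test_that("branch currents satisfy KCL and cross at tau ln 2 after onset", {
  circ <- membrane_circuit()
  sp <- stimulus("step", amplitude = 10, onset = 3, width = 30,
                 duration = 40)
  tr <- branch_currents(integrate_membrane(circ, sp, dt = 0.001))
  expect_lt(max(abs(tr$I_ext_uA - tr$I_C_uA - tr$I_leak_uA)),
            1e-9 * max(abs(tr$I_ext_uA)))
  # I_C = I_leak = I/2 at tau ln 2 after onset
  on <- tr$t_ms > 3 & tr$t_ms < 33
  k <- which.min(abs(tr$I_C_uA[on] - tr$I_leak_uA[on]))
  expect_equal(tr$t_ms[on][k], 3 + 10 * log(2), tolerance = 1e-3)
  # toward steady state the capacitor branch shuts off (3 tau elapsed here)
  k_end <- max(which(on))
  expect_equal(tr$I_C_uA[k_end], 10 * exp(-3), tolerance = 0.01)
  expect_equal(tr$I_leak_uA[k_end], 10 * (1 - exp(-3)), tolerance = 0.01)
})

test_that("pulse-train morphology classes match the canonical experiments", {
  circ <- membrane_circuit()
  run <- function(count, duration, dt = 0.01) {
    classify_response(integrate_membrane(
      circ, stimulus("pulse_train", amplitude = 10, count = count,
                     duration = duration), dt = dt))
  }
  # too little time to discharge between pulses: superposition, no APs
  expect_identical(as.character(run(4, 20)), "subthreshold_superposition")
  # long trains give full charge/discharge oscillations
  r16 <- run(16, 1000)
  expect_identical(as.character(r16), "oscillatory_potentials")
  expect_identical(attr(r16, "n_peaks"), 16L)
  r38 <- run(38, 1000)
  expect_identical(as.character(r38), "oscillatory_potentials")
  expect_identical(attr(r38, "n_peaks"), 38L)
  # peak count invariant under dt refinement
  expect_identical(attr(run(16, 1000, dt = 0.005), "n_peaks"), 16L)
  expect_identical(attr(run(4, 20, dt = 0.005), "n_peaks"),
                   attr(run(4, 20), "n_peaks"))
})

test_that("RC response is linear in stimulus amplitude", {
  circ <- membrane_circuit()
  tr1 <- integrate_membrane(circ, stimulus("pulse_train", amplitude = 10,
                                           count = 4, duration = 40))
  tr2 <- integrate_membrane(circ, stimulus("pulse_train", amplitude = 20,
                                           count = 4, duration = 40))
  expect_equal(tr2$V_mV, 2 * tr1$V_mV, tolerance = 1e-12)
})

test_that("a pinned memristor at M = R reproduces the RC trace exactly", {
  sp <- stimulus("pulse_train", amplitude = 10, count = 4, duration = 40)
  rc <- integrate_membrane(membrane_circuit(R = 1e4), sp)
  pinned <- membrane_circuit(memristor = memristor_params(flux_scale = 0))
  mc <- integrate_membrane(pinned, sp)
  expect_identical(mc$V_mV, rc$V_mV)
  # with live flux the memristive response differs (nonlinear leak)
  live <- integrate_membrane(
    membrane_circuit(memristor = memristor_params()), sp)
  expect_gt(max(abs(live$V_mV - rc$V_mV)), 0.1)
})

test_that("instability and precondition guards fire", {
  expect_error(integrate_membrane(membrane_circuit(R = 10),
                                  stimulus("none", duration = 10), dt = 0.05),
               "unstable")
  expect_error(integrate_membrane(membrane_circuit(),
                                  stimulus("none", duration = 1), dt = 2),
               "T > dt")
})
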