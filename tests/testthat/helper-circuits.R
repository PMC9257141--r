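# Shared fixtures: the reference circuits and small numeric oracles.

ref_rc <- function(...) series_circuit(E = 100, C = 1e-6, R = 1e3, ...)

mc_low <- function(V_C0 = 0) {
  # memristor frozen in its low-resistance state: phi at the upper threshold
  series_circuit(E = 100, C = 1e-6, memristor = memristor_params(),
                 phi0 = 0.25, V_C0 = V_C0)
}

# trapezoidal integral (independent of any package quadrature)
trapz_int <- function(x, y) sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))

# area of one hysteresis lobe: the v >= 0 half of the last full cycle
lobe_area <- function(h, n_per_cycle = 2000) {
  n <- nrow(h)
  idx <- (n - n_per_cycle + 1):(n - n_per_cycle / 2 + 1)
  abs(trapz_int(h$v_mV[idx], h$i_uA[idx]))
}

# small network configuration for fast property tests
small_net <- function(T = 400, ...) network_params(N_exc = 160, N_inh = 40,
                                                   T = T, ...)
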