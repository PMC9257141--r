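# Unit conventions used throughout: time ms, voltage mV, current uA,
# capacitance F, resistance ohm, charge coulomb, power W. Numerically
# mV/ms == V/s, so the SI form of each ODE right-hand side can be used
# directly on the mV/ms grid; currents convert as I_uA = 1000 * V_mV / R_ohm.

.current_uA <- function(v_mV, R_ohm) 1000 * v_mV / R_ohm
.charge_C <- function(C_F, v_mV) C_F * v_mV * 1e-3
.power_W <- function(v_mV, i_uA) (v_mV * 1e-3) * (i_uA * 1e-6)

#' Series charge/discharge circuit parameters
#'
#' A first-order series circuit of a supply, a capacitor and a leak element
#' that is either a fixed resistor (RC) or a flux-controlled memristor (MC).
#' The time constant is \eqn{\tau = RC} (or \eqn{MC}), reported in ms.
#'
#' @param E supply voltage, mV.
#' @param C capacitance, F; must be positive.
#' @param R leak resistance, ohm (RC circuit). Ignored when `memristor` is
#'   given.
#' @param memristor a [memristor_params()] object for an MC circuit, or
#'   `NULL` for RC.
#' @param phi0 initial memristor flux, flux-units (MC only).
#' @param V_C0 initial capacitor voltage, mV.
#' @return An object of class `series_circuit` with the derived time
#'   constant `tau_ms` (at the initial leak state for MC).
#' @examples
#' rc <- series_circuit(E = 100, C = 1e-6, R = 1e3)
#' rc$tau_ms  # 1 ms
#' @export
series_circuit <- function(E = 100, C = 1e-6, R = 1e3, memristor = NULL,
                           phi0 = 0, V_C0 = 0) {
  stopifnot(C > 0)
  if (is.null(memristor)) {
    stopifnot(is.numeric(R), R > 0)
    leak <- "R"
    R_init <- R
  } else {
    stopifnot(inherits(memristor, "memristor_params"))
    leak <- "memristor"
    R_init <- memristance(phi0, memristor)
  }
  structure(list(E = E, C = C, R = if (leak == "R") R else NULL,
                 memristor = memristor, phi0 = phi0, V_C0 = V_C0,
                 leak = leak, tau_ms = R_init * C * 1000),
            class = "series_circuit")
}

.leak_resistance <- function(circ, phi = circ$phi0) {
  if (circ$leak == "R") circ$R else memristance(phi, circ$memristor)
}

.new_transient_trace <- function(t, V_C, V_leak, I_uA, circ, direction,
                                 method, M_ohm = NULL) {
  tr <- data.frame(t_ms = t, V_C_mV = V_C, V_leak_mV = V_leak, I_uA = I_uA,
                   Q_C = .charge_C(circ$C, V_C))
  if (!is.null(M_ohm)) tr$M_ohm <- M_ohm
  tr <- structure(tr, class = c("transient_trace", "data.frame"),
                  circuit = circ, direction = direction, method = method)
  powers(tr)
}

#' RC charging transient (closed form)
#'
#' Exact solution of the series RC charging circuit from an uncharged
#' capacitor: \eqn{V_C = E(1 - e^{-t/\tau})}, \eqn{V_R = E e^{-t/\tau}},
#' \eqn{I = (E/R) e^{-t/\tau}}, with \eqn{\tau = RC}. At \eqn{t = \tau} the
#' capacitor has reached \eqn{1 - e^{-1} \approx 63.2\%} of the supply.
#'
#' @param circ a [series_circuit()] with resistive leak and `V_C0 = 0`.
#' @param t_grid evaluation times, ms.
#' @return A `transient_trace` data frame with columns `t_ms`, `V_C_mV`,
#'   `V_leak_mV`, `I_uA`, `Q_C`, `P_E_W`, `P_C_W`, `P_leak_W`.
#' @examples
#' tr <- rc_charge(series_circuit(), seq(0, 5, by = 0.001))
#' tr$V_C_mV[tr$t_ms == 1]  # 63.21 mV at t = tau
#' @export
rc_charge <- function(circ, t_grid) {
  stopifnot(inherits(circ, "series_circuit"), circ$leak == "R",
            circ$V_C0 == 0)
  tau <- circ$tau_ms
  V_C <- circ$E * (1 - exp(-t_grid / tau))
  V_R <- circ$E * exp(-t_grid / tau)
  I <- .current_uA(V_R, circ$R)
  .new_transient_trace(t_grid, V_C, V_R, I, circ, "charge", "closed_form")
}

#' RC discharging transient (closed form)
#'
#' Exact solution of the RC discharge from an initially charged capacitor:
#' \eqn{V_C = V_{C0} e^{-t/\tau}}, \eqn{V_R = -V_C},
#' \eqn{I = -(V_{C0}/R) e^{-t/\tau}}, \eqn{Q = Q_0 e^{-t/\tau}}.
#'
#' @param circ a [series_circuit()] with resistive leak and `V_C0 > 0`.
#' @param t_grid evaluation times, ms.
#' @return A `transient_trace` data frame.
#' @export
rc_discharge <- function(circ, t_grid) {
  stopifnot(inherits(circ, "series_circuit"), circ$leak == "R",
            circ$V_C0 > 0)
  tau <- circ$tau_ms
  V_C <- circ$V_C0 * exp(-t_grid / tau)
  V_R <- -V_C
  I <- .current_uA(V_R, circ$R)
  .new_transient_trace(t_grid, V_C, V_R, I, circ, "discharge", "closed_form")
}

#' MC charging and discharging transients
#'
#' Transients of the memristor-capacitor series circuit. In `"frozen"`
#' coupling (the default) the memristance is held at its value for the
#' initial flux `phi0` and the RC closed forms apply with \eqn{R}
#' replaced by \eqn{M} and \eqn{\tau = MC}; with the memristor in its
#' low-resistance state (M = 100 ohm, C = 1e-6 F) this gives
#' \eqn{\tau = 0.1} ms, an order of magnitude faster than the reference RC
#' circuit. In `"coupled"` coupling the flux evolves with the voltage across
#' the memristor and the trace is computed numerically by
#' [euler_transient()].
#'
#' @param circ a [series_circuit()] with memristor leak.
#' @param t_grid evaluation times, ms (frozen coupling evaluates the closed
#'   form on this grid; coupled coupling integrates to `max(t_grid)`).
#' @param coupling `"frozen"` or `"coupled"`.
#' @param dt step for coupled integration, ms (default: the smallest grid
#'   spacing).
#' @return A `transient_trace` data frame (with an `M_ohm` column when
#'   coupled).
#' @examples
#' mc <- series_circuit(memristor = memristor_params(), phi0 = 0.25)
#' mc$tau_ms  # 0.1 ms: M(0.25) = 100 ohm
#' @export
mc_charge <- function(circ, t_grid, coupling = c("frozen", "coupled"),
                      dt = NULL) {
  coupling <- match.arg(coupling)
  stopifnot(inherits(circ, "series_circuit"), circ$leak == "memristor")
  if (coupling == "frozen") {
    stopifnot(circ$V_C0 == 0)
    M <- .leak_resistance(circ)
    tau <- M * circ$C * 1000
    V_C <- circ$E * (1 - exp(-t_grid / tau))
    V_M <- circ$E * exp(-t_grid / tau)
    I <- .current_uA(V_M, M)
    .new_transient_trace(t_grid, V_C, V_M, I, circ, "charge",
                         "closed_form_frozen_M")
  } else {
    if (is.null(dt)) dt <- min(diff(t_grid))
    euler_transient(circ, dt, max(t_grid), "charge")
  }
}

#' @rdname mc_charge
#' @export
mc_discharge <- function(circ, t_grid, coupling = c("frozen", "coupled"),
                         dt = NULL) {
  coupling <- match.arg(coupling)
  stopifnot(inherits(circ, "series_circuit"), circ$leak == "memristor")
  if (coupling == "frozen") {
    stopifnot(circ$V_C0 > 0)
    M <- .leak_resistance(circ)
    tau <- M * circ$C * 1000
    V_C <- circ$V_C0 * exp(-t_grid / tau)
    V_M <- -V_C
    I <- .current_uA(V_M, M)
    .new_transient_trace(t_grid, V_C, V_M, I, circ, "discharge",
                         "closed_form_frozen_M")
  } else {
    if (is.null(dt)) dt <- min(diff(t_grid))
    euler_transient(circ, dt, max(t_grid), "discharge")
  }
}

#' Power bookkeeping for a transient trace
#'
#' Adds (or refreshes) the instantaneous powers \eqn{P_E = E I},
#' \eqn{P_C = V_C I} and \eqn{P_{leak} = V_{leak} I} (watt). During charging
#' these satisfy \eqn{P_E = P_C + P_{leak}} pointwise; during discharge the
#' supply is disconnected (\eqn{P_E = 0}) and \eqn{P_C + P_{leak} = 0}: the
#' capacitor sources exactly what the leak dissipates.
#'
#' @param trace a `transient_trace`.
#' @return The trace with columns `P_E_W`, `P_C_W`, `P_leak_W`.
#' @export
powers <- function(trace) {
  stopifnot(inherits(trace, "transient_trace"))
  circ <- attr(trace, "circuit")
  charging <- identical(attr(trace, "direction"), "charge")
  trace$P_E_W <- if (charging) .power_W(circ$E, trace$I_uA) else 0
  trace$P_C_W <- .power_W(trace$V_C_mV, trace$I_uA)
  trace$P_leak_W <- .power_W(trace$V_leak_mV, trace$I_uA)
  trace
}

#' Forward-Euler integration of the series transient
#'
#' First-order finite-difference solution of the charging/discharging
#' capacitor voltage,
#' \deqn{V_C(t+\Delta t) = V_C(t) + \frac{\Delta t}{\tau}\,(E - V_C(t)),}
#' with \eqn{E = 0} for discharge. For a memristor leak the flux is advanced
#' each step from the voltage across the device ([update_flux()]) and
#' \eqn{\tau = M(\varphi) C} is state-dependent. The global error is
#' O(\eqn{\Delta t}) against the closed forms and halves when the step
#' halves.
#'
#' The recurrence as sometimes printed with a minus sign in front of the
#' drive term, \eqn{V - (\Delta t/\tau)(E - V)}, diverges from the supply
#' voltage; it is available behind `verbatim_recurrence = TRUE` for
#' documentation purposes only.
#'
#' @param circ a [series_circuit()].
#' @param dt time step, ms. Steps above \eqn{\tau/10} trigger a warning;
#'   \eqn{dt \ge 2\tau} (forward-Euler instability) is an error.
#' @param T final time, ms.
#' @param direction `"charge"` or `"discharge"`.
#' @param verbatim_recurrence use the sign-flipped recurrence (divergent;
#'   for documentation only).
#' @return A `transient_trace` data frame (plus `M_ohm` for memristor leak).
#' @export
euler_transient <- function(circ, dt, T, direction = c("charge", "discharge"),
                            verbatim_recurrence = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(circ, "series_circuit"), dt > 0, T > dt)
  t <- seq(0, T, by = dt)
  n <- length(t)
  V <- numeric(n)
  V[1] <- circ$V_C0
  if (direction == "discharge" && circ$V_C0 <= 0)
    stop("discharge requires V_C0 > 0")
  memr <- circ$leak == "memristor"
  if (memr) {
    st <- memristor_state(circ$phi0, circ$memristor)
    Ms <- numeric(n)
    Ms[1] <- st$M
  }
  R0 <- .leak_resistance(circ)
  tau0 <- R0 * circ$C * 1000
  if (dt >= 2 * tau0) stop("dt >= 2*tau: forward Euler unstable")
  if (dt > tau0 / 10)
    warning("dt exceeds tau/10; accuracy degraded")
  E_drive <- if (direction == "charge") circ$E else 0
  R_t <- R0
  for (k in seq_len(n - 1L)) {
    tau <- R_t * circ$C * 1000
    if (dt >= 2 * tau) stop("dt >= 2*tau at step ", k, ": forward Euler unstable")
    step <- (dt / tau) * (E_drive - V[k])
    V[k + 1L] <- if (verbatim_recurrence) V[k] - step else V[k] + step
    if (memr) {
      v_leak <- E_drive - V[k]       # voltage across the leak element
      st <- update_flux(st, v_leak, dt, circ$memristor)
      Ms[k + 1L] <- st$M
      R_t <- st$M
    }
  }
  V_leak <- E_drive - V
  I <- .current_uA(V_leak, if (memr) Ms else R_t)
  .new_transient_trace(t, V, V_leak, I, circ, direction, "euler",
                       M_ohm = if (memr) Ms else NULL)
}

#' Time to a given charge fraction
#'
#' For a first-order charging circuit the capacitor reaches fraction
#' `threshold` of the supply at \eqn{t = \tau \ln(1/(1-\mathrm{threshold}))}.
#' With the conventional "fully charged" criterion
#' \eqn{1 - e^{-5}} (about 99.33\%) this is \eqn{5\tau}: 5 ms for the
#' reference RC circuit (\eqn{\tau} = 1 ms) and 0.5 ms for the MC circuit
#' frozen in its low-resistance state (\eqn{\tau} = 0.1 ms).
#'
#' @param circ a [series_circuit()]; for a memristor leak the time constant
#'   at the initial flux is used.
#' @param threshold charge fraction, in (0, 1); default \eqn{1 - e^{-5}}.
#' @return Time in ms.
#' @examples
#' full_charge_time(series_circuit(R = 1e3))  # 5 ms
#' @export
full_charge_time <- function(circ, threshold = 1 - exp(-5)) {
  stopifnot(inherits(circ, "series_circuit"))
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  circ$tau_ms * log(1 / (1 - threshold))
}

#' First crossing time of a voltage level in a trace
#'
#' Linear-interpolated time at which the capacitor voltage first reaches
#' `level` (rising for charge traces, falling for discharge traces).
#'
#' @param trace a `transient_trace`.
#' @param level voltage level, mV.
#' @return Time in ms, or `NA` if the level is never crossed.
#' @export
crossing_time <- function(trace, level) {
  stopifnot(inherits(trace, "transient_trace"))
  V <- trace$V_C_mV
  t <- trace$t_ms
  rising <- identical(attr(trace, "direction"), "charge")
  hit <- if (rising) which(V >= level) else which(V <= level)
  if (!length(hit)) return(NA_real_)
  k <- hit[1L]
  if (k == 1L) return(t[1L])
  # interpolate between k-1 and k
  t[k - 1L] + (level - V[k - 1L]) / (V[k] - V[k - 1L]) * (t[k] - t[k - 1L])
}

#' @export
`[.transient_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (at in c("circuit", "direction", "method"))
      attr(out, at) <- attr(x, at)
  }
  out
}

#' @export
print.transient_trace <- function(x, ...) {
  circ <- attr(x, "circuit")
  cat(sprintf("%s transient (%s), %s leak, tau = %g ms, %d samples over %g ms\n",
              attr(x, "direction"), attr(x, "method"),
              circ$leak, circ$tau_ms, nrow(x), max(x$t_ms)))
  cat(sprintf("  V_C: %g -> %g mV\n", x$V_C_mV[1], x$V_C_mV[nrow(x)]))
  invisible(x)
}

#' @export
plot.transient_trace <- function(x, ...) {
  graphics::matplot(x$t_ms, cbind(x$V_C_mV, x$V_leak_mV), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "t (ms)", ylab = "V (mV)", ...)
  graphics::legend("right", legend = c("V_C", "V_leak"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
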