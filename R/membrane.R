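#' Parallel membrane circuit parameters
#'
#' The parallel leak-element/capacitor model of the neuron cell membrane
#' driven by an external current: the capacitor stands for the phospholipid
#' bilayer, the leak (a resistor for RC or a flux-controlled memristor for
#' MC) for the ion channels. The membrane potential obeys
#' \deqn{\frac{dV_m}{dt} = \frac{I_{ext}}{C} - \frac{V_m}{RC}}
#' (with \eqn{R} replaced by \eqn{M(\varphi)} for the MC variant, where the
#' flux integrates the membrane voltage itself).
#'
#' @param C capacitance, F; default `1e-6`.
#' @param R leak resistance, ohm; default `1e4`. Ignored when `memristor`
#'   is given.
#' @param memristor a [memristor_params()] object for a memristive leak, or
#'   `NULL` for a fixed resistor.
#' @param phi0 initial memristor flux; the default 0 gives
#'   \eqn{M(0) = 10^4} ohm in reconciled mode.
#' @param V0 initial membrane potential, mV.
#' @return An object of class `membrane_circuit`.
#' @export
membrane_circuit <- function(C = 1e-6, R = 1e4, memristor = NULL,
                             phi0 = 0, V0 = 0) {
  stopifnot(C > 0)
  if (is.null(memristor)) {
    stopifnot(R > 0)
    leak <- "R"
    R_init <- R
  } else {
    stopifnot(inherits(memristor, "memristor_params"))
    leak <- "memristor"
    R_init <- memristance(phi0, memristor)
  }
  structure(list(C = C, R = if (leak == "R") R else NULL,
                 memristor = memristor, phi0 = phi0, V0 = V0,
                 leak = leak, tau_ms = R_init * C * 1000),
            class = "membrane_circuit")
}

# dV/dt in mV/ms for membrane potential v (mV) under drive i_ext (uA)
# through leak resistance R (ohm): V/s == mV/ms numerically.
.membrane_rhs <- function(v, i_ext, R, C) {
  (i_ext * 1e-6) / C - (v * 1e-3) / (R * C)
}

#' Integrate the membrane equation under a stimulus
#'
#' Solves the parallel membrane ODE by forward Euler (default) or classical
#' RK4 on a uniform grid. For a memristive leak the flux state is advanced
#' each step from the membrane voltage and the memristance re-evaluated
#' (RK4 holds the memristance fixed within a step). Branch currents are
#' recorded so that Kirchhoff's node law \eqn{I_{ext} = I_C + I_{leak}}
#' holds at every sample.
#'
#' The minimum achievable time constant (over the memristance range, for a
#' memristive leak) bounds the stable step: `dt >= 2*tau_min` is an error.
#'
#' @param circ a [membrane_circuit()].
#' @param spec a [stimulus()] specification.
#' @param dt time step, ms; default 0.01 (\eqn{\tau/1000} for the reference
#'   configuration \eqn{\tau = 10} ms).
#' @param T record length, ms; defaults to the stimulus duration.
#' @param method `"euler"` or `"rk4"`.
#' @return A data frame of class `membrane_trace` with columns `t_ms`,
#'   `V_mV`, `I_ext_uA`, `I_C_uA`, `I_leak_uA`, `Q_C` and, for a memristive
#'   leak, `M_ohm` and `phi`.
#' @examples
#' tr <- integrate_membrane(membrane_circuit(),
#'                          stimulus("step", amplitude = 10, onset = 3,
#'                                   width = 30, duration = 40))
#' max(tr$V_mV)  # approaches I*R = 100 mV
#' @export
integrate_membrane <- function(circ, spec, dt = 0.01, T = spec$duration,
                               method = c("euler", "rk4")) {
  method <- match.arg(method)
  stopifnot(inherits(circ, "membrane_circuit"), inherits(spec, "stimulus_spec"),
            dt > 0, T > dt)
  memr <- circ$leak == "memristor"
  tau_min <- if (memr) circ$memristor$M_on * circ$C * 1000 else circ$tau_ms
  if (dt >= 2 * tau_min)
    stop("dt >= 2*tau_min: integration unstable")
  t <- seq(0, T, by = dt)
  n <- length(t)
  I_ext <- sample_stimulus(spec, t)
  V <- numeric(n)
  V[1] <- circ$V0
  if (memr) {
    st <- memristor_state(circ$phi0, circ$memristor)
    Ms <- numeric(n); phis <- numeric(n)
    Ms[1] <- st$M; phis[1] <- st$phi
    R_t <- st$M
  } else {
    R_t <- circ$R
  }
  for (k in seq_len(n - 1L)) {
    if (method == "euler") {
      V[k + 1L] <- V[k] + dt * .membrane_rhs(V[k], I_ext[k], R_t, circ$C)
    } else {
      # sample-and-hold drive: I_ext constant over [t_k, t_{k+1})
      i <- I_ext[k]
      k1 <- .membrane_rhs(V[k], i, R_t, circ$C)
      k2 <- .membrane_rhs(V[k] + dt / 2 * k1, i, R_t, circ$C)
      k3 <- .membrane_rhs(V[k] + dt / 2 * k2, i, R_t, circ$C)
      k4 <- .membrane_rhs(V[k] + dt * k3, i, R_t, circ$C)
      V[k + 1L] <- V[k] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (memr) {
      st <- update_flux(st, V[k], dt, circ$memristor)
      Ms[k + 1L] <- st$M
      phis[k + 1L] <- st$phi
      R_t <- st$M
    }
  }
  R_vec <- if (memr) Ms else circ$R
  I_leak <- 1000 * V / R_vec
  tr <- data.frame(t_ms = t, V_mV = V, I_ext_uA = I_ext,
                   I_C_uA = I_ext - I_leak, I_leak_uA = I_leak,
                   Q_C = circ$C * V * 1e-3)
  if (memr) { tr$M_ohm <- Ms; tr$phi <- phis }
  structure(tr, class = c("membrane_trace", "data.frame"),
            circuit = circ, stimulus = spec, dt = dt, method = method)
}

#' Recompute branch currents of a membrane trace
#'
#' Decomposes the external drive into the leak and capacitive branches:
#' \eqn{I_{leak} = V / R} (or \eqn{V / M(\varphi)}) and
#' \eqn{I_C = I_{ext} - I_{leak}}, so the node law holds by construction.
#' Under a step of amplitude \eqn{I} the two branch currents cross
#' (\eqn{I_C = I_{leak} = I/2}) at \eqn{\tau \ln 2} after onset.
#'
#' @param trace a `membrane_trace`.
#' @param circ the [membrane_circuit()] that produced it (defaults to the
#'   one stored on the trace).
#' @return The trace with `I_leak_uA` and `I_C_uA` refreshed.
#' @export
branch_currents <- function(trace, circ = attr(trace, "circuit")) {
  stopifnot(inherits(trace, "membrane_trace"))
  R_vec <- if (circ$leak == "memristor") trace$M_ohm else circ$R
  trace$I_leak_uA <- 1000 * trace$V_mV / R_vec
  trace$I_C_uA <- trace$I_ext_uA - trace$I_leak_uA
  trace
}

.find_peaks <- function(V, min_height) {
  n <- length(V)
  if (n < 3L) return(integer(0))
  d <- diff(V)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  idx[V[idx] >= min_height]
}

#' Classify a membrane response
#'
#' Descriptive labeling of the trace morphology into three classes:
#' \describe{
#'   \item{`quiescent`}{the response never exceeds `quiescent_frac` of the
#'     steady-state scale \eqn{I_{max} R}.}
#'   \item{`oscillatory_potentials`}{repeated full charge/discharge
#'     excursions: at least two local maxima preceded by troughs below
#'     `trough_frac` of the peak, and such full excursions make up the
#'     majority of all peaks. This is what the drive produces when it
#'     leaves the membrane enough time to discharge between pulses.}
#'   \item{`subthreshold_superposition`}{anything in between: pulses arrive
#'     faster than the membrane can discharge, so responses stack without
#'     returning near baseline (only the leading ramp, at most, shows deep
#'     troughs).}
#' }
#' The majority requirement makes the label depend on the trace's
#' steady-state morphology rather than on the first one or two transient
#' excursions, and keeps it invariant under time-step refinement.
#' This is a morphological classifier of the first-order circuit's driven
#' oscillations, not a spike detector with a biophysical threshold.
#'
#' @param trace a `membrane_trace`.
#' @param circ the producing [membrane_circuit()].
#' @param quiescent_frac fraction of the \eqn{I_{max} R} scale below which
#'   the response counts as quiescent; default 0.01.
#' @param trough_frac trough depth (fraction of the following peak)
#'   required to count an excursion as a full oscillation; default 0.5.
#' @return A character label with attributes `n_peaks` (number of
#'   full-oscillation peaks) and `V_max`.
#' @examples
#' circ <- membrane_circuit()
#' tr <- integrate_membrane(circ, stimulus("pulse_train", count = 16,
#'                                         duration = 1000))
#' classify_response(tr)  # oscillatory_potentials
#' @export
classify_response <- function(trace, circ = attr(trace, "circuit"),
                              quiescent_frac = 0.01, trough_frac = 0.5) {
  stopifnot(inherits(trace, "membrane_trace"))
  V <- trace$V_mV
  I_max <- max(abs(trace$I_ext_uA))
  R_ref <- if (circ$leak == "memristor")
    memristance(circ$phi0, circ$memristor) else circ$R
  scale <- I_max * R_ref / 1000   # uA * ohm -> mV
  V_max <- max(abs(V))
  if (scale == 0 || V_max < quiescent_frac * scale) {
    return(structure("quiescent", n_peaks = 0L, V_max = V_max))
  }
  peaks <- .find_peaks(V, min_height = quiescent_frac * scale)
  n_osc <- 0L
  prev <- 1L
  for (p in peaks) {
    trough <- min(V[prev:p])
    if (trough < trough_frac * V[p]) n_osc <- n_osc + 1L
    prev <- p
  }
  label <- if (n_osc >= 2L && n_osc > length(peaks) / 2)
    "oscillatory_potentials" else "subthreshold_superposition"
  structure(label, n_peaks = n_osc, V_max = V_max)
}

#' @export
`[.membrane_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (at in c("circuit", "stimulus", "dt", "method", "label"))
      attr(out, at) <- attr(x, at)
  }
  out
}

#' @export
print.membrane_trace <- function(x, ...) {
  circ <- attr(x, "circuit")
  spec <- attr(x, "stimulus")
  cat(sprintf("Membrane trace: %s leak, %s drive, dt = %g ms, %g ms\n",
              circ$leak, spec$kind, attr(x, "dt"), max(x$t_ms)))
  cat(sprintf("  V in [%.3g, %.3g] mV\n", min(x$V_mV), max(x$V_mV)))
  invisible(x)
}

#' @export
plot.membrane_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t_ms, x$V_mV, type = "l", xlab = "t (ms)",
                 ylab = "V (mV)", ...)
  graphics::plot(x$t_ms, x$I_ext_uA, type = "s", xlab = "t (ms)",
                 ylab = "I_ext (uA)", col = "firebrick")
  invisible(x)
}
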