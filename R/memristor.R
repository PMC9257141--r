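#' Flux-controlled memristor parameters
#'
#' Defines the nonlinear leak element of the MC neuron circuit: a two-terminal
#' resistive device whose resistance (memristance) is a function of the flux
#' \eqn{\varphi(t) = \int v\,dt}, the time-integral of the voltage across it.
#'
#' Two memristance laws are provided. In `"verbatim"` mode the memristance is
#' the three-branch piecewise law
#' \deqn{M(\varphi) = \cases{20000 & \varphi < -0.75 \cr
#'   -3.98\times 10^8 \varphi + 10^8 & -0.75 \le \varphi < 0.25 \cr
#'   100 & \varphi \ge 0.25}}
#' with the printed inequality directions at the branch boundaries (strict
#' below `phi_low`, inclusive at and above `phi_high`). The linear branch of
#' this law is discontinuous at the thresholds and spans resistances far above
#' the device's stated operating range, so a `"reconciled"` mode (the default)
#' replaces it with a continuous linearization consistent with that range:
#' \deqn{M(\varphi) = \mathrm{clamp}(M_0 - s\,\varphi,\; M_{on},\, M_{off})}
#' with \eqn{M_0 = 10^4\ \Omega} at zero flux and slope
#' \eqn{s = (M_0 - M_{on})/\varphi_{high}} (39600 ohm per flux-unit for the
#' defaults) so that the low-resistance endpoint is reached exactly at
#' `phi_high`. The reconciled memristance is nonincreasing in flux and confined
#' to \eqn{[M_{on}, M_{off}]}.
#'
#' Internal flux units are millivolt-seconds: `flux_scale` converts
#' volt-seconds of applied flux into internal flux-units (default `1e3`,
#' i.e. 1 internal unit = 1 mV s), which places the switching thresholds on a
#' millisecond time base at millivolt drive.
#'
#' @param mode `"reconciled"` (continuous, range-limited law; default) or
#'   `"verbatim"` (exact three-branch piecewise law).
#' @param M_on low (on) resistance, ohm.
#' @param M_off high (off) resistance, ohm.
#' @param M0 memristance at zero flux in reconciled mode, ohm.
#' @param slope,intercept linear-branch coefficients of the verbatim law,
#'   ohm per flux-unit and ohm.
#' @param phi_low,phi_high flux thresholds (flux-units) of the high- and
#'   low-resistance branches.
#' @param flux_scale internal flux-units per volt-second.
#' @return An object of class `memristor_params`.
#' @seealso [memristance()], [update_flux()], [iv_hysteresis()]
#' @examples
#' m <- memristor_params("verbatim")
#' memristance(c(-1, 0, 0.3), m)   # 20000, 1e8, 100
#' memristance(0, memristor_params("reconciled"))  # 10000
#' @export
memristor_params <- function(mode = c("reconciled", "verbatim"),
                             M_on = 100, M_off = 20000, M0 = 10000,
                             slope = -3.98e8, intercept = 1e8,
                             phi_low = -0.75, phi_high = 0.25,
                             flux_scale = 1e3) {
  mode <- match.arg(mode)
  stopifnot(M_on < M_off, phi_low < phi_high, flux_scale >= 0,
            M_on < M0, M0 < M_off)
  structure(list(mode = mode, M_on = M_on, M_off = M_off, M0 = M0,
                 slope = slope, intercept = intercept,
                 phi_low = phi_low, phi_high = phi_high,
                 flux_scale = flux_scale),
            class = "memristor_params")
}

#' Memristance as a function of flux
#'
#' Evaluates the memristance law of a flux-controlled memristor. Memristance
#' depends only on the flux state, never on the instantaneous voltage.
#'
#' @param phi flux, internal flux-units (vectorized).
#' @param params a [memristor_params()] object.
#' @return Resistance in ohm, same length as `phi`.
#' @export
memristance <- function(phi, params) {
  stopifnot(inherits(params, "memristor_params"))
  if (!all(is.finite(phi))) stop("'phi' must be finite")
  if (params$mode == "verbatim") {
    ifelse(phi < params$phi_low, params$M_off,
           ifelse(phi >= params$phi_high, params$M_on,
                  params$slope * phi + params$intercept))
  } else {
    s <- (params$M0 - params$M_on) / params$phi_high
    pmin(pmax(params$M0 - s * phi, params$M_on), params$M_off)
  }
}

#' Memristor state (flux and cached memristance)
#'
#' @param phi initial flux, flux-units.
#' @param params a [memristor_params()] object.
#' @return An object of class `memristor_state` with fields `phi` and `M`,
#'   where `M == memristance(phi, params)` at all times.
#' @export
memristor_state <- function(phi = 0, params) {
  structure(list(phi = phi, M = memristance(phi, params)),
            class = "memristor_state")
}

#' Advance the memristor flux under an applied voltage
#'
#' Integrates the defining flux relation \eqn{d\varphi/dt = v} over one step
#' of piecewise-constant voltage:
#' \eqn{\varphi' = \varphi + \mathrm{flux\_scale}\cdot v\,dt} with
#' \eqn{v\,dt} in volt-seconds before scaling. The update is exact for
#' piecewise-constant voltage (independent of step size) and linear in `dt`.
#'
#' @param state a [memristor_state()].
#' @param v voltage across the device, mV.
#' @param dt time step, ms; must be positive.
#' @param params a [memristor_params()] object.
#' @return The updated `memristor_state` with memristance recomputed.
#' @export
update_flux <- function(state, v, dt, params) {
  stopifnot(inherits(state, "memristor_state"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number")
  phi <- state$phi + params$flux_scale * (v * 1e-3) * (dt * 1e-3)
  memristor_state(phi, params)
}

#' Pinched hysteresis loop of the memristor
#'
#' Drives the memristor with a sinusoidal voltage
#' \eqn{v(t) = A\sin(2\pi f t)}, integrating the flux along the way, and
#' records the current \eqn{i = v / M(\varphi)}. The resulting
#' current-voltage loop is pinched at the origin (i = 0 whenever v = 0) and
#' lies in the first and third quadrants; its lobe area shrinks as the drive
#' frequency increases, the signature of a memristive device.
#'
#' @param amplitude drive amplitude, mV; must be non-negative.
#' @param frequency drive frequency, Hz; must be positive.
#' @param cycles number of full drive periods to simulate.
#' @param params a [memristor_params()] object.
#' @param phi0 initial flux, flux-units.
#' @param n_per_cycle samples per drive period.
#' @return A data frame of class `hysteresis_trace` with columns
#'   `t_ms`, `v_mV`, `i_uA`, `phi`, `M_ohm`.
#' @examples
#' h <- iv_hysteresis(100, 50, cycles = 2)
#' max(abs(h$i_uA[abs(h$v_mV) < 1e-9]))  # pinched: zero current at zero volts
#' @export
iv_hysteresis <- function(amplitude, frequency, cycles = 3,
                          params = memristor_params(), phi0 = 0,
                          n_per_cycle = 2000) {
  stopifnot(amplitude >= 0, frequency > 0, cycles >= 1)
  period_ms <- 1000 / frequency
  dt <- period_ms / n_per_cycle
  t <- seq(0, cycles * period_ms, by = dt)
  v <- amplitude * sin(2 * pi * frequency * t / 1000)
  n <- length(t)
  phi <- numeric(n)
  phi[1] <- phi0
  # trapezoidal flux integration of the sinusoid
  for (k in seq_len(n - 1L)) {
    phi[k + 1L] <- phi[k] +
      params$flux_scale * 0.5 * (v[k] + v[k + 1L]) * 1e-3 * dt * 1e-3
  }
  M <- memristance(phi, params)
  i <- 1000 * v / M    # mV / ohm -> mA; x1000 -> uA
  structure(data.frame(t_ms = t, v_mV = v, i_uA = i, phi = phi, M_ohm = M),
            class = c("hysteresis_trace", "data.frame"))
}

#' @export
print.memristor_params <- function(x, ...) {
  cat(sprintf("Flux-controlled memristor (%s mode)\n", x$mode))
  cat(sprintf("  M_on = %g ohm, M_off = %g ohm, thresholds [%g, %g] flux-units\n",
              x$M_on, x$M_off, x$phi_low, x$phi_high))
  if (x$mode == "reconciled")
    cat(sprintf("  M(0) = %g ohm, slope %g ohm per flux-unit\n",
                x$M0, (x$M0 - x$M_on) / x$phi_high))
  else
    cat(sprintf("  linear branch %g * phi + %g ohm\n", x$slope, x$intercept))
  invisible(x)
}

#' @export
plot.hysteresis_trace <- function(x, ...) {
  graphics::plot(x$v_mV, x$i_uA, type = "l",
                 xlab = "v (mV)", ylab = "i (uA)",
                 main = "Pinched hysteresis loop", ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}
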