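#' External stimulus specification
#'
#' Parametric description of the external drive current applied to a
#' membrane circuit. Five kinds are supported:
#' \describe{
#'   \item{`none`}{zero drive.}
#'   \item{`step`}{constant `amplitude` from `onset` for `width` ms
#'     (default: until the end of the record).}
#'   \item{`single_pulse`}{one rectangular pulse of `width` ms at `onset`.}
#'   \item{`pulse_train`}{`count` rectangular pulses spread over `duration`
#'     ms. If `width`/`period` are not given they are derived by
#'     [train_layout()] with duty cycle `duty` (default 0.5): the pulses
#'     alternate on/off symmetrically within `period = duration/count`.}
#'   \item{`random_drive`}{Gaussian white current of standard deviation
#'     `sigma_exc`, reproducible under `seed`.}
#' }
#' Stimulus values use the sample-and-hold convention: the value at a grid
#' point applies over \eqn{[t, t+\Delta t)} (left-continuous steps), so a
#' pulse of width w is on for \eqn{onset \le t < onset + w}.
#'
#' @param kind one of `"none"`, `"step"`, `"single_pulse"`, `"pulse_train"`,
#'   `"random_drive"`.
#' @param amplitude current amplitude, uA.
#' @param onset time of stimulus onset, ms.
#' @param width pulse width, ms (pulse kinds; for `step`, the action time).
#' @param period pulse period, ms (`pulse_train`).
#' @param count number of pulses (`pulse_train`), at least 1.
#' @param duration total record/action time, ms; must be positive.
#' @param duty duty cycle used to derive `width`/`period` when not given.
#' @param sigma_exc,sigma_inh Gaussian current scales, uA (`random_drive`;
#'   `sigma_inh` is the scale applied to inhibitory populations in network
#'   use).
#' @param seed integer RNG seed (`random_drive`).
#' @return An object of class `stimulus_spec`.
#' @examples
#' sp <- stimulus("pulse_train", amplitude = 10, count = 16, duration = 100)
#' sp$period   # 6.25 ms
#' @export
stimulus <- function(kind = c("none", "step", "single_pulse", "pulse_train",
                              "random_drive"),
                     amplitude = 10, onset = 0, width = NULL, period = NULL,
                     count = NULL, duration = 100, duty = 0.5,
                     sigma_exc = 5, sigma_inh = 2, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(amplitude)) stop("'amplitude' must be finite")
  if (duration <= 0) stop("'duration' must be positive")
  if (kind == "pulse_train") {
    if (is.null(count) || count < 1) stop("'count' must be >= 1 for a pulse train")
    if (is.null(width) || is.null(period)) {
      lay <- train_layout(count, duration - onset, duty)
      width <- lay$width
      period <- lay$period
    }
    if (width > period) stop("'width' must not exceed 'period'")
  }
  if (kind == "single_pulse" && is.null(width)) width <- duty * (duration - onset)
  if (kind == "step" && is.null(width)) width <- Inf
  structure(list(kind = kind, amplitude = amplitude, onset = onset,
                 width = width, period = period, count = count,
                 duration = duration, duty = duty,
                 sigma_exc = sigma_exc, sigma_inh = sigma_inh,
                 seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' Pulse-train layout from count, total action time and duty cycle
#'
#' The train of `count` pulses occupies `duration` ms in total, so
#' `period = duration / count` and `width = duty * period`.
#'
#' @param count number of pulses.
#' @param duration total action time, ms.
#' @param duty on-fraction of each period, in (0, 1).
#' @return A list with elements `width` and `period` (ms).
#' @examples
#' train_layout(16, 100)   # period 6.25, width 3.125
#' @export
train_layout <- function(count, duration, duty = 0.5) {
  if (duty <= 0 || duty >= 1) stop("'duty' must be in (0, 1)")
  if (count * 1e-9 >= duration) stop("'duration' too short for 'count' pulses")
  period <- duration / count
  list(width = duty * period, period = period)
}

#' Sample a stimulus on a time grid
#'
#' Evaluates the drive current at each grid time. Non-random stimuli are
#' deterministic and idempotent; `random_drive` is reproducible under the
#' stimulus seed (the caller's RNG state is preserved). Values are zero outside
#' active intervals.
#'
#' @param spec a [stimulus()] specification.
#' @param t_grid strictly increasing times, ms.
#' @return Numeric vector of currents, uA.
#' @export
sample_stimulus <- function(spec, t_grid) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing")
  n <- length(t_grid)
  switch(spec$kind,
    none = numeric(n),
    step = {
      on <- t_grid >= spec$onset & t_grid < spec$onset + spec$width
      ifelse(on, spec$amplitude, 0)
    },
    single_pulse = {
      on <- t_grid >= spec$onset & t_grid < spec$onset + spec$width
      ifelse(on, spec$amplitude, 0)
    },
    pulse_train = {
      rel <- t_grid - spec$onset
      k <- floor(rel / spec$period)
      inpulse <- rel >= 0 & k < spec$count & (rel - k * spec$period) < spec$width
      ifelse(inpulse, spec$amplitude, 0)
    },
    random_drive = {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(spec$seed)
      stats::rnorm(n, mean = 0, sd = spec$sigma_exc)
    },
    stop("unknown stimulus kind: ", spec$kind)
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("Stimulus: %s, amplitude %g uA", x$kind, x$amplitude))
  if (x$kind == "pulse_train")
    cat(sprintf(", %d pulses (width %g ms, period %g ms)",
                x$count, x$width, x$period))
  if (x$kind %in% c("step", "single_pulse") && is.finite(x$width))
    cat(sprintf(", width %g ms", x$width))
  cat(sprintf(", onset %g ms, duration %g ms\n", x$onset, x$duration))
  invisible(x)
}
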