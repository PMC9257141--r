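#' Excitatory/inhibitory spiking network parameters
#'
#' Configuration of a randomly coupled spiking network of `N_exc` excitatory
#' and `N_inh` inhibitory neurons (default 1600/400, the 4:1 cortical
#' ratio), driven by random thalamic input for `T` ms. Neurons follow the
#' Izhikevich quadratic model with heterogeneous parameters: excitatory
#' cells span the regular-spiking to chattering continuum, inhibitory cells
#' the fast-spiking continuum. Spikes are detected at `spike_cut` (30 mV)
#' and recorded potentials are clipped there.
#'
#' The `izhikevich_mc` variant adds a memristive membrane leak
#' \eqn{-v / (M(\varphi) C_m)} per neuron, with each neuron's flux
#' integrating its own membrane potential (reconciled memristance law);
#' with `flux_scale = 0` on the memristor the variant reduces exactly to
#' the plain model.
#'
#' Scaling inhibitory synaptic weights down by two orders of magnitude
#' (`inhibitory_scale = 0.01`) releases the network into the synchronous
#' regime; `inhibitory_scale = 1` gives the asynchronous (cortical-like)
#' regime.
#'
#' @param N_exc,N_inh excitatory and inhibitory population sizes.
#' @param T simulated duration, ms.
#' @param dt outer step, ms (the membrane update uses two half-steps).
#' @param spike_cut spike detection/clipping threshold, mV.
#' @param inhibitory_scale multiplier on inhibitory synaptic strengths.
#' @param membrane_variant `"izhikevich"` or `"izhikevich_mc"`.
#' @param drive_exc,drive_inh thalamic drive s.d. for the two populations.
#' @param drive_gain multiplier on the thalamic drive (1 = reference).
#' @param C_m membrane capacitance of the memristive leak, F (MC variant).
#' @param memristor [memristor_params()] for the MC variant.
#' @param leak_R optional fixed leak resistance, ohm, for the plain variant
#'   (`NULL`, the default, runs the unmodified reference scheme). A pinned
#'   memristor (`flux_scale = 0`) is equivalent to `leak_R = M(phi0)`.
#' @param sample_neuron index of the neuron whose potential is recorded.
#' @param seed integer seed; network build uses `seed`, the run `seed + 1`.
#' @return An object of class `network_params`.
#' @export
network_params <- function(N_exc = 1600, N_inh = 400, T = 2000, dt = 1,
                           spike_cut = 30, inhibitory_scale = 1,
                           membrane_variant = c("izhikevich", "izhikevich_mc"),
                           drive_exc = 5, drive_inh = 2, drive_gain = 1,
                           C_m = 1e-6, memristor = memristor_params(),
                           leak_R = NULL, sample_neuron = 1L, seed = 1L) {
  membrane_variant <- match.arg(membrane_variant)
  if (N_exc + N_inh <= 0) stop("network must contain at least one neuron")
  stopifnot(T > 0, dt > 0, inhibitory_scale >= 0, drive_gain >= 0)
  structure(list(N_exc = as.integer(N_exc), N_inh = as.integer(N_inh),
                 N = as.integer(N_exc + N_inh), T = T, dt = dt,
                 spike_cut = spike_cut, inhibitory_scale = inhibitory_scale,
                 membrane_variant = membrane_variant,
                 drive_exc = drive_exc, drive_inh = drive_inh,
                 drive_gain = drive_gain, C_m = C_m, memristor = memristor,
                 leak_R = leak_R, sample_neuron = as.integer(sample_neuron),
                 seed = as.integer(seed)),
            class = "network_params")
}

#' Build the network state
#'
#' Draws the heterogeneous neuron parameters and the random coupling matrix
#' under `params$seed`. Excitatory neurons: \eqn{a = 0.02}, \eqn{b = 0.2},
#' \eqn{c = -65 + 15 r^2}, \eqn{d = 8 - 6 r^2} with \eqn{r \sim U(0,1)}
#' (regular spiking at r = 0, chattering at r = 1). Inhibitory neurons:
#' \eqn{a = 0.02 + 0.08 r}, \eqn{b = 0.25 - 0.05 r}, \eqn{c = -65},
#' \eqn{d = 2} (fast spiking). Weights: column j of `W` is neuron j's
#' projection, uniform in \eqn{[0, 0.5]} for excitatory and
#' \eqn{[-1, 0] \times} `inhibitory_scale` for inhibitory neurons, times a
#' size correction \eqn{1000/N} that keeps the summed synaptic input per
#' neuron at the reference scheme's level (defined at N = 1000) as the
#' population grows; without it the 2,000-neuron network saturates into
#' runaway firing in both regimes.
#'
#' @param params a [network_params()] object.
#' @return An object of class `population_state` with fields `v`, `u`,
#'   `a`, `b`, `c`, `d`, `W` and (MC variant) `phi`.
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "network_params"))
  set.seed(params$seed)
  Ne <- params$N_exc; Ni <- params$N_inh; N <- params$N
  re <- stats::runif(Ne); ri <- stats::runif(Ni)
  a <- c(rep(0.02, Ne), 0.02 + 0.08 * ri)
  b <- c(rep(0.2, Ne), 0.25 - 0.05 * ri)
  cc <- c(-65 + 15 * re^2, rep(-65, Ni))
  d <- c(8 - 6 * re^2, rep(2, Ni))
  W <- (1000 / N) *
    cbind(matrix(0.5 * stats::runif(N * Ne), N, Ne),
          -params$inhibitory_scale * matrix(stats::runif(N * Ni), N, Ni))
  v <- rep(-65, N)
  structure(list(v = v, u = b * v, a = a, b = b, c = cc, d = d, W = W,
                 phi = rep(0, N)),
            class = "population_state")
}

#' Run the spiking network
#'
#' Advances the population for `params$T` ms in 1 ms outer steps: fresh
#' Gaussian thalamic drive each step (s.d. `drive_exc` for excitatory,
#' `drive_inh` for inhibitory neurons, times `drive_gain`), spike detection
#' at `spike_cut` with reset \eqn{v \leftarrow c}, \eqn{u \leftarrow u + d},
#' synaptic input as the row sums of `W` over the neurons that fired, and
#' two 0.5 ms half-steps of the quadratic membrane update (recovery `u`
#' updated once per ms). In the `izhikevich_mc` variant each neuron's flux
#' is advanced from its membrane potential and the memristive leak is
#' applied as an exact exponential decay factor
#' \eqn{e^{-\Delta t/(M(\varphi) C_m)}} per half-step (explicit stepping of
#' this term would be unstable in the low-resistance state); the flux is
#' clamped to the interval over which the reconciled memristance law varies.
#'
#' Recorded quantities are clipped at `spike_cut`, so any run containing a
#' spike has a maximum recorded potential of exactly `spike_cut` (30 mV).
#'
#' @param state a [build_network()] population state.
#' @param params the matching [network_params()].
#' @return An object of class `spike_raster`: a list with `spikes` (data frame
#'   `t_ms`, `neuron`), `trace` (clipped potential of `sample_neuron`),
#'   `n_spikes`, `max_v` (maximum clipped recorded potential over all
#'   neurons and steps), and the run parameters.
#' @export
run_network <- function(state, params) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "network_params"))
  set.seed(params$seed + 1L)
  Ne <- params$N_exc; Ni <- params$N_inh; N <- params$N
  v <- state$v; u <- state$u
  a <- state$a; b <- state$b; cc <- state$c; d <- state$d
  W <- state$W
  mc <- params$membrane_variant == "izhikevich_mc"
  if (mc) {
    mp <- params$memristor
    phi <- state$phi
    s_rec <- (mp$M0 - mp$M_on) / mp$phi_high
    phi_lo <- (mp$M0 - mp$M_off) / s_rec   # below this M is clamped at M_off
    phi_hi <- mp$phi_high
  }
  n_steps <- as.integer(round(params$T / params$dt))
  spike_t <- vector("list", n_steps)
  spike_id <- vector("list", n_steps)
  trace <- numeric(n_steps)
  max_v <- -Inf
  cut <- params$spike_cut
  for (step in seq_len(n_steps)) {
    t_now <- step * params$dt
    I <- params$drive_gain *
      c(params$drive_exc * stats::rnorm(Ne), params$drive_inh * stats::rnorm(Ni))
    fired <- which(v >= cut)
    # record before reset, clipped at the spike cut
    trace[step] <- min(v[params$sample_neuron], cut)
    max_v <- max(max_v, min(max(v), cut))
    if (length(fired)) {
      spike_t[[step]] <- rep(t_now, length(fired))
      spike_id[[step]] <- fired
      v[fired] <- cc[fired]
      u[fired] <- u[fired] + d[fired]
      I <- I + rowSums(W[, fired, drop = FALSE])
    }
    half <- params$dt / 2
    for (h in 1:2) {
      v <- v + half * (0.04 * v^2 + 5 * v + 140 - u + I)
      if (mc) {
        M <- pmin(pmax(mp$M0 - s_rec * phi, mp$M_on), mp$M_off)
        v <- v * exp(-half * 1e-3 / (M * params$C_m))
        phi <- phi + mp$flux_scale * (v * 1e-3) * (half * 1e-3)
        phi <- pmin(pmax(phi, phi_lo), phi_hi)
      } else if (!is.null(params$leak_R)) {
        v <- v * exp(-half * 1e-3 / (params$leak_R * params$C_m))
      }
    }
    u <- u + a * (b * v - u)
    if (!all(is.finite(v)))
      stop("membrane potential diverged at step ", step)
  }
  spikes <- data.frame(t_ms = unlist(spike_t), neuron = unlist(spike_id))
  if (nrow(spikes) == 0L)
    spikes <- data.frame(t_ms = numeric(0), neuron = integer(0))
  structure(list(spikes = spikes,
                 trace = data.frame(t_ms = seq_len(n_steps) * params$dt,
                                    v_mV = trace),
                 n_spikes = nrow(spikes),
                 max_v = if (is.finite(max_v)) max_v else NA_real_,
                 params = params),
            class = "spike_raster")
}

#' Population synchrony index
#'
#' Variance-of-population-rate statistic: spike counts are binned per
#' neuron in windows of `bin` ms and the index is
#' \deqn{\chi^2 = \frac{\mathrm{Var}(\bar n(t))}{\langle \mathrm{Var}(n_i(t)) \rangle_i}}
#' the variance of the population-mean binned rate over the mean
#' single-neuron binned-rate variance. Independent (asynchronous) firing
#' gives an index near the finite-size floor \eqn{1/N}; coherent firing,
#' where many neurons share bins, gives a much larger value. The index is
#' non-negative, invariant to neuron relabeling, and defined as 0 for an
#' empty raster.
#'
#' @param raster a [run_network()] result.
#' @param bin bin width, ms; the run must cover at least 10 bins.
#' @return Dimensionless synchrony score.
#' @export
synchrony_index <- function(raster, bin = 10) {
  stopifnot(inherits(raster, "spike_raster"))
  params <- raster$params
  if (params$T < 10 * bin) stop("run too short: need T >= 10*bin")
  if (nrow(raster$spikes) == 0L) return(0)
  n_bins <- as.integer(floor(params$T / bin))
  b_idx <- pmin(as.integer(floor(raster$spikes$t_ms / bin)) + 1L, n_bins)
  counts <- matrix(0L, params$N, n_bins)
  tab <- table(factor(raster$spikes$neuron, levels = seq_len(params$N)),
               factor(b_idx, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  pop_rate <- colMeans(counts)
  per_neuron_var <- apply(counts, 1, stats::var)
  denom <- mean(per_neuron_var)
  if (denom == 0) return(0)
  stats::var(pop_rate) / denom
}

#' @export
print.spike_raster <- function(x, ...) {
  p <- x$params
  cat(sprintf("Spiking-network raster: %d+%d neurons (%s), %g ms, inh scale %g\n",
              p$N_exc, p$N_inh, p$membrane_variant, p$T, p$inhibitory_scale))
  cat(sprintf("  %d spikes, max recorded potential %.4g mV\n",
              x$n_spikes, x$max_v))
  invisible(x)
}

#' @export
plot.spike_raster <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$spikes$t_ms, x$spikes$neuron, pch = ".",
                 xlab = "t (ms)", ylab = "neuron", ...)
  graphics::plot(x$trace$t_ms, x$trace$v_mV, type = "l",
                 xlab = "t (ms)", ylab = "v (mV)", col = "steelblue")
  invisible(x)
}
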