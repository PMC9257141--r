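#' Experiment presets
#'
#' Canonical run configurations for the reproduced experiments: RC/MC
#' charge and discharge transients, the hysteresis loop, the step,
#' pulse-train and single-pulse membrane drives, and the four network
#' regimes (RC/MC x asynchronous/synchronous).
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() names(.presets)

.presets <- list(
  fig1d  = list(experiment = "hysteresis",
                amplitude = 100, frequency = 50, cycles = 3),
  fig3   = list(experiment = "charge", E = 100, C = 1e-6, R = 1e3,
                T = 6, dt = 0.001),
  fig4   = list(experiment = "charge", E = 100, C = 1e-6,
                leak = "memristor", phi0 = 0.25, T = 0.6, dt = 1e-4),
  fig5   = list(experiment = "discharge", C = 1e-6, R = 1e3, V_C0 = 100,
                T = 6, dt = 0.001),
  fig6   = list(experiment = "discharge", C = 1e-6, leak = "memristor",
                phi0 = 0.25, V_C0 = 100, T = 0.6, dt = 1e-4),
  fig7   = list(experiment = "step_response", C = 1e-6, R = 1e4,
                stimulus = list(kind = "step", amplitude = 10, onset = 3,
                                width = 30, duration = 40)),
  fig8   = list(experiment = "pulse_train", C = 1e-6, R = 1e4,
                stimulus = list(kind = "pulse_train", amplitude = 10,
                                count = 16, duration = 100)),
  fig9   = list(experiment = "pulse_train", C = 1e-6, R = 1e4,
                stimulus = list(kind = "pulse_train", amplitude = 10,
                                count = 16, duration = 1000)),
  fig10  = list(experiment = "pulse_train", C = 1e-6, R = 1e4,
                stimulus = list(kind = "pulse_train", amplitude = 10,
                                count = 38, duration = 1000)),
  fig11  = list(experiment = "pulse_train", C = 1e-6, R = 1e4,
                stimulus = list(kind = "pulse_train", amplitude = 10,
                                count = 4, duration = 20)),
  fig12  = list(experiment = "pulse_train", C = 1e-6, R = 1e4,
                stimulus = list(kind = "pulse_train", amplitude = 10,
                                count = 4, duration = 1000)),
  fig13  = list(experiment = "single_pulse", C = 1e-6, R = 1e4,
                stimulus = list(kind = "single_pulse", amplitude = 10,
                                width = 10, duration = 20)),
  fig14  = list(experiment = "single_pulse", C = 1e-6, R = 1e4,
                stimulus = list(kind = "single_pulse", amplitude = 10,
                                width = 500, duration = 1000)),
  fig15a = list(experiment = "network", variant = "izhikevich",
                inhibitory_scale = 1),
  fig15b = list(experiment = "network", variant = "izhikevich_mc",
                inhibitory_scale = 1),
  fig15c = list(experiment = "network", variant = "izhikevich",
                inhibitory_scale = 0.01),
  fig15d = list(experiment = "network", variant = "izhikevich_mc",
                inhibitory_scale = 0.01)
)

.experiments <- c("charge", "discharge", "step_response", "pulse_train",
                  "single_pulse", "hysteresis", "network")

#' Build a run configuration
#'
#' Assembles and validates the configuration for [run_experiment()], either
#' from a named preset (possibly with overrides) or from scratch.
#'
#' @param experiment one of `"charge"`, `"discharge"`, `"step_response"`,
#'   `"pulse_train"`, `"single_pulse"`, `"hysteresis"`, `"network"`.
#' @param preset optional preset name (see [list_presets()]); remaining
#'   arguments override preset fields.
#' @param seed integer seed.
#' @param ... experiment-specific fields (circuit parameters, `stimulus`
#'   list, solver settings).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(experiment = NULL, preset = NULL, seed = 1L, ...) {
  cfg <- list(...)
  if (!is.null(preset)) {
    if (!preset %in% names(.presets)) stop("unknown preset: ", preset)
    base <- .presets[[preset]]
    cfg <- utils::modifyList(base, cfg)
    cfg$preset <- preset
  }
  if (!is.null(experiment)) cfg$experiment <- experiment
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks experiment-specific required fields before any computation and
#' reports every offending field in one error.
#'
#' @param cfg a configuration list.
#' @return The validated config, classed `run_config`.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  if (is.null(cfg$experiment) || !cfg$experiment %in% .experiments)
    stop("config error: 'experiment' must be one of ",
         paste(.experiments, collapse = ", "))
  ex <- cfg$experiment
  if (ex %in% c("charge", "discharge")) {
    if (identical(cfg$leak, "memristor")) {
      if (is.null(cfg$phi0)) bad <- c(bad, "phi0")
    } else if (is.null(cfg$R)) bad <- c(bad, "R")
    if (is.null(cfg$C)) bad <- c(bad, "C")
    if (is.null(cfg$T)) bad <- c(bad, "T")
    if (ex == "discharge" && is.null(cfg$V_C0)) bad <- c(bad, "V_C0")
  }
  if (ex %in% c("step_response", "pulse_train", "single_pulse")) {
    if (is.null(cfg$stimulus)) bad <- c(bad, "stimulus")
    if (is.null(cfg$C)) bad <- c(bad, "C")
  }
  if (ex == "hysteresis") {
    if (is.null(cfg$amplitude)) bad <- c(bad, "amplitude")
    if (is.null(cfg$frequency)) bad <- c(bad, "frequency")
  }
  if (length(bad))
    stop("config error: missing required field(s): ",
         paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Run a configured experiment
#'
#' Executes the experiment described by a [run_config()] and, when
#' `out_dir` is given, writes the trace/raster CSV, a JSON summary, the
#' echoed config, and a manifest listing every file written with its MD5
#' checksum. Outputs are deterministic for a fixed config and seed.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional output directory (created if needed).
#' @return A list with the computed `result` (trace or raster), a
#'   `summary` list, and (if written) the `manifest` data frame.
#' @examples
#' res <- run_experiment(run_config(preset = "fig3"))
#' round(res$result$V_C_mV[res$result$t_ms == 1])  # 63 mV at t = tau
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  cfg <- validate_config(unclass(cfg))
  ex <- cfg$experiment
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  result <- switch(ex,
    charge = ,
    discharge = {
      memr <- identical(cfg$leak, "memristor")
      circ <- series_circuit(
        E = if (is.null(cfg$E)) 100 else cfg$E, C = cfg$C,
        R = if (memr) 1e3 else cfg$R,
        memristor = if (memr) memristor_params(
          if (is.null(cfg$mode)) "reconciled" else cfg$mode) else NULL,
        phi0 = if (is.null(cfg$phi0)) 0 else cfg$phi0,
        V_C0 = if (ex == "discharge") cfg$V_C0 else 0)
      t <- seq(0, cfg$T, by = cfg$dt)
      if (ex == "charge") {
        if (memr) mc_charge(circ, t) else rc_charge(circ, t)
      } else {
        if (memr) mc_discharge(circ, t) else rc_discharge(circ, t)
      }
    },
    step_response = ,
    pulse_train = ,
    single_pulse = {
      st <- do.call(stimulus, cfg$stimulus)
      memr <- identical(cfg$leak, "memristor")
      circ <- membrane_circuit(
        C = cfg$C, R = if (memr) 1e4 else cfg$R,
        memristor = if (memr) memristor_params() else NULL,
        phi0 = if (is.null(cfg$phi0)) 0 else cfg$phi0)
      dt <- if (is.null(cfg$dt)) 0.01 else cfg$dt
      tr <- integrate_membrane(circ, st, dt = dt,
                               method = if (is.null(cfg$method)) "euler"
                                        else cfg$method)
      attr(tr, "label") <- classify_response(tr, circ)
      tr
    },
    hysteresis = {
      iv_hysteresis(cfg$amplitude, cfg$frequency,
                    cycles = if (is.null(cfg$cycles)) 3 else cfg$cycles)
    },
    network = {
      p <- network_params(
        N_exc = if (is.null(cfg$N_exc)) 1600 else cfg$N_exc,
        N_inh = if (is.null(cfg$N_inh)) 400 else cfg$N_inh,
        T = if (is.null(cfg$T)) 2000 else cfg$T,
        inhibitory_scale = if (is.null(cfg$inhibitory_scale)) 1
                           else cfg$inhibitory_scale,
        membrane_variant = if (is.null(cfg$variant)) "izhikevich"
                           else cfg$variant,
        seed = seed)
      run_network(build_network(p), p)
    })
  summary <- .summarize_result(ex, result)
  out <- list(result = result, summary = summary, config = cfg)
  if (!is.null(out_dir)) out$manifest <- .write_outputs(cfg, result, summary,
                                                        out_dir)
  out
}

.summarize_result <- function(ex, result) {
  if (inherits(result, "spike_raster")) {
    list(experiment = ex, n_spikes = result$n_spikes,
         synchrony_index = synchrony_index(result), max_v = result$max_v)
  } else if (inherits(result, "membrane_trace")) {
    lab <- attr(result, "label")
    list(experiment = ex, label = as.character(lab),
         n_peaks = attr(lab, "n_peaks"), V_max = attr(lab, "V_max"))
  } else if (inherits(result, "transient_trace")) {
    list(experiment = ex, direction = attr(result, "direction"),
         V_C_final = result$V_C_mV[nrow(result)],
         tau_ms = attr(result, "circuit")$tau_ms)
  } else {
    list(experiment = ex, n_samples = nrow(result))
  }
}

.write_outputs <- function(cfg, result, summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  trace_path <- file.path(out_dir, "trace.csv")
  if (inherits(result, "spike_raster")) {
    utils::write.csv(result$spikes, file.path(out_dir, "raster.csv"),
                     row.names = FALSE)
    utils::write.csv(result$trace, trace_path, row.names = FALSE)
    files <- c(files, file.path(out_dir, "raster.csv"), trace_path)
  } else {
    write_trace_csv(result, trace_path)
    files <- c(files, trace_path)
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  config_path <- file.path(out_dir, "config.json")
  write_config(cfg, config_path)
  files <- c(files, summary_path, config_path)
  prov <- list(package = "memneuro",
               version = as.character(utils::packageVersion("memneuro")),
               config_md5 = unname(tools::md5sum(config_path)))
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE)
  files <- c(files, prov_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Write / read a trace as CSV
#'
#' Traces round-trip through CSV at full double precision (15 significant
#' digits), so a re-read trace equals the in-memory one to at least 12
#' significant digits.
#'
#' @param trace a `transient_trace`, `membrane_trace` or
#'   `hysteresis_trace`.
#' @param path file path.
#' @return `read_trace_csv` returns a plain data frame.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(lapply(trace, function(col)
    if (is.numeric(col)) signif(col, 15) else col))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) utils::read.csv(path)

#' Write / read a run configuration as JSON
#'
#' Configurations round-trip: `read_config(write_config(cfg))` re-parses to
#' an equal object.
#'
#' @param cfg a [run_config()] (or plain list).
#' @param path file path.
#' @return `read_config` returns the validated `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Generate the canonical fixture set
#'
#' Writes one JSON config per reproduced experiment preset plus three small
#' randomized stimulus/circuit configs for property tests. Byte-stable
#' under a fixed seed.
#'
#' @param seed integer seed for the randomized configs.
#' @param dir output directory.
#' @return Character vector of the files written (invisibly).
#' @export
generate_fixtures <- function(seed = 1L, dir = tempdir()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(.presets)) {
    cfg <- run_config(preset = nm, seed = seed)
    p <- file.path(dir, paste0(nm, ".json"))
    write_config(cfg, p)
    files <- c(files, p)
  }
  set.seed(seed)
  for (k in 1:3) {
    cfg <- run_config(
      experiment = "pulse_train", seed = seed,
      C = 1e-6, R = round(stats::runif(1, 5e3, 2e4)),
      stimulus = list(kind = "pulse_train",
                      amplitude = round(stats::runif(1, 5, 20), 1),
                      count = sample(2:40, 1),
                      duration = sample(c(100, 500, 1000), 1)))
    p <- file.path(dir, sprintf("random%d.json", k))
    write_config(cfg, p)
    files <- c(files, p)
  }
  invisible(files)
}
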