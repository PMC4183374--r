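# Seeded fixture generation, spike-train / trace input-output, run
# manifests and the figure-protocol orchestration.

# evaluate expr under a temporary R RNG seed, restoring the prior state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Seeded homogeneous Poisson spike train
#'
#' @param rate firing rate (spikes/s), nonnegative.
#' @param duration train length (s), positive.
#' @param seed RNG seed; R's global RNG state is saved and restored.
#' @return Sorted vector of spike times in `[0, duration)`.
#' @examples
#' tr <- generate_poisson_train(1, 100, seed = 42)
#' @export
generate_poisson_train <- function(rate, duration, seed = 1) {
  if (rate < 0) stop("rate must be nonnegative")
  if (duration <= 0) stop("duration must be positive")
  if (rate == 0) return(numeric(0))
  with_local_seed(seed, {
    n <- stats::rpois(1, rate * duration)
    sort(stats::runif(n, 0, duration))
  })
}

#' Read and write spike trains as two-column text
#'
#' Spike data are exchanged as whitespace-delimited text with columns
#' `time_s` and `neuron_id`.
#'
#' @param raster data frame with columns `time` and `neuron` (a plain
#'   vector of times is written with neuron id 0).
#' @param path file path.
#' @return `write_spike_train` invisibly returns `path`;
#'   `read_spike_train` returns a data frame with columns `time`,
#'   `neuron`.
#' @export
write_spike_train <- function(raster, path) {
  if (is.numeric(raster))
    raster <- data.frame(time = raster, neuron = 0L)
  utils::write.table(data.frame(time_s = raster$time,
                                neuron_id = raster$neuron),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("time", "neuron"))
  d
}

#' Write an efficacy or rate trace as CSV
#'
#' @param trace data frame (first column time in seconds).
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Every orchestrated run emits a manifest capturing the command, the full
#' configuration echo, all seeds, the package version, any desk-scale
#' substitutions applied, and the list of output files, so that re-running
#' the manifest reproduces all stochastic outputs bit for bit.
#'
#' @param command the command or protocol name.
#' @param config named list echoing the full configuration.
#' @param seed the seed(s) used.
#' @param substitutions character vector describing scale substitutions
#'   applied (empty if none).
#' @param outputs character vector of output file paths.
#' @param path optional path to write the manifest as JSON text.
#' @return The manifest list (invisibly if written).
#' @export
run_manifest <- function(command, config, seed, substitutions = character(),
                         outputs = character(), path = NULL) {
  man <- list(command = command, config = config, seed = seed,
              package_version =
                as.character(utils::packageVersion("casynapse")),
              substitutions = substitutions, outputs = outputs)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}

#' Run a canned experiment protocol
#'
#' Orchestrates the package's main experiments at desk scale:
#' * `fig2`: flat-potential ensemble decay at a given rate with
#'   exponential fit and truncated-OU theory overlay;
#' * `fig3`: bistable analysis (bifurcation rate, effective landscape and
#'   Kramers escape time at the requested rate);
#' * `fig5_scaled`: memory-implant experiment in the scaled recurrent
#'   network (flat potential);
#' * `fig6_scaled`: scaled in-vivo double-well network run reporting
#'   well-to-well transition counts.
#'
#' @param figure_id one of `"fig2"`, `"fig3"`, `"fig5_scaled"`,
#'   `"fig6_scaled"`.
#' @param overrides named list overriding protocol defaults (`preset`,
#'   `potential`, `rate`, `duration`, `n`, `net`, ...).
#' @param seed RNG seed.
#' @param out_dir optional output directory; when given, traces (CSV),
#'   summaries (JSON) and the manifest are written there.
#' @return The result bundle (named list); invisibly when written.
#' @export
run_figure_protocol <- function(figure_id, overrides = list(), seed = 1,
                                out_dir = NULL) {
  known <- c("fig2", "fig3", "fig5_scaled", "fig6_scaled")
  if (!figure_id %in% known)
    stop("unknown figure id '", figure_id, "'; known: ",
         paste(known, collapse = ", "))
  ov <- function(name, default)
    if (!is.null(overrides[[name]])) overrides[[name]] else default
  subs <- character()
  bundle <- switch(figure_id,
    fig2 = {
      preset <- ov("preset", "in_vitro")
      rate <- ov("rate", 1)
      p <- ca_preset(preset, potential = "flat")
      theory <- ou_summary(rate, rate, p)
      dur <- ov("duration", min(5 * theory$tau_eff, 1800))
      if (dur < 5 * theory$tau_eff)
        subs <- c(subs, sprintf(
          "duration capped at %g s (< 5 tau_theory)", dur))
      cfg <- experiment_config(rate, rate, dur, ov("n", 1000), seed)
      out <- run_decay_experiment(cfg, p)
      list(preset = preset, rate = rate, trace = out$trace,
           tau_fit = out$fit$tau_fit, tau_theory = theory$tau_eff,
           asymptote_fit = out$fit$asymptote_fit,
           rho_bar_theory = theory$rho_bar)
    },
    fig3 = {
      preset <- ov("preset", "in_vivo")
      rate <- ov("rate", 1)
      p <- ca_preset(preset, potential = "double_well")
      nu_c <- bifurcation_rate(p)
      L <- effective_potential(rate, p)
      list(preset = preset, rate = rate, nu_c = nu_c,
           fixed_points = L$fixed_points, barrier_dU = L$barrier_dU,
           sigma_eff = L$sigma_eff, T_escape = L$T_escape)
    },
    fig5_scaled = {
      preset <- ov("preset", "in_vitro")
      p <- ca_preset(preset, potential = "flat")
      net <- ov("net", network_params())
      dur <- ov("duration", 300)
      subs <- c(subs, "scaled network (N = N_E + N_I) replaces the full-size net")
      mf <- solve_meanfield(net, p)
      exp5 <- memory_implant_experiment(net, p, dur,
                                        fraction = ov("fraction", 0.05),
                                        target_rate = mf$nu_E, seed = seed)
      list(preset = preset, duration = dur, meanfield = unclass(mf),
           rate_E = exp5$rate_E,
           tau_fit = if (!is.null(exp5$fit)) exp5$fit$tau_fit else NA,
           tau_theory = decay_time_constant(exp5$rate_E, exp5$rate_E, p),
           rho_traces = exp5$run$rho_traces, rates = exp5$run$rates)
    },
    fig6_scaled = {
      preset <- ov("preset", "in_vivo")
      p <- ca_preset(preset, potential = "double_well")
      net <- ov("net", network_params())
      dur <- ov("duration", 600)
      subs <- c(subs,
                "scaled network and 10 min run replace the 120 min full-size run")
      exp6 <- memory_implant_experiment(net, p, dur,
                                        fraction = ov("fraction", 0.05),
                                        seed = seed)
      list(preset = preset, duration = dur, rate_E = exp6$rate_E,
           transitions = exp6$run$transitions,
           rho_traces = exp6$run$rho_traces, rates = exp6$run$rates)
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character()
    for (nm in names(bundle)) {
      if (is.data.frame(bundle[[nm]])) {
        f <- file.path(out_dir, paste0(figure_id, "_", nm, ".csv"))
        write_trace_csv(bundle[[nm]], f)
        outputs <- c(outputs, f)
      }
    }
    scal <- bundle[!vapply(bundle, is.data.frame, logical(1))]
    sj <- file.path(out_dir, paste0(figure_id, "_summary.json"))
    jsonlite::write_json(scal, sj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    outputs <- c(outputs, sj)
    run_manifest(paste0("run_figure_protocol:", figure_id),
                 config = overrides, seed = seed, substitutions = subs,
                 outputs = outputs,
                 path = file.path(out_dir, paste0(figure_id,
                                                  "_manifest.json")))
    return(invisible(bundle))
  }
  bundle
}
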