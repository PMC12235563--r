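# Multi-trial experiment execution: dipole ensembles, spike rasters, and
# population-mean spike rates.

#' Run a multi-trial experiment
#'
#' Runs `n_trials` independent trials that differ only through the Gaussian
#' jitter of the drive times (trial k uses seed `base_seed + k`). Each
#' trial's dipole is scaled and smoothed per the configuration; the
#' trial-mean is the pointwise mean of the per-trial traces (smoothing is
#' applied per trial, before averaging).
#'
#' @param config A `somasim_experiment` (see [get_experiment()] /
#'   [experiment_config()]).
#' @param network Optional pre-built network (rebuilt from
#'   `config$network` when NULL).
#' @param settle_ms Drive-free settling run used to bring the network to
#'   its resting steady state before each trial (computed once, reused
#'   across trials).
#' @param progress Print per-trial progress to stderr.
#' @return Object of class `somasim_ensemble`: `trials` (list of
#'   `somasim_dipole`), `mean` (trial-mean `somasim_dipole`), `raster`
#'   (data.frame trial/cell/population/spike_time_ms), `config`.
#' @export
run_experiment <- function(config, network = NULL, progress = FALSE,
                           settle_ms = 100) {
  stopifnot(inherits(config, "somasim_experiment"))
  if (is.null(network)) network <- build_network(config$network)
  no_events <- expand_drive_events(network, list())
  rest <- if (settle_ms > 0)
    integrate_network(network, no_events, settle_ms, config$dt)$state
  else NULL
  trials <- vector("list", config$n_trials)
  rasters <- vector("list", config$n_trials)
  for (k in seq_len(config$n_trials)) {
    seed <- config$base_seed + k
    tryCatch({
      ev <- expand_drive_events(network, config$drives, trial_seed = seed)
      ev <- ev[ev$time < config$duration, , drop = FALSE]
      tr <- integrate_network(network, ev, config$duration, config$dt,
                              init = rest)
      dip <- compute_dipole(tr)
      # baseline-correct each layer to its resting (pre-drive) level, as
      # evoked responses are referenced to the prestimulus baseline
      dip$layer2 <- dip$layer2 - dip$layer2[1]
      dip$layer5 <- dip$layer5 - dip$layer5[1]
      dip$aggregate <- dip$layer2 + dip$layer5
      dip <- scale_and_smooth(dip, config$scaling_factor,
                              config$smoothing_window)
      trials[[k]] <- dip
      rasters[[k]] <- if (nrow(tr$spikes)) data.frame(
        trial = k, cell_id = tr$spikes$cell,
        population = tr$spikes$population,
        spike_time_ms = tr$spikes$time
      ) else NULL
    }, error = function(e) {
      stop(sprintf("trial %d failed: %s", k, conditionMessage(e)),
           call. = FALSE)
    })
    if (progress)
      message(sprintf("[%s] trial %d/%d", config$name, k, config$n_trials))
  }
  mean_dip <- trials[[1]]
  if (config$n_trials > 1L) {
    mean_dip$aggregate <- rowMeans(vapply(trials, `[[`, mean_dip$aggregate,
                                          "aggregate"))
    mean_dip$layer2 <- rowMeans(vapply(trials, `[[`, mean_dip$layer2,
                                       "layer2"))
    mean_dip$layer5 <- rowMeans(vapply(trials, `[[`, mean_dip$layer5,
                                       "layer5"))
  }
  mean_dip$n_trials <- config$n_trials
  raster <- do.call(rbind, rasters[!vapply(rasters, is.null, TRUE)])
  if (is.null(raster))
    raster <- data.frame(trial = integer(0), cell_id = integer(0),
                         population = character(0),
                         spike_time_ms = numeric(0))
  structure(
    list(config = config, trials = trials, mean = mean_dip,
         raster = raster, network = network),
    class = "somasim_ensemble"
  )
}

#' Population-mean spike rate over time
#'
#' The average spike rate of a neuron of a given type: spikes are binned
#' over time and divided by (number of trials x population size x bin
#' width), giving rate in spikes/s. The integral of each population's rate
#' over the trial equals its total spike count per neuron per trial.
#'
#' @param ensemble A `somasim_ensemble`.
#' @param bin_ms Bin width (ms).
#' @return data.frame with columns `time_ms`, `population`, `rate_hz`.
#' @export
population_spike_rate <- function(ensemble, bin_ms = 1) {
  cfg <- ensemble$config
  breaks <- seq(0, cfg$duration + bin_ms, by = bin_ms)
  counts_pop <- table(ensemble$network$cells$population)
  out <- list()
  for (pop in POPULATIONS) {
    sp <- ensemble$raster$spike_time_ms[ensemble$raster$population == pop]
    h <- hist(sp, breaks = breaks, plot = FALSE)
    rate <- h$counts / (cfg$n_trials * counts_pop[[pop]] * bin_ms / 1000)
    out[[pop]] <- data.frame(time_ms = h$mids, population = pop,
                             rate_hz = rate)
  }
  do.call(rbind, out)
}

#' Write a spike raster TSV
#'
#' Columns: trial, cell_id, population, spike_time_ms.
#' @param raster data.frame as in `somasim_ensemble$raster`.
#' @param path Output file.
#' @export
write_spike_raster <- function(raster, path) {
  write.table(raster, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.somasim_ensemble <- function(x, ...) {
  cat(sprintf("somasim ensemble '%s': %d trials, %d ms, %d spikes total\n",
              x$config$name, x$config$n_trials, x$config$duration,
              nrow(x$raster)))
  invisible(x)
}
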