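# Experiment configuration serialization (JSON). Numbers are written at
# full precision so that read -> write -> read is an exact round trip.

drive_to_list <- function(d) {
  base <- unclass(d)
  base$weights <- lapply(base$weights, as.list)
  base
}

drive_from_list <- function(x) {
  weights <- lapply(x$weights, function(w) unlist(w))
  switch(x$kind,
    evoked = evoked_drive(x$name, x$location, x$mean_time, x$sd_time,
                          weights, x$seed_offset),
    burst = drive_burst(x$name, x$location, x$start_mean,
                        x$inter_drive_interval, x$count, x$sd_time,
                        weights, x$seed_offset),
    aperiodic = aperiodic_burst(x$name, x$location, unlist(x$window),
                                x$count, weights, x$synchronous,
                                x$seed_offset),
    stop("unknown drive kind: ", x$kind)
  )
}

#' Write an experiment configuration to JSON
#'
#' @param config A `somasim_experiment`.
#' @param path Output file.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$drives <- lapply(flatten_drives(config$drives), drive_to_list)
  net <- unclass(config$network)
  net$connection_table <- as.list(net$connection_table)
  x$network <- net
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an experiment configuration from JSON
#'
#' @param path File written by [write_experiment_config()].
#' @return A `somasim_experiment`.
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  drives <- lapply(x$drives, drive_from_list)
  netl <- x$network
  cp <- netl$cell_params
  for (pop in POPULATIONS) {
    for (f in c("compartments", "C", "gL", "g_couple", "apical_length")) {
      if (!is.null(cp[[pop]][[f]])) cp[[pop]][[f]] <- unlist(cp[[pop]][[f]])
    }
  }
  cp$Esyn <- unlist(cp$Esyn)
  net <- network_config(
    n_pyr_per_layer = netl$n_pyr_per_layer,
    n_basket_per_layer = netl$n_basket_per_layer,
    grid_spacing = netl$grid_spacing,
    space_constant = netl$space_constant,
    connection_table = as.data.frame(netl$connection_table,
                                     stringsAsFactors = FALSE),
    cell_params = cp
  )
  experiment_config(
    name = x$name, drives = drives, duration = x$duration,
    n_trials = x$n_trials, scaling_factor = x$scaling_factor,
    smoothing_window = x$smoothing_window, base_seed = x$base_seed,
    network = net, dt = x$dt
  )
}
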