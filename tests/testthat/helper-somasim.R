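# Small-network fixtures so unit tests integrate in milliseconds, plus a
# per-session cache for ensembles shared between acceptance checks.

tiny_config <- function(n_pyr = 16, n_basket = 5, ...) {
  network_config(n_pyr_per_layer = n_pyr, n_basket_per_layer = n_basket, ...)
}

tiny_network <- function(...) build_network(tiny_config(...))

# network with all local weights zero: cells respond only to drives
uncoupled_config <- function(n_pyr = 16, n_basket = 5) {
  tab <- connection_table_default()
  tab$weight <- 0
  tiny_config(n_pyr, n_basket, connection_table = tab)
}

single_drive_events <- function(network, location, time, weights,
                                trial_seed = 1L) {
  d <- evoked_drive("probe", location, time, 0, weights)
  expand_drive_events(network, d, trial_seed = trial_seed)
}

.somasim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.somasim_cache[[key]])) .somasim_cache[[key]] <- force(expr)
  .somasim_cache[[key]]
}
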