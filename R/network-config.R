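#' Default local connection table
#'
#' Base synaptic weights (maximal conductances, in microsiemens) for every
#' local connection in the column. Rows follow the convention that pyramidal
#' presynaptic populations are excitatory (AMPA/NMDA) and basket presynaptic
#' populations are inhibitory (GABA_A/GABA_B). The `target` column names the
#' postsynaptic compartment: excitation from pyramidal cells arrives at the
#' proximal apical dendrite of pyramidal targets and the soma of basket
#' targets; somatic inhibition targets the soma, except the L2/3 basket to
#' L5 pyramidal projection, which contacts the distal apical dendrite.
#'
#' @return A data.frame with columns `pre`, `post`, `receptor`, `weight`
#'   (uS), `target` (compartment), and `delay` (ms).
#' @export
connection_table_default <- function() {
  tab <- rbind(
    c("L2_pyramidal", "L2_pyramidal", "ampa",  2e-4,   "prox"),
    c("L2_pyramidal", "L2_pyramidal", "nmda",  2e-4,   "prox"),
    c("L2_pyramidal", "L5_pyramidal", "ampa",  2e-4,   "prox"),
    c("L2_pyramidal", "L2_basket",    "ampa",  5e-4,   "soma"),
    c("L2_pyramidal", "L5_basket",    "ampa",  2.5e-4, "soma"),
    c("L5_pyramidal", "L5_pyramidal", "ampa",  1e-3,   "prox"),
    c("L5_pyramidal", "L5_pyramidal", "nmda",  5e-4,   "prox"),
    c("L5_pyramidal", "L5_basket",    "ampa",  5e-4,   "soma"),
    c("L2_basket",    "L2_pyramidal", "gabaa", 5e-2,   "soma"),
    c("L2_basket",    "L2_pyramidal", "gabab", 5e-2,   "soma"),
    c("L2_basket",    "L5_pyramidal", "gabaa", 2e-3,   "dist"),
    c("L2_basket",    "L2_basket",    "gabaa", 2e-2,   "soma"),
    c("L5_basket",    "L5_pyramidal", "gabaa", 2e-2,   "soma"),
    c("L5_basket",    "L5_pyramidal", "gabab", 6e-2,   "soma"),
    c("L5_basket",    "L5_basket",    "gabaa", 2e-2,   "soma")
  )
  out <- data.frame(
    pre = tab[, 1], post = tab[, 2], receptor = tab[, 3],
    weight = as.numeric(tab[, 4]), target = tab[, 5], delay = 1,
    space_constant = NA_real_,
    stringsAsFactors = FALSE
  )
  # mutual basket inhibition is spatially tight: with the network-wide
  # fall-off the summed standing inhibition after a synchronous volley
  # silences the basket population for ~2 gamma cycles; the tight spread
  # tunes post-volley recovery to the ~25 ms GABA_A decay, so drives
  # spaced at the gamma period re-recruit the population while faster
  # spacings fall inside the suppressed window
  bb <- out$pre %in% BASKET_POPS & out$post %in% BASKET_POPS
  out$space_constant[bb] <- 1.2
  out
}

#' Default cell parameters
#'
#' Reduced cell models: three-compartment pyramidal cells (soma with fast
#' Na/K spiking conductances, passive proximal and distal apical
#' compartments coupled by an axial conductance strong enough for somatic
#' spikes to depolarize the dendrites) and single-compartment fast-spiking
#' basket cells. L5 pyramidal distal dendrites carry a slow depolarizing
#' (calcium-like) conductance. Units: capacitance nF, conductance uS,
#' potential mV, time ms. The apical length of L5 cells is twice that of
#' L2/3 cells so that the aggregate dipole is dominated by L5.
#'
#' Synaptic kinetics are dual-exponential per receptor; the decay constant
#' of GABA_A synapses onto basket cells (the basket-to-basket connections)
#' is 25 ms, setting the period of interneuron-generated gamma.
#'
#' @return Nested list of per-population biophysical parameters.
#' @export
cell_params_default <- function() {
  syn_pyr <- list(
    ampa  = list(rise = 0.5, decay = 5),
    nmda  = list(rise = 1,   decay = 20),
    gabaa = list(rise = 0.5, decay = 5),
    gabab = list(rise = 2,   decay = 45)
  )
  syn_basket <- syn_pyr
  syn_basket$gabaa$decay <- 25  # inhibitory-to-inhibitory decay constant
  pyr <- list(
    compartments = c("soma", "prox", "dist"),
    C = c(soma = 0.1, prox = 0.05, dist = 0.05),
    gL = c(soma = 0.005, prox = 0.005, dist = 0.005),
    EL = -65, gNa = 5, gK = 1,
    g_couple = c(soma_prox = 0.05, prox_dist = 0.05),
    apical_length = c(prox = 0.5, dist = 0.5),
    g_slow_dist = 0,
    synapses = syn_pyr
  )
  l5 <- pyr
  l5$apical_length <- c(prox = 1, dist = 1)
  l5$g_slow_dist <- 0.005
  basket <- list(
    compartments = "soma",
    C = c(soma = 0.05), gL = c(soma = 0.005),
    EL = -65, gNa = 5, gK = 1,
    synapses = syn_basket
  )
  list(
    L2_pyramidal = pyr, L5_pyramidal = l5,
    L2_basket = basket, L5_basket = basket,
    Esyn = c(ampa = 0, nmda = 0, gabaa = -80, gabab = -95),
    slow = list(E = 10, tau = 60, vmid = -40, k = 4)
  )
}

#' Create a network configuration
#'
#' @param n_pyr_per_layer Pyramidal cells per layer; must be a perfect
#'   square (arranged as a square grid). Default 100 (10 x 10).
#' @param n_basket_per_layer Basket cells per layer (default 35).
#' @param grid_spacing Distance between adjacent pyramidal grid positions.
#' @param space_constant Length constant (grid units) of the exponential
#'   synaptic weight fall-off with distance.
#' @param connection_table Local connections; see
#'   [connection_table_default()].
#' @param cell_params Biophysics; see [cell_params_default()].
#' @return Object of class `somasim_config`.
#' @export
network_config <- function(n_pyr_per_layer = 100,
                           n_basket_per_layer = 35,
                           grid_spacing = 1,
                           space_constant = 3,
                           connection_table = connection_table_default(),
                           cell_params = cell_params_default()) {
  cfg <- structure(
    list(
      n_pyr_per_layer = as.integer(n_pyr_per_layer),
      n_basket_per_layer = as.integer(n_basket_per_layer),
      grid_spacing = grid_spacing,
      space_constant = space_constant,
      connection_table = connection_table,
      cell_params = cell_params
    ),
    class = "somasim_config"
  )
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  if (cfg$n_pyr_per_layer <= 0 || cfg$n_basket_per_layer <= 0)
    stop("cell counts must be positive")
  side <- sqrt(cfg$n_pyr_per_layer)
  if (side != round(side))
    stop("n_pyr_per_layer must be a perfect square (grid layout)")
  if (cfg$space_constant <= 0) stop("space_constant must be positive")
  tab <- cfg$connection_table
  req <- c("pre", "post", "receptor", "weight", "target", "delay")
  if (is.null(tab$space_constant)) tab$space_constant <- NA_real_
  if (!all(req %in% names(tab)))
    stop("connection_table must have columns: ", paste(req, collapse = ", "))
  bad_pop <- setdiff(unique(c(tab$pre, tab$post)), POPULATIONS)
  if (length(bad_pop))
    stop("unknown population in connection_table: ",
         paste(bad_pop, collapse = ", "))
  if (any(tab$weight < 0)) {
    i <- which(tab$weight < 0)[1]
    stop(sprintf("negative weight for connection %s -> %s (%s)",
                 tab$pre[i], tab$post[i], tab$receptor[i]))
  }
  key <- paste(tab$pre, tab$post, tab$receptor)
  if (anyDuplicated(key))
    stop("duplicate (pre, post, receptor) entry: ", key[duplicated(key)][1])
  exc <- tab$pre %in% PYR_POPS
  if (any(exc & !(tab$receptor %in% EXCITATORY_RECEPTORS)))
    stop("pyramidal presynaptic populations may only use AMPA/NMDA")
  if (any(!exc & !(tab$receptor %in% INHIBITORY_RECEPTORS)))
    stop("basket presynaptic populations may only use GABA_A/GABA_B")
  for (pop in POPULATIONS) {
    syn <- cfg$cell_params[[pop]]$synapses
    for (r in RECEPTORS) {
      k <- syn[[r]]
      if (!(k$decay > k$rise && k$rise > 0))
        stop(sprintf("synaptic kinetics for %s/%s must satisfy decay > rise > 0",
                     pop, r))
    }
  }
  invisible(cfg)
}

#' Synaptic weight under exponential spatial fall-off
#'
#' @param pre_pos,post_pos Numeric length-2 grid coordinates.
#' @param base_weight Weight at zero distance (uS).
#' @param space_constant Exponential length constant (grid units), > 0.
#' @return `base_weight * exp(-d / space_constant)` with `d` the Euclidean
#'   distance between the two positions.
#' @export
synaptic_weight <- function(pre_pos, post_pos, base_weight, space_constant) {
  if (space_constant <= 0) stop("space_constant must be positive")
  d <- sqrt(sum((pre_pos - post_pos)^2))
  base_weight * exp(-d / space_constant)
}
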