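# Network realization: cell positions, compartment bookkeeping, and the
# expanded synapse lists consumed by the compiled integrator.

grid_positions <- function(n, spacing, extent_side = NULL) {
  side <- ceiling(sqrt(n))
  if (is.null(extent_side)) extent_side <- side
  xs <- seq(0, (extent_side - 1) * spacing, length.out = side)
  pos <- expand.grid(x = xs, y = xs)
  pos[seq_len(n), , drop = FALSE]
}

#' Build a network from a configuration
#'
#' Realizes the column: places pyramidal cells of each layer on a square
#' grid (basket cells on a coarser lattice spanning the same extent) and
#' expands the connection table into per-pair synapses with weight
#' `base_weight * exp(-d / space_constant)`, where `d` is the planar
#' Euclidean distance between the pre- and postsynaptic cells.
#' Self-connections are excluded. Construction is deterministic: `seed` is
#' recorded for provenance but the wiring contains no random element.
#'
#' @param config A [network_config()].
#' @param seed Integer recorded in the network object.
#' @return Object of class `somasim_network`.
#' @export
build_network <- function(config, seed = 1L) {
  validate_network_config(config)
  npyr <- config$n_pyr_per_layer
  nbask <- config$n_basket_per_layer
  pyr_side <- sqrt(npyr)

  pos_pyr <- grid_positions(npyr, config$grid_spacing)
  pos_bask <- grid_positions(nbask, config$grid_spacing *
                               (pyr_side - 1) / max(1, ceiling(sqrt(nbask)) - 1))

  cells <- data.frame(
    cell_id = seq_len(2L * npyr + 2L * nbask),
    population = rep(POPULATIONS, c(npyr, npyr, nbask, nbask)),
    stringsAsFactors = FALSE
  )
  cells$x <- c(pos_pyr$x, pos_pyr$x, pos_bask$x, pos_bask$x)
  cells$y <- c(pos_pyr$y, pos_pyr$y, pos_bask$y, pos_bask$y)

  # compartments: pyramids soma/prox/dist, baskets soma only
  cp <- config$cell_params
  n_cell <- nrow(cells)
  comp_of <- matrix(NA_integer_, n_cell, 3,
                    dimnames = list(NULL, c("soma", "prox", "dist")))
  comp_pop <- character(0)
  comp_name <- character(0)
  idx <- 0L
  for (i in seq_len(n_cell)) {
    pop <- cells$population[i]
    comps <- cp[[pop]]$compartments
    for (cmp in comps) {
      idx <- idx + 1L
      comp_of[i, cmp] <- idx
      comp_pop <- c(comp_pop, pop)
      comp_name <- c(comp_name, cmp)
    }
  }
  n_comp <- idx

  C <- gL <- EL <- gNa <- gK <- gSlow <- numeric(n_comp)
  for (k in seq_len(n_comp)) {
    p <- cp[[comp_pop[k]]]
    cmp <- comp_name[k]
    C[k] <- p$C[[cmp]]
    gL[k] <- p$gL[[cmp]]
    EL[k] <- p$EL
    if (cmp == "soma") { gNa[k] <- p$gNa; gK[k] <- p$gK }
    if (cmp == "dist" && !is.null(p$g_slow_dist)) gSlow[k] <- p$g_slow_dist
  }

  # axial edges (soma->prox, prox->dist), oriented soma side first so that
  # positive axial current flows up the apical dendrite
  ea <- eb <- el <- integer(0); eg <- elen <- numeric(0)
  for (i in seq_len(n_cell)) {
    pop <- cells$population[i]
    if (!pop %in% PYR_POPS) next
    p <- cp[[pop]]
    layer <- if (pop == "L2_pyramidal") 1L else 2L
    ea <- c(ea, comp_of[i, "soma"], comp_of[i, "prox"])
    eb <- c(eb, comp_of[i, "prox"], comp_of[i, "dist"])
    eg <- c(eg, p$g_couple[["soma_prox"]], p$g_couple[["prox_dist"]])
    elen <- c(elen, p$apical_length[["prox"]], p$apical_length[["dist"]])
    el <- c(el, layer, layer)
  }

  # NMDA voltage dependence: pyramidal receptors carry the standard Mg
  # block; basket-cell NMDA (GluN2C/D-like) is treated as unblocked so the
  # slow excitatory component can sustain interneuron firing
  nmda_mg <- as.numeric(comp_pop %in% PYR_POPS)

  # synaptic kinetics per compartment x receptor
  tau_rise <- tau_fall <- matrix(0, n_comp, 4,
                                 dimnames = list(NULL, RECEPTORS))
  for (k in seq_len(n_comp)) {
    syn <- cp[[comp_pop[k]]]$synapses
    for (r in seq_along(RECEPTORS)) {
      tau_rise[k, r] <- syn[[RECEPTORS[r]]]$rise
      tau_fall[k, r] <- syn[[RECEPTORS[r]]]$decay
    }
  }

  # expanded local connectivity, CSR over presynaptic cells
  tab <- config$connection_table
  pre_cell <- post_state <- integer(0)
  w <- delay <- numeric(0)
  pop_cells <- split(seq_len(n_cell), cells$population)
  if (is.null(tab$space_constant)) tab$space_constant <- NA_real_
  for (j in seq_len(nrow(tab))) {
    pres <- pop_cells[[tab$pre[j]]]
    posts <- pop_cells[[tab$post[j]]]
    rix <- match(tab$receptor[j], RECEPTORS)
    tgt <- tab$target[j]
    lambda <- if (is.na(tab$space_constant[j])) config$space_constant
              else tab$space_constant[j]
    for (pc in pres) {
      ps <- posts[posts != pc]
      if (!length(ps)) next
      d <- sqrt((cells$x[pc] - cells$x[ps])^2 + (cells$y[pc] - cells$y[ps])^2)
      wt <- tab$weight[j] * exp(-d / lambda)
      pre_cell <- c(pre_cell, rep(pc, length(ps)))
      post_state <- c(post_state, (comp_of[ps, tgt] - 1L) * 4L + (rix - 1L))
      w <- c(w, wt)
      delay <- c(delay, rep(tab$delay[j], length(ps)))
    }
  }
  ord <- order(pre_cell)
  pre_cell <- pre_cell[ord]; post_state <- post_state[ord]
  w <- w[ord]; delay <- delay[ord]
  conn_ptr <- c(0L, cumsum(tabulate(pre_cell, nbins = n_cell)))

  structure(
    list(
      config = config, seed = as.integer(seed),
      cells = cells, comp_of = comp_of,
      comp_pop = comp_pop, comp_name = comp_name, n_comp = n_comp,
      C = C, gL = gL, EL = EL, gNa = gNa, gK = gK, gSlow = gSlow,
      slow_par = unlist(cp$slow, use.names = FALSE),
      Esyn = unname(cp$Esyn[RECEPTORS]),
      tau_rise = tau_rise, tau_fall = tau_fall, nmda_mg = nmda_mg,
      edge_a = ea, edge_b = eb, edge_g = eg, edge_len = elen,
      edge_layer = el,
      conn_ptr = conn_ptr, conn_target = post_state, conn_w = w,
      conn_delay = delay, cell_soma = comp_of[, "soma"]
    ),
    class = "somasim_network"
  )
}

#' @export
print.somasim_network <- function(x, ...) {
  cat("somasim network:", nrow(x$cells), "cells,", x$n_comp,
      "compartments,", length(x$conn_w), "local synapses\n")
  print(table(x$cells$population))
  invisible(x)
}

# state index (0-based, comp*4 + receptor) for a compartment/receptor pair
syn_state_index <- function(network, comp, receptor) {
  (comp - 1L) * 4L + (match(receptor, RECEPTORS) - 1L)
}
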