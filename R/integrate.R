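# Wrapper around the compiled fixed-step integrator.

dual_exp_norm <- function(tau_rise, tau_fall) {
  # peak-normalization so a unit event produces a unit-amplitude conductance
  tp <- tau_rise * tau_fall / (tau_fall - tau_rise) * log(tau_fall / tau_rise)
  1 / (exp(-tp / tau_fall) - exp(-tp / tau_rise))
}

#' Integrate the network given a synaptic event schedule
#'
#' Fixed-step integration (exponential Euler) of all compartments. The
#' returned state trace carries the raw (unscaled, unsmoothed) per-layer
#' dipole signal computed from pyramidal intracellular axial currents,
#' spike times, and optionally recorded membrane potentials and synaptic
#' conductances. Bitwise reproducible for identical inputs.
#'
#' @param network A [build_network()] result.
#' @param events Event schedule from [expand_drive_events()] (may have
#'   zero rows).
#' @param duration Simulation length (ms), > 0.
#' @param dt Time step (ms), default 0.025.
#' @param record_v Integer vector of compartment indices whose membrane
#'   potential is recorded (NULL for none).
#' @param record_g data.frame with columns `comp`, `receptor` naming
#'   synaptic conductances to record (NULL for none).
#' @param spike_threshold Somatic spike detection threshold (mV).
#' @param refractory Minimum inter-spike interval (ms).
#' @param vbound Divergence guard: integration aborts if |V| exceeds this
#'   (mV).
#' @param init Optional initial state (element `state` of a previous
#'   trace), e.g. a settled resting state; default: all compartments at
#'   their leak reversal with gating variables at steady state.
#' @return Object of class `somasim_trace` with elements `time`,
#'   `dipole_l2`, `dipole_l5` (raw model units), `spikes` (data.frame:
#'   cell, population, time), and optional `v`, `g` matrices.
#' @export
integrate_network <- function(network, events, duration, dt = 0.025,
                              record_v = NULL, record_g = NULL,
                              spike_threshold = 0, refractory = 3,
                              vbound = 150, init = NULL) {
  if (duration <= 0 || dt <= 0) stop("duration and dt must be > 0")
  if (nrow(events) && (any(events$time < 0) || any(events$time >= duration)))
    stop("all event times must lie within [0, duration)")
  n_steps <- as.integer(round(duration / dt))

  tr <- as.vector(t(network$tau_rise))
  tf <- as.vector(t(network$tau_fall))
  g_states <- if (is.null(record_g)) integer(0) else
    syn_state_index(network, record_g$comp, record_g$receptor)

  ord <- order(events$time)
  out <- integrate_cpp(list(
    C = network$C, gL = network$gL, EL = network$EL,
    gNa = network$gNa, gK = network$gK, gSlow = network$gSlow,
    slow_par = network$slow_par,
    edge_a = network$edge_a - 1L, edge_b = network$edge_b - 1L,
    edge_g = network$edge_g, edge_len = network$edge_len,
    edge_layer = network$edge_layer,
    decay_rise = exp(-dt / tr), decay_fall = exp(-dt / tf),
    syn_norm = dual_exp_norm(tr, tf),
    Esyn = network$Esyn, nmda_idx = 1L,
    nmda_mg = network$nmda_mg,
    ev_step = as.integer(floor(events$time[ord] / dt)),
    ev_state = as.integer(events$state[ord]),
    ev_w = as.numeric(events$weight[ord]),
    cell_soma = network$cell_soma - 1L,
    conn_ptr = network$conn_ptr,
    conn_target = network$conn_target,
    conn_w = network$conn_w,
    conn_delay = pmax(1L, as.integer(round(network$conn_delay / dt))),
    n_steps = n_steps, dt = dt, vbound = vbound,
    spike_threshold = spike_threshold,
    refractory_steps = as.integer(round(refractory / dt)),
    record_v = if (is.null(record_v)) integer(0) else as.integer(record_v - 1L),
    record_g = as.integer(g_states),
    init = init
  ))

  spikes <- data.frame(
    cell = out$spike_cell,
    population = network$cells$population[out$spike_cell],
    time = out$spike_time
  )
  structure(
    list(
      time = seq(0, by = dt, length.out = n_steps + 1L), dt = dt,
      dipole_l2 = out$dipole_l2, dipole_l5 = out$dipole_l5,
      spikes = spikes,
      v = if (length(record_v)) out$v else NULL,
      g = if (length(g_states)) out$g else NULL,
      state = out$state,
      n_cells = nrow(network$cells)
    ),
    class = "somasim_trace"
  )
}
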