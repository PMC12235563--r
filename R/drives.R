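# Exogenous proximal/distal drives: definition, per-trial sampling of
# synchronous spike times, and expansion into per-compartment event
# schedules.

PROXIMAL_TARGETS <- c("L2_pyramidal", "L5_pyramidal", "L2_basket", "L5_basket")
DISTAL_TARGETS <- c("L2_pyramidal", "L5_pyramidal", "L2_basket")

#' Define an evoked drive
#'
#' An exogenous excitatory synaptic drive whose single presynaptic spike
#' time per trial is sampled from a Gaussian and applied synchronously to
#' every targeted cell. Proximal drives contact the proximal apical
#' dendrites of L2/3 and L5 pyramidal cells and the somas of L2/3 and L5
#' basket cells; distal drives contact the distal apical dendrites of both
#' pyramidal populations and the somas of L2/3 basket cells only.
#'
#' @param name Drive label (e.g. "evprox_1").
#' @param location "proximal" or "distal".
#' @param mean_time,sd_time Gaussian mean and SD of the drive time (ms).
#' @param weights Named list, one entry per target population, each a named
#'   numeric vector with elements `ampa` and/or `nmda` (uS).
#' @param seed_offset Integer separating this drive's random stream from
#'   others sharing a trial seed.
#' @return Object of class `somasim_drive`.
#' @export
evoked_drive <- function(name, location = c("proximal", "distal"),
                         mean_time, sd_time, weights, seed_offset = 0L) {
  location <- match.arg(location)
  if (sd_time < 0) stop("sd_time must be >= 0")
  allowed <- if (location == "proximal") PROXIMAL_TARGETS else DISTAL_TARGETS
  bad <- setdiff(names(weights), allowed)
  if (length(bad))
    stop(sprintf("%s drive may not target: %s", location,
                 paste(bad, collapse = ", ")))
  for (pop in names(weights)) {
    w <- weights[[pop]]
    if (length(setdiff(names(w), EXCITATORY_RECEPTORS)))
      stop("drives are excitatory only (AMPA/NMDA)")
    if (any(w < 0)) stop("drive weights must be >= 0")
  }
  structure(
    list(name = name, kind = "evoked", location = location,
         mean_time = mean_time, sd_time = sd_time, weights = weights,
         seed_offset = as.integer(seed_offset)),
    class = "somasim_drive"
  )
}

#' Define a burst of repetitive drives
#'
#' A train of `count` evoked drives whose mean times form an arithmetic
#' progression `start_mean + k * inter_drive_interval`, all sharing the
#' same SD and weights (e.g. the 4-input, 25 ms inter-drive-interval distal
#' burst used for the laser-evoked N1).
#'
#' @inheritParams evoked_drive
#' @param start_mean Mean time (ms) of the first drive in the burst.
#' @param inter_drive_interval Spacing (ms) between successive mean times.
#' @param count Number of drives (>= 1).
#' @return Object of class `somasim_burst`.
#' @export
drive_burst <- function(name, location = c("proximal", "distal"),
                        start_mean, inter_drive_interval, count, sd_time,
                        weights, seed_offset = 0L) {
  location <- match.arg(location)
  if (count < 1) stop("count must be >= 1")
  if (inter_drive_interval <= 0) stop("inter_drive_interval must be > 0")
  structure(
    list(name = name, kind = "burst", location = location,
         start_mean = start_mean,
         inter_drive_interval = inter_drive_interval,
         count = as.integer(count), sd_time = sd_time, weights = weights,
         seed_offset = as.integer(seed_offset)),
    class = "somasim_burst"
  )
}

#' Expand a burst into individual evoked drives
#'
#' @param burst A [drive_burst()].
#' @return List of [evoked_drive()] objects with means
#'   `start_mean + (k - 1) * inter_drive_interval`, k = 1..count.
#' @export
expand_burst <- function(burst) {
  stopifnot(inherits(burst, "somasim_burst"))
  lapply(seq_len(burst$count), function(k) {
    evoked_drive(
      name = sprintf("%s_%d", burst$name, k),
      location = burst$location,
      mean_time = burst$start_mean + (k - 1) * burst$inter_drive_interval,
      sd_time = burst$sd_time, weights = burst$weights,
      seed_offset = burst$seed_offset + (k - 1L)
    )
  })
}

#' Define an aperiodic (uniformly sampled) burst
#'
#' Control configuration in which `count` drive times are sampled i.i.d.
#' uniformly over a window instead of at regular intervals. With
#' `synchronous = FALSE`, independent times are drawn for every targeted
#' cell (the asynchronous control).
#'
#' @inheritParams evoked_drive
#' @param window Length-2 numeric, sampling window (ms).
#' @param count Number of drive times per trial.
#' @param synchronous One time per drive shared by all cells (TRUE), or
#'   independent times per cell (FALSE).
#' @return Object of class `somasim_aperiodic`.
#' @export
aperiodic_burst <- function(name, location = c("proximal", "distal"),
                            window, count, weights, synchronous = TRUE,
                            seed_offset = 0L) {
  location <- match.arg(location)
  if (length(window) != 2 || window[2] < window[1])
    stop("window must be c(lo, hi) with hi >= lo")
  structure(
    list(name = name, kind = "aperiodic", location = location,
         window = window, count = as.integer(count), weights = weights,
         synchronous = isTRUE(synchronous),
         seed_offset = as.integer(seed_offset)),
    class = "somasim_aperiodic"
  )
}

drive_seed <- function(trial_seed, seed_offset) {
  # multiplicative scrambling so consecutive trial seeds (and drives within
  # a trial) map to well-separated generator seeds
  x <- (as.double(trial_seed) * 48271 +
          (as.double(seed_offset) + 1) * 16807) %% 2147483647
  as.integer(x)
}

#' Sample per-trial drive times
#'
#' For each drive, exactly one Gaussian sample (evoked drives) or `count`
#' uniform samples (aperiodic bursts) per trial. The same sampled time is
#' applied to every targeted cell. Sampling is deterministic for a given
#' (drive list, trial seed); distinct `seed_offset`s give independent
#' streams. Negative samples are clamped to 0 with a warning.
#'
#' @param drives List of drive objects (bursts are expanded first).
#' @param trial_seed Integer trial seed.
#' @return Named list of numeric time vectors, one element per drive.
#' @export
sample_drive_times <- function(drives, trial_seed) {
  drives <- flatten_drives(drives)
  out <- lapply(drives, function(d) {
    set.seed(drive_seed(trial_seed, d$seed_offset))
    t <- switch(d$kind,
      evoked = rnorm(1, d$mean_time, d$sd_time),
      aperiodic = if (d$synchronous)
        runif(d$count, d$window[1], d$window[2]) else numeric(0)
    )
    if (any(t < 0)) {
      warning(sprintf("drive '%s': %d sampled time(s) < 0 clamped to 0",
                      d$name, sum(t < 0)))
      t[t < 0] <- 0
    }
    t
  })
  names(out) <- vapply(drives, `[[`, "", "name")
  out
}

#' Sample drive times for an aperiodic burst window
#'
#' @param window Length-2 numeric window (ms).
#' @param count Number of times per trial (per cell if asynchronous).
#' @param trial_seed Integer seed.
#' @param synchronous If FALSE, an independent set of `count` times is
#'   drawn for each of `n_cells` cells.
#' @param n_cells Number of targeted cells (asynchronous mode only).
#' @return Numeric vector (`synchronous = TRUE`) or `count x n_cells`
#'   matrix.
#' @export
sample_aperiodic_burst <- function(window, count, trial_seed,
                                   synchronous = TRUE, n_cells = 1L) {
  if (length(window) != 2 || window[2] < window[1])
    stop("window must be c(lo, hi) with hi >= lo")
  set.seed(drive_seed(trial_seed, 0L))
  if (synchronous) {
    runif(count, window[1], window[2])
  } else {
    matrix(runif(count * n_cells, window[1], window[2]), nrow = count)
  }
}

flatten_drives <- function(drives) {
  if (inherits(drives, "somasim_drive") || inherits(drives, "somasim_burst") ||
      inherits(drives, "somasim_aperiodic"))
    drives <- list(drives)
  out <- list()
  for (d in drives) {
    if (inherits(d, "somasim_burst")) out <- c(out, expand_burst(d))
    else out <- c(out, list(d))
  }
  out
}

drive_target_table <- function(network, drive) {
  # returns data.frame(cell, comp) of targeted compartments per population
  cells <- network$cells
  allowed <- if (drive$location == "proximal") PROXIMAL_TARGETS else DISTAL_TARGETS
  out <- list()
  for (pop in intersect(names(drive$weights), allowed)) {
    ix <- which(cells$population == pop)
    # proximal drive contacts the basal/perisomatic input zone of the
    # pyramids (soma compartment of the reduced cell), so that excitation
    # initially pushes current up the apical dendrite; distal drive
    # contacts the distal apical compartment and pushes current down
    cmp <- if (pop %in% PYR_POPS) {
      if (drive$location == "proximal") "soma" else "dist"
    } else "soma"
    out[[pop]] <- data.frame(cell = ix, comp = network$comp_of[ix, cmp],
                             population = pop)
  }
  do.call(rbind, out)
}

#' Expand drives into a per-compartment synaptic event schedule
#'
#' @param network A built network.
#' @param drives List of drive objects.
#' @param times Output of [sample_drive_times()] for the same drives, or
#'   NULL to sample internally with `trial_seed`.
#' @param trial_seed Seed used when `times` is NULL and for per-cell
#'   sampling of asynchronous aperiodic drives.
#' @return data.frame with columns `time` (ms), `state` (0-based
#'   compartment x receptor state index), `weight` (uS), `drive`.
#' @export
expand_drive_events <- function(network, drives, times = NULL,
                                trial_seed = 1L) {
  drives <- flatten_drives(drives)
  if (is.null(times)) times <- sample_drive_times(drives, trial_seed)
  ev <- list()
  for (d in drives) {
    tgt <- drive_target_table(network, d)
    if (is.null(tgt) || !nrow(tgt)) next
    tvec <- times[[d$name]]
    async <- d$kind == "aperiodic" && !d$synchronous
    if (async) {
      set.seed(drive_seed(trial_seed, d$seed_offset))
      tmat <- matrix(runif(d$count * nrow(tgt), d$window[1], d$window[2]),
                     nrow = d$count)
    }
    for (pop in unique(tgt$population)) {
      rows <- tgt[tgt$population == pop, ]
      w <- d$weights[[pop]]
      for (r in intersect(names(w), EXCITATORY_RECEPTORS)) {
        if (w[[r]] <= 0) next
        st <- syn_state_index(network, rows$comp, r)
        if (async) {
          sel <- match(rows$cell, tgt$cell)
          ev[[length(ev) + 1L]] <- data.frame(
            time = as.vector(tmat[, sel, drop = FALSE]),
            state = rep(st, each = d$count),
            weight = w[[r]], drive = d$name
          )
        } else {
          ev[[length(ev) + 1L]] <- data.frame(
            time = rep(tvec, times = length(st)),
            state = rep(st, each = length(tvec)),
            weight = w[[r]], drive = d$name
          )
        }
      }
    }
  }
  if (!length(ev))
    return(data.frame(time = numeric(0), state = integer(0),
                      weight = numeric(0), drive = character(0)))
  out <- do.call(rbind, ev)
  out[order(out$time), , drop = FALSE]
}
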