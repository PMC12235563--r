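# One-at-a-time parameter sensitivity: per-time-point SD of the trial-mean
# dipole contributed by each swept parameter.

parse_param_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[2] == "mean_time")
    list(drive = parts[1], field = "mean_time")
  else if (length(parts) == 2 && parts[2] == "idi")
    list(drive = parts[1], field = "idi")
  else if (length(parts) == 3)
    list(drive = parts[1], field = "weight", pop = parts[2],
         receptor = parts[3])
  else stop("malformed parameter id: ", id,
            " (expected 'drive:mean_time', 'burst:idi', or",
            " 'drive:population:receptor')")
}

# apply an IDI value: reposition drives k >= 2 of the burst whose members
# are named <prefix>_k, keeping the first drive's mean as the anchor
apply_idi <- function(config, prefix, idi) {
  config$drives <- flatten_drives(config$drives)
  nm <- vapply(config$drives, `[[`, "", "name")
  members <- grep(paste0("^", prefix, "_[0-9]+$"), nm)
  if (length(members) < 2) stop("no burst named '", prefix, "' in config")
  members <- members[order(vapply(config$drives[members], `[[`, 0,
                                  "mean_time"))]
  anchor <- config$drives[[members[1]]]$mean_time
  for (k in seq_along(members))
    config$drives[[members[k]]]$mean_time <- anchor + (k - 1) * idi
  config
}

#' Sweep one parameter and measure dipole SD over time
#'
#' Runs `n_samples` simulations in which only the named parameter varies;
#' all other parameters, and the per-trial jitter seeds, are held fixed
#' (common random numbers), so the reported SD reflects parameter
#' variation alone. Conductance parameters are sampled uniformly in log10
#' over the bounds (default 1e-5 to 1e-2 uS); timing parameters uniformly
#' over mean +/- `timing_halfwidth`.
#'
#' @param config A `somasim_experiment`.
#' @param param Parameter id: `"evdist_1:mean_time"`,
#'   `"evdist_1:L2_basket:ampa"`, or `"evdist:idi"` for a burst
#'   inter-drive interval.
#' @param bounds Optional c(lo, hi) sampling bounds.
#' @param n_samples Simulations per sweep (default 50).
#' @param n_trials Trials per simulation (default 25).
#' @param seed Seed for the parameter sampling stream.
#' @param timing_halfwidth Half-width (ms) of the default timing bounds
#'   (4 for MN-family, 10 for LE-family sweeps).
#' @return Object of class `somasim_sensitivity`: `time`, `sd` (nAm),
#'   `values` sampled, `param`, `drive`.
#' @export
sweep_parameter <- function(config, param, bounds = NULL, n_samples = 50L,
                            n_trials = 25L, seed = 1L,
                            timing_halfwidth = 4) {
  p <- parse_param_id(param)
  config$drives <- flatten_drives(config$drives)
  config$n_trials <- as.integer(n_trials)
  nm <- vapply(config$drives, `[[`, "", "name")
  if (p$field != "idi" && !p$drive %in% nm)
    stop("unknown drive '", p$drive, "' in config")

  set.seed(seed)
  if (p$field == "mean_time") {
    x0 <- get_param(config, p)
    if (is.null(bounds)) bounds <- c(x0 - timing_halfwidth,
                                     x0 + timing_halfwidth)
    values <- runif(n_samples, bounds[1], bounds[2])
  } else if (p$field == "idi") {
    if (is.null(bounds)) bounds <- c(25 - timing_halfwidth,
                                     25 + timing_halfwidth)
    values <- runif(n_samples, bounds[1], bounds[2])
  } else {
    if (is.null(bounds)) bounds <- c(1e-5, 1e-2)
    values <- 10^runif(n_samples, log10(bounds[1]), log10(bounds[2]))
  }

  network <- build_network(config$network)
  traces <- matrix(NA_real_, nrow = round(config$duration / config$dt) + 1L,
                   ncol = n_samples)
  for (s in seq_len(n_samples)) {
    cfg <- if (p$field == "idi") apply_idi(config, p$drive, values[s])
           else set_param(config, p, values[s])
    ens <- run_experiment(cfg, network = network)
    traces[, s] <- ens$mean$aggregate
  }
  structure(
    list(time = seq(0, by = config$dt,
                    length.out = nrow(traces)),
         sd = apply(traces, 1, sd), values = values,
         param = param, drive = p$drive),
    class = "somasim_sensitivity"
  )
}

#' Stack per-parameter SD traces and normalize
#'
#' @param results List of `somasim_sensitivity` sharing one time grid.
#' @return List with `time`, `raw` (matrix time x parameter, SD in nAm),
#'   `normalized` (each column divided by the pointwise total, so columns
#'   sum to 1 wherever total SD > 0), `drive` grouping labels.
#' @export
stack_and_normalize <- function(results) {
  if (!length(results)) stop("no sensitivity results")
  t0 <- results[[1]]$time
  for (r in results)
    if (!isTRUE(all.equal(r$time, t0))) stop("mismatched time grids")
  raw <- vapply(results, `[[`, t0, "sd")
  colnames(raw) <- vapply(results, `[[`, "", "param")
  total <- rowSums(raw)
  norm <- raw
  pos <- total > 0
  norm[pos, ] <- raw[pos, , drop = FALSE] / total[pos]
  norm[!pos, ] <- 0
  list(time = t0, raw = raw, normalized = norm,
       drive = vapply(results, `[[`, "", "drive"))
}

#' Named sensitivity parameter sets
#'
#' The parameter subsets swept for the MN and LE sensitivity analyses:
#' proximal drives contribute their mean time and NMDA conductances
#' (L2_pyramidal, L5_basket, L5_pyramidal); distal drives their mean time
#' and AMPA/NMDA conductances (L2_basket ampa, L2_pyramidal nmda,
#' L5_pyramidal nmda) for the MN case. The LE set spans the early/late
#' proximal drives, the first burst drive, and the burst inter-drive
#' interval.
#'
#' @param set "mn_sensitivity" or "le_sensitivity".
#' @return Character vector of parameter ids plus a `timing_halfwidth`
#'   attribute (ms).
#' @export
sensitivity_set <- function(set = c("mn_sensitivity", "le_sensitivity")) {
  set <- match.arg(set)
  if (set == "mn_sensitivity") {
    ids <- c(
      "evprox_1:mean_time", "evprox_1:L2_pyramidal:nmda",
      "evprox_1:L5_basket:nmda", "evprox_1:L5_pyramidal:nmda",
      "evdist_1:mean_time", "evdist_1:L2_basket:ampa",
      "evdist_1:L2_pyramidal:nmda", "evdist_1:L5_pyramidal:nmda",
      "evdist_2:mean_time", "evdist_2:L2_basket:ampa",
      "evdist_2:L2_pyramidal:nmda", "evdist_2:L5_pyramidal:nmda",
      "evprox_2:mean_time", "evprox_2:L2_pyramidal:nmda",
      "evprox_2:L5_basket:nmda", "evprox_2:L5_pyramidal:nmda"
    )
    attr(ids, "timing_halfwidth") <- 4
  } else {
    ids <- c(
      "evprox_2:mean_time", "evprox_2:L2_basket:ampa",
      "evprox_2:L2_pyramidal:ampa", "evprox_2:L5_basket:nmda",
      "evdist_1:mean_time", "evdist_1:L2_basket:ampa",
      "evdist_1:L2_pyramidal:ampa", "evdist_1:L2_basket:nmda",
      "evdist:idi",
      "evprox_1:mean_time", "evprox_1:L2_pyramidal:ampa",
      "evprox_1:L5_pyramidal:ampa", "evprox_1:L5_pyramidal:nmda"
    )
    attr(ids, "timing_halfwidth") <- 10
  }
  ids
}
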