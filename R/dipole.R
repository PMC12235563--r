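# Current-dipole readout: per-layer and aggregate dipole time series,
# trial scaling, and Hamming-window smoothing.

#' Compute the current-dipole time series from a state trace
#'
#' Per-layer dipole = sum over that layer's pyramidal cells of the
#' intracellular axial current times the inter-compartment length, signed
#' positive for current flowing up the apical dendrites (deep to
#' superficial). The aggregate is the sum of the two layers. Output is
#' unscaled and unsmoothed (raw model units).
#'
#' @param trace A `somasim_trace` from [integrate_network()].
#' @return Object of class `somasim_dipole` with fields `time`, `aggregate`,
#'   `layer2`, `layer5`, `scaling_factor`, `smoothing_window`, `n_trials`.
#' @export
compute_dipole <- function(trace) {
  if (is.null(trace$dipole_l2) || is.null(trace$dipole_l5))
    stop("trace is missing axial-current dipole signals")
  structure(
    list(
      time = trace$time, dt = trace$dt,
      aggregate = trace$dipole_l2 + trace$dipole_l5,
      layer2 = trace$dipole_l2, layer5 = trace$dipole_l5,
      scaling_factor = 1, smoothing_window = 0, n_trials = 1L
    ),
    class = "somasim_dipole"
  )
}

#' Unit-gain Hamming smoothing kernel
#'
#' @param window_ms Kernel width (ms); the kernel length is the nearest odd
#'   number of samples spanning this width.
#' @param dt Sample interval (ms).
#' @return Numeric kernel summing to 1.
#' @export
hamming_kernel <- function(window_ms, dt) {
  n <- 2L * floor(window_ms / (2 * dt)) + 1L
  k <- signal::hamming(n)
  k / sum(k)
}

smooth_reflect <- function(x, kernel) {
  n <- length(x); half <- (length(kernel) - 1L) / 2L
  if (length(kernel) > n) stop("smoothing window wider than trace")
  if (half == 0) return(x)
  padded <- c(rev(x[2:(half + 1L)]), x, rev(x[(n - half):(n - 1L)]))
  as.numeric(stats::filter(padded, kernel, sides = 2))[(half + 1L):(half + n)]
}

#' Scale and smooth a dipole time series
#'
#' Multiplies by the dipole scaling factor (mapping raw model units to nAm)
#' and convolves aggregate and per-layer traces with the same unit-gain
#' Hamming kernel (reflection padding at the edges, so a constant trace is
#' preserved). `window_ms = 0` disables smoothing.
#'
#' @param dipole A `somasim_dipole`.
#' @param scaling_factor Dimensionless multiplier (10/40/2500 for the
#'   TE/MN/LE experiment families).
#' @param window_ms Hamming window width (ms); 5 during optimization, 20
#'   for final waveforms by convention.
#' @return A `somasim_dipole` with updated traces and metadata.
#' @export
scale_and_smooth <- function(dipole, scaling_factor = 1, window_ms = 0) {
  if (window_ms < 0) stop("window_ms must be >= 0")
  out <- dipole
  if (window_ms > 0) {
    k <- hamming_kernel(window_ms, dipole$dt)
    out$aggregate <- smooth_reflect(dipole$aggregate, k)
    out$layer2 <- smooth_reflect(dipole$layer2, k)
    out$layer5 <- smooth_reflect(dipole$layer5, k)
  }
  out$aggregate <- out$aggregate * scaling_factor
  out$layer2 <- out$layer2 * scaling_factor
  out$layer5 <- out$layer5 * scaling_factor
  out$scaling_factor <- dipole$scaling_factor * scaling_factor
  out$smoothing_window <- window_ms
  out
}

#' Write a dipole time series as TSV
#'
#' Columns: `time_ms`, `agg_nAm`, `L2_nAm`, `L5_nAm`.
#' @param dipole A `somasim_dipole`.
#' @param path Output file.
#' @export
write_dipole_tsv <- function(dipole, path) {
  df <- data.frame(time_ms = dipole$time, agg_nAm = dipole$aggregate,
                   L2_nAm = dipole$layer2, L5_nAm = dipole$layer5)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dipole/waveform TSV
#'
#' Accepts the 4-column dialect written by [write_dipole_tsv()] or any
#' 2-column (time_ms, dipole) file such as an exported empirical waveform.
#' Validates strictly increasing time.
#'
#' @param path Input file.
#' @return A `somasim_dipole` (2-column input fills the layer traces with
#'   NA).
#' @export
read_dipole_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t")
  if (!ncol(df) %in% c(2L, 4L))
    stop("expected 2 or 4 tab-separated columns, found ", ncol(df))
  if (any(diff(df[[1]]) <= 0)) stop("time column must be strictly increasing")
  dt <- stats::median(diff(df[[1]]))
  structure(
    list(
      time = df[[1]], dt = dt, aggregate = df[[2]],
      layer2 = if (ncol(df) == 4L) df[[3]] else rep(NA_real_, nrow(df)),
      layer5 = if (ncol(df) == 4L) df[[4]] else rep(NA_real_, nrow(df)),
      scaling_factor = 1, smoothing_window = 0, n_trials = 1L
    ),
    class = "somasim_dipole"
  )
}
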