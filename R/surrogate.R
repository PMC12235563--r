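# Surrogate "empirical" evoked waveforms: sums of Gaussian deflections
# with the canonical MN/LE/TE deflection structure, so that fitting and
# optimization can run without any recorded dataset. These are synthetic
# stand-ins for empirical source waveforms, not recorded data.

#' Surrogate waveform specification
#'
#' Default deflection lists (latency ms, signed amplitude, Gaussian width
#' ms) encode the canonical structure of each response family. MN: small
#' upward N1 near 20 ms, dominant downward P1 at 35-40 ms, sustained
#' sub-baseline P2/prolonged depression over 50-100 ms, then a partial
#' rebound. LE: a single large, prolonged downward N1 within 100-200 ms
#' followed by a smaller upward rebound before 300 ms. TE: like MN with a
#' later, shallower main trough.
#'
#' @param kind "MN", "LE", or "TE".
#' @param deflections data.frame with columns `latency`, `amplitude`,
#'   `width`; defaults per `kind`.
#' @param noise_sd White-noise SD added to the waveform (same units as
#'   amplitudes).
#' @param duration,dt Time grid (ms).
#' @param seed Seed for the noise.
#' @return Object of class `somasim_surrogate_spec`.
#' @export
surrogate_spec <- function(kind = c("MN", "LE", "TE"), deflections = NULL,
                           noise_sd = 0.02, duration = NULL, dt = 0.5,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(deflections)) {
    deflections <- switch(kind,
      MN = data.frame(
        latency = c(20, 37, 72, 130),
        amplitude = c(0.35, -1.0, -0.35, 0.12),
        width = c(4, 5, 22, 15)
      ),
      LE = data.frame(
        latency = c(170, 260),
        amplitude = c(-1.0, 0.25),
        width = c(32, 22)
      ),
      TE = data.frame(
        latency = c(19.6, 65.7, 100),
        amplitude = c(0.5, -1.0, 0.25),
        width = c(4, 9, 12)
      )
    )
  }
  if (is.null(duration)) duration <- if (kind == "LE") 300 else 170
  structure(
    list(kind = kind, deflections = deflections, noise_sd = noise_sd,
         duration = duration, dt = dt, seed = as.integer(seed)),
    class = "somasim_surrogate_spec"
  )
}

#' Generate a surrogate evoked waveform
#'
#' Sum of Gaussian deflections plus white noise; baseline 0 outside
#' deflections; deterministic per seed.
#'
#' @param spec A [surrogate_spec()].
#' @return A `somasim_dipole` whose aggregate trace is the surrogate
#'   waveform (layer traces are NA).
#' @export
make_surrogate <- function(spec) {
  stopifnot(inherits(spec, "somasim_surrogate_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  y <- rep(0, length(t))
  for (i in seq_len(nrow(spec$deflections))) {
    d <- spec$deflections[i, ]
    y <- y + d$amplitude * exp(-(t - d$latency)^2 / (2 * d$width^2))
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    y <- y + rnorm(length(t), 0, spec$noise_sd)
  }
  structure(
    list(time = t, dt = spec$dt, aggregate = y,
         layer2 = rep(NA_real_, length(t)), layer5 = rep(NA_real_, length(t)),
         scaling_factor = 1, smoothing_window = 0, n_trials = 1L),
    class = "somasim_dipole"
  )
}

#' Normalize a waveform by its most prominent deflection
#'
#' Scalar division by the maximal absolute value, so the output's largest
#' |value| is exactly 1 and the shape is preserved.
#'
#' @param waveform A `somasim_dipole` or numeric vector.
#' @return Same type as the input, normalized.
#' @export
normalize_waveform <- function(waveform) {
  y <- if (inherits(waveform, "somasim_dipole")) waveform$aggregate
       else waveform
  m <- max(abs(y))
  if (m == 0) stop("cannot normalize an all-zero waveform")
  if (inherits(waveform, "somasim_dipole")) {
    waveform$aggregate <- waveform$aggregate / m
    if (!all(is.na(waveform$layer2))) waveform$layer2 <- waveform$layer2 / m
    if (!all(is.na(waveform$layer5))) waveform$layer5 <- waveform$layer5 / m
    waveform
  } else {
    y / m
  }
}
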