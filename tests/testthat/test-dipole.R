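# Dipole readout: signs, additivity, scaling, Hamming smoothing, TSV IO.

test_that("a drive-free trace yields a (near-)zero dipole", {
  cfg <- tiny_config()
  cfg$cell_params$L5_pyramidal$g_slow_dist <- 0
  net <- build_network(cfg)
  tr <- integrate_network(net, expand_drive_events(net, list()), 50)
  dip <- compute_dipole(tr)
  # uniform initial state: axial currents are exactly zero at t = 0
  expect_identical(dip$aggregate[1], 0)
  # at rest the only asymmetry is the tiny standing Na/K window current
  # at the soma; compare against the scale of an actual response
  w <- list(L2_pyramidal = c(ampa = 1e-3))
  resp <- compute_dipole(integrate_network(
    net, single_drive_events(net, "distal", 10, w), 50))
  expect_lt(max(abs(dip$aggregate)), 1e-3 * max(abs(resp$aggregate)))
})

test_that("aggregate equals the sum of the layer dipoles exactly", {
  net <- tiny_network()
  w <- list(L2_pyramidal = c(ampa = 2e-2), L5_pyramidal = c(ampa = 2e-2))
  tr <- integrate_network(net, single_drive_events(net, "proximal", 20, w),
                          80)
  dip <- compute_dipole(tr)
  expect_identical(dip$aggregate, dip$layer2 + dip$layer5)
  sm <- scale_and_smooth(dip, 40, 5)
  expect_equal(sm$aggregate, sm$layer2 + sm$layer5, tolerance = 1e-12)
})

test_that("subthreshold drive polarity fixes the first deflection sign", {
  net <- build_network(uncoupled_config(4, 1))
  set.seed(42)
  first_defl <- function(location, w) {
    wl <- list(L2_pyramidal = c(ampa = w), L5_pyramidal = c(ampa = w))
    tr <- integrate_network(net, single_drive_events(net, location, 10, wl),
                            40)
    agg <- compute_dipole(tr)$aggregate
    agg[which.max(abs(agg))]
  }
  for (w in runif(20, 1e-4, 2e-3)) {
    expect_lte(first_defl("distal", w), 0)
    expect_gte(first_defl("proximal", w), 0)
  }
})

test_that("scaling is exactly linear", {
  net <- tiny_network()
  w <- list(L2_pyramidal = c(ampa = 1e-3))
  tr <- integrate_network(net, single_drive_events(net, "distal", 10, w), 40)
  dip <- compute_dipole(tr)
  s <- scale_and_smooth(dip, 2500, 0)
  expect_identical(s$aggregate, 2500 * dip$aggregate)
  expect_identical(s$layer5, 2500 * dip$layer5)
})

test_that("Hamming smoothing preserves constants and has unit DC gain", {
  t <- seq(0, 100, by = 0.1)
  dip <- structure(list(time = t, dt = 0.1,
                        aggregate = rep(3.7, length(t)),
                        layer2 = rep(1.7, length(t)),
                        layer5 = rep(2.0, length(t)),
                        scaling_factor = 1, smoothing_window = 0,
                        n_trials = 1L),
                   class = "somasim_dipole")
  out <- scale_and_smooth(dip, 1, 20)
  expect_equal(out$aggregate, rep(3.7, length(t)), tolerance = 1e-12)
  k <- hamming_kernel(20, 0.1)
  expect_equal(sum(k), 1)
})

test_that("sinusoid attenuation matches the kernel's frequency response", {
  dt <- 0.1
  t <- seq(0, 1000, by = dt)
  f <- 40 / 1000  # 40 Hz in cycles/ms
  dip <- structure(list(time = t, dt = dt,
                        aggregate = sin(2 * pi * f * t),
                        layer2 = sin(2 * pi * f * t),
                        layer5 = rep(0, length(t)),
                        scaling_factor = 1, smoothing_window = 0,
                        n_trials = 1L),
                   class = "somasim_dipole")
  out <- scale_and_smooth(dip, 1, 20)
  # analytic gain: |sum_k w_k exp(-i 2 pi f k dt)| for the unit-sum kernel
  k <- hamming_kernel(20, dt)
  half <- (length(k) - 1) / 2
  lags <- (-half:half) * dt
  gain <- Mod(sum(k * exp(-1i * 2 * pi * f * lags)))
  mid <- t > 200 & t < 800
  expect_equal(max(out$aggregate[mid]), gain, tolerance = 1e-3)
})

test_that("smoothing rejects windows wider than the trace", {
  t <- seq(0, 5, by = 0.5)
  dip <- structure(list(time = t, dt = 0.5,
                        aggregate = rnorm(length(t)),
                        layer2 = rnorm(length(t)), layer5 = rnorm(length(t)),
                        scaling_factor = 1, smoothing_window = 0,
                        n_trials = 1L),
                   class = "somasim_dipole")
  expect_error(scale_and_smooth(dip, 1, 50), "wider")
})

test_that("dipole TSV round-trips and validates", {
  net <- tiny_network()
  w <- list(L2_pyramidal = c(ampa = 1e-3))
  tr <- integrate_network(net, single_drive_events(net, "distal", 10, w), 40)
  dip <- compute_dipole(tr)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dipole_tsv(dip, path)
  back <- read_dipole_tsv(path)
  expect_equal(back$aggregate, dip$aggregate, tolerance = 1e-12)
  expect_equal(back$time, dip$time, tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_ms\tagg_nAm", "1\t0", "1\t0"), bad)
  expect_error(read_dipole_tsv(bad), "increasing")
})
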