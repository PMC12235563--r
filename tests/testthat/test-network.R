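# Column construction, spatial weight fall-off, and integrator behavior.

test_that("default configuration realizes the canonical cell counts", {
  net <- build_network(network_config())
  counts <- table(net$cells$population)
  expect_equal(nrow(net$cells), 270L)
  expect_equal(unname(counts[["L2_pyramidal"]]), 100L)
  expect_equal(unname(counts[["L5_pyramidal"]]), 100L)
  expect_equal(unname(counts[["L2_basket"]]), 35L)
  expect_equal(unname(counts[["L5_basket"]]), 35L)
})

test_that("configuration validation rejects malformed inputs", {
  tab <- connection_table_default()
  tab$pre[1] <- "L9_pyramidal"
  expect_error(network_config(connection_table = tab), "L9_pyramidal")

  tab <- connection_table_default()
  tab$weight[3] <- -1
  expect_error(network_config(connection_table = tab), "negative weight")

  tab <- connection_table_default()
  tab <- rbind(tab, tab[1, ])
  expect_error(network_config(connection_table = tab), "duplicate")

  tab <- connection_table_default()
  tab$receptor[tab$pre == "L2_pyramidal"][1] <- "gabaa"
  expect_error(network_config(connection_table = tab), "AMPA/NMDA")

  cp <- cell_params_default()
  cp$L2_pyramidal$synapses$ampa$rise <- 10  # rise > decay
  expect_error(network_config(cell_params = cp), "decay > rise")

  expect_error(network_config(n_pyr_per_layer = 0), "positive")
})

test_that("synaptic weight follows exponential fall-off with distance", {
  expect_identical(synaptic_weight(c(0, 0), c(0, 0), 5e-2, 3), 5e-2)
  # Table value for L2/3 basket -> L2/3 pyramidal GABA_A at one length
  # constant of separation
  expect_equal(synaptic_weight(c(0, 0), c(3, 0), 5e-2, 3), 5e-2 * exp(-1))
  expect_lt(synaptic_weight(c(0, 0), c(100, 0), 5e-2, 3), 1e-10)
  d <- seq(0, 10, by = 0.5)
  w <- vapply(d, function(x) synaptic_weight(c(0, 0), c(x, 0), 1, 2), 0)
  expect_true(all(diff(w) <= 0))
  expect_error(synaptic_weight(c(0, 0), c(1, 0), 1, 0), "positive")
})

test_that("realized network weights match a brute-force enumeration", {
  # one connection type on a 3x3 grid with unit space constant
  tab <- data.frame(pre = "L2_pyramidal", post = "L2_pyramidal",
                    receptor = "ampa", weight = 2e-4, target = "prox",
                    delay = 1, space_constant = NA_real_)
  cfg <- network_config(n_pyr_per_layer = 9, n_basket_per_layer = 1,
                        space_constant = 1, connection_table = tab)
  net <- build_network(cfg)
  # brute force over all ordered pairs of grid positions
  pos <- expand.grid(x = 0:2, y = 0:2)
  expected <- c()
  for (i in 1:9) for (j in 1:9) {
    if (i == j) next
    d <- sqrt((pos$x[i] - pos$x[j])^2 + (pos$y[i] - pos$y[j])^2)
    expected <- c(expected, 2e-4 * exp(-d / 1))
  }
  expect_equal(length(net$conn_w), length(expected))
  expect_equal(sort(net$conn_w), sort(expected))
})

test_that("a zero-weight table yields uncoupled single-cell responses", {
  net1 <- build_network(uncoupled_config(1, 1))
  netN <- build_network(uncoupled_config(16, 1))
  w <- list(L2_pyramidal = c(ampa = 2e-3))
  tr1 <- integrate_network(net1, single_drive_events(net1, "distal", 20, w),
                           60)
  trN <- integrate_network(netN, single_drive_events(netN, "distal", 20, w),
                           60)
  # N identical uncoupled cells produce exactly N times one cell's dipole
  expect_equal(trN$dipole_l2, 16 * tr1$dipole_l2, tolerance = 1e-10)
})

test_that("a resting network without drive stays quiescent", {
  net <- tiny_network()
  ev <- expand_drive_events(net, list())
  tr <- integrate_network(net, ev, 100, record_v = seq_len(net$n_comp))
  expect_equal(nrow(tr$spikes), 0L)
  expect_true(all(abs(tr$v - (-65)) < 2))
})

test_that("integration is bitwise reproducible", {
  net <- tiny_network()
  w <- list(L2_pyramidal = c(ampa = 2e-2), L5_pyramidal = c(ampa = 2e-2))
  ev <- single_drive_events(net, "proximal", 20, w)
  tr1 <- integrate_network(net, ev, 80)
  tr2 <- integrate_network(net, ev, 80)
  expect_identical(tr1$dipole_l2, tr2$dipole_l2)
  expect_identical(tr1$dipole_l5, tr2$dipole_l5)
  expect_identical(tr1$spikes, tr2$spikes)
})

test_that("strong synchronous proximal drive spikes both pyramidal layers", {
  net <- tiny_network()
  w <- list(L2_pyramidal = c(ampa = 2.5e-2), L5_pyramidal = c(ampa = 2.5e-2))
  tr <- integrate_network(net, single_drive_events(net, "proximal", 20, w),
                          60)
  expect_gt(sum(tr$spikes$population == "L2_pyramidal"), 0)
  expect_gt(sum(tr$spikes$population == "L5_pyramidal"), 0)
})

test_that("numerical divergence is reported with time and compartment", {
  net <- tiny_network()
  w <- list(L2_pyramidal = c(ampa = 2.5e-2))
  ev <- single_drive_events(net, "proximal", 20, w)
  expect_error(integrate_network(net, ev, 60, vbound = 30), "diverged")
  expect_error(integrate_network(net, ev, 60, vbound = 30), "compartment")
})

test_that("event times outside the window are rejected", {
  net <- tiny_network()
  ev <- data.frame(time = 70, state = 0L, weight = 1e-3, drive = "x")
  expect_error(integrate_network(net, ev, 60), "within")
})

test_that("simulated conductance matches the closed-form dual exponential", {
  net <- build_network(uncoupled_config(1, 1))
  cell <- which(net$cells$population == "L2_pyramidal")[1]
  comp <- net$comp_of[cell, "dist"]
  w <- list(L2_pyramidal = c(ampa = 1e-3))
  ev <- single_drive_events(net, "distal", 10, w)
  tr <- integrate_network(net, ev, 60,
                          record_g = data.frame(comp = comp,
                                                receptor = "ampa"))
  t_rel <- tr$time - 10  # event lands at the start of its own step
  tau_r <- 0.5; tau_d <- 5
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  norm <- 1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
  g_exact <- ifelse(t_rel <= 0, 0,
                    1e-3 * norm * (exp(-t_rel / tau_d) - exp(-t_rel / tau_r)))
  expect_equal(as.numeric(tr$g), g_exact, tolerance = 1e-6)
  expect_equal(max(tr$g), 1e-3, tolerance = 1e-3)  # peak-normalized weight
})

test_that("subthreshold response amplitude is linear in conductance", {
  net <- build_network(uncoupled_config(1, 1))
  peak_defl <- function(w) {
    ev <- single_drive_events(net, "distal", 10,
                              list(L2_pyramidal = c(ampa = w)))
    tr <- integrate_network(net, ev, 60)
    max(abs(tr$dipole_l2))
  }
  r <- peak_defl(2e-4) / peak_defl(1e-4)
  expect_equal(r, 2, tolerance = 0.05)
})

test_that("basket interspike intervals concentrate at the gamma period
           under deterministic 25 ms repetitive distal events", {
  net <- build_network(network_config())
  bask <- which(net$cells$population == "L2_basket")
  w <- list(L2_basket = c(ampa = 1e-2, nmda = 4e-3))
  drives <- lapply(1:6, function(k)
    evoked_drive(sprintf("d%d", k), "distal", 50 + (k - 1) * 25, 0, w, k))
  ev <- expand_drive_events(net, drives, trial_seed = 1)
  tr <- integrate_network(net, ev, 250)
  st <- tr$spikes[tr$spikes$population == "L2_basket", ]
  isis <- unlist(lapply(split(st$time, st$cell), function(x) diff(sort(x))))
  expect_gt(length(isis), 50)
  expect_lt(abs(median(isis) - 25), 3)
})
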