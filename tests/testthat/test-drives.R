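# Drive definition, per-trial sampling, burst expansion, and event
# schedules.

test_that("degenerate Gaussian returns the mean exactly", {
  d <- evoked_drive("d", "proximal", 20.8, 0, list(L2_pyramidal = c(ampa = 1e-3)))
  expect_identical(sample_drive_times(list(d), 1L)$d, 20.8)
})

test_that("Monte-Carlo sampling recovers the drive time distribution", {
  # post-optimization late MN proximal drive statistics
  d <- evoked_drive("d", "proximal", 20.8, 4.1,
                    list(L2_pyramidal = c(ampa = 1e-3)))
  n <- 10000
  t <- vapply(seq_len(n), function(k) sample_drive_times(list(d), k)$d, 0)
  se_mean <- 4.1 / sqrt(n)
  expect_lt(abs(mean(t) - 20.8), 4 * se_mean)
  expect_lt(abs(sd(t) - 4.1), 4 * 4.1 / sqrt(2 * n))
})

test_that("distinct seed offsets give different reproducible streams", {
  w <- list(L2_pyramidal = c(ampa = 1e-3))
  d1 <- evoked_drive("a", "proximal", 50, 5, w, seed_offset = 0L)
  d2 <- evoked_drive("b", "proximal", 50, 5, w, seed_offset = 1L)
  s1 <- sample_drive_times(list(d1, d2), 7L)
  s2 <- sample_drive_times(list(d1, d2), 7L)
  expect_identical(s1, s2)
  expect_false(s1$a == s1$b)
})

test_that("samples across trials are statistically independent", {
  d <- evoked_drive("d", "proximal", 50, 5, list(L2_pyramidal = c(ampa = 1e-3)))
  t <- vapply(1:10000, function(k) sample_drive_times(list(d), k)$d, 0)
  r <- cor(t[-1], t[-length(t)])
  expect_lt(abs(r), 0.05)
})

test_that("negative sampled times clamp to zero with a warning", {
  d <- evoked_drive("d", "proximal", 0.01, 5,
                    list(L2_pyramidal = c(ampa = 1e-3)))
  neg_seed <- NULL
  for (k in 1:200) {
    t <- suppressWarnings(sample_drive_times(list(d), k)$d)
    if (t == 0) { neg_seed <- k; break }
  }
  expect_false(is.null(neg_seed))
  expect_warning(sample_drive_times(list(d), neg_seed), "clamped")
})

test_that("burst expansion produces the arithmetic progression of means", {
  w <- list(L2_pyramidal = c(ampa = 1e-3))
  b <- drive_burst("evdist", "distal", 120, 25, 4L, 8, w)
  means <- vapply(expand_burst(b), `[[`, 0, "mean_time")
  expect_equal(means, c(120, 145, 170, 195))
  expect_equal(vapply(expand_burst(b), `[[`, 0, "sd_time"), rep(8, 4))

  b1 <- drive_burst("x", "distal", 120, 25, 1L, 8, w)
  expect_equal(vapply(expand_burst(b1), `[[`, 0, "mean_time"), 120)

  b7 <- drive_burst("x", "distal", 120, 12.5, 7L, 8, w)
  expect_equal(vapply(expand_burst(b7), `[[`, 0, "mean_time"),
               seq(120, 195, by = 12.5))
})

test_that("aperiodic sampling stays inside the window", {
  t <- sample_aperiodic_burst(c(120, 200), 4, 1L)
  expect_true(all(t >= 120 & t <= 200))
  expect_identical(sample_aperiodic_burst(c(150, 150), 4, 1L), rep(150, 4))
  m <- vapply(1:2000, function(k)
    mean(sample_aperiodic_burst(c(120, 200), 4, k)), 0)
  se <- (80 / sqrt(12)) / sqrt(4 * 2000)
  expect_lt(abs(mean(m) - 160), 4 * se)
  tm <- sample_aperiodic_burst(c(120, 200), 3, 1L, synchronous = FALSE,
                               n_cells = 10)
  expect_equal(dim(tm), c(3L, 10L))
})

test_that("drive target pathways are exclusive and excitatory", {
  net <- tiny_network()
  w_all <- list(L2_pyramidal = c(ampa = 1e-3, nmda = 1e-3),
                L5_pyramidal = c(ampa = 1e-3),
                L2_basket = c(ampa = 1e-3))
  dist <- evoked_drive("dist", "distal", 50, 0, w_all)
  ev <- expand_drive_events(net, dist, trial_seed = 1)
  comp <- (ev$state %/% 4L) + 1L
  rec <- c("ampa", "nmda", "gabaa", "gabab")[(ev$state %% 4L) + 1L]
  pops <- net$comp_pop[comp]
  cmps <- net$comp_name[comp]
  # distal never reaches L5 baskets nor pyramidal somatic/proximal zones
  expect_false(any(pops == "L5_basket"))
  expect_false(any(cmps %in% c("soma", "prox") &
                     pops %in% c("L2_pyramidal", "L5_pyramidal")))
  expect_true(all(rec %in% c("ampa", "nmda")))
  # proximal drives may not target distal compartments at all
  expect_error(evoked_drive("p", "proximal", 50, 0,
                            c(w_all, list(L5_basket = c(gabaa = 1e-3)))),
               "excitatory")
  prox <- evoked_drive("prox", "proximal", 50, 0,
                       list(L2_pyramidal = c(ampa = 1e-3),
                            L5_basket = c(ampa = 1e-3)))
  evp <- expand_drive_events(net, prox, trial_seed = 1)
  compp <- (evp$state %/% 4L) + 1L
  expect_false(any(net$comp_name[compp] == "dist"))
})

test_that("distal drives cannot be declared against L5 baskets", {
  expect_error(evoked_drive("d", "distal", 50, 0,
                            list(L5_basket = c(ampa = 1e-3))),
               "may not target")
})

test_that("asynchronous aperiodic drives schedule per-cell times", {
  net <- tiny_network()
  ap <- aperiodic_burst("ap", "distal", c(50, 90), 2L,
                        list(L2_pyramidal = c(ampa = 1e-3)),
                        synchronous = FALSE)
  ev <- expand_drive_events(net, ap, trial_seed = 3)
  # 16 targeted cells x 2 events, times not shared across cells
  expect_equal(nrow(ev), 32L)
  expect_gt(length(unique(ev$time)), 16)
  expect_true(all(ev$time >= 50 & ev$time <= 90))
})
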