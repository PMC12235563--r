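# One-at-a-time sweeps: sampling distributions, SD stacking, normalization.

sens_fixture <- function() {
  experiment_config(
    "sens", drives = list(
      evoked_drive("evprox_1", "proximal", 25, 2,
                   list(L2_pyramidal = c(ampa = 2e-2),
                        L5_pyramidal = c(ampa = 2e-2)), 0L),
      evoked_drive("evdist_1", "distal", 50, 2,
                   list(L2_pyramidal = c(ampa = 5e-3, nmda = 1e-3),
                        L2_basket = c(ampa = 8e-3)), 10L)),
    duration = 80, n_trials = 2L, scaling_factor = 10,
    smoothing_window = 5, network = tiny_config())
}

test_that("zero-width bounds give identically zero SD", {
  cfg <- sens_fixture()
  res <- sweep_parameter(cfg, "evdist_1:mean_time", bounds = c(50, 50),
                         n_samples = 3L, n_trials = 1L)
  expect_true(all(res$sd == 0))
})

test_that("conductance sampling is log10-uniform over the stated range", {
  cfg <- sens_fixture()
  vals <- c()
  for (s in 1:5) {
    res <- sweep_parameter(cfg, "evdist_1:L2_basket:ampa", n_samples = 10L,
                           n_trials = 1L, seed = s)
    vals <- c(vals, res$values)
  }
  expect_true(all(vals >= 1e-5 & vals <= 1e-2))
  ks <- suppressWarnings(ks.test(log10(vals), "punif", -5, -2))
  expect_gt(ks$p.value, 0.01)
})

test_that("timing bounds default to the family half-width", {
  cfg <- sens_fixture()
  res <- sweep_parameter(cfg, "evprox_1:mean_time", n_samples = 20L,
                         n_trials = 1L, timing_halfwidth = 4)
  expect_true(all(res$values >= 21 & res$values <= 29))
})

test_that("unknown parameters are rejected with a clear error", {
  cfg <- sens_fixture()
  expect_error(sweep_parameter(cfg, "evdist_9:mean_time"), "unknown drive")
  expect_error(sweep_parameter(cfg, "gibberish"), "malformed")
})

test_that("stacking normalizes to unit sum wherever total SD is positive", {
  t <- seq(0, 10, by = 1)
  mk <- function(sd, p) structure(
    list(time = t, sd = sd, values = 1:3, param = p, drive = p),
    class = "somasim_sensitivity")
  one <- stack_and_normalize(list(mk(c(0, rep(2, 10)), "a")))
  expect_equal(unname(one$normalized[-1, 1]), rep(1, 10))
  expect_equal(unname(one$normalized[1, 1]), 0)

  two <- stack_and_normalize(list(mk(rep(3, 11), "a"), mk(rep(3, 11), "b")))
  expect_true(all(two$normalized == 0.5))

  x <- stack_and_normalize(list(mk(rep(1, 11), "a"), mk(rep(2, 11), "b"),
                                mk(rep(5, 11), "c")))
  expect_equal(unname(x$normalized[1, ]), c(1, 2, 5) / 8)
  expect_equal(unname(rowSums(x$normalized)), rep(1, 11))

  bad <- mk(rep(1, 11), "d"); bad$time <- t + 0.5
  expect_error(stack_and_normalize(list(mk(rep(1, 11), "a"), bad)),
               "mismatched")
})

test_that("sweeps use common random numbers so jitter does not leak in", {
  cfg <- sens_fixture()
  # sweeping a weight of a drive with zero influence on the early window
  res <- sweep_parameter(cfg, "evdist_1:L2_pyramidal:nmda", n_samples = 4L,
                         n_trials = 2L, seed = 2)
  early <- res$time < 40  # before the swept drive can act
  expect_true(all(res$sd[early] < 1e-9))
})

test_that("named sweep sets match the published parameter subsets", {
  mn <- sensitivity_set("mn_sensitivity")
  expect_equal(attr(mn, "timing_halfwidth"), 4)
  expect_true(all(c("evprox_1:L5_basket:nmda", "evdist_1:L2_basket:ampa",
                    "evprox_2:mean_time") %in% mn))
  expect_false(any(grepl("evprox_1:L2_basket", mn)))  # proximal NMDA only
  le <- sensitivity_set("le_sensitivity")
  expect_equal(attr(le, "timing_halfwidth"), 10)
  expect_true("evdist:idi" %in% le)
})

test_that("sensitivity is temporally local to each drive's window", {
  cfg <- sens_fixture()
  r_early <- sweep_parameter(cfg, "evprox_1:mean_time", bounds = c(21, 29),
                             n_samples = 6L, n_trials = 2L, seed = 1)
  r_late <- sweep_parameter(cfg, "evdist_1:mean_time", bounds = c(46, 54),
                            n_samples = 6L, n_trials = 2L, seed = 1)
  split_t <- 42
  # the late drive's variance lives late; the early drive dominates overall
  expect_lt(sum(r_late$sd[r_late$time < split_t]),
            sum(r_late$sd[r_late$time >= split_t]))
  expect_gt(sum(r_early$sd), sum(r_late$sd) * 0.5)
})
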