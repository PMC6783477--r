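# The synthetic-experiment generator.

test_that("simulated tide tables are semidiurnal and valid", {
  t0 <- as.POSIXct("2016-05-01 00:00:00", tz = "UTC")
  tt <- simulate_tide_table(t0, 1)
  expect_s3_class(tt, "tide_table")
  expect_true(nrow(tt) %in% 4:5)  # ~2 highs + 2 lows per day
  expect_equal(unique(diff(as.numeric(tt$time))), 12.42 * 3600 / 2)
  expect_true(all(tt$type[c(TRUE, FALSE)] == "high"))
  tt2 <- simulate_tide_table(t0, 3, first_high_offset_h = 2.5)
  expect_equal(as.numeric(tt2$time[1] - t0, units = "hours"), 2.5)
  expect_error(simulate_tide_table(t0, 0), ">= 1")
})

test_that("the default design reproduces the study layout", {
  d <- simulation_design()
  expect_equal(sum(d$n_per_estuary), 222)
  expect_equal(unname(d$n_per_estuary[c("Vasseide", "Vinnesvag",
                                        "Torvesund", "Stolmen")]),
               c(49, 36, 24, 113))
  expect_equal(d$p_orient, 0.7)
  expect_equal(d$group_resultant_target, 0.2)
  expect_equal(vonmises_r_from_kappa(d$kappa_pop), 0.2, tolerance = 1e-8)
  expect_error(simulation_design(n_per_estuary = c(Lost = 5)), "known")
  expect_error(simulation_design(p_orient = 1.2), "p_orient")
})

test_that("simulate_experiment emits the full dataset deterministically", {
  d <- simulation_design(seed = 17)
  ex1 <- simulate_experiment(d)
  expect_length(ex1$tracks, 222)
  expect_equal(nrow(ex1$metadata), 222)
  expect_setequal(unique(ex1$manifest$phase), c("ebb", "flood"))
  expect_equal(sort(unique(ex1$metadata$condition)), c(0, 90, 180, 270))
  # round-robin conditions: near-equal allocation
  expect_true(all(table(ex1$metadata$condition) %in% 55:56))
  # same seed -> identical experiment (tracks, schedule, manifest)
  ex2 <- simulate_experiment(d)
  expect_identical(ex1$manifest, ex2$manifest)
  expect_identical(ex1$tracks[[101]]$samples, ex2$tracks[[101]]$samples)
  # a different seed changes the draws
  ex3 <- simulate_experiment(simulation_design(seed = 18))
  expect_false(identical(ex1$tracks[[1]]$samples, ex3$tracks[[1]]$samples))
})

test_that("track emission inverts the analysis chain at high concentration", {
  tides <- fixture_tides()
  d <- simulation_design(kappa_track = 700, seed = 2)
  t_fl <- flood_time(tides)
  for (cond in c(0, 90, 180, 270)) {
    tr <- simulate_eel_track(
      list(eel_id = "k", estuary = "Stolmen", phenotype = "orienting",
           true_relative_heading = 77, condition = cond, test_start = t_fl,
           compass_offset = 123),
      d, tides, seed = 42)
    res <- analyze_individual(trim_acclimation(tr), default_estuaries(),
                              tides)
    expect_lt(abs(angular_difference(res$relative_bearing, 77)), 0.5)
  }
})

test_that("non-orienting animals yield uniform Rayleigh p-values", {
  tides <- fixture_tides()
  d <- simulation_design(seed = 3)
  t_ebb <- ebb_time(tides)
  ps <- vapply(1:1000, function(i) {
    tr <- simulate_eel_track(
      list(eel_id = "n", estuary = "Vasseide", phenotype = "non_orienting",
           true_relative_heading = NA, condition = 0, test_start = t_ebb,
           compass_offset = 0),
      d, tides, seed = 100000 + i)
    rayleigh_test(trim_acclimation(tr)$bearings)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("phase-switch signature: fixed flow heading flips 180 in the lab", {
  # animals holding flow-frame heading 0 have magnetic headings that differ
  # by 180 between ebb- and flood-tested animals at the same estuary
  tides <- fixture_tides()
  d <- simulation_design(kappa_track = 700, seed = 9)
  est <- default_estuaries()
  for (nm in est$name) {
    mags <- vapply(c(ebb_time(tides), flood_time(tides)), function(tt) {
      tr <- simulate_eel_track(
        list(eel_id = "p", estuary = nm, phenotype = "orienting",
             true_relative_heading = 0, condition = 90, test_start = tt,
             compass_offset = 45),
        d, tides, seed = 7)
      analyze_individual(trim_acclimation(tr), est,
                         tides)$mean_bearing_magnetic
    }, numeric(1))
    expect_equal(abs(angular_difference(mags[1], mags[2])), 180,
                 tolerance = 0.5)
  }
})

test_that("within-track concentration rises monotonically with kappa", {
  tides <- fixture_tides()
  t_ebb <- ebb_time(tides)
  kappas <- c(0.5, 1, 2, 4)
  mean_r <- vapply(kappas, function(k) {
    d <- simulation_design(kappa_track = k, seed = 5)
    mean(vapply(1:40, function(i) {
      tr <- simulate_eel_track(
        list(eel_id = "m", estuary = "Vasseide", phenotype = "orienting",
             true_relative_heading = 0, condition = 0, test_start = t_ebb,
             compass_offset = 0),
        d, tides, seed = 2000 + i)
      circ_mean(trim_acclimation(tr)$bearings)$resultant_length
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
  # at 600 bearings the individual filter saturates, so the oriented-rate
  # monotonicity is visible at small n instead
  set.seed(64)
  rate <- vapply(kappas, function(k)
    mean(vapply(1:300, function(i)
      rayleigh_test(rvonmises(10, 0, k))$p_value < 0.05, logical(1))),
    numeric(1))
  expect_true(all(diff(rate) > 0))
})

test_that("lag-1 mixing makes the individual test anti-conservative", {
  # the mixing scheme autocorrelates and concentrates bearings, inflating
  # rejection relative to independent draws at matched kappa_track
  tides <- fixture_tides()
  t_ebb <- ebb_time(tides)
  rej <- vapply(c(0, 0.8), function(rho) {
    d <- simulation_design(kappa_track = 0.15, rho_track = rho, seed = 6)
    mean(vapply(1:60, function(i) {
      tr <- simulate_eel_track(
        list(eel_id = "r", estuary = "Vasseide", phenotype = "orienting",
             true_relative_heading = 0, condition = 0, test_start = t_ebb,
             compass_offset = 0),
        d, tides, seed = 5000 + i)
      rayleigh_test(trim_acclimation(tr)$bearings)$p_value < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_gt(rej[2], rej[1])
})

test_that("single-cohort recovery lands near the flow reference", {
  d <- simulation_design(seed = 23)
  ex <- simulate_experiment(d)
  fit <- fit_orientation(ex$tracks, ex$tides, seed = 23)
  # circular SE of the group mean at the design spread is ~16 degrees
  expect_lt(abs(angular_difference(fit$group$mean_direction, 0)), 48)
  expect_gt(fit$group$proportion_oriented, 0.6)
  expect_lt(fit$group$proportion_oriented, 0.85)
})
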