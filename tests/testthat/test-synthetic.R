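# Synthetic campaign generator: runoff series, entrainment plume, profile
# sampling, campaign determinism and behavioural invariants.

test_that("runoff series is the clipped sum of Gaussian pulses", {
  cfg <- synthetic_config(
    start = as.Date("2012-08-01"), end = as.Date("2012-09-30"),
    runoff_peaks = data.frame(day = as.Date("2012-08-20"),
                              amplitude = 220, width = 3))
  r <- generate_runoff_series(cfg)
  expect_equal(nrow(r), 61)
  expect_equal(r$discharge[r$day == as.Date("2012-08-20")], 220)
  expect_true(all(r$discharge >= 0))
  # no pulses: identically zero
  cfg0 <- synthetic_config(runoff_peaks = data.frame(day = as.Date(character()),
                                                     amplitude = numeric(),
                                                     width = numeric()))
  expect_true(all(generate_runoff_series(cfg0)$discharge == 0))
  # two well-separated pulses: the series maximum is the larger amplitude
  cfg2 <- synthetic_config(runoff_peaks = data.frame(
    day = as.Date(c("2012-08-10", "2012-10-10")),
    amplitude = c(150, 70), width = c(2, 2)))
  expect_equal(max(generate_runoff_series(cfg2)$discharge), 150,
               tolerance = 1e-9)
})

test_that("plume field obeys the entrainment-plume structure", {
  f <- build_plume_field(50, 100)
  expect_equal(f$f_core_fun(0), 1)                     # undiluted at source
  expect_true(all(diff(f$f_core) <= 1e-12))            # dilution monotone
  expect_true(all(diff(f$b) >= -1e-9))                 # radius non-decreasing
  expect_true(all(f$f_core >= 0 & f$f_core <= 1))
  # zero source flux: no plume anywhere
  f0 <- build_plume_field(0, 100)
  expect_true(all(f0$f_core_fun(c(0, 36, 99)) == 0))
  expect_error(build_plume_field(-1, 100), "non-negative")
})

test_that("profile sampling mixes on the runoff line and inverts exactly", {
  em <- test_endmembers()
  cfg <- synthetic_config(noise = FALSE)
  amb <- sealplume:::make_ambient_fun(cfg)
  cal <- calibrate_plume(220, 100, target_fsg = 0.27, target_depth = 64)
  src <- c(431000, 8752200)
  # on the axis, noise off: the watermass module recovers f_core exactly
  smp <- sample_profile_at(src, cal$field, src, amb, em, depths = 41:64,
                           noise = FALSE)
  r <- decompose_fractions(ct_from_insitu(smp$psal, smp$temp_insitu,
                                          smp$pressure),
                           sa_from_sp(smp$psal), em)
  expect_equal(r$f_sg, smp$fsg_true, tolerance = 1e-6)
  expect_equal(max(smp$fsg_true), 0.27, tolerance = 1e-9)
  expect_equal(smp$depth[which.max(smp$fsg_true)], 64)
  # far from the axis the profile is pure ambient
  far <- sample_profile_at(src + c(5000, 0), cal$field, src, amb, em,
                           depths = 1:80, noise = FALSE)
  expect_equal(far$fsg_true, rep(0, 80), tolerance = 1e-12)
  expect_equal(far$sa_true, amb(1:80)[, "sa"], tolerance = 1e-12)
  # zero flux: no salinity departure anywhere
  f0 <- build_plume_field(0, 100)
  none <- sample_profile_at(src, f0, src, amb, em, depths = 1:80,
                            noise = FALSE)
  expect_true(all(none$fsg_true == 0))
})

test_that("campaigns are byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_seals = 1, end = as.Date("2012-08-20"), seed = 5L)
  g <- test_geometry()
  a <- simulate_campaign(cfg, geometry = g)
  b <- simulate_campaign(cfg, geometry = g)
  expect_identical(a$profiles$dives, b$profiles$dives)
  expect_identical(a$profiles$samples, b$profiles$samples)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$truth$dives, b$truth$dives)
})

test_that("near-terminus share is monotone in the behavioural gain", {
  g <- test_geometry()
  shares <- vapply(c(0, 0.4, 0.8), function(gain) {
    sim <- simulate_campaign(
      synthetic_config(n_seals = 2, end = as.Date("2012-09-10"),
                       near_terminus_gain = gain, seed = 3L),
      geometry = g)
    mean(sim$truth$dives$true_region == "kronebreen_near")
  }, 0)
  expect_true(all(diff(shares) >= 0))
  expect_gt(shares[3], shares[1])
})

test_that("uniform placement matches the area ratio under a null behaviour", {
  g <- test_geometry()
  sim <- simulate_campaign(
    synthetic_config(n_seals = 3, end = as.Date("2012-09-15"),
                     near_terminus_base_prob = 0, near_terminus_gain = 0,
                     near_terminus_diffuse_prob = 0, p_value_interp = 0,
                     seed = 13L),
    geometry = g)
  td <- sim$truth$dives
  near <- mean(td$true_region == "kronebreen_near" & !td$designated)
  a <- g$region_areas
  expected <- a[["kronebreen_near"]] / sum(a)
  n <- nrow(td)
  expect_lt(abs(near - expected), 4 * sqrt(expected * (1 - expected) / n))
})

test_that("a runoff-free campaign produces no salinity spikes", {
  cfg <- synthetic_config(n_seals = 1, end = as.Date("2012-08-25"),
                          runoff_peaks = data.frame(day = as.Date(character()),
                                                    amplitude = numeric(),
                                                    width = numeric()),
                          noise = FALSE, seed = 2L)
  sim <- simulate_campaign(cfg, geometry = test_geometry())
  amb <- sealplume:::make_ambient_fun(cfg)
  dev <- sim$profiles$samples$sa_true -
    amb(sim$profiles$samples$depth)[, "sa"]
  expect_true(all(abs(dev) < 5 * cfg$sigma_s))
  expect_equal(length(sim$truth$plume_active_days), 0)
})

test_that("the truth record closes the loop on the configured maximum", {
  sim <- small_campaign()
  td <- sim$truth$dives
  expect_equal(max(td$true_max_fsg), 0.27, tolerance = 1e-9)
  expect_equal(sum(td$designated), 1)
  des <- td[td$designated, ]
  expect_equal(des$true_region, "kronebreen_near")
  # every non-designated dive stays below the calibration cap
  expect_lte(max(td$true_max_fsg[!td$designated]), 0.9 * 0.27 + 1e-9)
  # profile CSV round-trip preserves the campaign
  stem <- tempfile()
  write_profiles_csv(sim$profiles, stem)
  back <- read_profiles_csv(stem)
  expect_equal(back$dives$profile_id, sim$profiles$dives$profile_id)
  expect_equal(back$samples$psal, sim$profiles$samples$psal,
               tolerance = 1e-12)
  unlink(paste0(stem, c("_dives.csv", "_samples.csv")))
})
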