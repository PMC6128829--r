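# Three-endmember decomposition: exact inversion on the simplex, Gade
# endmember arithmetic, spike detection boundaries.

test_that("Gade effective temperature matches hand evaluation", {
  # -1.9 - 3.35e5/3.98e3 - (2.1e3/3.98e3) * (-1.9 + 10) = -90.34472...
  expect_equal(gade_effective_temperature(-1.9), -90.3447, tolerance = 1e-4)
  # no ice-warming term
  expect_equal(gade_effective_temperature(-1.9, ci = 0),
               -1.9 - 3.35e5 / 3.98e3)
  # zero temperature deficit
  expect_equal(gade_effective_temperature(-1.9, Ti = -1.9),
               -1.9 - 3.35e5 / 3.98e3)
  expect_error(gade_effective_temperature(-1.9, cp = 0), "cp")
})

test_that("decomposition inverts convex combinations exactly", {
  em <- test_endmembers()
  # the ambient endmember maps to (1, 0, 0)
  r <- decompose_fractions(em$ambient["theta"], em$ambient["sa"], em)
  expect_equal(unlist(r[1, c("f_ambient", "f_sg", "f_melt")]),
               c(f_ambient = 1, f_sg = 0, f_melt = 0), tolerance = 1e-12)
  expect_true(r$valid)
  # a 0.73/0.27 runoff mixture returns f_sg = 0.27 exactly
  th <- 0.73 * em$ambient[["theta"]] + 0.27 * em$runoff[["theta"]]
  sa <- 0.73 * em$ambient[["sa"]]
  r <- decompose_fractions(th, sa, em)
  expect_equal(r$f_sg, 0.27, tolerance = 1e-12)
  expect_equal(r$f_melt, 0, tolerance = 1e-12)
  # random points on the simplex invert to machine precision
  set.seed(11)
  f <- matrix(rexp(300), ncol = 3)
  f <- f / rowSums(f)
  A <- rbind(c(em$ambient[["theta"]], em$runoff[["theta"]],
               em$meltwater[["theta"]]),
             c(em$ambient[["sa"]], 0, 0))
  th <- f %*% A[1, ]; sa <- f %*% A[2, ]
  r <- decompose_fractions(as.numeric(th), as.numeric(sa), em)
  expect_equal(r$f_ambient, f[, 1], tolerance = 1e-10)
  expect_equal(r$f_sg, f[, 2], tolerance = 1e-10)
  expect_equal(r$f_melt, f[, 3], tolerance = 1e-10)
  # conservation holds to machine precision for arbitrary samples
  th2 <- runif(50, -2, 6); sa2 <- runif(50, 0, 35)
  r2 <- decompose_fractions(th2, sa2, em)
  expect_equal(r2$f_ambient + r2$f_sg + r2$f_melt, rep(1, 50),
               tolerance = 1e-12)
  # pure two-endmember meltwater mixtures have f_sg = 0
  fm <- runif(20)
  r3 <- decompose_fractions((1 - fm) * em$ambient[["theta"]] +
                              fm * em$meltwater[["theta"]],
                            (1 - fm) * em$ambient[["sa"]], em)
  expect_equal(r3$f_sg, rep(0, 20), tolerance = 1e-10)
})

test_that("collinear endmembers are rejected", {
  em <- test_endmembers()
  em$meltwater <- em$runoff  # degenerate
  expect_error(decompose_fractions(1, 30, em), "collinear")
})

test_that("mixing lines start at ambient and end at the endmembers", {
  em <- test_endmembers()
  ml <- mixing_lines(em, n = 11)
  expect_equal(unname(ml$runoff[1, c("theta", "sa")]),
               data.frame(em$ambient[["theta"]], em$ambient[["sa"]]),
               ignore_attr = TRUE)
  expect_equal(ml$runoff$theta[11], em$runoff[["theta"]])
  expect_equal(ml$runoff$sa[11], 0)
  # meltwater line slope dTheta/dS_A = (Theta_a - Theta_m) / S_A_a
  slope <- diff(range(ml$meltwater$theta)) / diff(range(ml$meltwater$sa))
  expect_equal(slope,
               (em$ambient[["theta"]] - em$meltwater[["theta"]]) /
                 em$ambient[["sa"]])
})

test_that("endmembers build from pre-cutoff fjord profiles", {
  # a single constant fjord profile defines the ambient endmember exactly
  prof <- make_profiles(n_samples = 12, psal = sp_from_sa(34.0), temp = 3.0)
  prof$samples$pressure <- seq(15, 125, by = 10)
  prof <- convert_teos10(prof)
  prof$dives$region <- "fjord"
  prof$dives$x <- 434000; prof$dives$y <- 8752000
  em <- build_endmembers(prof, as.Date("2012-09-20"), test_geometry(),
                         reference_pressure = 100)
  expect_equal(em$ambient[["sa"]], 34.0, tolerance = 1e-6)
  expect_equal(em$ambient[["theta"]],
               ct_from_insitu(sp_from_sa(34), 3.0, 90), tolerance = 0.01)
  # cutoff before all data is an error
  expect_error(build_endmembers(prof, as.Date("2012-08-01"), test_geometry()),
               "cutoff")
})

test_that("spike detection threshold is a strict 5-sigma boundary", {
  amb <- function(z) rep(34, length(z))
  smp <- data.frame(profile_id = c("a", "a", "b"),
                    depth = c(50, 60, 55),
                    sa = c(34 - 0.49, 34 - 0.51, 34))
  out <- detect_salinity_spikes(smp, amb, k = 5, sigma_s = 0.1)
  expect_equal(out$is_spike, c(FALSE, TRUE, FALSE))
  expect_equal(unname(out$in_plume), c(TRUE, FALSE))
  expect_equal(out$spikes$depth, 60)
  # identical-to-ambient profile has no spikes
  none <- detect_salinity_spikes(data.frame(profile_id = "c",
                                            depth = 1:10, sa = rep(34, 10)),
                                 amb)
  expect_equal(nrow(none$spikes), 0)
})

test_that("max_fsg returns the maximum over valid in-plume samples", {
  d <- data.frame(profile_id = c("a", "a", "b", "b"),
                  depth = c(40, 64, 30, 50),
                  f_sg = c(0.1, 0.27, 0.5, 0.2),
                  valid = c(TRUE, TRUE, FALSE, TRUE))
  in_plume <- c(a = TRUE, b = FALSE)
  out <- max_fsg(d, in_plume)
  expect_equal(out$f_sg, 0.27)
  expect_equal(out$depth, 64)
  expect_equal(out$profile_id, "a")
  # empty result, not an error
  none <- max_fsg(d[d$valid == FALSE, ], in_plume)
  expect_true(is.na(none$f_sg))
  expect_equal(none$n, 0L)
})

test_that("propagated fraction uncertainty matches Monte Carlo", {
  em <- test_endmembers()
  sig <- fsg_uncertainty(em, sigma_theta = 0.02, sigma_sa = 0.1)
  set.seed(3)
  th <- 0.9 * em$ambient[["theta"]] + 0.1 * em$runoff[["theta"]] +
    rnorm(20000, 0, 0.02)
  sa <- 0.9 * em$ambient[["sa"]] + rnorm(20000, 0, 0.1)
  mc <- sd(decompose_fractions(th, sa, em)$f_sg)
  expect_equal(mc, unname(sig["f_sg"]), tolerance = 0.05)
})
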