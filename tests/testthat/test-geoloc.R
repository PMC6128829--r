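# Dive geolocation: bracketing-fix interpolation, region classification,
# region statistics, density gridding.

fix_at <- function(t, x, y) {
  list(seal_id = "s1", time = as.POSIXct(t, tz = "UTC"), x = x, y = y)
}

test_that("dive locations interpolate linearly in time between fixes", {
  f0 <- fix_at("2012-08-10 10:00:00", 1000, 2000)
  f1 <- fix_at("2012-08-10 12:00:00", 2000, 2000)
  # at the first fix
  at0 <- interpolate_dive_location(f0, f1, f0$time)
  expect_equal(c(at0$x, at0$y), c(1000, 2000))
  expect_equal(at0$location_source, "interpolated")
  # exactly midway between fixes 1000 m apart: midpoint, 500 m from each
  mid <- interpolate_dive_location(f0, f1, as.POSIXct("2012-08-10 11:00:00",
                                                      tz = "UTC"))
  expect_equal(c(mid$x, mid$y), c(1500, 2000))
  # hand-computed time ratios
  for (mins in c(15, 45, 100)) {
    p <- interpolate_dive_location(f0, f1, f0$time + mins * 60)
    expect_equal(p$x, 1000 + 1000 * mins / 120)
  }
  # coincident fixes return the common position
  same <- interpolate_dive_location(f0, f0, f0$time)
  expect_equal(same$x, 1000)
  # outside the bracket is an error
  expect_error(interpolate_dive_location(f0, f1, f1$time + 1), "outside")
  f_other <- f1; f_other$seal_id <- "s2"
  expect_error(interpolate_dive_location(f0, f_other, f0$time), "seals")
})

test_that("region classification is total, deterministic, tie-broken", {
  g <- test_geometry()
  on_line <- g$kronebreen[1, ]
  expect_equal(classify_region(on_line, g), "kronebreen_near")
  # > 500 m from both termini, inside polygon
  mid <- c(mean(g$fjord[, 1]), mean(g$fjord[, 2]))
  expect_equal(classify_region(mid, g), "fjord")
  # outside the polygon
  expect_equal(classify_region(g$fjord[1, ] - c(2000, 2000), g), "outside")
  # equidistant within buffer of two fronts resolves to Kronebreen
  g2 <- terminus_geometry(cbind(c(0, 0), c(0, 1000)),
                          cbind(c(800, 800), c(0, 1000)),
                          cbind(c(-100, 900, 900, -100), c(-100, -100, 1100, 1100)),
                          buffer_distance = 500, zone = 33,
                          region_areas = c(kronebreen_near = 0.55,
                                           kongsbreen_near = 0.45,
                                           fjord = 0.1))
  expect_equal(classify_region(c(400, 500), g2), "kronebreen_near")
  # classification is total over random points
  set.seed(5)
  pts <- cbind(runif(200, 425000, 445000), runif(200, 8745000, 8760000))
  expect_true(all(classify_region(pts, g) %in%
                    c("kronebreen_near", "kongsbreen_near", "fjord",
                      "outside")))
})

test_that("region percentages reproduce printed-count arithmetic", {
  regions <- rep(c("kronebreen_near", "kongsbreen_near", "fjord"),
                 c(277, 32, 339))
  tab <- region_percentages(regions)
  expect_equal(tab$percent_int, c(43, 5, 52))
  expect_equal(tab$percent, c(42.7, 4.9, 52.3))
  expect_equal(sum(tab$count), 648)
  # all profiles in one region
  expect_equal(region_percentages(rep("fjord", 7))$percent_int[
    region_percentages(rep("fjord", 7))$region == "fjord"], 100)
  # simple quarters
  tab2 <- region_percentages(rep(c("kronebreen_near", "kongsbreen_near",
                                   "fjord"), c(1, 1, 2)))
  expect_equal(tab2$percent, c(25, 25, 50))
  expect_error(region_percentages(character(0)), "no classified")
})

test_that("uniform expectation lies in the printed 4-5% band", {
  g <- test_geometry()
  g$region_areas <- c(kronebreen_near = 2.0, kongsbreen_near = 1.6,
                      fjord = 42.6)
  for (denom in c("total", "fjord")) {
    e <- uniform_expectation(g, denom)
    expect_gte(e[["kronebreen_near"]], 4)
    expect_lte(e[["kronebreen_near"]], 5)
  }
  # a region covering the whole study area expects 100%
  g$region_areas <- c(kronebreen_near = 42.6, kongsbreen_near = 1e-9,
                      fjord = 1e-9)
  expect_equal(uniform_expectation(g, "total")[["kronebreen_near"]], 100,
               tolerance = 1e-6)
  g$region_areas <- c(kronebreen_near = 1, kongsbreen_near = 1, fjord = 2)
  expect_equal(unname(uniform_expectation(g, "total")), c(25, 25))
})

test_that("synthetic geometry areas approximate the study's regions", {
  a <- test_geometry()$region_areas
  expect_equal(a[["kronebreen_near"]], 2.0, tolerance = 0.05)
  expect_equal(a[["kongsbreen_near"]], 1.6, tolerance = 0.05)
  expect_equal(a[["fjord"]], 42.6, tolerance = 0.05)
})

test_that("density grid uses half-open bins and conserves counts", {
  pts <- matrix(rep(c(430050, 8750050), each = 5), ncol = 2)
  g <- density_grid(pts, 100)
  expect_equal(sum(g$counts), 5)
  expect_equal(max(g$counts), 5)
  # a point exactly on a bin edge goes to the higher bin
  g2 <- density_grid(rbind(c(100, 0)), 100, origin = c(0, 0))
  expect_equal(dim(g2$counts), c(2, 1))
  expect_equal(g2$counts[2, 1], 1L)
  # conservation under origin shift for random scatter
  set.seed(9)
  pts <- cbind(runif(300, 0, 2000), runif(300, 0, 1500))
  for (shift in c(0, 37, 50)) {
    gg <- density_grid(pts, 100, origin = c(-shift, -shift))
    expect_equal(sum(gg$counts), 300)
  }
})

test_that("geometry GeoJSON round-trips through WGS84", {
  g <- test_geometry()
  path <- tempfile(fileext = ".geojson")
  write_geometry_geojson(g, path)
  g2 <- read_geometry_geojson(path)
  expect_equal(g2$zone, g$zone)
  expect_equal(g2$buffer_distance, g$buffer_distance)
  expect_equal(g2$kronebreen, g$kronebreen, tolerance = 1e-6)
  expect_equal(g2$fjord, g$fjord, tolerance = 1e-6)
  expect_equal(g2$region_areas, g$region_areas, tolerance = 1e-6)
  unlink(path)
})
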