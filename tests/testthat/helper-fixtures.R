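# Shared fixtures, built in code. Geometry construction integrates region
# areas, so cache one instance per test run.

test_geometry <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- synthetic_fjord_geometry()
    g
  }
})

# a small noise-free campaign for unit tests (2 seals, two months)
small_campaign <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) {
      sim <<- simulate_campaign(
        synthetic_config(n_seals = 2, end = as.Date("2012-09-30"),
                         noise = FALSE, seed = 7L),
        geometry = test_geometry())
    }
    sim
  }
})

# hand-built raw profile set: one seal, constant water column unless
# overridden
make_profiles <- function(n_dives = 1, n_samples = 5,
                          psal = 33, temp = 3,
                          interp_run = 0L, interp_s_at = integer(0),
                          lon = 12.4, lat = 78.93) {
  dives <- data.frame(
    profile_id = sprintf("p%02d", seq_len(n_dives)),
    seal_id = "s1",
    dive_time = as.POSIXct("2012-08-15 06:00:00", tz = "UTC") +
      3600 * seq_len(n_dives),
    lon = lon, lat = lat,
    location_source = "gps",
    interp_run_length = as.integer(interp_run)
  )
  samples <- do.call(rbind, lapply(seq_len(n_dives), function(i) {
    data.frame(profile_id = dives$profile_id[i],
               pressure = seq(10, by = 10, length.out = n_samples),
               temp_insitu = rep_len(temp, n_samples),
               psal = rep_len(psal, n_samples),
               interp_t = FALSE,
               interp_s = seq_len(n_samples) %in% interp_s_at)
  }))
  profile_set(dives, samples)
}

# default endmembers for decomposition tests
test_endmembers <- function() {
  endmember_set(c(2.8, 34.3), reference_pressure = 100)
}
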