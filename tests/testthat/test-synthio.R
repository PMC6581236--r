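# Synthetic-data generation: registries, calibrated tracks, waveform
# traces, dataset round-trips.

test_that("make_birds draws the configured population", {
  b <- make_birds(20, seed = 1)
  expect_equal(nrow(b), 20)
  expect_lt(abs(mean(b$solo_freq_hz) - 5.48), 3 * 0.19 / sqrt(20))
  expect_true(all(b$tarsus_mm > 0 & b$mass_g > 0))
  expect_true(all(b$solo_freq_hz > 2 & b$solo_freq_hz < 12))
  # degenerate distribution
  one <- make_birds(1, seed = 2, freq_sd_hz = 0, tarsus_sd_mm = 0,
                    mass_sd_g = 0)
  expect_equal(one$solo_freq_hz, 5.48)
  expect_equal(one$tarsus_mm, 33.5)
  expect_equal(one$mass_g, 450)
  # determinism
  expect_identical(make_birds(12, seed = 9), make_birds(12, seed = 9))
  expect_error(make_birds(0), ">= 1")
  expect_error(make_birds(5, freq_sd_hz = -1), ">= 0")
})

test_that("truth_record validates its invariants", {
  expect_error(truth_record(accuracy_solo = 1.2), "accuracy")
  expect_error(truth_record(upstroke_frac = 1.2), "upstroke")
  expect_error(truth_record(residual_sd_hz = -0.1), "residual")
  tr <- truth_record()
  expect_equal(tr$delta0_hz, 1.00)
  expect_equal(tr$spacing_slope_hz_per_m, -0.011)
})

test_that("Bessel-ratio calibration: mean cosine matches the target", {
  set.seed(13)
  for (a in c(0.3, 0.6, 0.86, 0.95, 0.99)) {
    kappa <- vm_concentration(a)
    expect_lt(abs(mean(cos(rvonmises(1e4, kappa))) - a), 0.01)
  }
  expect_error(vm_concentration(0), "strictly")
  expect_error(vm_concentration(1), "strictly")
})

test_that("simulate_track calibration: straight line and target mean", {
  birds <- make_birds(2, seed = 1)
  truth <- truth_record()
  plan <- list(flight_id = "T1", condition = "solo", bird1 = "S01",
               wind_speed_ms = 0, wind_dir_deg = 0)
  exact <- simulate_track(plan, birds, truth, seed = 1, gps_jitter_sd = 0,
                          accuracy = 1)[[1]]
  expect_equal(route_accuracy(exact, LOFT), 1, tolerance = 1e-3)
  accs <- vapply(1:40, function(i) {
    g <- simulate_track(plan, birds, truth, seed = i, gps_jitter_sd = 0)[[1]]
    route_accuracy(g, LOFT)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.86), 0.01)
  expect_error(simulate_track(plan, birds, truth, accuracy = 1.5), "accuracy")
})

test_that("paired tracks stay within range with a consistent leader", {
  birds <- make_birds(2, seed = 1)
  truth <- truth_record()
  plan <- list(flight_id = "P1", condition = "pair", bird1 = "S01",
               bird2 = "S02", wind_speed_ms = 3, wind_dir_deg = 200)
  ok <- 0
  for (i in 1:5) {
    g <- simulate_track(plan, birds, truth, seed = 100 + i)
    ps <- pair_spacing(g[[1]], g[[2]])
    ok <- ok + (mean(ps$matches$within_range) >= 0.8)
    expect_equal(ps$median_spacing_m, truth$spacing_mean_m,
                 tolerance = 0.4)
    expect_equal(ps$front_bird, "A")
  }
  expect_equal(ok, 5)
})

test_that("simulate_accel round-trips through the kinematics pipeline", {
  birds <- make_birds(1, seed = 3, freq_sd_hz = 0)  # mu = 5.48 exactly
  truth <- truth_record(residual_sd_hz = 0)
  plan <- list(flight_id = "A1", condition = "solo", bird1 = "S01")
  tr <- simulate_accel(plan, birds, truth, seed = 4)[[1]]
  wb <- wingbeat_metrics(tr)
  expect_equal(median(wb$freq_hz), 5.48, tolerance = 0.01 / 5.48)
  expect_equal(median(wb$pp_accel_g), 2.5, tolerance = 0.02)
  # pure-sinusoid mode matches the harmonic closed form
  sin_tr <- simulate_accel(plan, birds, truth, seed = 4,
                           waveform = "sinusoid")[[1]]
  wb_s <- wingbeat_metrics(sin_tr)
  expect_equal(median(wb_s$pp_disp_mm, na.rm = TRUE),
               2.5 * 9.80665 / (2 * pi * 5.48)^2 * 1000,
               tolerance = 0.5 / 20.7)
  # determinism
  tr2 <- simulate_accel(plan, birds, truth, seed = 4)[[1]]
  expect_identical(tr$az_g, tr2$az_g)
  # non-positive frequency is rejected
  bad <- truth_record(delta0_hz = -20, residual_sd_hz = 0)
  plan2 <- list(flight_id = "A2", condition = "pair", bird1 = "S01",
                bird2 = "S01")
  expect_error(simulate_accel(plan2, birds, bad, seed = 1), "non-positive")
})

test_that("paired waveform upstroke shortening is recoverable", {
  # mu 5.48 and a pairing shift chosen to shorten the upstroke by
  # 28.63 ms while the downstroke stays fixed
  birds <- make_birds(2, seed = 3, freq_sd_hz = 0)
  f_pair <- 1 / (1 / 5.48 - 0.02863)
  truth <- truth_record(delta0_hz = f_pair - 5.48, residual_sd_hz = 0,
                        spacing_slope_hz_per_m = 0)
  solo <- simulate_accel(list(flight_id = "S", condition = "solo",
                              bird1 = "S01"), birds, truth, seed = 5)[[1]]
  pair <- simulate_accel(list(flight_id = "P", condition = "pair",
                              bird1 = "S01", bird2 = "S02"),
                         birds, truth, seed = 5)[[1]]
  up_solo <- median(wingbeat_metrics(solo)$up_ms)
  up_pair <- median(wingbeat_metrics(pair)$up_ms)
  down_solo <- median(wingbeat_metrics(solo)$down_ms)
  down_pair <- median(wingbeat_metrics(pair)$down_ms)
  expect_equal(up_pair - up_solo, -28.63, tolerance = 0.1)
  # the generated downstroke is exactly constant; the smoothing step of
  # the full pipeline shifts the apex slightly more at the paired
  # curvature ratio, hence the 2 ms allowance here (the raw-waveform
  # phase checks in test-kinematics pin the durations at +/- 1 ms)
  expect_lt(abs(down_pair - down_solo), 2)
})

test_that("emit_dataset round-trips and is byte-deterministic", {
  birds <- make_birds(4, seed = 6)
  truth <- truth_record()
  plans <- make_flight_plans(birds, flights_per_phase = 1, seed = 6)
  plans <- plans[plans$phase %in% c(1, 2), ][1:3, ]
  tracks <- list(); traces <- list()
  for (i in seq_len(nrow(plans))) {
    tracks <- c(tracks, simulate_track(plans[i, ], birds, truth,
                                       seed = i,
                                       release = as.list(
                                         destination_point(LOFT$lat,
                                                           LOFT$lon,
                                                           282, 900))))
    traces <- c(traces, simulate_accel(plans[i, ], birds, truth, seed = i,
                                       duration_s = 5))
  }
  weather <- weather_table(plans, duration_s = 120)
  d1 <- file.path(tempdir(), "pf_ds1")
  emit_dataset(plans, tracks, traces, weather, birds, d1, truth)
  ds <- read_dataset(d1)
  expect_equal(ds$birds, birds)
  expect_equal(nrow(ds$flights), nrow(plans))
  expect_equal(ds$gps$lat_deg,
               unlist(lapply(tracks, function(t) t$lat_deg)))
  expect_equal(ds$accel$az_g,
               unlist(lapply(traces, function(t) t$az_g)))
  expect_equal(ds$truth$delta0_hz, truth$delta0_hz)
  # byte-identical on re-emission
  d2 <- file.path(tempdir(), "pf_ds2")
  emit_dataset(plans, tracks, traces, weather, birds, d2, truth)
  for (f in c("birds.csv", "gps.csv", "accel.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # empty plans still give schema-valid files
  d3 <- file.path(tempdir(), "pf_ds3")
  empty_plans <- plans[0, ]
  emit_dataset(empty_plans, list(), list(), weather_table(empty_plans),
               birds, d3, truth)
  g <- read_dataset(d3)
  expect_equal(nrow(g$gps), 0)
  expect_true(all(c("t_s", "lat_deg", "lon_deg") %in% names(g$gps)))
  # id mismatch is reported with the offender
  bad_tracks <- tracks
  attr(bad_tracks[[1]], "flight_id") <- "NOPE"
  expect_error(emit_dataset(plans, bad_tracks, traces, weather, birds,
                            tempdir(), truth), "NOPE")
})

test_that("flight plans follow the 4-phase design", {
  birds <- make_birds(6, seed = 2)
  plans <- make_flight_plans(birds, flights_per_phase = 2, seed = 2)
  expect_setequal(unique(plans$phase), 1:4)
  expect_true(all(plans$condition[plans$phase %in% c(1, 4)] == "solo"))
  expect_true(all(plans$condition[plans$phase %in% c(2, 3)] == "pair"))
  expect_true(all(is.na(plans$bird2[plans$condition == "solo"])))
  expect_true(all(!is.na(plans$bird2[plans$condition == "pair"])))
  expect_true(all(plans$wind_speed_ms < 7))
  # similar pairs have smaller tarsus differences than different pairs
  td <- function(ph) {
    p <- plans[plans$phase == ph, ]
    mean(abs(birds$tarsus_mm[match(p$bird1, birds$bird_id)] -
               birds$tarsus_mm[match(p$bird2, birds$bird_id)]))
  }
  expect_lt(td(2), td(3))
})
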