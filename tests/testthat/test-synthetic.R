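test_that("degenerate parameters give a clean triangular run", {
  cfg <- synthetic_config(n_excursions_mean = 0, travel_speed_kmd_sd = 0,
                          residence_days_mean = 0, residence_days_sd = 0,
                          dwell_jitter_km = 0, entry_date_sd = c(lower = 0, upper = 0))
  set.seed(51)
  tr <- simulate_track("upper", 2017, cfg)
  km <- tr$river_km
  peak <- which.max(km)
  expect_true(all(diff(km[1:peak]) >= 0))
  expect_true(all(diff(km[peak:length(km)]) <= 0))
  expect_gte(max(km), 160); expect_lte(max(km), 200)
  expect_lt(km[1], 43); expect_lt(km[length(km)], 43)
})

test_that("upper-contingent retreats stay above the retreat floor", {
  set.seed(52)
  cfg <- synthetic_config()
  for (i in 1:20) {
    tr <- simulate_track("upper", 2017, cfg)
    km <- tr$river_km
    reach <- which(km >= 160)
    expect_gte(min(km[min(reach):max(reach)]), 150)
    expect_lte(max(km), 245)
  }
})

test_that("simulated entry dates centre on the configured mean", {
  set.seed(53)
  cfg <- synthetic_config()
  entries <- replicate(1000, {
    tr <- simulate_track("lower", 2017, cfg)
    as.numeric(min(tr$date[tr$river_km >= 43]))
  })
  target <- as.numeric(as.Date("2017-04-18"))
  expect_lt(abs(mean(entries) - target), 2)
})

test_that("detection emission respects the probability extremes", {
  set.seed(54)
  recv <- default_receivers_for_test()
  tr <- simulate_track("upper", 2017, synthetic_config())
  in_array <- tr$date[tr$river_km >= 43 & tr$river_km <= 245]
  ev1 <- emit_detections("f", tr, recv, daily_detection_prob = 1)
  days1 <- unique(as.Date(ev1$timestamp - 5 * 3600, tz = "UTC"))
  expect_setequal(as.character(days1), as.character(in_array))
  ev0 <- emit_detections("f", tr, recv, daily_detection_prob = 0)
  expect_equal(nrow(ev0), 0L)
  expect_error(emit_detections("f", tr, recv[0, ], 1), "no river receivers")
})

test_that("every detection lies within one receiver spacing of the latent position", {
  set.seed(55)
  recv <- default_receivers_for_test()
  riv <- recv[!is.na(recv$river_km), ]
  spacing <- max(diff(sort(riv$river_km)))
  tr <- simulate_track("lower", 2017, synthetic_config())
  ev <- emit_detections("f", tr, recv, daily_detection_prob = 1)
  d <- as.Date(ev$timestamp - 5 * 3600, tz = "UTC")
  km_recv <- riv$river_km[match(ev$receiver_id, riv$receiver_id)]
  km_true <- tr$river_km[match(d, tr$date)]
  expect_true(all(abs(km_recv - km_true) <= spacing))
})

test_that("observed-day counts per run bracket the field calibration", {
  set.seed(56)
  sim <- simulate_runs(synthetic_config(n_fish = c(lower = 250, upper = 250)),
                       years = 2017)
  riv <- sim$receivers[!is.na(sim$receivers$river_km), ]
  det <- sim$detections[sim$detections$receiver_id %in% riv$receiver_id, ]
  day <- as.Date(det$timestamp - 5 * 3600, tz = "UTC")
  obs_days <- tapply(day, det$tag_id, function(d) length(unique(d)))
  expect_gte(mean(obs_days), 14)
  expect_lte(mean(obs_days), 34)
})

test_that("mortality draws are exponential with censoring at study end", {
  set.seed(57)
  exit <- as.Date("2017-06-01")
  m0 <- simulate_mortality(rep(exit, 50), 0, as.Date("2017-12-31"))
  expect_true(all(!m0$event))
  expect_true(all(m0$last_date == as.Date("2017-12-31")))
  m <- simulate_mortality(rep(exit, 1e4), 5e-3, exit + 1e5)
  expect_lt(abs(mean(m$time_days) - 200) / 200, 0.03)
  expect_error(simulate_mortality(exit, 5e-3, exit - 1), "invalid window")
  expect_error(simulate_mortality(exit, -1, exit + 10), ">= 0")
})

test_that("environmental series follows the configured logistic warming", {
  cfg <- synthetic_config()
  env <- simulate_environment(2017, cfg)
  expect_equal(temperature_at(env, as.Date("2017-05-01")), 13.5)
  expect_true(all(diff(env$water_temp_C) >= 0))
  expect_true(all(env$discharge_m3s > 0))
  expect_lt(env$water_temp_C[1], 5); expect_gt(env$water_temp_C[nrow(env)], 22)
  # zero scale degenerates to a step at the midpoint
  step <- simulate_environment(2017, synthetic_config(temp_scale_days = 0))
  expect_equal(temperature_at(step, as.Date("2017-04-30")), 4)
  expect_equal(temperature_at(step, as.Date("2017-05-01")), 13.5)
  expect_equal(temperature_at(step, as.Date("2017-05-02")), 23)
  # shifting the midpoint shifts the experienced-temperature lookup
  late <- simulate_environment(2017, synthetic_config(temp_midpoint = "05-06"))
  expect_equal(temperature_at(late, as.Date("2017-05-06")), 13.5)
  expect_lt(temperature_at(late, as.Date("2017-05-01")),
            temperature_at(env, as.Date("2017-05-01")))
})

test_that("identical config and seed reproduce the detection log exactly", {
  cfg <- synthetic_config(n_fish = c(lower = 5, upper = 5))
  s1 <- simulate_runs(cfg, years = c(2017, 2018), seed = 99)
  s2 <- simulate_runs(cfg, years = c(2017, 2018), seed = 99)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$truth, s2$truth)
})

test_that("config validation rejects impossible parameters", {
  expect_error(synthetic_config(daily_detection_prob = 1.2), "0, 1")
  expect_error(synthetic_config(post_run_hazard_per_day = c(lower = -1, upper = 0)),
               "non-negative")
  expect_error(synthetic_config(retreat_floor_km = c(lower = 120, upper = 150)),
               "target reach")
})
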