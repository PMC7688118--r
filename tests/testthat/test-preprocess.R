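test_that("daily mean position averages within-day detections", {
  recv <- data.frame(receiver_id = c("A", "B", "C", "S"),
                     river_km = c(90, 120, 43, NA),
                     region = c(NA, NA, NA, "MA"))
  ts <- function(s) as.POSIXct(s, tz = "UTC")
  ev <- data.frame(tag_id = "f", receiver_id = c("A", "B", "C", "A", "A", "B", "S"),
                   timestamp = ts(c("2017-05-01 10:00", "2017-05-01 20:00",
                                    "2017-05-02 12:00", "2017-05-03 08:00",
                                    "2017-05-03 09:00", "2017-05-03 10:00",
                                    "2017-05-04 10:00")))
  out <- daily_mean_position(ev, recv, tz_offset_hours = 0)
  expect_equal(out$river_km, c((90 + 120) / 2, 43, (90 + 90 + 120) / 3))
  expect_equal(out$date, as.Date(c("2017-05-01", "2017-05-02", "2017-05-03")))
  # shelf-only day (S) contributes nothing; unknown receiver errors by name
  ev$receiver_id[1] <- "ZZ"
  expect_error(daily_mean_position(ev, recv), "ZZ")
})

test_that("daily binning uses the configured local civil date", {
  recv <- data.frame(receiver_id = "A", river_km = 100, region = NA)
  ev <- data.frame(tag_id = "f", receiver_id = "A",
                   timestamp = as.POSIXct("2017-05-02 03:00:00", tz = "UTC"))
  expect_equal(daily_mean_position(ev, recv, tz_offset_hours = -5)$date,
               as.Date("2017-05-01"))
  expect_equal(daily_mean_position(ev, recv, tz_offset_hours = 0)$date,
               as.Date("2017-05-02"))
})

test_that("EWMA imputation matches hand-computed weighted means", {
  expect_equal(unclass(impute_gaps(c(5, NA, 5)))[2], 5)
  expect_equal(as.numeric(impute_gaps(c(0, NA, NA, 3))), c(0, 1, 2, 3))
  # no gaps: unchanged, nothing marked imputed
  x <- c(1, 2, 3)
  expect_equal(as.numeric(impute_gaps(x)), x)
  expect_false(any(attr(impute_gaps(x), "imputed")))
  # observed values never change, imputed bounded by in-window neighbours
  set.seed(21)
  for (i in 1:20) {
    y <- runif(15, 35, 200)
    miss <- sample(2:14, 4)
    z <- y; z[miss] <- NA
    filled <- impute_gaps(z)
    expect_equal(as.numeric(filled)[-miss], y[-miss])
    for (m in miss) {
      nb <- which(!is.na(z) & abs(seq_along(z) - m) <= 4)
      expect_gte(as.numeric(filled)[m], min(z[nb]) - 1e-12)
      expect_lte(as.numeric(filled)[m], max(z[nb]) + 1e-12)
    }
  }
})

test_that("wide gaps fall back to linear interpolation with a message", {
  x <- c(0, rep(NA, 9), 10)
  expect_message(filled <- impute_gaps(x, window = 4), "linear")
  # one-sided EWMA where a window neighbour exists; linear bridge at the
  # centre point that no window reaches
  expect_equal(as.numeric(filled), c(0, 0, 0, 0, 0, 5, 10, 10, 10, 10, 10))
  expect_error(impute_gaps(c(NA, 1, 2)), "padding")
  expect_error(impute_gaps(c(1, NA, NA)), "two observed")
})

test_that("run extraction takes the outermost threshold crossings", {
  mk <- function(kms) data.frame(date = as.Date("2017-04-01") + seq_along(kms) - 1,
                                 river_km = kms, provenance = "observed")
  expect_null(extract_run(mk(c(40, 41, 42))))
  seg <- extract_run(mk(c(40, 50, 60, 50, 40)))
  expect_equal(seg$entry_date, as.Date("2017-04-02"))
  expect_equal(seg$exit_date, as.Date("2017-04-04"))
  # double crossing: outermost bounds, interior dip retained verbatim
  seg2 <- extract_run(mk(c(40, 50, 40, 50, 40)))
  expect_equal(seg2$entry_date, as.Date("2017-04-02"))
  expect_equal(seg2$exit_date, as.Date("2017-04-04"))
  expect_equal(seg2$series$river_km, c(50, 40, 50))
})

test_that("catenation pads every series to the union span at exactly pad km", {
  s1 <- make_segment("2017-04-10", rep(50, 22))   # Apr 10 - May 1
  s2 <- make_segment("2017-04-20", rep(60, 31))   # Apr 20 - May 20
  s3 <- make_segment("2017-04-15", rep(70, 26))   # Apr 15 - May 10
  X <- catenate_pad(list(a = s1, b = s2, c = s3), pad_km = 35)
  expect_equal(ncol(X), 41L)  # Apr 10 .. May 20
  expect_equal(dim(attr(X, "provenance")), dim(unclass(X)))
  P <- attr(X, "provenance")
  expect_true(all(unclass(X)[P == "pad"] == 35))
  expect_identical(unique(unclass(X)[P == "pad"]), 35)  # bit-exact
  expect_equal(unname(unclass(X)["a", 1:22]), rep(50, 22))
  expect_equal(unname(unclass(X)["b", 1:10]), rep(35, 10))
  # single segment: equals its own span, no interior padding
  X1 <- catenate_pad(list(only = s1))
  expect_equal(ncol(X1), 22L)
  expect_true(all(attr(X1, "provenance") == "observed"))
  expect_error(catenate_pad(list()), "no run segments")
})

test_that("shifting all detections by one day shifts entry/exit by one day", {
  recv <- data.frame(receiver_id = sprintf("R%02d", 1:21),
                     river_km = seq(43, 243, by = 10), region = NA)
  set.seed(31)
  cfg <- synthetic_config(n_fish = c(lower = 1, upper = 1))
  tr <- simulate_track("upper", 2017, cfg)
  ev <- emit_detections("f1", tr, recv, daily_detection_prob = 0.8)
  chain <- function(events) {
    sp <- daily_mean_position(events, recv)
    extract_run(dense_daily_series(sp))
  }
  base <- chain(ev)
  ev2 <- ev; ev2$timestamp <- ev2$timestamp + 86400
  shifted <- chain(ev2)
  expect_equal(shifted$entry_date, base$entry_date + 1)
  expect_equal(shifted$exit_date, base$exit_date + 1)
})
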