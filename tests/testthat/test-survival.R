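test_that("Kaplan-Meier reproduces the no-censoring closed forms", {
  # 21 fish, 9 deaths at distinct times, 12 followed to one year
  rec <- make_records(death_times = seq(30, 270, by = 30), n_censored = 12,
                      end = 365)
  km <- kaplan_meier(rec)
  at <- km_at(km, 365)
  expect_equal(unname(at["surv"]), 12 / 21)
  expect_equal(round(100 * at["surv"], 1), c(surv = 57.1))
  expect_equal(unname(at["se"]), sqrt((12 / 21) * (9 / 21) / 21))
  expect_equal(round(100 * at["se"], 1), c(se = 10.8))
  # 45 fish, 8 deaths
  rec2 <- make_records(seq(20, 160, by = 20), 37, 365)
  at2 <- km_at(kaplan_meier(rec2), 365)
  expect_equal(round(100 * at2, 1), c(surv = 82.2, se = 5.7))
  # no events: flat survival
  rec3 <- make_records(numeric(0), 5, 100)
  expect_equal(nrow(kaplan_meier(rec3)$curve), 0L)
  expect_equal(unname(km_at(kaplan_meier(rec3), 50)), c(1, 0))
})

test_that("Kaplan-Meier agrees with the survival package on censored data", {
  set.seed(41)
  for (i in 1:10) {
    n <- 40
    time <- round(rexp(n, 1 / 200)) + 1
    event <- runif(n) < 0.7
    km <- kaplan_meier(time, event)
    sf <- summary(survival::survfit(survival::Surv(time, event) ~ 1))
    expect_equal(km$curve$surv, sf$surv, tolerance = 1e-10)
    pos <- km$curve$surv > 0   # Greenwood SE is degenerate once S hits 0
    expect_equal(km$curve$se[pos], sf$std.err[pos], tolerance = 1e-10)
    expect_equal(km$curve$n_risk, as.numeric(sf$n.risk))
  }
})

test_that("uncensored KM equals the empirical survivor function", {
  set.seed(42)
  for (i in 1:10) {
    time <- sample(1:500, 25, replace = TRUE)
    km <- kaplan_meier(time, rep(TRUE, 25))
    for (t in sample(1:500, 5)) {
      at <- km_at(km, t)
      p <- mean(time > t)
      expect_equal(unname(at["surv"]), p)
      expect_equal(unname(at["se"]), sqrt(p * (1 - p) / 25))
    }
  }
})

test_that("loss rate is exact on a forced exponential decline", {
  t <- 0:100
  fit <- loss_rate(data.frame(day = t, count = 66 * exp(-0.005 * t)))
  expect_equal(fit$Z, 0.005, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(loss_rate(data.frame(day = 0:10, count = rep(7, 11)))$Z, 0)
  expect_error(loss_rate(data.frame(day = 0:1, count = c(2, 1))), "at least 3")
  # zero-count dates are dropped, not log-transformed
  fit2 <- loss_rate(data.frame(day = 0:20,
                               count = c(66 * exp(-0.005 * 0:19), 0)))
  expect_equal(fit2$Z, 0.005, tolerance = 1e-12)
})

test_that("loss rate recovers a simulated hazard", {
  set.seed(43)
  mort <- simulate_mortality(rep(as.Date("2017-06-01"), 500), 4.9e-3,
                             as.Date("2018-06-01"))
  rec <- data.frame(origin_date = as.Date("2017-06-01"),
                    end_date = mort$last_date, event = mort$event)
  fit <- loss_rate(rec)
  expect_lt(abs(fit$Z - 4.9e-3) / 4.9e-3, 0.10)
})

test_that("identical groups give a null weighted log-rank statistic", {
  rec <- make_records(c(10, 40, 90), 5, 365)
  tst <- weighted_logrank(rec, rec)
  expect_equal(tst$statistic, 0)
  expect_equal(tst$p_value, 1)
  expect_error(weighted_logrank(make_records(numeric(0), 3, 10),
                                make_records(numeric(0), 3, 10)), "no events")
})

test_that("unit weights reduce exactly to the standard log-rank test", {
  set.seed(44)
  for (i in 1:10) {
    a <- make_records(sort(sample(1:300, 8)), 6, 365, "a")
    b <- make_records(sort(sample(1:300, 12)), 4, 365, "b")
    mine <- weighted_logrank(a, b, weights = "logrank")
    both <- rbind(a, b)
    sd0 <- survival::survdiff(
      survival::Surv(time_days, event) ~ group, data = both, rho = 0)
    expect_equal(mine$statistic, unname(sd0$chisq), tolerance = 1e-10)
  }
})

test_that("chi-square p approximates the permutation null at moderate n", {
  set.seed(45)
  a <- make_records(c(20, 45, 80, 120, 200, 260), 9, 365, "a")
  b <- make_records(c(60, 140, 210, 280, 330), 10, 365, "b")
  obs <- weighted_logrank(a, b)$statistic
  pool_t <- c(a$time_days, b$time_days)
  pool_e <- c(a$event, b$event)
  na <- nrow(a)
  stats <- replicate(2000, {
    idx <- sample(length(pool_t), na)
    pa <- data.frame(time_days = pool_t[idx], event = pool_e[idx])
    pb <- data.frame(time_days = pool_t[-idx], event = pool_e[-idx])
    weighted_logrank(pa, pb)$statistic
  })
  p_perm <- mean(stats >= obs - 1e-12)
  p_chisq <- weighted_logrank(a, b)$p_value
  expect_lt(abs(p_perm - p_chisq), 0.06)
})

test_that("differential hazards of the field scenario are usually detected", {
  # lower-reach-like hazard 4.9e-3 vs upper-reach-like 1.0e-3, n = 21 vs 45
  set.seed(46)
  hits <- replicate(20, {
    ta <- pmin(rexp(21, 4.9e-3), 365); tb <- pmin(rexp(45, 1.0e-3), 365)
    a <- data.frame(time_days = ta, event = ta < 365)
    b <- data.frame(time_days = tb, event = tb < 365)
    weighted_logrank(a, b)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("record building censors inside the terminal window only", {
  ts <- function(d) as.POSIXct(paste(d, "12:00:00"), tz = "UTC")
  det <- data.frame(
    tag_id = c("A", "A", "B", "B", "C"),
    timestamp = ts(c("2017-06-10", "2017-09-15", "2017-06-10", "2017-12-31",
                     "2016-01-01")),
    receiver_id = "R1")
  groups <- c(A = "lower", B = "lower", C = "upper")
  origin <- as.Date(c(A = "2017-06-01", B = "2017-06-01", C = "2017-06-01"))
  expect_message(
    rec <- build_records(det, groups, origin,
                         as.Date(c("2017-06-01", "2017-12-31")),
                         censor_window_days = 30),
    "excluded")
  expect_equal(nrow(rec), 2L)
  a <- rec[rec$tag_id == "A", ]
  expect_true(a$event)                     # 100+ d before period end
  expect_equal(a$end_date, as.Date("2017-09-15"))
  b <- rec[rec$tag_id == "B", ]
  expect_false(b$event)                    # last seen on the period end date
  expect_equal(b$end_date, as.Date("2017-12-31"))
})

test_that("record events recover true death dates from the detection log", {
  cfg <- synthetic_config(n_fish = c(lower = 10, upper = 10),
                          shelf_detection_prob = 1)  # detected daily at large
  sim <- simulate_runs(cfg, years = 2017, seed = 47)
  truth <- sim$truth
  groups <- setNames(truth$true_contingent, truth$tag_id)
  origin <- setNames(truth$true_exit, truth$tag_id)
  rec <- build_records(sim$detections, groups, origin,
                       c(min(truth$true_exit), sim$study_end))
  # exact recovery expected where the fish was at large long enough to be
  # seen (death at least 2 d after exit) and clear of the censoring window
  died <- truth[!truth$censored & truth$death_date >= truth$true_exit + 2 &
                  truth$death_date < sim$study_end - 30, ]
  for (i in seq_len(nrow(died))) {
    r <- rec[rec$tag_id == died$tag_id[i], ]
    expect_equal(r$end_date, died$death_date[i])
    expect_true(r$event)
  }
})
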