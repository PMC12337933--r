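test_that("event time is the end of the first high-PDC half-year window", {
  # full coverage from day 0: first 180-day window already has PDC 1
  tl <- covered_intervals(0, 720)
  ev <- adherence_event_times(tl, 1080)
  expect_equal(ev$time, 180); expect_true(ev$event)
  # no coverage at all: censored at the horizon
  ev0 <- adherence_event_times(covered_intervals(numeric(0), numeric(0)),
                               2000)
  expect_equal(ev0$time, 1080); expect_false(ev0$event)
  # windows 0.5, 0.5, then >=0.8: event at day 540
  tl3 <- covered_intervals(c(0, 180, 360), c(90, 90, 180))
  ev3 <- adherence_event_times(tl3, 1080)
  expect_equal(ev3$time, 540); expect_true(ev3$event)
  # censoring before the first full window
  ev4 <- adherence_event_times(tl, 150)
  expect_equal(ev4$time, 150); expect_false(ev4$event)
})

test_that("Kaplan-Meier matches hand product-limit fixtures exactly", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 2], 1 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 3], 0, tolerance = 1e-12)
  # first subject censored at 1
  km2 <- km_estimate(c(1, 2, 3), c(FALSE, TRUE, TRUE))
  expect_equal(km2$surv[km2$time == 2], 1 / 2, tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 3], 0, tolerance = 1e-12)
  # no events: survival stays 1
  km3 <- km_estimate(c(5, 6), c(FALSE, FALSE))
  expect_true(all(km3$surv == 1))
  # agreement with the hand oracle on random data, and monotone
  set.seed(8)
  t4 <- sample(1:50, 80, TRUE); e4 <- runif(80) < 0.7
  km4 <- km_estimate(t4, e4)
  ok4 <- oracle_km(t4, as.integer(e4))
  got <- km4$surv[match(ok4$time, km4$time)]
  expect_equal(got, ok4$surv, tolerance = 1e-12)
  expect_true(all(diff(km4$surv) <= 1e-12))
})

sim_confounded <- function(n, seed, true_hr = 2, confound = 1) {
  # binary covariate z raises both exposure probability and hazard
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  expo <- factor(ifelse(runif(n) < plogis(-0.5 + confound * z), "BB",
                        "CCB"), levels = c("BB", "CCB"))
  rate <- 0.002 * true_hr^(expo == "CCB") * exp(0.8 * confound * z)
  t_ev <- rexp(n, rate)
  cens <- runif(n, 200, 2000)
  list(time = pmin(t_ev, cens), event = t_ev <= cens, exposure = expo,
       z = data.frame(z = factor(z)))
}

test_that("stabilized weights are centred at 1 and balance covariates", {
  d <- sim_confounded(5000, seed = 1)
  ipw <- stabilized_ipw(d$exposure, d$z)
  expect_equal(mean(ipw$weights), 1, tolerance = 0.05)
  expect_true(all(ipw$smd$smd_weighted < 0.1))
  expect_true(any(ipw$smd$smd_unweighted > 0.1))  # confounding was real
  # no confounding: weights near 1 for everyone
  d0 <- sim_confounded(5000, seed = 2, confound = 0)
  ipw0 <- stabilized_ipw(d0$exposure, d0$z)
  expect_lt(max(abs(ipw0$weights - 1)), 0.1)
})

test_that("Cox recovers a true hazard ratio and IPW removes confounding bias", {
  # unconfounded two-group fit, true HR 2.0
  d <- sim_confounded(2000, seed = 3, confound = 0)
  fit <- cox_fit(d$time, d$event, d$exposure)
  hr <- fit$hr$hr[fit$hr$term == "exposureCCB"]
  expect_gte(hr, 1.8); expect_lte(hr, 2.2)
  # weighted fit with unit weights equals the unweighted fit exactly
  fitw <- cox_fit(d$time, d$event, d$exposure, weights = rep(1, 2000))
  expect_equal(fit$hr$hr, fitw$hr$hr, tolerance = 1e-12)
  # crude vs IPW under confounding (moderate replicate count)
  better <- 0
  for (s in 1:15) {
    dc <- sim_confounded(2000, seed = 100 + s)
    crude <- cox_fit(dc$time, dc$event, dc$exposure)
    ipw <- stabilized_ipw(dc$exposure, dc$z)
    adj <- cox_fit(dc$time, dc$event, dc$exposure, weights = ipw$weights)
    h_c <- crude$hr$hr[1]; h_a <- adj$hr$hr[1]
    if (abs(h_a - 2) < abs(h_c - 2)) better <- better + 1
  }
  expect_gte(better / 15, 0.9)
})

test_that("null exposures give confidence intervals covering 1", {
  cover <- 0
  for (s in 1:30) {
    d <- sim_confounded(600, seed = 300 + s, true_hr = 1, confound = 0)
    fit <- cox_fit(d$time, d$event, d$exposure)
    if (fit$hr$hr_low[1] <= 1 && fit$hr$hr_high[1] >= 1) cover <- cover + 1
  }
  expect_gte(cover / 30, 0.9)
})

test_that("piecewise time-dependent effects recover an early/late reversal", {
  sim_td <- function(n, seed) {
    # exposure B doubles the hazard before day 180 and halves it after
    set.seed(seed)
    expo <- factor(rep(c("BB", "CCB"), n / 2), levels = c("BB", "CCB"))
    base <- 0.003
    t1 <- rexp(n, base * ifelse(expo == "CCB", 2, 1))
    t_ev <- ifelse(t1 <= 180, t1,
                   180 + rexp(n, base * ifelse(expo == "CCB", 0.5, 1)))
    cens <- runif(n, 400, 1500)
    list(time = pmin(t_ev, cens), event = t_ev <= cens, exposure = expo)
  }
  ok <- 0
  for (s in 1:10) {
    d <- sim_td(1500, seed = 400 + s)
    fit <- cox_fit(d$time, d$event, d$exposure, time_dependent = TRUE,
                   cutpoints = c(180, 540))
    hrs <- fit$hr$hr[grep("exposureCCB", fit$hr$term)]
    if (hrs[1] > 1 && hrs[3] < 1) ok <- ok + 1
  }
  expect_gte(ok / 10, 0.9)
})

test_that("survival metrics behave at the closed-form extremes", {
  # risk score perfectly ordering event times, no censoring: C = 1
  n <- 60
  time <- seq_len(n); event <- rep(TRUE, n)
  risk <- -time   # highest risk fails first
  fit <- cox_fit(time, event, factor(rep(c("BB", "CCB"), n / 2)))
  m <- survival_metrics(fit, time, event, risk = risk, tau = 30)
  expect_equal(m$c_index, 1.0)
  # random scores: C near 0.5
  set.seed(12)
  t2 <- rexp(2000, 0.01); e2 <- rep(TRUE, 2000)
  fit2 <- cox_fit(t2, e2, factor(rep(c("BB", "CCB"), 1000)))
  m2 <- survival_metrics(fit2, t2, e2, risk = rnorm(2000), tau = 100)
  expect_equal(m2$c_index, 0.5, tolerance = 0.03)
  # null model: Nagelkerke 0
  expect_equal(m2$nagelkerke_r2, 0, tolerance = 0.01)
})

test_that("IPCW AUC reduces to the plain AUC without censoring", {
  set.seed(14)
  n <- 500
  risk <- rnorm(n)
  t_ev <- rexp(n, 0.002 * exp(risk))
  time <- pmin(t_ev, 3000); event <- t_ev <= 3000   # all observed by 3000
  tau <- 500
  got <- rxadhere:::ipcw_auc(time, event, risk, tau)
  want <- rxadhere:::auc_rank(as.integer(time <= tau), risk)
  expect_equal(got, want, tolerance = 1e-12)
})
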