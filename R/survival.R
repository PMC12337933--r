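#' Time to first high-adherence window
#'
#' Evaluates PDC on consecutive `interval_len`-day windows from the index
#' date (180 days representing half a year) and records an event at the end
#' of the first fully observed window with PDC at or above `threshold`;
#' patients with no such window are censored at
#' `min(followup_end_day, horizon)`.
#'
#' @param timeline a [covered_intervals()] timeline of the initial class.
#' @param followup_end_day follow-up end in days since index.
#' @param interval_len window length in days (default 180).
#' @param horizon analysis horizon in days (default 1080, three years).
#' @param threshold high-adherence PDC cutoff (default 0.8).
#' @return list with `time` (days) and `event` (logical).
#' @export
adherence_event_times <- function(timeline, followup_end_day,
                                  interval_len = 180, horizon = 1080,
                                  threshold = 0.8) {
  end <- min(followup_end_day, horizon)
  j <- 1
  while (interval_len * j <= end) {
    pdc <- covered_days(timeline, interval_len * (j - 1),
                        interval_len * j) / interval_len
    if (pdc >= threshold) {
      return(list(time = interval_len * j, event = TRUE))
    }
    j <- j + 1
  }
  list(time = end, event = FALSE)
}

#' Kaplan-Meier estimate of remaining in low adherence
#'
#' Product-limit estimator with right censoring; "survival" is the
#' probability of not yet having attained a high-adherence window.
#'
#' @param time event/censoring times in days.
#' @param event logical event indicator (attained high adherence).
#' @param group optional grouping factor (e.g. exposure class).
#' @return data.frame of step-function points: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  sf <- survival::survfit(survival::Surv(time, as.integer(event)) ~ g,
                          data = data.frame(time = time, event = event,
                                            g = group))
  st <- summary(sf, censored = TRUE)
  grp <- if (is.null(st$strata)) rep(levels(factor(group))[1],
                                     length(st$time))
         else sub("^g=", "", as.character(st$strata))
  data.frame(group = grp, time = st$time, n_risk = st$n.risk,
             n_event = st$n.event, surv = st$surv)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Fits a multinomial-logistic propensity model of the five-class exposure
#' on the baseline covariates and returns stabilized weights: the marginal
#' class probability divided by the fitted conditional probability,
#' truncated at the stated percentiles of the weight distribution. A fitted
#' probability near zero (non-overlap) triggers a warning.
#'
#' @param exposure factor of exposure classes (every class present).
#' @param covariates data.frame of baseline covariates.
#' @param truncation lower/upper truncation percentiles (default 1%/99%).
#' @return list with `weights`, `n_truncated`, `model`, and `smd` —
#'   post-weighting maximum pairwise standardized mean differences per
#'   covariate dummy (with the unweighted values alongside).
#' @export
stabilized_ipw <- function(exposure, covariates, truncation = c(0.01, 0.99)) {
  exposure <- droplevels(as.factor(exposure))
  stopifnot(nlevels(exposure) >= 2L)
  dat <- data.frame(.expo = exposure, covariates)
  fit <- nnet::multinom(.expo ~ ., data = dat, trace = FALSE, maxit = 200)
  ph <- stats::fitted(fit)
  if (nlevels(exposure) == 2L) ph <- cbind(1 - ph, ph)  # nnet returns p2 only
  colnames(ph) <- levels(exposure)
  p_own <- ph[cbind(seq_along(exposure), as.integer(exposure))]
  if (any(p_own < 1e-6)) {
    warning(sum(p_own < 1e-6),
            " observation(s) with fitted exposure probability < 1e-6")
  }
  marg <- as.numeric(prop.table(table(exposure)))[as.integer(exposure)]
  w <- marg / p_own
  lim <- stats::quantile(w, truncation)
  n_trunc <- sum(w < lim[1] | w > lim[2])
  w <- pmin(pmax(w, lim[1]), lim[2])
  smd <- covariate_balance(exposure, covariates, w)
  list(weights = as.numeric(w), n_truncated = n_trunc, model = fit,
       smd = smd)
}

#' Standardized mean differences across exposure groups
#'
#' Dummy-codes the covariates and reports, per dummy, the maximum pairwise
#' absolute standardized mean difference across exposure groups, weighted
#' and unweighted.
#'
#' @param exposure exposure factor.
#' @param covariates covariate data.frame.
#' @param weights observation weights (default 1).
#' @return data.frame with `covariate`, `smd_unweighted`, `smd_weighted`.
#' @export
covariate_balance <- function(exposure, covariates, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(exposure))
  x <- stats::model.matrix(~., data = as.data.frame(covariates))[, -1,
                                                                 drop = FALSE]
  lev <- levels(droplevels(as.factor(exposure)))
  max_smd <- function(w) {
    apply(x, 2, function(col) {
      ms <- vapply(lev, function(g) {
        sel <- exposure == g
        stats::weighted.mean(col[sel], w[sel])
      }, numeric(1))
      vs <- vapply(lev, function(g) {
        sel <- exposure == g
        m <- stats::weighted.mean(col[sel], w[sel])
        sum(w[sel] * (col[sel] - m)^2) / sum(w[sel])
      }, numeric(1))
      mx <- 0
      for (i in seq_along(lev)[-1]) for (j in seq_len(i - 1)) {
        pool <- sqrt((vs[i] + vs[j]) / 2)
        smd <- if (pool > 0) abs(ms[i] - ms[j]) / pool else 0
        mx <- max(mx, smd)
      }
      mx
    })
  }
  data.frame(covariate = colnames(x),
             smd_unweighted = max_smd(rep(1, length(exposure))),
             smd_weighted = max_smd(weights), row.names = NULL)
}

#' Cox model of time to high adherence
#'
#' Proportional-hazards fit of the exposure classes (reference: BB) with
#' optional covariates and weights (robust sandwich variance whenever
#' weights differ from 1; Efron tie handling). With
#' `time_dependent = TRUE`, the data are expanded to counting-process
#' episodes over the cutpoints (default 0-180, 180-540, 540-1080 days) and
#' interval-specific exposure coefficients are estimated.
#'
#' @param time,event event times (days) and logical event indicators.
#' @param exposure factor of exposure classes.
#' @param covariates optional covariate data.frame.
#' @param weights optional observation weights.
#' @param time_dependent estimate interval-specific exposure effects.
#' @param cutpoints interior episode boundaries (default `c(180, 540)`).
#' @param reference reference exposure level (default `"BB"`).
#' @return object of class `survival_report`: `hr` (term, interval, HR, CI,
#'   p), the `coxph` `fit`, `loglik`, `concordance`, `n`, `n_event`.
#' @importFrom survival Surv strata
#' @export
cox_fit <- function(time, event, exposure, covariates = NULL, weights = NULL,
                    time_dependent = FALSE, cutpoints = c(180, 540),
                    reference = "BB") {
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events")
  exposure <- droplevels(as.factor(exposure))
  if (reference %in% levels(exposure)) {
    exposure <- stats::relevel(exposure, ref = reference)
  }
  dat <- data.frame(time = time, event = event, exposure = exposure)
  covs <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covs <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  dat$.w <- if (is.null(weights)) 1 else weights
  dat$.id <- seq_len(nrow(dat))
  robust <- !is.null(weights) && any(abs(dat$.w - 1) > 1e-12)
  if (!time_dependent) {
    form <- stats::as.formula(paste(
      "Surv(time, event) ~ exposure",
      if (length(covs)) paste("+", paste(covs, collapse = " + ")) else ""))
    fit <- survival::coxph(form, data = dat, weights = .w, ties = "efron",
                           robust = robust)
  } else {
    sdat <- survival::survSplit(Surv(time, event) ~ ., data = dat,
                                cut = cutpoints, episode = "tgroup")
    # explicit exposure-by-episode indicators: one log-HR vs the reference
    # class per (class, interval) cell
    terms_td <- character(0)
    for (lev in levels(exposure)[-1]) {
      for (g in sort(unique(sdat$tgroup))) {
        nm <- paste0("exposure", lev, "_t", g)
        sdat[[nm]] <- as.integer(sdat$exposure == lev & sdat$tgroup == g)
        terms_td <- c(terms_td, nm)
      }
    }
    form <- stats::as.formula(paste(
      "Surv(tstart, time, event) ~",
      paste(c(terms_td, covs), collapse = " + ")))
    fit <- survival::coxph(form, data = sdat, weights = .w, id = .id,
                           ties = "efron", robust = robust)
  }
  sm <- summary(fit)
  est <- sm$coefficients
  secol <- if (robust) "robust se" else "se(coef)"
  hr <- data.frame(term = rownames(est), hr = exp(est[, "coef"]),
                   hr_low = exp(est[, "coef"] - 1.96 * est[, secol]),
                   hr_high = exp(est[, "coef"] + 1.96 * est[, secol]),
                   p_value = est[, ncol(est)], row.names = NULL)
  structure(list(hr = hr, fit = fit, loglik = fit$loglik,
                 concordance = unname(sm$concordance["C"]),
                 n = fit$n, n_event = fit$nevent,
                 time_dependent = time_dependent,
                 robust = robust),
            class = "survival_report")
}

# inverse-probability-of-censoring weighted cumulative/dynamic AUC at tau:
# cases are subjects with an observed event by tau, controls subjects still
# at risk beyond tau; weights come from the Kaplan-Meier estimate of the
# censoring distribution
ipcw_auc <- function(time, event, risk, tau) {
  event <- as.integer(event)
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv))
  Gm <- function(t) {   # left-continuous G(t-)
    vapply(t, function(tt) G(max(tt - 1e-9, 0)), numeric(1))
  }
  # controls are known event-free at tau: observed beyond tau, or censored
  # administratively at exactly tau without an event
  case <- which(time <= tau & event == 1)
  ctrl <- which(time > tau | (time == tau & event == 0))
  if (length(case) == 0L || length(ctrl) == 0L) return(NA_real_)
  wc <- 1 / pmax(Gm(time[case]), 1e-10)
  wk <- rep(1 / pmax(G(tau), 1e-10), length(ctrl))
  num <- 0
  for (i in seq_along(case)) {
    gt <- sum(wk[risk[ctrl] < risk[case[i]]])
    eq <- sum(wk[risk[ctrl] == risk[case[i]]])
    num <- num + wc[i] * (gt + 0.5 * eq)
  }
  num / (sum(wc) * sum(wk))
}

#' Performance metrics for a fitted Cox model
#'
#' Cumulative/dynamic time-dependent AUC at `tau` days with
#' inverse-probability-of-censoring weights, sensitivity and specificity at
#' the Youden-optimal threshold of the `tau`-day risk score, Nagelkerke
#' R-squared from the partial-likelihood ratio, and Harrell's C-index over
#' usable pairs.
#'
#' @param report a [cox_fit()] `survival_report`.
#' @param time,event the event data the model was fitted to (one row per
#'   subject; for time-dependent fits pass the pre-expansion data and
#'   `risk` explicitly).
#' @param risk optional risk scores (defaults to the model's linear
#'   predictor).
#' @param tau evaluation horizon in days (default 1080).
#' @return list with `auc`, `sensitivity`, `specificity`, `nagelkerke_r2`,
#'   `c_index`.
#' @export
survival_metrics <- function(report, time, event, risk = NULL, tau = 1080) {
  event <- as.integer(event)
  if (is.null(risk)) risk <- as.numeric(stats::predict(report$fit,
                                                       type = "lp"))
  stopifnot(length(risk) == length(time))
  auc <- ipcw_auc(time, event, risk, tau)
  # weighted sensitivity/specificity over thresholds; Youden maximum
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv))
  case <- which(time <= tau & event == 1)
  ctrl <- which(time > tau | (time == tau & event == 0))
  sens <- spec <- NA_real_
  if (length(case) > 0L && length(ctrl) > 0L) {
    wc <- 1 / pmax(vapply(time[case],
                          function(t) G(max(t - 1e-9, 0)), numeric(1)),
                   1e-10)
    thr <- sort(unique(risk))
    best <- -Inf
    for (ct in thr) {
      se <- sum(wc[risk[case] >= ct]) / sum(wc)
      sp <- mean(risk[ctrl] < ct)
      if (se + sp - 1 > best) { best <- se + sp - 1; sens <- se; spec <- sp }
    }
  }
  ll <- report$loglik
  n <- report$n
  cs <- 1 - exp(-2 * (ll[2] - ll[1]) / n)
  cs_max <- 1 - exp(2 * ll[1] / n)
  r2 <- if (cs_max > 0) min(1, cs / cs_max) else 0
  cfit <- survival::concordance(Surv(time, event) ~ risk,
                                reverse = TRUE)
  list(auc = auc, sensitivity = sens, specificity = spec,
       nagelkerke_r2 = r2, c_index = unname(cfit$concordance))
}
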