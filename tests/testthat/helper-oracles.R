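# Independent brute-force oracles. Each works day by day on boolean arrays
# or by exhaustive scanning, deliberately sharing no code with the package's
# interval arithmetic.

# day-by-day boolean coverage oracle; returns covered-day indicator over
# days 0 .. horizon-1
oracle_coverage <- function(days, supply, policy, horizon) {
  covered <- rep(FALSE, horizon)
  o <- order(days)
  days <- days[o]; supply <- supply[o]
  if (policy == "truncate") {
    for (i in seq_along(days)) {
      span <- seq(days[i], days[i] + supply[i] - 1)
      span <- span[span >= 0 & span < horizon]
      covered[span + 1] <- TRUE
    }
  } else {
    next_free <- 0
    for (i in seq_along(days)) {
      s <- max(days[i], next_free)
      span <- seq(s, s + supply[i] - 1)
      next_free <- s + supply[i]
      span <- span[span >= 0 & span < horizon]
      covered[span + 1] <- TRUE
    }
  }
  covered
}

# exhaustive day-scan pattern oracle mirroring the printed definitions:
# discontinuation = first supply-end day e with no same-class dispensing in
# (e, e+180] and the whole gap observable before follow-up end; switch =
# first other dispensing in (e, e+180]; add-on = first other dispensing on a
# covered day before any discontinuation
oracle_patterns <- function(same_days, same_supply, other_days, other_labels,
                            followup_end, gap = 180, window = 180) {
  horizon <- max(followup_end, max(c(same_days + same_supply, other_days,
                                     0)) + gap + 2)
  covered <- oracle_coverage(same_days, same_supply, "carryover", horizon)
  disc <- NA
  d <- 0
  while (d < horizon - 1) {
    # e is a supply-end day: covered on e-1, uncovered on e
    if (d > 0 && covered[d] && !covered[d + 1]) {
      e <- d
      gap_free <- !any(same_days > e & same_days <= e + gap)
      if (gap_free && e + gap < followup_end) { disc <- e; break }
    }
    d <- d + 1
  }
  sw_day <- NA; sw_lab <- NA; ad_day <- NA; ad_lab <- NA
  if (length(other_days) > 0) {
    o <- order(other_days)
    other_days <- other_days[o]; other_labels <- other_labels[o]
    if (!is.na(disc)) {
      for (i in seq_along(other_days)) {
        if (other_days[i] > disc && other_days[i] <= disc + window) {
          sw_day <- other_days[i]; sw_lab <- other_labels[i]; break
        }
      }
    }
    for (i in seq_along(other_days)) {
      dd <- other_days[i]
      if (dd >= 0 && dd < horizon && covered[dd + 1] &&
          (is.na(disc) || dd < disc)) {
        ad_day <- dd; ad_lab <- other_labels[i]; break
      }
    }
  }
  list(continuation = is.na(disc) && is.na(sw_day) && is.na(ad_day),
       disc_day = disc, switch_day = sw_day, switch_target = sw_lab,
       addon_day = ad_day, addon_target = ad_lab)
}

# random one-patient dispensing history for oracle-equivalence testing
random_history <- function() {
  n_same <- sample(1:8, 1)
  same_days <- sort(sample(0:600, n_same))
  same_days[1] <- 0
  same_supply <- sample(c(30, 60, 90), n_same, replace = TRUE)
  n_other <- sample(0:3, 1)
  other_days <- if (n_other > 0) sort(sample(1:900, n_other)) else integer(0)
  other_labels <- if (n_other > 0) {
    sample(c("CCB", "ACEI", "FDC"), n_other, replace = TRUE)
  } else {
    character(0)
  }
  list(same_days = same_days, same_supply = same_supply,
       other_days = other_days, other_labels = other_labels,
       followup_end = sample(300:1200, 1))
}

# hand product-limit estimator (no survival package)
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# exhaustive PAM cost minimum over all k-subsets (tiny n only)
oracle_pam_cost <- function(d, k) {
  d <- as.matrix(d)
  sets <- utils::combn(nrow(d), k)
  min(apply(sets, 2, function(med) {
    sum(apply(d[, med, drop = FALSE], 1, min))
  }))
}

# categorical feature table with k planted archetypes (distinct level
# patterns plus label noise) for cluster-recovery tests
planted_archetypes <- function(n, k_true, p_vars = 10, noise = 0.08) {
  arch <- sample(seq_len(k_true), n, replace = TRUE)
  # archetype r gets level pattern shifted by r: any two archetypes differ
  # on every variable
  base <- t(vapply(seq_len(k_true), function(r) {
    letters[((seq_len(p_vars) + r) %% 6) + 1]
  }, character(p_vars)))
  x <- base[arch, , drop = FALSE]
  flip <- matrix(runif(n * p_vars) < noise, n, p_vars)
  x[flip] <- sample(letters[1:6], sum(flip), replace = TRUE)
  list(features = as.data.frame(x, stringsAsFactors = TRUE), labels = arch)
}
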