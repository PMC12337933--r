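#' Configuration for the synthetic dispensing-data generator
#'
#' The generator emulates a new-user antihypertensive monotherapy population:
#' every patient gets an index dispensing of exactly one of the five classes,
#' a refill sequence whose inter-dispensing gaps are
#' `days_supply * delay_factor * U(1 - jitter, 1 + jitter)`, archetype-driven
#' later events (stopping refills; starting a new class within 180 days of
#' supply exhaustion; starting a second class during ongoing coverage), and
#' comorbidity-drug dispensings in the first 180 days linked to the planted
#' covariate flags. Covariates are drawn first; high adherence is drawn from
#' a logistic model on the covariates (`covariate_effects` are log-odds) and
#' sets the refill delay factor, so downstream models see a known signal.
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param archetype_mix named proportions over `continuer`, `discontinuer`,
#'   `switcher`, `adder`; must sum to 1.
#' @param exposure_mix named proportions over the five exposure classes;
#'   must sum to 1.
#' @param adherence_propensity_by_archetype per-archetype mean refill-delay
#'   factor (multiplies the high/low delay factor).
#' @param delay_high,delay_low mean refill-delay factor for planted
#'   high-adherence (default 1.0, PDC near 1) and low-adherence (default
#'   1.45, PDC near 0.69) patients.
#' @param jitter half-width of the uniform refill-delay noise (default 0.1;
#'   0 gives deterministic schedules).
#' @param covariate_effects named log-odds of high adherence; recognised
#'   names: `intercept`, `male`, `middle`, `older`, the nine comorbidity
#'   group names, `period_2000_2010`, `period_2010_2020`.
#' @param comorbidity_prevalence named probabilities for the nine flags.
#' @param age_band_mix proportions for young/middle/older.
#' @param p_male probability of male sex.
#' @param days_supply days of supply per exposure dispensing (default 90).
#' @param disc_geom_p geometric parameter for the number of refills before a
#'   planted discontinuation (default 0.3).
#' @param exposure_confounding log-odds strength with which older age and
#'   diabetes tilt the exposure-class draw (default 0 = no confounding).
#' @param study_start,study_end study window; index dates are drawn
#'   uniformly over `[study_start, index_latest]`.
#' @param index_latest latest index date (default 2017-12-31, guaranteeing
#'   at least three years of observable history for every patient).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000, seed = 1,
                       archetype_mix = c(continuer = 0.30,
                                         discontinuer = 0.40,
                                         switcher = 0.12, adder = 0.18),
                       exposure_mix = c(thiazide = 0.15, CCB = 0.15,
                                        ACEI = 0.30, ARB = 0.10, BB = 0.30),
                       adherence_propensity_by_archetype =
                         c(continuer = 1, discontinuer = 1,
                           switcher = 1, adder = 1),
                       delay_high = 1.0, delay_low = 1.45, jitter = 0.1,
                       covariate_effects = c(intercept = 1.1, male = 0,
                                             middle = 0.35, older = 0.5,
                                             diabetes = 0.4,
                                             asthma_copd = 0.3,
                                             psycholeptics = -0.4,
                                             period_2000_2010 = 0.3,
                                             period_2010_2020 = 0.45),
                       comorbidity_prevalence =
                         c(diabetes = 0.08, ra = 0.04, asthma_copd = 0.10,
                           antiepileptics = 0.03, antiparkinson = 0.02,
                           psycholeptics = 0.12, psychoanaleptics = 0.10,
                           addictive_disorders = 0.03,
                           antineoplastics = 0.02),
                       age_band_mix = c(young = 0.25, middle = 0.55,
                                        older = 0.20),
                       p_male = 0.48, days_supply = 90, disc_geom_p = 0.3,
                       exposure_confounding = 0,
                       study_start = as.Date("1996-01-01"),
                       study_end = as.Date("2020-12-31"),
                       index_latest = as.Date("2017-12-31")) {
  cfg <- as.list(environment())
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  check_mix <- function(x, levels, what) {
    if (!setequal(names(x), levels) || any(x < 0) ||
        abs(sum(x) - 1) > 1e-9) {
      stop(what, " must be non-negative proportions over {",
           paste(levels, collapse = ", "), "} summing to 1")
    }
  }
  check_mix(cfg$archetype_mix,
            c("continuer", "discontinuer", "switcher", "adder"),
            "archetype_mix")
  check_mix(cfg$exposure_mix, exposure_levels(), "exposure_mix")
  if (jitter < 0 || jitter >= 1) stop("jitter must lie in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

# representative ATC code for each exposure class / group prefix
sim_atc <- function(class_map) {
  c(vapply(class_map$exposure_classes, `[`, character(1), 1),
    FDC = class_map$fdc_prefixes[1])
}

#' Simulate one patient's exposure dispensing history
#'
#' Generates the index-class refill sequence and the archetype event for one
#' patient, in day offsets since index. Continuers refill to the horizon
#' (never leaving a gap over 180 days and never starting a second class);
#' discontinuers stop refilling with no successor class; switchers start a
#' different class within `(0, 180]` days after their supply ends; adders
#' start a second class on a day strictly inside initial-class coverage.
#' Planted event days are capped so each event is observable inside the
#' horizon.
#'
#' @param archetype one of `continuer`, `discontinuer`, `switcher`, `adder`.
#' @param index_class exposure class of the initial monotherapy.
#' @param delay_factor mean refill-delay factor (1 = exactly on time).
#' @param horizon observation horizon in days since index.
#' @param config a [sim_config()] object (supply, jitter, event parameters).
#' @return list with `disp` (data.frame `day`, `class`) and the planted
#'   `disc_day`, `switch_day`, `switch_class`, `addon_day`, `addon_class`.
#' @export
simulate_patient_history <- function(archetype, index_class, delay_factor,
                                     horizon, config = sim_config()) {
  stopifnot(archetype %in% c("continuer", "discontinuer", "switcher",
                             "adder"))
  supply <- config$days_supply
  jit <- config$jitter
  gap <- function() supply * delay_factor * stats::runif(1, 1 - jit, 1 + jit)
  truth <- list(disc_day = NA_real_, switch_day = NA_real_,
                switch_class = NA_character_, addon_day = NA_real_,
                addon_class = NA_character_)

  # refill schedule on integer days; cap_end: stop early so that coverage
  # end + 181 <= horizon (the planted gap stays observable)
  refill_days <- function(max_n = Inf, cap_end = FALSE) {
    days <- 0; cov_end <- supply; n <- 0
    repeat {
      nxt <- round(days[length(days)] + gap())
      if (nxt > horizon || n >= max_n) break
      nxt_end <- max(nxt, cov_end) + supply
      if (cap_end && nxt_end + 181 > horizon) break
      days <- c(days, nxt); cov_end <- nxt_end; n <- n + 1
    }
    list(days = days, cov_end = cov_end)
  }

  other_class <- function() {
    sample(setdiff(exposure_levels(), index_class), 1)
  }

  if (archetype == "continuer") {
    r <- refill_days()
    disp <- data.frame(day = r$days, class = index_class)
  } else if (archetype %in% c("discontinuer", "switcher")) {
    n_ref <- stats::rgeom(1, config$disc_geom_p)
    r <- refill_days(max_n = n_ref, cap_end = TRUE)
    truth$disc_day <- r$cov_end
    disp <- data.frame(day = r$days, class = index_class)
    if (archetype == "switcher") {
      sw_day <- r$cov_end + sample.int(180, 1)
      sw_cls <- other_class()
      truth$switch_day <- sw_day; truth$switch_class <- sw_cls
      sw_days <- sw_day
      repeat {
        nxt <- round(sw_days[length(sw_days)] + gap())
        if (nxt > horizon) break
        sw_days <- c(sw_days, nxt)
      }
      disp <- rbind(disp, data.frame(day = sw_days, class = sw_cls))
    }
  } else { # adder
    r <- refill_days()
    disp <- data.frame(day = r$days, class = index_class)
    iv <- covered_intervals(r$days, supply, "carryover")$intervals
    # candidate add-on days: strictly inside coverage, >= 30, before horizon
    cand <- unlist(lapply(seq_len(nrow(iv)), function(i) {
      lo <- max(30, ceiling(iv$start[i])); hi <- floor(iv$end[i]) - 1
      if (hi >= lo) seq(lo, hi) else numeric(0)
    }))
    cand <- cand[cand < horizon]
    if (length(cand) > 0L) {
      ad_day <- if (length(cand) == 1L) cand else sample(cand, 1)
      ad_cls <- other_class()
      truth$addon_day <- ad_day; truth$addon_class <- ad_cls
      ad_days <- ad_day
      repeat {
        nxt <- round(ad_days[length(ad_days)] + gap())
        if (nxt > horizon) break
        ad_days <- c(ad_days, nxt)
      }
      disp <- rbind(disp, data.frame(day = ad_days, class = ad_cls))
    }
  }
  list(disp = disp, truth = truth)
}

#' Simulate a synthetic new-user population
#'
#' Draws covariates, high-adherence labels, archetypes and exposure classes
#' per [sim_config()], generates every patient's dispensing history with
#' [simulate_patient_history()], and plants comorbidity-drug dispensings in
#' the first 180 days for each true covariate flag.
#'
#' @param config a [sim_config()] object.
#' @param class_map a [default_class_map()] object supplying ATC codes.
#' @return list of three data.frames: `patients` (patient_id, birth_date,
#'   sex), `dispensings` (patient_id, dispense_date, atc_code, days_supply)
#'   and `truth` (one row per patient with every planted label).
#' @export
simulate_population <- function(config = sim_config(),
                                class_map = default_class_map()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  atc <- sim_atc(class_map)
  pid <- sprintf("P%05d", seq_len(n))

  idx_span <- as.numeric(config$index_latest - config$study_start)
  index_date <- config$study_start + sample.int(idx_span + 1, n,
                                                replace = TRUE) - 1
  horizon <- pmin(as.numeric(config$study_end - index_date), 3780)

  band <- sample(names(config$age_band_mix), n, replace = TRUE,
                 prob = config$age_band_mix)
  age <- ifelse(band == "young", sample(18:39, n, replace = TRUE),
                ifelse(band == "middle", sample(40:69, n, replace = TRUE),
                       sample(70:90, n, replace = TRUE)))
  # extra margin of >= 3 days so calendar drift never undershoots the
  # planted age (bands are recomputed from the actual birth date below)
  birth_date <- index_date - round(age * 365.25) - sample(3:180, n,
                                                          replace = TRUE)
  age <- completed_years(birth_date, index_date)     # exact completed years
  band <- as.character(cut(age, c(18, 40, 70, Inf), right = FALSE,
                           labels = c("young", "middle", "older")))
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  como <- sapply(names(config$comorbidity_prevalence), function(g) {
    stats::runif(n) < config$comorbidity_prevalence[[g]]
  })
  yr <- as.integer(format(index_date, "%Y"))
  period <- as.character(cut(yr, c(1996, 2000, 2010, 2021), right = FALSE,
                             labels = c("1996-2000", "2000-2010",
                                        "2010-2020")))

  eff <- function(nm) if (nm %in% names(config$covariate_effects))
    config$covariate_effects[[nm]] else 0
  eta <- rep(eff("intercept"), n) +
    eff("male") * (sex == "male") +
    eff("middle") * (band == "middle") + eff("older") * (band == "older") +
    eff("period_2000_2010") * (period == "2000-2010") +
    eff("period_2010_2020") * (period == "2010-2020")
  for (g in colnames(como)) eta <- eta + eff(g) * como[, g]
  p_high <- stats::plogis(eta)
  high <- stats::runif(n) < p_high

  archetype <- sample(names(config$archetype_mix), n, replace = TRUE,
                      prob = config$archetype_mix)
  if (config$exposure_confounding != 0) {
    # older age / diabetes tilt patients toward thiazide and CCB starts
    cls <- character(n)
    base <- log(config$exposure_mix)
    for (i in seq_len(n)) {
      lg <- base
      tilt <- config$exposure_confounding *
        ((band[i] == "older") + como[i, "diabetes"])
      lg[c("thiazide", "CCB")] <- lg[c("thiazide", "CCB")] + tilt
      pr <- exp(lg - max(lg)); pr <- pr / sum(pr)
      cls[i] <- sample(names(pr), 1, prob = pr)
    }
  } else {
    cls <- sample(names(config$exposure_mix), n, replace = TRUE,
                  prob = config$exposure_mix)
  }
  delay <- config$adherence_propensity_by_archetype[archetype] *
    ifelse(high, config$delay_high, config$delay_low)

  disp <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    h <- simulate_patient_history(archetype[i], cls[i], delay[i],
                                  horizon[i], config)
    d <- h$disp
    rows <- data.frame(patient_id = pid[i],
                       dispense_date = index_date[i] + d$day,
                       atc_code = unname(atc[d$class]),
                       days_supply = config$days_supply,
                       stringsAsFactors = FALSE)
    flags <- colnames(como)[como[i, ]]
    if (length(flags) > 0L) {
      cdays <- sample(0:170, length(flags), replace = TRUE)
      rows <- rbind(rows, data.frame(
        patient_id = pid[i],
        dispense_date = index_date[i] + cdays,
        atc_code = vapply(flags, function(g)
          class_map$comorbidity_groups[[g]][1], character(1)),
        days_supply = 30, stringsAsFactors = FALSE))
    }
    disp[[i]] <- rows
    truth[[i]] <- data.frame(
      patient_id = pid[i], archetype = archetype[i], index_class = cls[i],
      index_date = index_date[i], horizon = horizon[i], age = age[i],
      age_band = band[i], sex = sex[i], calendar_period = period[i],
      true_high_prob = p_high[i], high_adherence = high[i],
      delay_factor = unname(delay[i]),
      disc_day = h$truth$disc_day, switch_day = h$truth$switch_day,
      switch_class = h$truth$switch_class, addon_day = h$truth$addon_day,
      addon_class = h$truth$addon_class, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth <- cbind(truth, as.data.frame(como))
  dispensings <- do.call(rbind, disp)
  dispensings <- dispensings[order(dispensings$patient_id,
                                   dispensings$dispense_date,
                                   dispensings$atc_code), ]
  rownames(dispensings) <- NULL
  list(patients = data.frame(patient_id = pid, birth_date = birth_date,
                             sex = sex, stringsAsFactors = FALSE),
       dispensings = dispensings,
       truth = truth)
}

#' Write a simulated population to CSV files
#'
#' @param population output of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "dispensings.csv", "truth.csv"))
  utils::write.csv(population$patients, paths[1], row.names = FALSE)
  utils::write.csv(population$dispensings, paths[2], row.names = FALSE)
  utils::write.csv(population$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
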