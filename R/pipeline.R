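#' Pipeline configuration
#'
#' One structured configuration drives the whole analytic chain:
#' simulate (or read) dispensing data, build the new-user cohort, compute
#' adherence, classify drug-utilization patterns, cluster risk profiles,
#' fit prediction models, and run the time-to-high-adherence survival
#' analysis. Any stage can be toggled off.
#'
#' @param synthetic use the synthetic generator (`TRUE`) or read
#'   `patients.csv`/`dispensings.csv` from `input_dir`.
#' @param sim a [sim_config()] for synthetic mode.
#' @param input_dir directory with input CSVs when `synthetic = FALSE`.
#' @param class_map a [default_class_map()] object.
#' @param study_start,study_end study window dates.
#' @param policy coverage overlap policy (default `"carryover"`).
#' @param objective1,objective2,objective3 stage toggles: descriptive
#'   adherence + patterns; clustering + prediction models; survival.
#' @param k_range candidate cluster counts.
#' @param cluster_subsample_threshold,cluster_subsample_size above the
#'   threshold, clustering runs on a seeded subsample and assigns the rest
#'   to the nearest medoid (see [cluster_patients()]).
#' @param seed master seed for split/fold/subsample randomness.
#' @param lambda_rule lambda choice for the pipeline's penalized fits:
#'   `"min"` (default; CV-deviance minimum, sensitive to the modest effect
#'   sizes typical of dispensing data, where the near-flat CV curve makes
#'   the one-standard-error rule collapse to the null model) or `"1se"`.
#' @param cutpoints time-dependent Cox episode boundaries.
#' @param survival_horizon survival analysis horizon in days (default 1080).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE, sim = sim_config(),
                            input_dir = NULL,
                            class_map = default_class_map(),
                            study_start = as.Date("1996-01-01"),
                            study_end = as.Date("2020-12-31"),
                            policy = "carryover",
                            objective1 = TRUE, objective2 = TRUE,
                            objective3 = TRUE,
                            k_range = 2:10,
                            cluster_subsample_threshold = 2000,
                            cluster_subsample_size = 1500, seed = 1,
                            lambda_rule = "min",
                            cutpoints = c(180, 540),
                            survival_horizon = 1080) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every enabled stage and writes each stage's tables to
#' `out_dir`, plus a manifest (`manifest.json`) from which the run can be
#' reproduced: configuration echo, seeds, package and R versions, and row
#' counts per filter step. Rerunning with the same configuration produces
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir artifact directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  res <- list()

  if (config$synthetic) {
    pop <- simulate_population(config$sim, config$class_map)
  } else {
    if (is.null(config$input_dir)) stop("input_dir required when synthetic = FALSE")
    pop <- list(
      patients = utils::read.csv(file.path(config$input_dir, "patients.csv"),
                                 colClasses = c(birth_date = "Date")),
      dispensings = utils::read.csv(
        file.path(config$input_dir, "dispensings.csv"),
        colClasses = c(dispense_date = "Date")))
    check_dispensing_schema(pop$dispensings)
  }
  res$population <- pop
  wcsv(pop$patients, "patients.csv")
  wcsv(pop$dispensings, "dispensings.csv")
  if (!is.null(pop$truth)) wcsv(pop$truth, "truth.csv")

  coh <- build_cohort(pop$dispensings, pop$patients, config$class_map,
                      config$study_start, config$study_end)
  res$cohort <- coh
  wcsv(coh, "cohort.csv")
  wcsv(attr(coh, "attrition"), "attrition.csv")

  if (config$objective1) {
    adh <- adherence_table(coh, pop$dispensings, config$class_map,
                           config$policy)
    res$adherence <- adh
    wcsv(adh$annual, "adherence_annual.csv")
    wcsv(adh$overall, "adherence_overall.csv")
    yrs <- sort(unique(adh$annual$year))
    summ <- do.call(rbind, lapply(yrs, function(k) {
      a <- adh$annual[adh$annual$year == k, ]
      data.frame(year = k, n = nrow(a), mean_pdc = mean(a$pdc),
                 sd_pdc = stats::sd(a$pdc),
                 adherence_rate = 100 * mean(a$adherence == "high"))
    }))
    res$adherence_summary <- summ
    wcsv(summ, "adherence_summary.csv")

    pat_cohort <- subcohort_monotherapy(coh, 360)
    prof <- classify_patterns(pat_cohort, pop$dispensings, config$class_map,
                              config$study_end, config$policy)
    res$patterns <- prof
    wcsv(prof, "patterns.csv")
    res$pattern_rates <- pattern_rates(prof)
    wcsv(res$pattern_rates, "pattern_rates.csv")
    wcsv(as.data.frame(switch_addon_matrix(prof, "switch")),
         "switch_matrix.csv")
    wcsv(as.data.frame(switch_addon_matrix(prof, "addon")),
         "addon_matrix.csv")
  }

  if (config$objective2) {
    sub <- subcohort_monotherapy(coh, 360)
    adh1 <- adherence_year1(sub, pop$dispensings, config$class_map,
                            config$policy)
    feats <- feature_table(sub)
    y <- adh1 == "high"
    res$cramers_v <- cramers_v_matrix(feats)
    wcsv(as.data.frame(res$cramers_v), "cramers_v.csv")
    dsg <- make_design_matrix(feats)
    res$vif <- vif_screen(dsg$x)
    wcsv(res$vif, "vif.csv")
    fits <- lapply(c("ridge", "lasso", "elastic_net"), function(p) {
      cv_penalized_fit(dsg$x, y, p, seed = config$seed,
                       lambda_rule = config$lambda_rule)
    })
    names(fits) <- vapply(fits, `[[`, character(1), "penalty")
    res$penalty_comparison <- compare_penalties(fits)
    wcsv(res$penalty_comparison, "penalty_comparison.csv")
    res$final_model <- final_logistic_from_lasso(fits$lasso, feats, y, dsg)
    wcsv(res$final_model$coefficients, "final_model_coefficients.csv")
    wcsv(data.frame(metric = c(names(res$final_model$metrics),
                               "hosmer_lemeshow_p", "nagelkerke_r2"),
                    value = c(unname(res$final_model$metrics),
                              res$final_model$hosmer_lemeshow$p_value,
                              res$final_model$nagelkerke_r2)),
         "final_model_metrics.csv")
    cl <- cluster_patients(feats, config$k_range,
                           subsample_threshold =
                             config$cluster_subsample_threshold,
                           subsample_size = config$cluster_subsample_size,
                           seed = config$seed)
    res$clusters <- cl
    wcsv(data.frame(patient_id = sub$patient_id, cluster = cl$assignment),
         "cluster_assignment.csv")
    wcsv(cl$profile, "silhouette_by_k.csv")
  }

  if (config$objective3) {
    sub <- subcohort_records(coh, pop$dispensings, config$survival_horizon)
    if (nrow(sub) >= 50 && sum(table(sub$index_class) > 0) >= 2) {
      ev <- survival_records(sub, pop$dispensings, config$class_map,
                             config$policy, config$survival_horizon)
      res$event_records <- ev
      km <- km_estimate(ev$time, ev$event, ev$exposure)
      wcsv(km, "km_points.csv")
      covs <- ev[, setdiff(names(ev), c("patient_id", "time", "event",
                                        "exposure")), drop = FALSE]
      ipw <- stabilized_ipw(ev$exposure, covs)
      res$ipw <- ipw
      wcsv(ipw$smd, "ipw_balance.csv")
      variants <- list(
        crude = cox_fit(ev$time, ev$event, ev$exposure,
                        cutpoints = config$cutpoints),
        ipw = cox_fit(ev$time, ev$event, ev$exposure,
                      weights = ipw$weights, cutpoints = config$cutpoints),
        crude_td = cox_fit(ev$time, ev$event, ev$exposure,
                           time_dependent = TRUE,
                           cutpoints = config$cutpoints),
        ipw_td = cox_fit(ev$time, ev$event, ev$exposure,
                         weights = ipw$weights, time_dependent = TRUE,
                         cutpoints = config$cutpoints))
      res$cox <- variants
      hr <- do.call(rbind, lapply(names(variants), function(v) {
        cbind(variant = v, variants[[v]]$hr)
      }))
      wcsv(hr, "hr_table.csv")
      mets <- do.call(rbind, lapply(c("crude", "ipw"), function(v) {
        m <- survival_metrics(variants[[v]], ev$time, ev$event,
                              tau = config$survival_horizon)
        data.frame(variant = v, metric = names(m),
                   value = unlist(m), row.names = NULL)
      }))
      res$survival_metrics <- mets
      wcsv(mets, "survival_metrics.csv")
    } else {
      message("survival stage skipped: too few eligible patients")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rxadhere")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    synthetic = config$synthetic,
    sim_seed = if (config$synthetic) config$sim$seed else NULL,
    n_patients = nrow(pop$patients),
    n_dispensings = nrow(pop$dispensings),
    attrition = attr(coh, "attrition"),
    objectives = c(objective1 = config$objective1,
                   objective2 = config$objective2,
                   objective3 = config$objective3),
    policy = config$policy,
    study_start = as.character(config$study_start),
    study_end = as.character(config$study_end),
    cutpoints = config$cutpoints)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' First-year adherence flag per cohort row
#'
#' Annual PDC of treatment year 1 (360-day denominator), binarized at 0.8.
#'
#' @param cohort cohort data.frame.
#' @param dispensings dispensing records.
#' @param class_map a [default_class_map()] object.
#' @param policy coverage overlap policy.
#' @return factor `high`/`low` (`NA` where year 1 is not evaluable).
#' @export
adherence_year1 <- function(cohort, dispensings, class_map,
                            policy = "carryover") {
  disp_by_pat <- split(dispensings, dispensings$patient_id)
  pdc <- vapply(seq_len(nrow(cohort)), function(i) {
    tl <- patient_timeline(disp_by_pat[[cohort$patient_id[i]]],
                           cohort$index_date[i], cohort$index_class[i],
                           class_map, policy)
    annual_pdc(tl, 1, cohort$followup_end_day[i])
  }, numeric(1))
  binarize_adherence(pdc)
}

#' Categorical risk-factor table for clustering and prediction
#'
#' Exposure class, sex, age band, calendar period and the nine
#' comorbidity-drug flags as factors; optionally the adherence flag (used
#' when patterns rather than adherence are the outcome).
#'
#' @param cohort cohort data.frame with covariates.
#' @param adherence optional adherence factor to append.
#' @return data.frame of factors, one row per cohort entry.
#' @export
feature_table <- function(cohort, adherence = NULL) {
  ft <- data.frame(
    index_class = factor(cohort$index_class, levels = exposure_levels()),
    sex = cohort$sex, age_band = cohort$age_band,
    calendar_period = cohort$calendar_period)
  for (g in c("diabetes", "ra", "asthma_copd", "antiepileptics",
              "antiparkinson", "psycholeptics", "psychoanaleptics",
              "addictive_disorders", "antineoplastics")) {
    ft[[g]] <- factor(ifelse(cohort[[g]], "yes", "no"),
                      levels = c("no", "yes"))
  }
  if (!is.null(adherence)) ft$adherence <- adherence
  droplevels(ft)
}

#' Per-patient time-to-high-adherence records with baseline covariates
#'
#' Applies [adherence_event_times()] to every cohort entry and attaches the
#' exposure class and covariates, ready for [stabilized_ipw()] and
#' [cox_fit()].
#'
#' @param cohort cohort data.frame with covariates.
#' @param dispensings dispensing records.
#' @param class_map a [default_class_map()] object.
#' @param policy coverage overlap policy.
#' @param horizon analysis horizon in days (default 1080).
#' @return data.frame with `patient_id`, `time`, `event`, `exposure` and
#'   the covariate columns.
#' @export
survival_records <- function(cohort, dispensings, class_map,
                             policy = "carryover", horizon = 1080) {
  disp_by_pat <- split(dispensings, dispensings$patient_id)
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    tl <- patient_timeline(disp_by_pat[[cohort$patient_id[i]]],
                           cohort$index_date[i], cohort$index_class[i],
                           class_map, policy)
    te <- adherence_event_times(tl, cohort$followup_end_day[i],
                                horizon = horizon)
    data.frame(patient_id = cohort$patient_id[i], time = te$time,
               event = te$event, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, out)
  ev <- ev[ev$time > 0, , drop = FALSE]
  keep <- match(ev$patient_id, cohort$patient_id)
  ev$exposure <- factor(cohort$index_class[keep],
                        levels = exposure_levels())
  cbind(ev, feature_table(cohort[keep, , drop = FALSE])[,
        -1, drop = FALSE])
}

check_dispensing_schema <- function(d) {
  need <- c("patient_id", "dispense_date", "atc_code", "days_supply")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dispensing table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$days_supply < 1)) {
    stop("days_supply must be >= 1 (first offending row: ",
         which(d$days_supply < 1)[1], ")")
  }
  bad <- !grepl("^[A-Z][0-9A-Z]{0,6}$", d$atc_code)
  if (any(bad)) stop("invalid ATC code (first offending row: ",
                     which(bad)[1], ")")
  invisible(d)
}
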