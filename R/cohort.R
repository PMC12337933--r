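#' Identify new-user index events
#'
#' The index date is the date of a patient's first dispensing of any of the
#' five antihypertensive monotherapy classes within the study window. A
#' patient qualifies as a starter only if no dispensing of any of the five
#' classes (including records before the study window) occurred in the
#' `lookback_days` before that date. Patients dispensed two or more distinct
#' exposure classes on the index date are rejected: that is not monotherapy.
#'
#' @param dispensings data.frame with `patient_id`, `dispense_date` (Date),
#'   `atc_code`, `days_supply`.
#' @param class_map a [default_class_map()] object.
#' @param lookback_days washout window before the index date (default 730).
#' @param study_start,study_end study window dates; candidates are exposure
#'   dispensings inside the window.
#' @return data.frame with `patient_id`, `index_date`, `index_class`.
#' @export
identify_index <- function(dispensings, class_map, lookback_days = 730,
                           study_start = as.Date("1996-01-01"),
                           study_end = as.Date("2020-12-31")) {
  if (nrow(dispensings) == 0L) {
    return(data.frame(patient_id = character(0),
                      index_date = as.Date(character(0)),
                      index_class = character(0)))
  }
  cls <- exposure_class_of(dispensings$atc_code, class_map)
  expo <- dispensings[!is.na(cls), , drop = FALSE]
  expo$class <- cls[!is.na(cls)]
  out <- lapply(split(expo, expo$patient_id), function(d) {
    in_win <- d$dispense_date >= study_start & d$dispense_date <= study_end
    if (!any(in_win)) return(NULL)
    idx <- min(d$dispense_date[in_win])
    prior <- d$dispense_date < idx & d$dispense_date >= idx - lookback_days
    if (any(prior)) return(NULL)            # prevalent user, not a starter
    on_idx <- unique(d$class[d$dispense_date == idx])
    if (length(on_idx) > 1L) return(NULL)   # combination start, not monotherapy
    data.frame(patient_id = d$patient_id[1], index_date = idx,
               index_class = on_idx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0),
                      index_date = as.Date(character(0)),
                      index_class = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Apply cohort exclusion rules
#'
#' Removes candidates with any exclusion-drug dispensing (acute
#' cardiovascular therapy, heart failure, migraine, adrenal,
#' hyperparathyroidism or thyroid drugs) in
#' `[index - lookback, index + post_window]`, and candidates younger than 18
#' at the index date.
#'
#' @param candidates output of [identify_index()].
#' @param dispensings full dispensing records.
#' @param patients patient table with `patient_id`, `birth_date`, `sex`.
#' @param class_map a [default_class_map()] object.
#' @param lookback,post_window exclusion window bounds (defaults 730 and 90).
#' @return the retained candidates; attribute `n_excluded` records counts
#'   per exclusion reason.
#' @export
apply_exclusions <- function(candidates, dispensings, patients, class_map,
                             lookback = 730, post_window = 90) {
  if (nrow(candidates) == 0L) return(candidates)
  excl <- dispensings[atc_match(dispensings$atc_code,
                                class_map$exclusion_prefixes), , drop = FALSE]
  excl_by_pat <- split(excl$dispense_date, excl$patient_id)
  drug_excl <- vapply(seq_len(nrow(candidates)), function(i) {
    dt <- excl_by_pat[[candidates$patient_id[i]]]
    idx <- candidates$index_date[i]
    !is.null(dt) && any(dt >= idx - lookback & dt <= idx + post_window)
  }, logical(1))
  m <- match(candidates$patient_id, patients$patient_id)
  age <- completed_years(patients$birth_date[m], candidates$index_date)
  under_age <- is.na(age) | age < 18
  keep <- !drug_excl & !under_age
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- c(exclusion_drug = sum(drug_excl),
                               under_18 = sum(under_age & !drug_excl))
  out
}

# completed years between two dates
completed_years <- function(birth, at) {
  by <- as.integer(format(birth, "%Y")); ay <- as.integer(format(at, "%Y"))
  bm <- format(birth, "%m%d"); am <- format(at, "%m%d")
  ay - by - as.integer(am < bm)
}

#' Determine follow-up end and censoring reason
#'
#' Follow-up ends at the earliest of: the study end, 3780 days (10 years)
#' after index, the first acute-cardiovascular-drug dispensing, the end of
#' supply of the last initial-class dispensing, and the first change of the
#' initial monotherapy (a dispensing of another exposure class or an
#' antihypertensive fixed-dose combination). "End of supply" means last
#' dispensing day plus its days of supply, so a patient is not censored
#' mid-supply. Ties are resolved in the order listed.
#'
#' @param cohort data.frame with `patient_id`, `index_date`, `index_class`.
#' @param dispensings full dispensing records.
#' @param class_map a [default_class_map()] object.
#' @param study_end study end date.
#' @param max_days follow-up cap (default 3780).
#' @return `cohort` with `followup_end_day` and `censor_reason` columns.
#' @export
determine_followup_end <- function(cohort, dispensings, class_map,
                                   study_end = as.Date("2020-12-31"),
                                   max_days = 3780) {
  disp_by_pat <- split(dispensings, dispensings$patient_id)
  fu <- numeric(nrow(cohort)); reason <- character(nrow(cohort))
  reasons <- c("study_end", "max_3780", "acute_cv_drug",
               "last_exposure_supply_end", "regimen_change")
  for (i in seq_len(nrow(cohort))) {
    idx <- cohort$index_date[i]
    d <- disp_by_pat[[cohort$patient_id[i]]]
    days <- as.numeric(d$dispense_date - idx)
    cls <- exposure_class_of(d$atc_code, class_map)
    is_fdc <- atc_match(d$atc_code, class_map$fdc_prefixes)
    same <- !is.na(cls) & cls == cohort$index_class[i] & days >= 0
    acute <- days[atc_match(d$atc_code, class_map$acute_cv_prefixes) &
                    days > 0]
    change <- days[((!is.na(cls) & cls != cohort$index_class[i]) | is_fdc) &
                     days > 0]
    cand <- c(study_end = as.numeric(study_end - idx),
              max_3780 = max_days,
              acute_cv_drug = if (length(acute)) min(acute) else Inf,
              last_exposure_supply_end =
                max(days[same] + d$days_supply[same]),
              regimen_change = if (length(change)) min(change) else Inf)
    j <- which.min(cand)  # which.min returns the first minimum: tie order
    fu[i] <- cand[j]; reason[i] <- reasons[j]
  }
  cohort$followup_end_day <- fu
  cohort$censor_reason <- factor(reason, levels = reasons)
  cohort[cohort$followup_end_day > 0, , drop = FALSE]
}

#' Derive baseline covariates for the cohort
#'
#' Adds age (completed years at index) and its band (18-39 young, 40-69
#' middle, >= 70 older), sex, the nine comorbidity-drug flags (at least one
#' matching dispensing within `[index, index + window]` days), and the
#' calendar period of the index date (half-open bins 1996-2000, 2000-2010,
#' 2010-2020). Records with missing birth date or sex are dropped with a
#' message.
#'
#' @param cohort cohort data.frame with follow-up columns.
#' @param dispensings full dispensing records.
#' @param patients patient table (`patient_id`, `birth_date`, `sex`).
#' @param class_map a [default_class_map()] object.
#' @param window comorbidity ascertainment window in days (default 180,
#'   closed at both ends).
#' @return cohort with covariate columns appended.
#' @export
assign_covariates <- function(cohort, dispensings, patients, class_map,
                              window = 180) {
  m <- match(cohort$patient_id, patients$patient_id)
  birth <- patients$birth_date[m]; sex <- as.character(patients$sex)[m]
  bad <- is.na(birth) | is.na(sex)
  if (any(bad)) {
    message(sum(bad), " cohort record(s) dropped: missing birth date or sex")
    cohort <- cohort[!bad, , drop = FALSE]
    birth <- birth[!bad]; sex <- sex[!bad]
  }
  cohort$age <- completed_years(birth, cohort$index_date)
  cohort$age_band <- cut(cohort$age, c(18, 40, 70, Inf), right = FALSE,
                         labels = c("young", "middle", "older"))
  cohort$sex <- factor(sex, levels = c("female", "male"))
  yr <- as.integer(format(cohort$index_date, "%Y"))
  cohort$calendar_period <- cut(yr, c(1996, 2000, 2010, 2021), right = FALSE,
                                labels = c("1996-2000", "2000-2010",
                                           "2010-2020"))
  disp_by_pat <- split(dispensings, dispensings$patient_id)
  for (g in names(class_map$comorbidity_groups)) {
    pref <- class_map$comorbidity_groups[[g]]
    cohort[[g]] <- vapply(seq_len(nrow(cohort)), function(i) {
      d <- disp_by_pat[[cohort$patient_id[i]]]
      if (is.null(d)) return(FALSE)
      off <- as.numeric(d$dispense_date - cohort$index_date[i])
      any(atc_match(d$atc_code, pref) & off >= 0 & off <= window)
    }, logical(1))
  }
  rownames(cohort) <- NULL
  cohort
}

#' Build the full new-user cohort
#'
#' Chains [identify_index()], [apply_exclusions()],
#' [determine_followup_end()] and [assign_covariates()], recording an
#' attrition table of row counts per step.
#'
#' @inheritParams identify_index
#' @param patients patient table (`patient_id`, `birth_date`, `sex`).
#' @return cohort data.frame; attribute `attrition` holds the step counts.
#' @export
build_cohort <- function(dispensings, patients, class_map = default_class_map(),
                         study_start = as.Date("1996-01-01"),
                         study_end = as.Date("2020-12-31"),
                         lookback_days = 730) {
  idx <- identify_index(dispensings, class_map, lookback_days,
                        study_start, study_end)
  kept <- apply_exclusions(idx, dispensings, patients, class_map,
                           lookback_days)
  n_after_excl <- nrow(kept)
  coh <- determine_followup_end(kept, dispensings, class_map, study_end)
  coh <- assign_covariates(coh, dispensings, patients, class_map)
  attr(coh, "attrition") <- data.frame(
    step = c("patients_with_dispensings", "index_identified",
             "after_exclusions", "final_cohort"),
    n = c(length(unique(dispensings$patient_id)), nrow(idx),
          n_after_excl, nrow(coh)))
  coh
}

#' Objective-specific sub-cohorts
#'
#' `subcohort_monotherapy()` keeps patients on the original monotherapy for
#' more than `days` days (follow-up, which ends at supply end or regimen
#' change, exceeds `days`). `subcohort_records()` keeps patients whose drug
#' records of any kind span more than `days` days after index.
#'
#' @param cohort cohort data.frame.
#' @param days minimum span in days (e.g. 360, 1080).
#' @param dispensings full dispensing records (for `subcohort_records`).
#' @return filtered cohort.
#' @export
subcohort_monotherapy <- function(cohort, days) {
  cohort[cohort$followup_end_day > days, , drop = FALSE]
}

#' @rdname subcohort_monotherapy
#' @export
subcohort_records <- function(cohort, dispensings, days) {
  last <- tapply(as.numeric(dispensings$dispense_date),
                 dispensings$patient_id, max)
  idx <- as.numeric(cohort$index_date)
  span <- last[cohort$patient_id] - idx
  cohort[!is.na(span) & span > days, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
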