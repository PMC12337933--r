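#' Detect discontinuation of the initial drug class
#'
#' Discontinuation is a refill gap of more than `gap_days` (default 180)
#' days: the first end `e` of a covered interval such that no same-class
#' dispensing occurs in `(e, e + gap_days]`. The event is dated at the end of
#' supply, not at the last dispensing. A gap running into the censoring date
#' is not a discontinuation: the event requires `e + gap_days <
#' followup_end_day`, so the whole gap is observable inside follow-up.
#'
#' @param timeline a [covered_intervals()] timeline of the initial class.
#' @param same_class_days integer days (since index) of all initial-class
#'   dispensings.
#' @param followup_end_day end of observation (days since index).
#' @param gap_days gap threshold (default 180).
#' @return the discontinuation day, or `NA` if none.
#' @export
detect_discontinuation <- function(timeline, same_class_days,
                                   followup_end_day, gap_days = 180) {
  iv <- timeline$intervals
  if (nrow(iv) == 0L) return(NA_real_)
  for (i in seq_len(nrow(iv))) {
    e <- iv$end[i]
    if (e + gap_days >= followup_end_day) next
    if (!any(same_class_days > e & same_class_days <= e + gap_days)) {
      return(e)
    }
  }
  NA_real_
}

#' Detect switch and add-on events
#'
#' A switch is the first dispensing of a different antihypertensive class or
#' fixed-dose combination within `window` days after a discontinuation, i.e.
#' on a day in `(disc_day, disc_day + window]`. An add-on is the first
#' other-class/FDC dispensing on a day inside initial-class coverage (the
#' half-open interval convention puts the exact end-of-supply day outside
#' coverage, hence on the switch side) and before any discontinuation. One
#' patient can have both, at different times.
#'
#' @param disc_day discontinuation day or `NA`, from
#'   [detect_discontinuation()].
#' @param timeline initial-class [covered_intervals()] timeline.
#' @param other_days integer days of other-class/FDC dispensings.
#' @param other_labels class labels parallel to `other_days`.
#' @param window switch window after discontinuation (default 180).
#' @return list with `switch_day`, `switch_target`, `addon_day`,
#'   `addon_target` (`NA` where absent).
#' @export
detect_switch_addon <- function(disc_day, timeline, other_days, other_labels,
                                window = 180) {
  res <- list(switch_day = NA_real_, switch_target = NA_character_,
              addon_day = NA_real_, addon_target = NA_character_)
  if (length(other_days) > 0L) {
    o <- order(other_days)
    other_days <- other_days[o]; other_labels <- other_labels[o]
    if (!is.na(disc_day)) {
      hit <- which(other_days > disc_day & other_days <= disc_day + window)
      if (length(hit) > 0L) {
        res$switch_day <- other_days[hit[1]]
        res$switch_target <- other_labels[hit[1]]
      }
    }
    iv <- timeline$intervals
    inside <- rep(FALSE, length(other_days))
    for (i in seq_len(nrow(iv))) {
      inside <- inside | (other_days >= iv$start[i] & other_days < iv$end[i])
    }
    if (!is.na(disc_day)) inside <- inside & other_days < disc_day
    hit <- which(inside)
    if (length(hit) > 0L) {
      res$addon_day <- other_days[hit[1]]
      res$addon_target <- other_labels[hit[1]]
    }
  }
  res
}

#' Classify one patient's drug-utilization pattern
#'
#' Continuation means staying on the baseline monotherapy from index to the
#' end of follow-up with no discontinuation, no switch and no add-on;
#' otherwise the profile carries each detected event. The categories other
#' than continuation are not mutually exclusive.
#'
#' @param timeline initial-class [covered_intervals()] timeline.
#' @param same_class_days days of initial-class dispensings.
#' @param other_days,other_labels other-class/FDC dispensing days and labels.
#' @param followup_end_day end of observation (days since index).
#' @param gap_days,window thresholds, both default 180.
#' @return one-row data.frame (a pattern profile): `continuation`,
#'   `disc_day`, `switch_day`, `switch_target`, `addon_day`, `addon_target`.
#' @export
classify_patient <- function(timeline, same_class_days, other_days,
                             other_labels, followup_end_day,
                             gap_days = 180, window = 180) {
  disc <- detect_discontinuation(timeline, same_class_days, followup_end_day,
                                 gap_days)
  sa <- detect_switch_addon(disc, timeline, other_days, other_labels, window)
  data.frame(continuation = is.na(disc) && is.na(sa$switch_day) &&
               is.na(sa$addon_day),
             disc_day = disc,
             switch_day = sa$switch_day, switch_target = sa$switch_target,
             addon_day = sa$addon_day, addon_target = sa$addon_target,
             stringsAsFactors = FALSE)
}

#' Classify drug-utilization patterns for a whole cohort
#'
#' Runs [classify_patient()] for every cohort entry. Patterns are assessed
#' over an observation horizon that, unlike the PDC follow-up end, is not
#' censored at supply end or regimen change (a switch, by definition, happens
#' after the initial therapy stops): the default horizon is
#' `min(study_end - index, 3780, first acute-CV day)`.
#'
#' @param cohort cohort data.frame from [build_cohort()].
#' @param dispensings dispensing records data.frame.
#' @param class_map a [default_class_map()] object.
#' @param study_end study end date.
#' @param policy coverage policy for the initial-class timeline.
#' @param gap_days,window thresholds, both default 180.
#' @param max_days follow-up cap in days (default 3780).
#' @return data.frame of pattern profiles, one row per cohort entry, with
#'   `patient_id`, `index_class` and `horizon` prepended.
#' @export
classify_patterns <- function(cohort, dispensings, class_map, study_end,
                              policy = "carryover", gap_days = 180,
                              window = 180, max_days = 3780) {
  disp_by_pat <- split(dispensings, dispensings$patient_id)
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    disp <- disp_by_pat[[pid]]
    idx <- cohort$index_date[i]
    horizon <- min(as.numeric(study_end - idx), max_days)
    days <- as.numeric(disp$dispense_date - idx)
    keep <- days >= 0 & days <= horizon
    disp <- disp[keep, , drop = FALSE]; days <- days[keep]
    cls <- exposure_class_of(disp$atc_code, class_map)
    is_fdc <- atc_match(disp$atc_code, class_map$fdc_prefixes)
    acute <- days[atc_match(disp$atc_code, class_map$acute_cv_prefixes) &
                    days > 0]
    if (length(acute) > 0L) horizon <- min(horizon, min(acute))
    same <- !is.na(cls) & cls == cohort$index_class[i]
    other <- (!is.na(cls) & cls != cohort$index_class[i]) | is_fdc
    lab <- ifelse(is_fdc, "FDC", cls)
    tl <- covered_intervals(days[same], disp$days_supply[same], policy,
                            patient_id = pid,
                            drug_class = cohort$index_class[i])
    prof <- classify_patient(tl, days[same], days[other], lab[other],
                             horizon, gap_days, window)
    out[[i]] <- cbind(data.frame(patient_id = pid,
                                 index_class = cohort$index_class[i],
                                 horizon = horizon,
                                 stringsAsFactors = FALSE),
                      prof)
  }
  do.call(rbind, out)
}

#' Pattern rates by exposure class
#'
#' Percentage of patients per index class with each pattern. Categories other
#' than continuation are not mutually exclusive, so rows can sum to more
#' than 100.
#'
#' @param profiles output of [classify_patterns()].
#' @return data.frame with one row per class and columns `n`,
#'   `continuation`, `discontinuation`, `switch`, `addon` (percentages).
#' @export
pattern_rates <- function(profiles) {
  sp <- split(profiles, profiles$index_class)
  out <- lapply(names(sp), function(cl) {
    p <- sp[[cl]]
    data.frame(index_class = cl, n = nrow(p),
               continuation = 100 * mean(p$continuation),
               discontinuation = 100 * mean(!is.na(p$disc_day)),
               switch = 100 * mean(!is.na(p$switch_day)),
               addon = 100 * mean(!is.na(p$addon_day)))
  })
  do.call(rbind, out)
}

#' Class-by-target switch or add-on matrix
#'
#' @param profiles output of [classify_patterns()].
#' @param type `"switch"` or `"addon"`.
#' @return contingency table of index class by target class/FDC.
#' @export
switch_addon_matrix <- function(profiles, type = c("switch", "addon")) {
  type <- match.arg(type)
  tgt <- if (type == "switch") profiles$switch_target else profiles$addon_target
  keep <- !is.na(tgt)
  table(index_class = profiles$index_class[keep], target = tgt[keep])
}
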