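#' Build the covered-day timeline for one patient and drug class
#'
#' Converts a set of dispensings (day offsets since the index date plus days
#' of supply) into an ordered list of disjoint half-open coverage intervals
#' `[start, end)`. Two overlap policies are supported:
#'
#' * `"carryover"` (default): an early refill is stockpiled — its supply
#'   starts when the previous supply runs out, so overlapping supplies are
#'   pushed forward. This is the usual PDC convention for chronic therapy.
#' * `"truncate"`: intervals are the plain set-union of
#'   `[dispense_day, dispense_day + days_supply)`; overlapping days are
#'   counted once and oversupply is discarded.
#'
#' @param days integer vector of dispensing day offsets (day 0 = index date).
#' @param supply integer vector of days of supply (recycled if length 1).
#' @param policy `"carryover"` or `"truncate"`.
#' @param patient_id,drug_class optional identifiers carried on the object.
#' @return an object of class `coverage_timeline`: a list with `intervals`
#'   (data.frame with `start`, `end`), `policy`, and the identifiers.
#' @examples
#' tl <- covered_intervals(c(0, 60), c(90, 90), policy = "carryover")
#' covered_days(tl)  # 180: the early refill is pushed forward
#' @export
covered_intervals <- function(days, supply, policy = c("carryover", "truncate"),
                              patient_id = NA_character_,
                              drug_class = NA_character_) {
  policy <- match.arg(policy)
  stopifnot(length(days) == length(supply) || length(supply) == 1L)
  if (length(supply) == 1L) supply <- rep(supply, length(days))
  if (any(supply <= 0)) stop("days_supply must be positive")
  o <- order(days, supply)
  days <- as.numeric(days[o]); supply <- as.numeric(supply[o])
  if (length(days) == 0L) {
    iv <- data.frame(start = numeric(0), end = numeric(0))
  } else if (policy == "carryover") {
    start <- numeric(length(days)); end <- numeric(length(days))
    prev_end <- -Inf
    for (i in seq_along(days)) {
      start[i] <- max(days[i], prev_end)
      end[i] <- start[i] + supply[i]
      prev_end <- end[i]
    }
    iv <- merge_intervals(start, end)
  } else {
    iv <- merge_intervals(days, days + supply)
  }
  structure(list(intervals = iv, policy = policy,
                 patient_id = patient_id, drug_class = drug_class),
            class = "coverage_timeline")
}

# union of half-open intervals; inputs sorted by start
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- numeric(0); me <- numeric(0)
  for (i in seq_along(start)) {
    if (length(ms) > 0L && start[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end[i])
    } else {
      ms <- c(ms, start[i]); me <- c(me, end[i])
    }
  }
  data.frame(start = ms, end = me)
}

#' Covered days of a timeline, optionally restricted to a window
#'
#' @param timeline a [covered_intervals()] object.
#' @param from,to half-open window `[from, to)`; defaults to the whole line.
#' @return number of covered days inside the window.
#' @export
covered_days <- function(timeline, from = -Inf, to = Inf) {
  iv <- timeline$intervals
  if (nrow(iv) == 0L) return(0)
  sum(pmax(0, pmin(iv$end, to) - pmax(iv$start, from)))
}

#' Annual proportion of days covered
#'
#' PDC of treatment year `k`, defined on the fixed 360-day window
#' `[360(k-1), 360k)` with a fixed 360-day denominator. When the follow-up
#' end is supplied and the window is not fully inside follow-up, the year is
#' flagged not evaluable (`NA`) rather than reported as a deflated rate;
#' year-k estimates are thereby restricted to patients persisting more than
#' 360·k days.
#'
#' @param timeline a [covered_intervals()] object.
#' @param k treatment year index (1-based).
#' @param followup_end_day optional follow-up end (days since index).
#' @param year_len window length in days (default 360).
#' @return PDC in `[0, 1]`, or `NA` if the window is not evaluable.
#' @export
annual_pdc <- function(timeline, k, followup_end_day = NULL, year_len = 360) {
  stopifnot(k >= 1)
  if (!is.null(followup_end_day) && year_len * k > followup_end_day) {
    return(NA_real_)
  }
  min(1, covered_days(timeline, year_len * (k - 1), year_len * k) / year_len)
}

#' Overall proportion of days covered during follow-up
#'
#' @param timeline a [covered_intervals()] object.
#' @param followup_end_day follow-up end in days since index (>= 1).
#' @return PDC in `[0, 1]` over `[0, followup_end_day)`.
#' @export
overall_pdc <- function(timeline, followup_end_day) {
  stopifnot(followup_end_day >= 1)
  min(1, covered_days(timeline, 0, followup_end_day) / followup_end_day)
}

#' Binarize adherence at the 0.8 threshold
#'
#' High adherence is PDC >= 0.8 (inclusive); below 0.8 is low.
#'
#' @param pdc numeric vector of PDC values in `[0, 1]` (`NA` allowed).
#' @param threshold cutoff, default 0.8.
#' @return factor with levels `high`, `low` (`NA` preserved).
#' @export
binarize_adherence <- function(pdc, threshold = 0.8) {
  ok <- is.na(pdc) | (pdc >= 0 & pdc <= 1)
  if (!all(ok)) stop("pdc values must lie in [0, 1]")
  factor(ifelse(pdc >= threshold, "high", "low"), levels = c("high", "low"))
}

#' Per-patient annual and overall adherence table
#'
#' Applies the two PDC formulas to every cohort patient: annual PDC on fixed
#' 360-day windows for evaluable years, and overall PDC over follow-up.
#'
#' @param cohort a cohort data.frame from [build_cohort()].
#' @param dispensings dispensing records data.frame.
#' @param class_map a [default_class_map()] object.
#' @param policy coverage overlap policy, see [covered_intervals()].
#' @param max_years maximum treatment year reported (default 10).
#' @return list with `annual` (patient_id, year, pdc, adherence) and
#'   `overall` (patient_id, pdc, adherence) data.frames.
#' @export
adherence_table <- function(cohort, dispensings, class_map,
                            policy = "carryover", max_years = 10) {
  ann <- vector("list", nrow(cohort)); ove <- vector("list", nrow(cohort))
  disp_by_pat <- split(dispensings, dispensings$patient_id)
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    tl <- patient_timeline(disp_by_pat[[pid]], cohort$index_date[i],
                           cohort$index_class[i], class_map, policy)
    fu <- cohort$followup_end_day[i]
    ks <- seq_len(max_years)
    pdc <- vapply(ks, function(k) annual_pdc(tl, k, fu), numeric(1))
    keep <- !is.na(pdc)
    if (any(keep)) {
      ann[[i]] <- data.frame(patient_id = pid, year = ks[keep],
                             pdc = pdc[keep])
    }
    ove[[i]] <- data.frame(patient_id = pid, pdc = overall_pdc(tl, fu))
  }
  annual <- do.call(rbind, ann[!vapply(ann, is.null, logical(1))])
  if (is.null(annual)) {
    annual <- data.frame(patient_id = character(0), year = integer(0),
                         pdc = numeric(0))
  }
  overall <- do.call(rbind, ove)
  annual$adherence <- binarize_adherence(annual$pdc)
  overall$adherence <- binarize_adherence(overall$pdc)
  list(annual = annual, overall = overall)
}

# timeline of the index class for one patient, days relative to index
patient_timeline <- function(disp, index_date, index_class, class_map,
                             policy = "carryover") {
  if (is.null(disp) || nrow(disp) == 0L) {
    return(covered_intervals(numeric(0), numeric(0), policy,
                             drug_class = index_class))
  }
  cls <- exposure_class_of(disp$atc_code, class_map)
  sel <- !is.na(cls) & cls == index_class
  days <- as.numeric(disp$dispense_date[sel] - index_date)
  sel2 <- days >= 0
  covered_intervals(days[sel2], disp$days_supply[sel][sel2], policy,
                    patient_id = disp$patient_id[1], drug_class = index_class)
}
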