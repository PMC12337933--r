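#' ATC class map for exposure, exclusion and comorbidity drug groups
#'
#' The class map drives every ATC-based decision in the pipeline: which
#' dispensings count as one of the five antihypertensive monotherapy classes,
#' which products are fixed-dose combinations (FDCs), which dispensings
#' trigger cohort exclusion or follow-up censoring, and which define the nine
#' baseline comorbidity-drug flags.
#'
#' The five exposure classes are fixed by the Dutch first-line monotherapy
#' guideline: thiazides (C03AA), calcium channel blockers (C08C/C08D/C08E),
#' ACE inhibitors (C09A), angiotensin II receptor blockers (C09C) and
#' beta-blockers (C07A). All other prefix lists are editable defaults: source
#' material for this design names conditions and drug groups, not codes, so
#' the shipped ATC prefixes are this package's own operationalization.
#'
#' @param exposure_classes named list mapping the five class names
#'   (`thiazide`, `CCB`, `ACEI`, `ARB`, `BB`) to character vectors of ATC
#'   prefixes.
#' @param fdc_prefixes ATC prefixes of antihypertensive fixed-dose
#'   combinations (targets for switch/add-on, and regimen-change triggers).
#' @param exclusion_prefixes ATC prefixes whose dispensing in the exclusion
#'   window removes a candidate from the cohort (acute cardiovascular
#'   therapy, chronic heart failure, migraine, adrenal disease,
#'   hyperparathyroidism, thyroid disease).
#' @param acute_cv_prefixes subset of exclusion drugs whose first dispensing
#'   after the index date ends follow-up.
#' @param comorbidity_groups named list of the nine comorbidity drug groups
#'   (ATC prefixes) used as baseline covariates.
#' @return an object of class `class_map` (a validated list).
#' @examples
#' cm <- default_class_map()
#' names(cm$exposure_classes)
#' @export
default_class_map <- function(exposure_classes = list(
                                thiazide = "C03AA",
                                CCB = c("C08C", "C08D", "C08E"),
                                ACEI = "C09A",
                                ARB = "C09C",
                                BB = "C07A"),
                              fdc_prefixes = c("C02L", "C03E", "C07B", "C07C",
                                               "C07D", "C07F", "C08G", "C09B",
                                               "C09D"),
                              exclusion_prefixes = c("C01", "B01", "C03C",
                                                     "N02C", "H02", "H05",
                                                     "H03"),
                              acute_cv_prefixes = c("C01", "B01"),
                              comorbidity_groups = list(
                                diabetes = "A10",
                                ra = c("M01A", "L04A"),
                                asthma_copd = "R03",
                                antiepileptics = "N03",
                                antiparkinson = "N04",
                                psycholeptics = "N05",
                                psychoanaleptics = "N06",
                                addictive_disorders = "N07B",
                                antineoplastics = "L01")) {
  cm <- list(exposure_classes = exposure_classes,
             fdc_prefixes = fdc_prefixes,
             exclusion_prefixes = exclusion_prefixes,
             acute_cv_prefixes = acute_cv_prefixes,
             comorbidity_groups = comorbidity_groups)
  class(cm) <- "class_map"
  validate_class_map(cm)
  cm
}

validate_class_map <- function(cm) {
  wanted <- c("thiazide", "CCB", "ACEI", "ARB", "BB")
  if (!setequal(names(cm$exposure_classes), wanted)) {
    stop("exposure_classes must be exactly {thiazide, CCB, ACEI, ARB, BB}")
  }
  all_pref <- unlist(cm[c("exposure_classes", "fdc_prefixes",
                          "exclusion_prefixes", "acute_cv_prefixes",
                          "comorbidity_groups")], use.names = FALSE)
  if (!all(grepl("^[A-Z][0-9A-Z]{0,6}$", all_pref))) {
    stop("every ATC prefix must match the ATC alphanumeric pattern (1-7 chars)")
  }
  if (length(names(cm$comorbidity_groups)) != 9L) {
    stop("comorbidity_groups must define nine groups")
  }
  invisible(cm)
}

#' Match ATC codes against a set of prefixes
#'
#' @param codes character vector of ATC codes.
#' @param prefixes character vector of ATC prefixes.
#' @return logical vector, `TRUE` where a code starts with any prefix.
#' @export
atc_match <- function(codes, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(codes)))
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

#' Map ATC codes to exposure class names
#'
#' @param codes character vector of ATC codes.
#' @param class_map a [default_class_map()] object.
#' @return character vector of class names, `NA` where no class matches.
#' @export
exposure_class_of <- function(codes, class_map) {
  out <- rep(NA_character_, length(codes))
  for (cl in names(class_map$exposure_classes)) {
    hit <- atc_match(codes, class_map$exposure_classes[[cl]])
    out[hit & is.na(out)] <- cl
  }
  out
}

exposure_levels <- function() c("thiazide", "CCB", "ACEI", "ARB", "BB")
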