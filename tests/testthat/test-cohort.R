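mk_disp <- function(pid, dates, atc, supply = 90) {
  data.frame(patient_id = pid, dispense_date = as.Date(dates),
             atc_code = atc, days_supply = supply, stringsAsFactors = FALSE)
}
mk_pat <- function(pid, birth = "1960-01-01", sex = "female") {
  data.frame(patient_id = pid, birth_date = as.Date(birth), sex = sex,
             stringsAsFactors = FALSE)
}
cm <- default_class_map()

test_that("index detection finds first monotherapy starters only", {
  d <- mk_disp("A", "2005-03-01", "C09A01")
  idx <- identify_index(d, cm)
  expect_equal(idx$index_date, as.Date("2005-03-01"))
  expect_equal(idx$index_class, "ACEI")
  # exposure 400 days before the in-window candidate (a pre-window record):
  # prevalent user, no index event
  d2 <- rbind(mk_disp("B", "2004-01-27", "C07A05"),
              mk_disp("B", "2005-03-02", "C09A01"))
  expect_equal(nrow(identify_index(d2, cm,
                                   study_start = as.Date("2005-01-01"))), 0)
  # two classes dispensed on the index day: not monotherapy
  d3 <- rbind(mk_disp("C", "2005-03-01", "C09A01"),
              mk_disp("C", "2005-03-01", "C03AA03"))
  expect_equal(nrow(identify_index(d3, cm)), 0)
  expect_equal(nrow(identify_index(d[0, ], cm)), 0)
})

test_that("exclusion window is [index-730, index+90] and adults only", {
  pat <- rbind(mk_pat("A"), mk_pat("B"), mk_pat("C", "1990-01-01"))
  base <- rbind(mk_disp("A", "2005-03-01", "C09A01"),
                mk_disp("B", "2005-03-01", "C09A01"),
                mk_disp("C", "2005-03-01", "C09A01"))
  # migraine drug 30 days after index: excluded
  d <- rbind(base, mk_disp("A", "2005-03-31", "N02CC01", 10))
  idx <- identify_index(d, cm)
  kept <- apply_exclusions(idx, d, pat, cm)
  expect_false("A" %in% kept$patient_id)
  # exclusion drug at index+91: retained
  d2 <- rbind(base, mk_disp("B", "2005-05-31", "N02CC01", 10))
  kept2 <- apply_exclusions(identify_index(d2, cm), d2, pat, cm)
  expect_true("B" %in% kept2$patient_id)
  # aged 15 at index: excluded (C born 1990)
  expect_false("C" %in% kept$patient_id)
})

test_that("follow-up ends at the earliest of the five censoring rules", {
  pat <- mk_pat("A")
  # continuous refills past the study end
  d <- mk_disp("A", as.character(seq(as.Date("2019-06-01"),
                                     as.Date("2021-06-01"), by = 90)),
               "C09A01")
  coh <- determine_followup_end(identify_index(d, cm), d, cm,
                                as.Date("2020-12-31"))
  expect_equal(as.character(coh$censor_reason), "study_end")
  expect_equal(coh$followup_end_day,
               as.numeric(as.Date("2020-12-31") - as.Date("2019-06-01")))
  # refills for 12 years: capped at 3780
  d2 <- mk_disp("A", as.character(seq(as.Date("1996-01-01"),
                                      by = 90, length.out = 50)), "C09A01")
  coh2 <- determine_followup_end(identify_index(d2, cm), d2, cm,
                                 as.Date("2020-12-31"))
  expect_equal(coh2$followup_end_day, 3780)
  expect_equal(as.character(coh2$censor_reason), "max_3780")
  # last exposure dispensing day 270 + 90 days supply, nothing else
  d3 <- mk_disp("A", c("2000-01-01", "2000-04-01", "2000-09-27"), "C09A01")
  coh3 <- determine_followup_end(identify_index(d3, cm), d3, cm,
                                 as.Date("2020-12-31"))
  expect_equal(coh3$followup_end_day, 270 + 90)
  expect_equal(as.character(coh3$censor_reason), "last_exposure_supply_end")
  # regimen change: other-class dispensing at day 100 precedes supply end
  d4 <- rbind(mk_disp("A", c("2000-01-01", "2000-04-01"), "C09A01"),
              mk_disp("A", "2000-04-10", "C08CA01"))
  coh4 <- determine_followup_end(identify_index(d4, cm), d4, cm,
                                 as.Date("2020-12-31"))
  expect_equal(coh4$followup_end_day, 100)
  expect_equal(as.character(coh4$censor_reason), "regimen_change")
})

test_that("follow-up min-rule equals a brute-force day scan on synthetic patients", {
  pop <- simulate_population(sim_config(n_patients = 200, seed = 31))
  coh <- build_cohort(pop$dispensings, pop$patients)
  study_end <- as.Date("2020-12-31")
  disp_by_pat <- split(pop$dispensings, pop$dispensings$patient_id)
  for (i in seq_len(nrow(coh))) {
    d <- disp_by_pat[[coh$patient_id[i]]]
    days <- as.numeric(d$dispense_date - coh$index_date[i])
    cls <- exposure_class_of(d$atc_code, cm)
    is_fdc <- atc_match(d$atc_code, cm$fdc_prefixes)
    stop_day <- Inf
    for (t in seq_len(3780)) {           # brute-force day scan
      if (t >= as.numeric(study_end - coh$index_date[i])) { stop_day <- t; break }
      if (any(days == t & (atc_match(d$atc_code, cm$acute_cv_prefixes)))) {
        stop_day <- t; break
      }
      same <- !is.na(cls) & cls == coh$index_class[i] & days >= 0
      if (t >= max(days[same] + d$days_supply[same])) { stop_day <- t; break }
      if (any(days == t & ((!is.na(cls) & cls != coh$index_class[i]) |
                             is_fdc))) { stop_day <- t; break }
    }
    expect_equal(coh$followup_end_day[i], min(stop_day, 3780),
                 info = coh$patient_id[i])
  }
})

test_that("covariates follow the printed windows and bands", {
  pat <- rbind(mk_pat("A", "1935-03-01", "male"),   # 70 at index
               mk_pat("B", "1935-03-02", "female")) # 69 at index
  d <- rbind(mk_disp("A", "2005-03-01", "C09A01"),
             mk_disp("B", "2005-03-01", "C09A01"),
             mk_disp("A", "2005-06-09", "A10BA02", 30),  # day 100: diabetes
             mk_disp("B", "2005-09-17", "A10BA02", 30))  # day 200: outside
  coh <- build_cohort(d, pat)
  a <- coh[coh$patient_id == "A", ]; b <- coh[coh$patient_id == "B", ]
  expect_true(a$diabetes); expect_false(b$diabetes)
  expect_equal(as.character(a$age_band), "older")
  expect_equal(as.character(b$age_band), "middle")
  expect_equal(as.character(a$calendar_period), "2000-2010")
  # records with missing sex are dropped with a message
  pat2 <- rbind(mk_pat("A", "1960-01-01", NA), mk_pat("B"))
  expect_message(coh2 <- build_cohort(d, pat2), "missing")
  expect_false("A" %in% coh2$patient_id)
})

test_that("cohort construction is idempotent and sub-cohorts nest", {
  pop <- simulate_population(sim_config(n_patients = 150, seed = 5))
  coh <- build_cohort(pop$dispensings, pop$patients)
  # re-apply exclusion predicates: nothing further removed
  again <- apply_exclusions(coh[, c("patient_id", "index_date",
                                    "index_class")],
                            pop$dispensings, pop$patients, cm)
  expect_equal(nrow(again), nrow(coh))
  # year-(k+1) monotherapy cohort is a subset of the year-k cohort
  for (k in 1:4) {
    a <- subcohort_monotherapy(coh, 360 * k)$patient_id
    b <- subcohort_monotherapy(coh, 360 * (k + 1))$patient_id
    expect_true(all(b %in% a))
  }
  r <- subcohort_records(coh, pop$dispensings, 1080)$patient_id
  r2 <- subcohort_records(coh, pop$dispensings, 2160)$patient_id
  expect_true(all(r2 %in% r))
})
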