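test_that("DMT efficacy classification matches the published drug lists", {
  expect_equal(classify_dmt("natalizumab"), "high")
  expect_equal(classify_dmt("teriflunomide"), "moderate")
  expect_equal(classify_dmt("ibuprofen"), "unclassified")
  # case/whitespace tolerance and interferon spelling variants
  expect_equal(classify_dmt(c("  Ocrelizumab ", "Interferon Beta-1a",
                              "pegylated interferon", "PEGINTERFERON")),
               c("high", "moderate", "moderate", "moderate"))
  # the named drugs partition into exactly 10 high and >= 5 moderate
  high <- msphase:::HIGH_EFFICACY_DMTS
  moderate <- c(msphase:::MODERATE_EFFICACY_DMTS, "interferon beta-1a",
                "interferon beta-1b", "peginterferon")
  expect_length(high, 10)
  expect_gte(length(moderate), 5)
  expect_true(all(classify_dmt(high) == "high"))
  expect_true(all(classify_dmt(moderate) == "moderate"))
})

test_that("registry round-trips through CSV files unchanged", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_registry(co, dir)
  co2 <- read_registry(dir)
  expect_equal(co2$patients, co$patients)
  expect_equal(co2$relapses, co$relapses)
  expect_equal(co2$edss, co$edss)
  expect_equal(co2$treatments, co$treatments)
})

test_that("loading repairs duplicates and open episodes, and flags invariant violations", {
  # duplicate relapse rows collapse to one event
  co <- ms_cohort(make_patient("x", end_day = 1000),
                  relapses = data.frame(patient_id = c("x", "x"),
                                        relapse_day = c(5L, 5L)))
  expect_equal(nrow(co$relapses), 1)
  expect_equal(attr(co, "repairs")$relapses_deduplicated, 1)

  # open treatment episode is clipped at end of follow-up
  co <- ms_cohort(make_patient("x", end_day = 1000),
                  treatments = data.frame(patient_id = "x",
                                          drug_name = "rituximab",
                                          start_day = 10L,
                                          stop_day = NA_integer_))
  expect_equal(co$treatments$stop_day, 1000L)

  # violations name the offending patient
  expect_error(
    ms_cohort(make_patient("pz", end_day = 100),
              relapses = data.frame(patient_id = "pz", relapse_day = 200L)),
    "pz")
  expect_error(
    ms_cohort(make_patient("pq", rrms_dx_day = 10, onset_day = 50)),
    "pq")
  expect_error(
    ms_cohort(data.frame(patient_id = "m", sex = "female")),
    "onset_day")
})

test_that("cumulative exposure accrues, merges abutting episodes, and is monotone", {
  eps <- data.frame(patient_id = "x", drug_name = "natalizumab",
                    start_day = 0L, stop_day = 730L,
                    efficacy_class = "high")
  expect_equal(cumulative_exposure(eps, 730, "high"), 730 / 365.25)
  expect_equal(cumulative_exposure(eps, -10, "high"), 0)
  expect_equal(cumulative_exposure(eps, 365, "moderate"), 0)

  # abutting episodes merge: total overlap is 200 days, not double-counted
  ab <- data.frame(patient_id = "x", drug_name = "teriflunomide",
                   start_day = c(0L, 100L), stop_day = c(100L, 200L),
                   efficacy_class = "moderate")
  expect_equal(cumulative_exposure(ab, 200, "moderate"), 200 / 365.25)
  # fully overlapping episodes of the same class are not double-counted
  ov <- data.frame(patient_id = "x", drug_name = "teriflunomide",
                   start_day = c(0L, 50L), stop_day = c(100L, 150L),
                   efficacy_class = "moderate")
  expect_equal(cumulative_exposure(ov, 150, "moderate"), 150 / 365.25)

  # piecewise-linear and non-decreasing over a fine grid
  tt <- seq(-50, 900, by = 7)
  v <- cumulative_exposure(eps, tt, "high")
  expect_true(all(diff(v) >= 0))
  inside <- tt[-1] > 0 & tt[-1] <= 730  # linear accrual inside the episode
  expect_equal(diff(v)[inside][-1], rep(7 / 365.25, sum(inside) - 1))
})
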