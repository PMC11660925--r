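test_that("degenerate cohort: all processes off leaves everyone RRMS", {
  pars <- cohort_params(n_patients = 40, seed = 2, relapse_base_rate = 0,
                        spms_base_hazard = 0, death_base_hazard = 0)
  co <- simulate_cohort(pars)
  expect_equal(nrow(co$relapses), 0)
  expect_true(all(is.na(co$patients$spms_dx_day)))
  expect_true(all(co$patients$end_reason == "admin_censor"))
})

test_that("cohort simulation is reproducible and valid by construction", {
  pars <- cohort_params(n_patients = 60, seed = 7)
  co1 <- simulate_cohort(pars)
  co2 <- simulate_cohort(pars)
  expect_identical(co1$patients, co2$patients)
  expect_identical(co1$relapses, co2$relapses)
  expect_identical(co1$edss, co2$edss)
  expect_identical(co1$treatments, co2$treatments)

  # survives a write/load round trip (re-validation of all invariants)
  dir <- withr::local_tempdir()
  write_registry(co1, dir)
  co3 <- read_registry(dir)
  expect_equal(co3$patients$end_day, co1$patients$end_day)
  expect_equal(nrow(co3$relapses), nrow(co1$relapses))
})

test_that("relapse process mean matches the Poisson rate in a neutral setting", {
  # constant 0.5/year with all modifiers off: two-year windows before
  # diagnosis should hold 1.0 relapse on average
  pars <- cohort_params(n_patients = 1500, seed = 13,
                        relapse_base_rate = 0.5, relapse_age_loghr = 0,
                        relapse_duration_loghr = 0, relapse_sex_loghr = 0,
                        relapse_treatment_loghr = c(high = 0, moderate = 0),
                        relapse_post_spms_factor = 1,
                        spms_base_hazard = 0, death_base_hazard = 0,
                        onset_to_dx_mean_years = 8)
  co <- simulate_cohort(pars)
  p <- co$patients
  rel <- split(co$relapses$relapse_day, co$relapses$patient_id)
  keep <- (p$rrms_dx_day - p$onset_day) >= 730
  cnt <- vapply(which(keep), function(i) {
    r <- rel[[p$patient_id[i]]]
    if (is.null(r)) 0L else
      sum(r > p$rrms_dx_day[i] - 730 & r <= p$rrms_dx_day[i])
  }, integer(1))
  se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - 1.0), 3 * se)
})

test_that("generator output is consistent with the classifier", {
  # no diagnostic delay and no residual post-onset relapses: anyone
  # relapsing at SPMS diagnosis must indeed have a window relapse
  pars <- cohort_params(n_patients = 150, seed = 21,
                        spms_dx_delay_mean_years = 0,
                        relapse_post_spms_factor = 0)
  co <- simulate_cohort(pars)
  p <- co$patients
  rel <- split(co$relapses$relapse_day, co$relapses$patient_id)
  for (i in which(!is.na(p$spms_dx_day))) {
    r <- rel[[p$patient_id[i]]] %||% integer(0)
    st <- state_at(p[i, ], r, p$spms_dx_day[i])
    has_window_relapse <- any(r > p$spms_dx_day[i] - 730 &
                                r <= p$spms_dx_day[i])
    expect_equal(st == "rSPMS", has_window_relapse)
  }
})

test_that("CTMC panel simulator: degenerate, closed-form and expm checks", {
  st2 <- two_state_structure()
  # all intensities zero: nobody moves
  m0 <- msm_model(st2, log_q0 = c("alive->dead" = -Inf))
  pan0 <- simulate_panel_ctmc(m0, n = 30, schedule = 0:5, seed = 3)
  expect_true(all(pan0$state == "alive"))
  expect_equal(sum(pan0$obs_type == "exact_death"), 0)

  # q = 0.1/year over 5 years: fraction dead ~ 1 - e^{-0.5}
  mq <- msm_model(st2, log_q0 = c("alive->dead" = log(0.1)))
  pan <- simulate_panel_ctmc(mq, n = 2000, schedule = c(0, 5), seed = 9)
  dead <- tapply(pan$state == "dead", pan$patient_id, any)
  p_true <- 1 - exp(-0.5)
  se <- sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(mean(dead) - p_true), 3 * se)

  # same seed gives identical output
  expect_identical(pan, simulate_panel_ctmc(mq, n = 2000, schedule = c(0, 5),
                                            seed = 9))

  # one-step transition frequencies over a fine schedule track expm(Q dt);
  # a fully transient chain keeps every scheduled pair observable (exactly
  # recorded deaths would drop the scheduled observation after them)
  st3 <- ms_structure(c("A", "B", "C"),
                      data.frame(from = c("A", "B", "C", "C"),
                                 to = c("B", "C", "A", "B")))
  m3 <- random_q_model(st3, seed = 4)
  dt <- 0.5
  pan3 <- simulate_panel_ctmc(m3, n = 800, schedule = seq(0, 4, by = dt),
                              seed = 14)
  P_theory <- expm_pade(intensity_matrix(m3) * dt)
  pan3 <- pan3[order(pan3$patient_id, pan3$obs_day), ]
  sameid <- pan3$patient_id[-nrow(pan3)] == pan3$patient_id[-1]
  step <- abs(diff(pan3$obs_day) - dt * 365.25) < 2
  i1 <- which(sameid & step)
  from <- pan3$state_num[i1]; to <- pan3$state_num[i1 + 1]
  for (s in 1:3) {
    n_s <- sum(from == s)
    if (n_s < 50) next
    for (t in 1:3) {
      phat <- mean(to[from == s] == t)
      se <- sqrt(max(P_theory[s, t] * (1 - P_theory[s, t]), 1e-6) / n_s)
      expect_lt(abs(phat - P_theory[s, t]), 4 * se + 0.01)
    }
  }

  # starting in the absorbing state is rejected
  expect_error(simulate_panel_ctmc(mq, n = 2, schedule = 0:2,
                                   initial_state = "dead"), "absorbing")
})

test_that("time-rescaling: scaling hazards by c and time by 1/c preserves counts", {
  st2 <- two_state_structure()
  m_slow <- msm_model(st2, log_q0 = c("alive->dead" = log(0.1)))
  m_fast <- msm_model(st2, log_q0 = c("alive->dead" = log(0.4)))
  pan_slow <- simulate_panel_ctmc(m_slow, n = 1500, schedule = c(0, 8),
                                  seed = 6)
  pan_fast <- simulate_panel_ctmc(m_fast, n = 1500, schedule = c(0, 2),
                                  seed = 60)
  d_slow <- mean(tapply(pan_slow$state == "dead", pan_slow$patient_id, any))
  d_fast <- mean(tapply(pan_fast$state == "dead", pan_fast$patient_id, any))
  p <- 1 - exp(-0.8)
  se <- sqrt(2 * p * (1 - p) / 1500)
  expect_lt(abs(d_slow - d_fast), 4 * se)
})
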