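test_that("intensity matrix: baseline, covariate effects, conservation", {
  st <- ms_default_structure()
  labs <- st$labels
  q0 <- setNames(log(c(0.05, 0.02, 0.1, 0.3, 0.01, 0.02, 0.03)), labs)
  m <- msm_model(st, covariates = list("RRMS->nrSPMS" = "age"),
                 log_q0 = q0,
                 beta = list("RRMS->nrSPMS" = c(age = log(1.044))))
  Q <- intensity_matrix(m, c(age = 0))
  expect_equal(Q["RRMS", "nrSPMS"], 0.05)
  expect_equal(Q["nrSPMS", "rSPMS"], 0.1)
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(Q["Death", ], c(RRMS = 0, nrSPMS = 0, rSPMS = 0, Death = 0))

  # one more year of age multiplies only the affected transition
  Q1 <- intensity_matrix(m, c(age = 1))
  expect_equal(Q1["RRMS", "nrSPMS"] / Q["RRMS", "nrSPMS"], 1.044)
  expect_equal(Q1["nrSPMS", "rSPMS"], Q["nrSPMS", "rSPMS"])
  expect_equal(Q1["RRMS", "rSPMS"], Q["RRMS", "rSPMS"])

  expect_error(intensity_matrix(m, c(sex_female = 1)), "age")
})

test_that("transition probabilities: identity, closed form, semigroup", {
  st2 <- two_state_structure()
  m2 <- msm_model(st2, log_q0 = c("alive->dead" = log(0.1)))
  expect_equal(transition_probability(m2, NULL, 3, 3),
               diag(2), ignore_attr = TRUE)
  P5 <- transition_probability(m2, NULL, 0, 5)
  expect_equal(P5["alive", "alive"], exp(-0.5), tolerance = 1e-12)

  # product over two equal-covariate segments collapses to one segment
  m <- random_q_model(ms_default_structure(), seed = 5)
  path <- data.frame(time = c(0, 2))  # same (empty) covariates both segments
  expect_equal(transition_probability(m, path, 0, 7),
               transition_probability(m, NULL, 0, 7), tolerance = 1e-12)
  expect_equal(unname(rowSums(transition_probability(m, NULL, 0, 7))),
               rep(1, 4), tolerance = 1e-10)

  expect_error(transition_probability(m2, data.frame(time = 2), 0, 5),
               "cover")
})

test_that("panel likelihood matches closed forms and the ODE oracle", {
  skip_if_not_installed("deSolve")
  # two same-state observations under Q = 0 contribute log(1) = 0
  st2 <- two_state_structure()
  m0 <- msm_model(st2, log_q0 = c("alive->dead" = -Inf))
  pan <- data.frame(patient_id = "x", obs_day = c(0, 365.25),
                    state_num = c(1, 1), obs_type = "panel")
  expect_equal(panel_loglik(m0, pan), 0)

  # exact-death contribution is the exponential density q e^{-q dt}
  q <- 0.23
  mq <- msm_model(st2, log_q0 = c("alive->dead" = log(q)))
  pand <- data.frame(patient_id = "x", obs_day = c(0, 3 * 365.25),
                     state_num = c(1, 2),
                     obs_type = c("panel", "exact_death"))
  expect_equal(panel_loglik(mq, pand), log(q * exp(-q * 3)),
               tolerance = 1e-10)
  # panel (not exactly observed) death is the interval probability instead
  panp <- pand
  panp$obs_type <- "panel"
  expect_equal(panel_loglik(mq, panp), log(1 - exp(-q * 3)),
               tolerance = 1e-10)

  # random 3-state instances against Kolmogorov-forward integration
  st3 <- three_state_structure()
  for (s in 1:10) {
    m3 <- random_q_model(st3, seed = s)
    pan3 <- simulate_panel_ctmc(m3, n = 8, schedule = seq(0, 6, by = 1.5),
                                seed = s + 100)
    expect_equal(panel_loglik(m3, pan3), ode_panel_loglik(m3, pan3),
                 tolerance = 1e-6)
  }
})

test_that("zero-probability transitions are flagged with the offending pair", {
  st3 <- three_state_structure()
  m3 <- msm_model(st3, log_q0 = setNames(c(log(0.2), -Inf, log(0.2), -Inf),
                                         st3$labels))
  # A -> C impossible under this model
  pan <- data.frame(patient_id = "bad", obs_day = c(0, 365.25),
                    state_num = c(1, 3), obs_type = "panel")
  ll <- panel_loglik(m3, pan)
  expect_true(is.infinite(ll) && ll < 0)
  expect_equal(attr(ll, "bad_pairs")$patient_id, "bad")
})

test_that("fitting recovers a known rate and is a fixed point at the optimum", {
  st2 <- two_state_structure()
  m2 <- msm_model(st2, log_q0 = c("alive->dead" = log(0.2)))
  pan <- simulate_panel_ctmc(m2, n = 500, schedule = 0:8, seed = 31)
  fit <- fit_msm(pan, structure = st2, covariates = NULL)
  expect_true(fit$converged)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[[1]] - log(0.2)), 3 * se[[1]])

  # refitting from the optimum stays there
  fit2 <- fit_msm(pan, structure = st2, covariates = NULL,
                  init = fit$model, control = list(hessian = FALSE))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-5)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)

  # analytic check: with exact-death data the MLE is deaths / person-years
  iv <- fit$intervals
  deaths <- sum(iv$is_death)
  py <- sum(iv$dtu[iv$comb + 1])
  expect_equal(exp(coef(fit)[[1]]), deaths / py, tolerance = 1e-5)
})

test_that("hazard ratio table and Wald intervals", {
  st2 <- two_state_structure()
  mod <- msm_model(st2, covariates = list("alive->dead" = "x"),
                   log_q0 = c("alive->dead" = log(0.3)),
                   beta = list("alive->dead" = c(x = log(2))))
  covfn <- function(i) data.frame(time = 0, x = rbinom(1, 1, 0.5))
  pan <- simulate_panel_ctmc(mod, covfn, n = 600, schedule = 0:6, seed = 8)
  fit <- fit_msm(pan, structure = st2,
                 covariates = list("alive->dead" = "x"))
  hr <- hazard_ratios(fit)
  expect_equal(hr$transition, "alive->dead")
  expect_lt(abs(hr$loghr - log(2)), 3 * hr$se)
  expect_equal(hr$lower, exp(hr$loghr - 1.959964 * hr$se))
  expect_equal(hr$upper, exp(hr$loghr + 1.959964 * hr$se))
  # formatted like "1.044 (1.035-1.053)"
  expect_match(fmt_est_ci(1.0435, 1.0351, 1.0528, digits = 3),
               "^1\\.044 \\(1\\.035–1\\.053\\)$")
})

test_that("predicted probabilities: degenerate vcov, conservation, seed", {
  st2 <- two_state_structure()
  m2 <- msm_model(st2, log_q0 = c("alive->dead" = log(0.15)))
  pan <- simulate_panel_ctmc(m2, n = 200, schedule = 0:5, seed = 77)
  fit <- fit_msm(pan, structure = st2, covariates = NULL)

  # zero covariance: all draws collapse onto the point estimate
  fit0 <- fit
  fit0$vcov[] <- 0
  pr0 <- predicted_probabilities(fit0, horizons = 5, n_draws = 20, seed = 1)
  expect_equal(pr0$lower, pr0$estimate, tolerance = 1e-12)
  expect_equal(pr0$upper, pr0$estimate, tolerance = 1e-12)

  pr <- predicted_probabilities(fit, horizons = c(5, 10), n_draws = 50,
                                seed = 42)
  # each (horizon, from) row of the probability table sums to 1
  for (h in c(5, 10)) {
    for (f in st2$states) {
      expect_equal(sum(pr$estimate[pr$horizon == h & pr$from == f]), 1,
                   tolerance = 1e-10)
    }
  }
  expect_true(all(pr$lower <= pr$estimate + 1e-12))
  expect_true(all(pr$upper >= pr$estimate - 1e-12))
  pr2 <- predicted_probabilities(fit, horizons = c(5, 10), n_draws = 50,
                                 seed = 42)
  expect_identical(pr, pr2)
})

test_that("observed and expected prevalence agree at the first observation", {
  st2 <- two_state_structure()
  m2 <- msm_model(st2, log_q0 = c("alive->dead" = log(0.2)))
  pan <- simulate_panel_ctmc(m2, n = 100, schedule = 0:5, seed = 5)
  fit <- fit_msm(pan, structure = st2, covariates = NULL,
                 control = list(hessian = FALSE))
  prev <- expected_prevalence(fit, pan, grid = c(0, 2, 4))
  at0 <- prev[prev$time == 0, ]
  expect_equal(at0$observed, at0$expected, tolerance = 1e-12)
  expect_equal(at0$observed[at0$state == "alive"], 1)
  # proportions sum to one at every grid time
  for (t in unique(prev$time)) {
    expect_equal(sum(prev$observed[prev$time == t]), 1, tolerance = 1e-12)
    expect_equal(sum(prev$expected[prev$time == t]), 1, tolerance = 1e-10)
  }
  expect_error(expected_prevalence(fit, pan, grid = numeric(0)), "empty")
})

test_that("state relabelling permutes outputs consistently", {
  # same chain with states listed in a different order
  st <- three_state_structure()
  q0 <- setNames(log(c(0.3, 0.1, 0.25, 0.15)), st$labels)
  m <- msm_model(st, log_q0 = q0)
  stp <- ms_structure(c("B", "A", "C"),
                      data.frame(from = c("A", "A", "B", "B"),
                                 to = c("B", "C", "A", "C")),
                      absorbing = "C")
  mp <- msm_model(stp, log_q0 = q0)
  P <- transition_probability(m, NULL, 0, 2)
  Pp <- transition_probability(mp, NULL, 0, 2)
  expect_equal(Pp[c("A", "B", "C"), c("A", "B", "C")],
               P[c("A", "B", "C"), c("A", "B", "C")], tolerance = 1e-12)
})
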