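test_that("Aalen-Johansen reproduces the hand-enumerated competing-risks example", {
  recs <- data.frame(entry_time = 0, exit_time = c(1, 2, 3, 4, 5),
                     event = c("A", "censored", "B", "A", "censored"))
  aj <- aalen_johansen(recs)
  # risk sets 5, 3, 2 at the event times 1, 3, 4
  expect_equal(cif_at(aj, 4, "A"), 7 / 15, tolerance = 1e-12)
  expect_equal(cif_at(aj, 4, "B"), 4 / 15, tolerance = 1e-12)
  # conservation at every step
  expect_equal(aj$surv + rowSums(aj$cif), rep(1, length(aj$times)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(aalen_johansen(recs[0, ]), "no records")

  # all censored: flat at zero incidence
  recs0 <- data.frame(entry_time = 0, exit_time = 1:4, event = "censored")
  aj0 <- aalen_johansen(recs0)
  expect_true(all(aj0$surv == 1))
})

test_that("single-event-type Aalen-Johansen equals one minus Kaplan-Meier", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 60
    recs <- data.frame(
      entry_time = 0,
      exit_time = round(rexp(n, 0.3), 3) + 0.01,
      event = ifelse(runif(n) < 0.6, "fail", "censored"))
    aj <- aalen_johansen(recs)
    km <- kaplan_meier(recs)
    grid <- sort(unique(recs$exit_time))
    km_at <- function(t) {
      idx <- findInterval(t, km$times)
      c(1, km$surv)[idx + 1]
    }
    expect_equal(cif_at(aj, grid, "fail"), 1 - km_at(grid),
                 tolerance = 1e-12)
  }
})

test_that("Cox coefficient matches a dense grid-search oracle on a toy dataset", {
  recs <- data.frame(entry_time = 0,
                     exit_time = c(1, 2, 3, 4, 5, 6),
                     event = c("e", "e", "censored", "e", "e", "censored"),
                     x = c(1, 0, 1, 1, 0, 0))
  fit <- cox_ph(recs, "x")

  # Breslow partial likelihood by direct enumeration
  breslow_lp <- function(beta) {
    ev <- recs$event == "e"
    ll <- 0
    for (i in which(ev)) {
      risk <- recs$exit_time >= recs$exit_time[i]
      ll <- ll + beta * recs$x[i] - log(sum(exp(beta * recs$x[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_grid <- grid[which.max(vapply(grid, breslow_lp, numeric(1)))]
  expect_equal(unname(fit$coefficients["x"]), beta_grid, tolerance = 1e-4)

  # rank invariance: doubling all times leaves the estimate unchanged
  recs2 <- recs
  recs2$exit_time <- recs2$exit_time * 2
  fit2 <- cox_ph(recs2, "x")
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)

  # constant covariate: no information, coefficient 0 with warning
  recs$flat <- 1
  expect_warning(f0 <- cox_ph(recs, "flat"), "constant")
  expect_equal(unname(f0$coefficients["flat"]), 0)
})

test_that("Poisson rates: exact intercept, robust vs model-based variance", {
  # one subject, two relapses over two years: rate exactly 1
  pr <- suppressWarnings(poisson_arr(2L, 2))  # robust SE degenerate at n = 1
  expect_equal(unname(pr$rate["estimate"]), 1, tolerance = 1e-8)

  # intercept-only model returns total events over total exposure exactly
  set.seed(3)
  cnt <- rpois(40, 2)
  ex <- runif(40, 0.5, 3)
  pr <- poisson_arr(cnt, ex)
  expect_equal(unname(pr$rate["estimate"]), sum(cnt) / sum(ex),
               tolerance = 1e-8)
  expect_error(poisson_arr(c(1, 2), c(1, 0)), "positive")

  # overdispersed counts: robust interval at least as wide as model-based
  set.seed(4)
  y <- rnbinom(400, size = 0.5, mu = 2)
  ex <- rep(1, 400)
  pr <- poisson_arr(y, ex)
  fit <- pr$glm
  se_model <- sqrt(diag(vcov(fit)))[1]
  se_robust <- sqrt(diag(pr$vcov_robust))[1]
  expect_gt(se_robust, se_model)
})

test_that("GEE degenerates to the Poisson GLM and respects clustering", {
  # independence working correlation, one row per subject == GLM
  set.seed(5)
  n <- 80
  x <- rnorm(n)
  off <- log(runif(n, 0.5, 2))
  y <- rpois(n, exp(0.3 + 0.5 * x + off))
  X <- cbind(1, x)
  colnames(X) <- c("(Intercept)", "x")
  gfit <- gee_poisson(y, X, offset = off, id = seq_len(n),
                      corstr = "independence")
  ref <- glm(y ~ x + offset(off), family = poisson())
  expect_true(gfit$converged)
  expect_equal(unname(gfit$coefficients), unname(coef(ref)),
               tolerance = 1e-8)

  # estimates invariant to cluster ordering
  set.seed(6)
  id <- rep(1:30, each = 3)
  u <- rep(rnorm(30, sd = 0.4), each = 3)
  g <- rep(rbinom(30, 1, 0.5), each = 3)
  yy <- rpois(90, exp(0.2 + log(2) * g + u))
  XX <- cbind(1, g)
  colnames(XX) <- c("(Intercept)", "g")
  tidx <- rep(1:3, 30)
  f1 <- gee_poisson(yy, XX, id = id, timeidx = tidx,
                    corstr = "exchangeable")
  perm <- sample(90)
  f2 <- gee_poisson(yy[perm], XX[perm, ], id = id[perm],
                    timeidx = tidx[perm], corstr = "exchangeable")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)

  # clustered counts with a known rate ratio of 2: recovered within 3 SE
  expect_lt(abs(f1$coefficients["g"] - log(2)), 3 * f1$se["g"])

  # unstructured correlation with unbalanced bins falls back with a warning
  id_u <- c(1, 1, 2)
  t_u <- c(1, 2, 3)  # bin 3 never co-observed with the others
  expect_warning(
    gee_poisson(c(1, 2, 1), cbind(1, c(0, 1, 0)), id = id_u, timeidx = t_u,
                corstr = "unstructured"),
    "exchangeable")
})

test_that("GEE relapse trajectories on a simulated cohort behave sensibly", {
  co <- simulate_cohort(cohort_params(n_patients = 250, seed = 17))
  tab <- relapse_age_table(co)
  expect_true(all(tab$exposure_years > 0))
  expect_true(all(tab$count >= 0))
  # SPMS patients' relapsing-remitting phase ends two years before diagnosis
  p <- co$patients
  spms <- p[!is.na(p$spms_dx_day), ]
  for (pid in head(spms$patient_id, 5)) {
    rows <- tab[tab$patient_id == pid, ]
    aao <- p$age_at_onset[p$patient_id == pid]
    dur_max <- (p$spms_dx_day[p$patient_id == pid] - 730 -
                  p$onset_day[p$patient_id == pid]) / 365.25
    expect_lte(max(rows$age + 1), aao + dur_max + 1 + 1e-9)
  }
  g <- gee_poisson_arr(tab, corstr = "exchangeable")
  expect_true(g$fit$converged)
  expect_true(all(is.finite(g$arr$arr)))
  expect_true(all(g$arr$arr >= 0))
})

test_that("EDSS milestone analysis censors at SPMS diagnosis", {
  co <- simulate_cohort(cohort_params(n_patients = 300, seed = 23))
  ms <- edss_milestones(co, thresholds = c(3, 6))
  expect_named(ms, c("EDSS3", "EDSS6"))
  for (f in ms) {
    expect_true(all(is.finite(f$hr$hr)))
  }
  # lower milestones are reached at least as often as higher ones
  expect_gte(attr(ms$EDSS3, "n_events"), attr(ms$EDSS6, "n_events"))
})
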