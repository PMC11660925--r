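# Shared fixtures, built in code.

make_patient <- function(patient_id = "p1", sex = "female", onset_day = -365,
                         rrms_dx_day = 0, spms_dx_day = NA_integer_,
                         end_day = 3650, end_reason = "admin_censor",
                         age_at_onset = 34) {
  data.frame(patient_id = patient_id, sex = sex, onset_day = onset_day,
             rrms_dx_day = rrms_dx_day, spms_dx_day = spms_dx_day,
             end_day = end_day, end_reason = end_reason,
             age_at_onset = age_at_onset, stringsAsFactors = FALSE)
}

# the worked-example patient: SPMS diagnosis at day 0, a relapse 100 days
# before diagnosis and another at day 6547, follow-up through day 6721
fig2_patient <- function() {
  make_patient(patient_id = "fig2", rrms_dx_day = 0, spms_dx_day = 0,
               onset_day = -2000, end_day = 6721)
}
fig2_relapses <- function() c(-100L, 6547L)

small_cohort <- function() {
  pats <- rbind(
    make_patient("a", "female", -400, 0, NA, 4000),
    make_patient("b", "male", -100, 50, 900, 3000, "death", 40),
    make_patient("c", "female", 0, 0, NA, 2000, "emigration", 28))
  rel <- data.frame(patient_id = c("a", "b", "b"),
                    relapse_day = c(10L, 400L, 1200L))
  eds <- data.frame(patient_id = c("a", "a", "b", "c"),
                    obs_day = c(0L, 900L, 100L, 10L),
                    edss = c(1, 2.5, 3, 2))
  trt <- data.frame(patient_id = c("a", "b"),
                    drug_name = c("natalizumab", "teriflunomide"),
                    start_day = c(100L, 60L), stop_day = c(1500L, NA))
  ms_cohort(pats, rel, eds, trt)
}

# random generator matrix for a given structure
random_q_model <- function(structure, seed = 1, rate_range = c(0.02, 0.6)) {
  set.seed(seed)
  labs <- structure$labels
  msm_model(structure,
            log_q0 = setNames(log(runif(length(labs), rate_range[1],
                                        rate_range[2])), labs))
}

two_state_structure <- function() {
  ms_structure(c("alive", "dead"), data.frame(from = "alive", to = "dead"),
               absorbing = "dead")
}

three_state_structure <- function() {
  ms_structure(c("A", "B", "C"),
               data.frame(from = c("A", "A", "B", "B"),
                          to = c("B", "C", "A", "C")),
               absorbing = "C")
}

# Kolmogorov-forward ODE likelihood oracle for a constant-Q interval:
# integrates dP/dt = P Q row-wise with deSolve and reads off the entry.
ode_interval_logprob <- function(Q, dt, from, to) {
  n <- nrow(Q)
  p0 <- numeric(n); p0[from] <- 1
  deriv <- function(t, y, parms) list(as.vector(y %*% Q))
  sol <- deSolve::ode(y = p0, times = c(0, dt), func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  unname(log(sol[2, 1 + to]))
}

ode_panel_loglik <- function(model, panel) {
  covnames <- msphase:::model_covnames(model)
  ll <- 0
  for (pid in unique(panel$patient_id)) {
    pp <- panel[panel$patient_id == pid, , drop = FALSE]
    pp <- pp[order(pp$obs_day), , drop = FALSE]
    if (nrow(pp) < 2) next
    for (i in seq_len(nrow(pp) - 1)) {
      z <- if (length(covnames)) unlist(pp[i, covnames, drop = FALSE]) else
        NULL
      Q <- intensity_matrix(model, z)
      dt <- (pp$obs_day[i + 1] - pp$obs_day[i]) / 365.25
      if (identical(pp$obs_type[i + 1], "exact_death")) {
        n <- nrow(Q)
        dead <- n  # death is the last state by construction in these tests
        p <- 0
        P <- expm_pade(Q * dt)
        for (s in seq_len(n - 1)) {
          p <- p + P[pp$state_num[i], s] * Q[s, dead]
        }
        ll <- ll + log(p)
      } else {
        ll <- ll + ode_interval_logprob(Q, dt, pp$state_num[i],
                                        pp$state_num[i + 1])
      }
    }
  }
  ll
}
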