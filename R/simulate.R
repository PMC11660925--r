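# Synthetic registry generation, in two modes.
#
# 1. simulate_cohort(): a mechanistic registry simulator producing the four
#    registry tables with known latent ground truth. Relapses follow a
#    thinned inhomogeneous Poisson process whose log rate is linear in age,
#    sex and current treatment class; latent SPMS onset follows a hazard
#    log-linear in age and current latent EDSS; the recorded SPMS diagnosis
#    lags latent onset by an exponential diagnostic delay; EDSS is a
#    non-decreasing-in-expectation jump process observed at jittered visits;
#    DMT episodes alternate with gaps; death and administrative censoring
#    compete. This mode deliberately violates the Markov model, as real
#    registries do.
# 2. simulate_panel_ctmc(): exact continuous-time Markov chain trajectories
#    under a given intensity model, recorded only at scheduled observation
#    days, for sharp parameter-recovery tests of the fitting engine.

#' Parameters of the mechanistic cohort simulator
#'
#' Defaults are the "registry-like" preset: 70% female, age at onset
#' 34.1 +/- 9.2 years, a relapse rate near 2/year at disease onset that fades
#' with age and disease duration (annualised pre-diagnosis relapse rate
#' around 1.7), treatment effects that reduce the relapse rate (moderate- and
#' high-efficacy), an SPMS-onset hazard increasing with age and EDSS
#' calibrated to roughly a third of patients converting over two decades, a
#' mean two-year diagnostic delay from latent SPMS onset to the recorded
#' diagnosis, and a low age-increasing death hazard.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param sex_p_female Probability of female sex.
#' @param age_at_onset `c(mean, sd)` of age at onset, years.
#' @param relapse_base_rate Relapse rate (events/year) at disease onset for
#'   an untreated male at the reference age (30 years).
#' @param relapse_age_loghr Per-year-of-age log rate slope.
#' @param relapse_duration_loghr Per-year-of-disease-duration log rate slope
#'   (relapse activity fades as disease advances).
#' @param relapse_sex_loghr Additive log rate for female sex.
#' @param relapse_treatment_loghr Named `c(high=, moderate=)` log rate while
#'   on treatment of each efficacy class.
#' @param relapse_post_spms_factor Multiplier on the relapse rate after
#'   latent SPMS onset (residual relapse activity; the registry literature
#'   gives no value, so this is a documented free knob).
#' @param spms_base_hazard Latent SPMS-onset hazard (/year) at reference age
#'   and EDSS 2.
#' @param spms_age_loghr,spms_edss_loghr Log-hazard slopes per year of age
#'   and per EDSS point.
#' @param spms_dx_delay_mean_years Mean of the exponential delay between
#'   latent SPMS onset and recorded diagnosis.
#' @param edss_visit_interval `c(mean, jitter)` days between EDSS visits.
#' @param edss_drift Expected EDSS increment per year during RRMS (doubled
#'   after latent SPMS onset).
#' @param death_base_hazard Death hazard (/year) at the reference age (60).
#' @param death_age_loghr Per-year-of-age log slope of the death hazard.
#' @param admin_horizon Administrative censoring, days after RRMS diagnosis.
#' @param onset_to_dx_mean_years Mean onset-to-diagnosis delay (exponential).
#' @return A validated `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 500, seed = 1,
                          sex_p_female = 0.70,
                          age_at_onset = c(34.1, 9.2),
                          relapse_base_rate = 2.0,
                          relapse_age_loghr = -0.01,
                          relapse_duration_loghr = -0.08,
                          relapse_sex_loghr = 0.1,
                          relapse_treatment_loghr = c(high = log(0.3),
                                                      moderate = log(0.6)),
                          relapse_post_spms_factor = 0.15,
                          spms_base_hazard = 0.005,
                          spms_age_loghr = 0.03,
                          spms_edss_loghr = 0.25,
                          spms_dx_delay_mean_years = 2,
                          edss_visit_interval = c(365, 120),
                          edss_drift = 0.18,
                          death_base_hazard = 0.004,
                          death_age_loghr = 0.09,
                          admin_horizon = 22 * 365,
                          onset_to_dx_mean_years = 2) {
  p <- as.list(environment())
  stopifnot(p$n_patients >= 1,
            p$sex_p_female >= 0, p$sex_p_female <= 1,
            p$relapse_base_rate >= 0, p$spms_base_hazard >= 0,
            p$death_base_hazard >= 0, p$relapse_post_spms_factor >= 0,
            p$admin_horizon > 0, p$edss_visit_interval[1] > 0)
  class(p) <- "cohort_params"
  p
}

# thinned inhomogeneous Poisson process on [0, t_end] (days) with piecewise
# log-linear rate given by rate_fn(day) (events/year); exact by thinning
# against a dominating constant rate.
sim_relapse_days <- function(rate_fn, t_end, rate_max) {
  if (rate_max <= 0 || t_end <= 0) return(integer(0))
  out <- integer(0)
  t <- 0
  repeat {
    t <- t + rexp(1, rate_max / DAYS_PER_YEAR)
    if (t > t_end) break
    if (runif(1) < rate_fn(t) / rate_max) out <- c(out, as.integer(floor(t)))
  }
  unique(out)
}

#' Simulate a registry-like cohort
#'
#' Generates the four registry tables (patients, relapses, EDSS, treatments)
#' from the mechanistic model described in [cohort_params()], together with
#' the latent ground truth. Output always satisfies the registry invariants
#' (it is re-validated through [ms_cohort()]).
#'
#' @param params A `cohort_params`.
#' @return An `ms_cohort` with an extra attribute `"truth"`: the parameters
#'   plus per-patient latent SPMS onset days.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_patients
  pat <- vector("list", n)
  rel <- vector("list", n)
  eds <- vector("list", n)
  trt <- vector("list", n)
  latent_spms <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    sex <- if (runif(1) < params$sex_p_female) "female" else "male"
    aao <- max(18, rnorm(1, params$age_at_onset[1], params$age_at_onset[2]))
    onset <- as.integer(round(runif(1, 0, 11 * DAYS_PER_YEAR)))
    dx <- onset + as.integer(ceiling(
      rexp(1, 1 / (params$onset_to_dx_mean_years * DAYS_PER_YEAR))))
    horizon <- dx + as.integer(params$admin_horizon)

    # treatment episodes: first start after diagnosis, alternating on/off
    t_cur <- dx + rexp(1, 1 / DAYS_PER_YEAR)
    ep_start <- integer(0); ep_stop <- integer(0); ep_drug <- character(0)
    while (t_cur < horizon) {
      dur <- rexp(1, 1 / (3 * DAYS_PER_YEAR))
      drug <- if (runif(1) < 0.35) {
        sample(HIGH_EFFICACY_DMTS, 1)
      } else if (runif(1) < 0.95) {
        sample(c(MODERATE_EFFICACY_DMTS, "interferon beta-1a",
                 "peginterferon"), 1)
      } else {
        "unclassified supplement"     # registries contain non-DMT entries
      }
      s <- as.integer(ceiling(t_cur))
      e <- as.integer(floor(min(t_cur + dur, horizon)))
      if (e > s) {
        ep_start <- c(ep_start, s); ep_stop <- c(ep_stop, e)
        ep_drug <- c(ep_drug, drug)
      }
      t_cur <- t_cur + dur + rexp(1, 1 / DAYS_PER_YEAR)
    }
    ep_class <- classify_dmt(ep_drug)
    on_class <- function(day) {
      k <- which(ep_start <= day & day < ep_stop)
      if (!length(k)) return("none")
      cls <- ep_class[k]
      if ("high" %in% cls) "high" else if ("moderate" %in% cls) "moderate"
      else "none"
    }

    # latent EDSS path + latent SPMS onset + death, stepped monthly
    step <- 30
    day <- onset
    edss_lat <- 1.5 + rgamma(1, 2, 4)
    spms_lat <- NA_integer_
    death_day <- NA_integer_
    edss_days <- integer(0); edss_vals <- numeric(0)
    next_visit <- dx + as.integer(round(runif(1, 0,
                                              params$edss_visit_interval[1])))
    while (day < horizon) {
      age <- aao + (day - onset) / DAYS_PER_YEAR
      dt_yr <- step / DAYS_PER_YEAR
      drift <- params$edss_drift * (if (is.na(spms_lat)) 1 else 2)
      edss_lat <- min(10, edss_lat + rgamma(1, shape = drift * dt_yr * 4,
                                            rate = 4))
      if (is.na(spms_lat)) {
        h_spms <- params$spms_base_hazard *
          exp(params$spms_age_loghr * (age - 30) +
                params$spms_edss_loghr * (edss_lat - 2))
        if (runif(1) < 1 - exp(-h_spms * dt_yr)) spms_lat <- day
      }
      h_death <- params$death_base_hazard *
        exp(params$death_age_loghr * (age - 60))
      if (runif(1) < 1 - exp(-h_death * dt_yr)) {
        death_day <- day
        break
      }
      if (day >= next_visit) {
        obs <- min(10, max(0, round(edss_lat * 2) / 2))
        edss_days <- c(edss_days, day)
        edss_vals <- c(edss_vals, obs)
        next_visit <- day + as.integer(round(
          params$edss_visit_interval[1] +
            runif(1, -1, 1) * params$edss_visit_interval[2]))
      }
      day <- day + step
    }

    end_day <- if (!is.na(death_day)) death_day else horizon
    end_reason <- if (!is.na(death_day)) "death" else "admin_censor"
    if (end_day <= dx) { end_day <- dx + 1L; end_reason <- "admin_censor" }

    # recorded SPMS diagnosis: latent onset + diagnostic delay
    spms_dx <- NA_integer_
    if (!is.na(spms_lat)) {
      cand <- spms_lat + as.integer(ceiling(
        rexp(1, 1 / max(params$spms_dx_delay_mean_years * DAYS_PER_YEAR,
                        1e-9))))
      if (cand <= end_day) spms_dx <- max(cand, dx)
    }

    # relapses: from onset; suppressed after latent SPMS onset
    rate_fn <- function(d) {
      age <- aao + d / DAYS_PER_YEAR   # d measured from onset
      abs_day <- onset + d
      r <- params$relapse_base_rate *
        exp(params$relapse_age_loghr * (age - 30) +
              params$relapse_duration_loghr * d / DAYS_PER_YEAR +
              params$relapse_sex_loghr * (sex == "female"))
      cls <- on_class(abs_day)
      if (cls != "none") r <- r * exp(params$relapse_treatment_loghr[[cls]])
      if (!is.na(spms_lat) && abs_day >= spms_lat) {
        r <- r * params$relapse_post_spms_factor
      }
      r
    }
    # dominating constant rate for thinning (valid for either slope sign)
    rate_max <- params$relapse_base_rate *
      exp(abs(params$relapse_age_loghr) * abs(aao - 30) +
            max(0, params$relapse_age_loghr) * 70 +
            max(0, params$relapse_duration_loghr) * 70 +
            max(0, params$relapse_sex_loghr) +
            max(0, max(params$relapse_treatment_loghr))) *
      max(1, params$relapse_post_spms_factor) + 1e-12
    rdays <- onset + sim_relapse_days(rate_fn, end_day - onset, rate_max)
    rdays <- rdays[rdays <= end_day]

    pat[[i]] <- data.frame(patient_id = pid, sex = sex, onset_day = onset,
                           rrms_dx_day = dx, spms_dx_day = spms_dx,
                           end_day = as.integer(end_day),
                           end_reason = end_reason, age_at_onset = aao,
                           stringsAsFactors = FALSE)
    if (length(rdays)) {
      rel[[i]] <- data.frame(patient_id = pid, relapse_day = rdays,
                             stringsAsFactors = FALSE)
    }
    keep <- edss_days <= end_day
    if (any(keep)) {
      eds[[i]] <- data.frame(patient_id = pid, obs_day = edss_days[keep],
                             edss = edss_vals[keep], stringsAsFactors = FALSE)
    }
    keep <- ep_start < end_day
    if (any(keep)) {
      trt[[i]] <- data.frame(patient_id = pid, drug_name = ep_drug[keep],
                             start_day = ep_start[keep],
                             stop_day = pmin(ep_stop[keep],
                                             as.integer(end_day)),
                             stringsAsFactors = FALSE)
    }
    latent_spms[i] <- if (is.na(spms_lat)) NA_integer_ else
      as.integer(spms_lat)
  }

  cohort <- ms_cohort(do.call(rbind, pat), do.call(rbind, rel),
                      do.call(rbind, eds), do.call(rbind, trt))
  attr(cohort, "truth") <- list(params = params,
                                latent_spms_day = setNames(
                                  latent_spms,
                                  vapply(pat, function(d) d$patient_id,
                                         character(1))))
  cohort
}

#' Simulate exact CTMC trajectories observed as panel data
#'
#' Draws continuous-time Markov chain paths under an intensity model, segment
#' by segment along each patient's piecewise-constant covariate path using
#' competing exponential clocks, then records the state only at the given
#' observation times (panel censoring). Entry into the absorbing death state
#' is recorded exactly, as in registry data.
#'
#' @param model An `msm_model` with the true parameters.
#' @param covariate_fn Function of the patient index returning that patient's
#'   covariate path: a data frame with a `time` column (years, starting at 0)
#'   and one column per model covariate. Ignored if the model has no
#'   covariates.
#' @param n Number of patients.
#' @param schedule Numeric vector of observation times in years (from 0), or
#'   a function of the patient index returning one.
#' @param seed Optional integer seed.
#' @param initial_state State label (or index) at time 0; must not be
#'   absorbing.
#' @return A panel data frame (`patient_id`, `obs_day`, `state`, `state_num`,
#'   `obs_type`, covariate columns) ready for [fit_msm()], with the true
#'   model attached as attribute `"truth"`.
#' @export
simulate_panel_ctmc <- function(model, covariate_fn = NULL, n = 100,
                                schedule = 0:10, seed = NULL,
                                initial_state = 1) {
  stopifnot(inherits(model, "msm_model"))
  st <- model$structure
  if (is.character(initial_state)) {
    initial_state <- match(initial_state, st$states)
  }
  if (st$states[initial_state] %in% st$absorbing) {
    stop("initial state is absorbing", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  covnames <- model_covnames(model)
  absorbing_idx <- match(st$absorbing, st$states)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- if (is.function(schedule)) schedule(i) else schedule
    sched <- sort(unique(as.numeric(sched)))
    t_end <- max(sched)
    path <- if (length(covnames)) {
      covariate_fn(i)
    } else {
      data.frame(time = 0)
    }
    path <- path[order(path$time), , drop = FALSE]
    stopifnot(path$time[1] <= 0)
    seg_start <- path$time
    seg_end <- c(path$time[-1], Inf)

    # exact trajectory: jump times and states
    jump_t <- 0
    jump_s <- initial_state
    cur_s <- initial_state
    cur_t <- 0
    seg <- max(findInterval(0, seg_start), 1L)
    death_t <- NA_real_
    while (cur_t < t_end && !(cur_s %in% absorbing_idx)) {
      z <- if (length(covnames)) {
        unlist(path[seg, covnames, drop = FALSE])
      } else NULL
      Q <- intensity_matrix(model, z)
      rates <- Q[cur_s, ]
      rates[cur_s] <- 0
      tot <- sum(rates)
      boundary <- min(seg_end[seg], t_end)
      if (tot <= 0) {
        cur_t <- boundary
      } else {
        w <- rexp(1, tot)
        if (cur_t + w < boundary) {
          cur_t <- cur_t + w
          cur_s <- sample.int(length(rates), 1, prob = rates)
          jump_t <- c(jump_t, cur_t)
          jump_s <- c(jump_s, cur_s)
          if (cur_s %in% absorbing_idx) death_t <- cur_t
        } else {
          cur_t <- boundary
        }
      }
      if (cur_t >= seg_end[seg] && seg < nrow(path)) seg <- seg + 1L
    }

    obs_t <- sched
    if (!is.na(death_t)) obs_t <- c(obs_t[obs_t < death_t], death_t)
    if (!length(obs_t)) obs_t <- death_t
    state_idx <- jump_s[findInterval(obs_t, jump_t)]
    obs_type <- rep("panel", length(obs_t))
    if (!is.na(death_t)) obs_type[length(obs_t)] <- "exact_death"
    zmat <- if (length(covnames)) {
      path[pmax(findInterval(obs_t, seg_start), 1L), covnames,
           drop = FALSE]
    } else NULL
    df <- data.frame(patient_id = sprintf("S%05d", i),
                     obs_day = round(obs_t * DAYS_PER_YEAR),
                     state = st$states[state_idx],
                     state_num = state_idx,
                     obs_type = obs_type, stringsAsFactors = FALSE)
    if (!is.null(zmat)) df <- cbind(df, zmat)
    # day rounding can land an exact death on the preceding visit day;
    # drop the visit record in that case
    nr <- nrow(df)
    if (nr > 1 && df$obs_day[nr] == df$obs_day[nr - 1]) {
      df <- df[-(nr - 1), , drop = FALSE]
    }
    out[[i]] <- df
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  attr(panel, "truth") <- model
  panel
}
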