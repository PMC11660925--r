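# Non-Markov estimators: Aalen-Johansen cumulative incidence under competing
# risks, Kaplan-Meier, Cox proportional hazards for EDSS milestones, and
# Poisson rates with robust (sandwich) variance. Standard machinery is
# delegated to the survival package (counting-process survfit/coxph); the
# functions here define the event-record interface and the registry-specific
# analyses built on it.

#' Event records for time-to-event analyses
#'
#' Validates a data frame of (possibly late-entry) event records: columns
#' `entry_time`, `exit_time` (years, `entry_time < exit_time`) and `event`
#' (a character/factor; `"censored"` means no event), plus arbitrary
#' covariate columns. Ties between an event and a censoring at the same time
#' are resolved events-first by the counting-process estimators.
#'
#' @param records Data frame as above; `entry_time` defaults to 0 if absent.
#' @return The validated data frame (invisibly classed `event_records`).
#' @export
event_records <- function(records) {
  records <- as.data.frame(records)
  if (!"entry_time" %in% names(records)) records$entry_time <- 0
  stopifnot(all(c("exit_time", "event") %in% names(records)))
  records$event <- as.character(records$event)
  if (any(records$entry_time >= records$exit_time)) {
    stop("entry_time must be strictly before exit_time", call. = FALSE)
  }
  class(records) <- c("event_records", "data.frame")
  records
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Nonparametric cumulative incidence functions for each competing event
#' type, adjusted for the other types: at each event time the cause-specific
#' incidence increments by the left-limit overall survival times the
#' cause-specific hazard. Late entry is supported through risk-set counting.
#' Implemented via the counting-process multi-state estimator of
#' `survival::survfit`.
#'
#' @param records An [event_records()] data frame with at least one
#'   non-censoring event type.
#' @return A `cif_estimate`: list with `times`, `surv` (overall event-free
#'   probability), `cif` (matrix, one column per event type), `at_risk`.
#'   At every time `surv + rowSums(cif) = 1`.
#' @export
aalen_johansen <- function(records) {
  records <- event_records(records)
  if (!nrow(records)) stop("no records", call. = FALSE)
  types <- sort(setdiff(unique(records$event), "censored"))
  if (!length(types)) {
    tmax <- max(records$exit_time)
    return(structure(list(times = tmax, surv = 1,
                          cif = matrix(0, 1, 0,
                                       dimnames = list(NULL, character(0))),
                          at_risk = nrow(records), types = character(0)),
                     class = "cif_estimate"))
  }
  ev <- factor(records$event, levels = c("censored", types))
  fit <- survival::survfit(
    survival::Surv(records$entry_time, records$exit_time, ev) ~ 1,
    id = seq_len(nrow(records)))
  ps <- fit$pstate
  colnames(ps) <- fit$states
  s0 <- which(fit$states == "(s0)")
  structure(list(times = fit$time, surv = ps[, s0],
                 cif = ps[, types, drop = FALSE],
                 at_risk = fit$n.risk[, s0], types = types),
            class = "cif_estimate")
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat("Aalen-Johansen cumulative incidence,", length(x$types),
      "competing event type(s)\n")
  df <- data.frame(time = x$times, surv = x$surv)
  for (tp in x$types) df[[paste0("CIF_", tp)]] <- x$cif[, tp]
  print(head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("...", nrow(df) - 10, "more rows\n")
  invisible(x)
}

#' Evaluate a CIF estimate at given times
#'
#' @param x A `cif_estimate`.
#' @param times Times at which to read off the right-continuous step
#'   functions.
#' @param type Event type (column of `x$cif`); if `NULL`, overall survival.
#' @return Numeric vector.
#' @export
cif_at <- function(x, times, type = NULL) {
  idx <- findInterval(times, x$times)
  vals <- if (is.null(type)) c(1, x$surv) else c(0, x$cif[, type])
  vals[idx + 1L]
}

#' @export
plot.cif_estimate <- function(x, ...) {
  stacked <- t(apply(x$cif, 1, cumsum))
  graphics::matplot(x$times, cbind(stacked, 1 - x$surv + 0), type = "s",
                    lty = 1, xlab = "Time (years)",
                    ylab = "Cumulative probability", ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = x$types, lty = 1,
                   col = seq_along(x$types), bty = "n")
  invisible(x)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator for a single event type, with late entry. The
#' failure curve of the corresponding time-to-event outcome is
#' `1 - surv`.
#'
#' @param records An [event_records()] data frame whose `event` column has at
#'   most one non-censoring value.
#' @return List `times`, `surv`, `at_risk`, classed `km_estimate`.
#' @export
kaplan_meier <- function(records) {
  records <- event_records(records)
  types <- setdiff(unique(records$event), "censored")
  if (length(types) > 1) {
    stop("kaplan_meier expects a single event type; got: ",
         paste(types, collapse = ", "), call. = FALSE)
  }
  status <- as.integer(records$event != "censored")
  fit <- survival::survfit(
    survival::Surv(records$entry_time, records$exit_time, status) ~ 1)
  structure(list(times = fit$time, surv = fit$surv, at_risk = fit$n.risk),
            class = "km_estimate")
}

#' Cox proportional hazards regression
#'
#' Breslow-tie partial-likelihood Cox model over the given covariates, with
#' late entry. Zero-variance covariates carry no information and are
#' reported with coefficient 0 and a warning; monotone-likelihood
#' (separation) warnings from the underlying Newton iteration are propagated.
#'
#' @param records An [event_records()] data frame (single event type).
#' @param covariates Character vector of covariate column names.
#' @return List with `coefficients`, `se`, `hr` table (`term`, `hr`,
#'   `lower`, `upper`), `loglik`, and the underlying `coxph` fit; classed
#'   `coxph_fit`.
#' @export
cox_ph <- function(records, covariates) {
  records <- event_records(records)
  status <- as.integer(records$event != "censored")
  if (!any(status == 1)) stop("no events", call. = FALSE)
  constant <- vapply(covariates, function(v) {
    x <- records[[v]]
    if (is.character(x) || is.factor(x)) {
      length(unique(x)) < 2
    } else {
      sd(as.numeric(x)) == 0 || !is.finite(sd(as.numeric(x)))
    }
  }, logical(1))
  if (any(constant)) {
    warning("covariate(s) constant across subjects carry no information: ",
            paste(covariates[constant], collapse = ", "), call. = FALSE)
  }
  active <- covariates[!constant]
  cf <- setNames(rep(0, length(covariates)), covariates)
  se <- setNames(rep(NA_real_, length(covariates)), covariates)
  ll <- NA_real_
  cox <- NULL
  if (length(active)) {
    df <- records
    df$.status <- status
    fml <- as.formula(paste("survival::Surv(entry_time, exit_time, .status) ~",
                            paste(active, collapse = " + ")))
    cox <- survival::coxph(fml, data = df, ties = "breslow")
    cc <- coef(cox)
    cf[names(cc)] <- cc
    se[names(cc)] <- sqrt(diag(vcov(cox)))
    ll <- cox$loglik[length(cox$loglik)]
    # match terms back to covariate names for factor covariates
    for (v in active) {
      if (!v %in% names(cc)) {
        hit <- grep(paste0("^", v), names(cc))
        if (length(hit) == 1) {
          cf[v] <- cc[hit]
          se[v] <- sqrt(diag(vcov(cox)))[hit]
        }
      }
    }
  }
  hr <- data.frame(term = covariates, hr = exp(cf),
                   lower = exp(cf - WALD_Z * se),
                   upper = exp(cf + WALD_Z * se), row.names = NULL)
  structure(list(coefficients = cf, se = se, hr = hr, loglik = ll,
                 coxph = cox), class = "coxph_fit")
}

#' @export
print.coxph_fit <- function(x, ...) {
  hr <- x$hr
  hr$`HR (95% CI)` <- fmt_est_ci(hr$hr, hr$lower, hr$upper, digits = 3)
  print(hr[, c("term", "HR (95% CI)")], row.names = FALSE)
  invisible(x)
}

#' Poisson event rates with robust variance
#'
#' Log-link Poisson regression of event counts with the log of exposure time
#' as an offset, standard errors from the sandwich (robust) variance.
#' With no covariates the fitted rate is exactly total events over total
#' person-years.
#'
#' @param counts Integer vector of event counts per subject.
#' @param exposure_years Positive exposures (person-years).
#' @param covariates Optional data frame of covariates (same rows).
#' @return List with `rate` (intercept-scale rate and robust 95% CI),
#'   `coefficients` table (term, estimate = rate or rate ratio, lower,
#'   upper), and the underlying `glm`; classed `poisson_rate`.
#' @export
poisson_arr <- function(counts, exposure_years, covariates = NULL) {
  if (any(exposure_years <= 0) || sum(exposure_years) <= 0) {
    stop("exposures must be positive", call. = FALSE)
  }
  df <- data.frame(.y = counts, .off = log(exposure_years))
  terms <- "1"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    terms <- names(covariates)
  }
  fml <- as.formula(paste(".y ~", paste(terms, collapse = " + "),
                          "+ offset(.off)"))
  fit <- glm(fml, family = poisson(), data = df)
  vc <- sandwich::vcovHC(fit, type = "HC0")
  b <- coef(fit)
  se <- sqrt(diag(vc))
  tab <- data.frame(term = names(b), estimate = exp(b),
                    lower = exp(b - WALD_Z * se),
                    upper = exp(b + WALD_Z * se), row.names = NULL)
  rate <- tab[tab$term == "(Intercept)", c("estimate", "lower", "upper")]
  structure(list(rate = unlist(rate), coefficients = tab, glm = fit,
                 vcov_robust = vc), class = "poisson_rate")
}

#' @export
print.poisson_rate <- function(x, ...) {
  cat("Poisson rate model (robust variance)\n")
  cat("  rate:", fmt_est_ci(x$rate[1], x$rate[2], x$rate[3], digits = 3),
      "per person-year\n")
  if (nrow(x$coefficients) > 1) {
    tab <- x$coefficients[-1, ]
    tab$`ratio (95% CI)` <- fmt_est_ci(tab$estimate, tab$lower, tab$upper,
                                       digits = 3)
    print(tab[, c("term", "ratio (95% CI)")], row.names = FALSE)
  }
  invisible(x)
}

# ---- registry-specific analyses built on the estimators ------------------

#' Annualised relapse rate before RRMS diagnosis
#'
#' Counts relapses in the two years before each patient's RRMS diagnosis
#' (truncated at onset for patients diagnosed within two years of onset) and
#' fits an intercept-only robust-variance Poisson model, per subgroup if
#' `group` is given.
#'
#' @param cohort An `ms_cohort`.
#' @param group Optional named character vector `patient_id -> group label`.
#' @return Data frame `group`, `n`, `arr`, `lower`, `upper`.
#' @export
arr_before_diagnosis <- function(cohort, group = NULL) {
  p <- cohort$patients
  win_start <- pmax(p$onset_day, p$rrms_dx_day - RELAPSE_WINDOW_DAYS)
  expo <- pmax(p$rrms_dx_day - win_start, 1L) / DAYS_PER_YEAR
  cnt <- integer(nrow(p))
  rel <- split(cohort$relapses$relapse_day, cohort$relapses$patient_id)
  for (i in seq_len(nrow(p))) {
    r <- rel[[p$patient_id[i]]]
    if (!is.null(r)) {
      cnt[i] <- sum(r > win_start[i] & r <= p$rrms_dx_day[i])
    }
  }
  g <- if (is.null(group)) rep("all", nrow(p)) else
    unname(group[p$patient_id])
  out <- lapply(split(seq_len(nrow(p)), g), function(idx) {
    pr <- poisson_arr(cnt[idx], expo[idx])
    data.frame(group = g[idx][1], n = length(idx), arr = pr$rate[1],
               lower = pr$rate[2], upper = pr$rate[3])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cox milestone analysis of EDSS landmarks
#'
#' For SPMS patients classified as relapsing or non-relapsing at SPMS
#' diagnosis, compares the rate of reaching EDSS milestones (first recorded
#' score at or above the threshold, unconfirmed) during the
#' relapsing-remitting phase. Follow-up runs from onset of disease until the
#' milestone or censoring at SPMS diagnosis; the model adjusts for age at
#' onset and sex.
#'
#' @param cohort An `ms_cohort`.
#' @param thresholds EDSS thresholds (default 3, 4, 6).
#' @param window Classification window (days) for the SPMS subgroup labels.
#' @return Named list (one per threshold) of `coxph_fit`s; each records the
#'   milestone events analysed in attribute `"n_events"`.
#' @export
edss_milestones <- function(cohort, thresholds = c(3, 4, 6),
                            window = RELAPSE_WINDOW_DAYS) {
  p <- cohort$patients
  spms <- p[!is.na(p$spms_dx_day), , drop = FALSE]
  if (!nrow(spms)) stop("no SPMS patients in cohort", call. = FALSE)
  rel <- split(cohort$relapses$relapse_day, cohort$relapses$patient_id)
  grp <- vapply(seq_len(nrow(spms)), function(i) {
    state_at(spms[i, ], rel[[spms$patient_id[i]]] %||% integer(0),
             spms$spms_dx_day[i], window)
  }, character(1))
  edss <- split(cohort$edss, cohort$edss$patient_id)
  out <- list()
  for (thr in thresholds) {
    recs <- lapply(seq_len(nrow(spms)), function(i) {
      pid <- spms$patient_id[i]
      e <- edss[[pid]]
      hit_day <- NA_integer_
      if (!is.null(e)) {
        h <- e$obs_day[e$edss >= thr & e$obs_day <= spms$spms_dx_day[i]]
        if (length(h)) hit_day <- min(h)
      }
      exit_day <- if (!is.na(hit_day)) hit_day else spms$spms_dx_day[i]
      exit_t <- (exit_day - spms$onset_day[i]) / DAYS_PER_YEAR
      if (exit_t <= 0) exit_t <- 0.5 / DAYS_PER_YEAR
      data.frame(patient_id = pid, entry_time = 0, exit_time = exit_t,
                 event = if (!is.na(hit_day)) "milestone" else "censored",
                 rspms = as.numeric(grp[i] == "rSPMS"),
                 age_at_onset = spms$age_at_onset[i],
                 sex_female = as.numeric(spms$sex[i] == "female"),
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    fit <- cox_ph(recs, c("rspms", "age_at_onset", "sex_female"))
    attr(fit, "n_events") <- sum(recs$event == "milestone")
    out[[paste0("EDSS", thr)]] <- fit
  }
  out
}

#' Per-age-year relapse counts during the relapsing-remitting phase
#'
#' Builds the age-binned count table for the relapse-trajectory GEE: for
#' every (integer) year of age within a patient's relapsing-remitting phase,
#' the number of relapses and the exposure time in that year of age. The
#' relapsing-remitting phase runs from disease onset to the end of follow-up
#' for patients who remain RRMS, and to two years before the SPMS diagnosis
#' for SPMS patients (so the relapses that define the SPMS subgroup labels
#' are excluded).
#'
#' @param cohort An `ms_cohort` whose patients table has `age_at_onset`.
#' @param window Classification window (days).
#' @return Data frame `patient_id`, `group` (`RRMS`/`nrSPMS`/`rSPMS` at SPMS
#'   diagnosis), `sex_female`, `age` (integer year of age), `count`,
#'   `exposure_years`.
#' @export
relapse_age_table <- function(cohort, window = RELAPSE_WINDOW_DAYS) {
  p <- cohort$patients
  if (anyNA(p$age_at_onset)) {
    stop("age_at_onset required for the relapse-age table", call. = FALSE)
  }
  rel <- split(cohort$relapses$relapse_day, cohort$relapses$patient_id)
  rows <- list()
  for (i in seq_len(nrow(p))) {
    pid <- p$patient_id[i]
    has_spms <- !is.na(p$spms_dx_day[i])
    phase_end <- if (has_spms) p$spms_dx_day[i] - window else p$end_day[i]
    if (phase_end <= p$onset_day[i]) next
    grp <- if (!has_spms) "RRMS" else {
      state_at(p[i, ], rel[[pid]] %||% integer(0), p$spms_dx_day[i], window)
    }
    r <- rel[[pid]] %||% integer(0)
    r <- r[r >= p$onset_day[i] & r <= phase_end]
    age_start <- p$age_at_onset[i]
    age_end <- age_start + (phase_end - p$onset_day[i]) / DAYS_PER_YEAR
    for (a in seq(floor(age_start), floor(age_end))) {
      lo <- max(age_start, a)
      hi <- min(age_end, a + 1)
      if (hi <= lo) next
      day_lo <- p$onset_day[i] + (lo - age_start) * DAYS_PER_YEAR
      day_hi <- p$onset_day[i] + (hi - age_start) * DAYS_PER_YEAR
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, group = grp,
        sex_female = as.numeric(p$sex[i] == "female"),
        age = a, count = sum(r >= day_lo & r < day_hi),
        exposure_years = hi - lo, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
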