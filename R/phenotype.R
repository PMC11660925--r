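# Day-resolution phenotype classification. After an SPMS diagnosis a day t is
# rSPMS when at least one relapse falls in the half-open retrospective window
# (t - W, t] with W = 730 days, i.e. a relapse at day r makes days
# [r, r + W - 1] relapsing; otherwise the day is nrSPMS. Before the SPMS
# diagnosis every day is RRMS. Relapses recorded before the SPMS diagnosis
# (including before RRMS diagnosis) count toward the window.

RELAPSE_WINDOW_DAYS <- 730L

#' Phenotype state on a given day of follow-up
#'
#' Applies the daily classification rule directly: `RRMS` while no SPMS
#' diagnosis is in effect, otherwise `rSPMS` if the patient had at least one
#' relapse in the 730-day half-open window `(t - 730, t]` and `nrSPMS` if not.
#' A relapse on day `t` itself counts; the first non-relapsing day after an
#' isolated relapse at day `r` is therefore `r + 730`.
#'
#' @param patient A single-row data frame (or list) with `rrms_dx_day`,
#'   `spms_dx_day` and `end_day`.
#' @param relapse_days Integer vector of the patient's relapse days.
#' @param t Integer day(s) within `[rrms_dx_day, end_day]`.
#' @param window Retrospective window length in days (default 730, two years).
#' @return Character vector over `t` in `c("RRMS", "nrSPMS", "rSPMS")`.
#' @export
state_at <- function(patient, relapse_days, t, window = RELAPSE_WINDOW_DAYS) {
  t <- as.integer(t)
  if (any(t < patient$rrms_dx_day | t > patient$end_day)) {
    stop("assessment day outside follow-up for patient ",
         patient$patient_id %||% "?", call. = FALSE)
  }
  spms <- patient$spms_dx_day
  if (length(spms) == 0 || is.na(spms)) return(rep("RRMS", length(t)))
  relapse_days <- as.integer(relapse_days)
  out <- ifelse(t < spms, "RRMS", "nrSPMS")
  if (length(relapse_days)) {
    in_spms <- t >= spms
    if (any(in_spms)) {
      hit <- vapply(t[in_spms], function(tt) {
        any(relapse_days > tt - window & relapse_days <= tt)
      }, logical(1))
      out[in_spms][hit] <- "rSPMS"
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition follow-up into phenotype-state intervals
#'
#' Event-driven equivalent of evaluating [state_at()] at every day of
#' follow-up: each relapse at day `r` covers days `[r, r + 729]` as relapsing
#' SPMS, so the rSPMS days after diagnosis are the union of those ranges and
#' the complement is nrSPMS. Runs in O(number of relapses), independent of
#' follow-up length. Interval bounds are inclusive.
#'
#' @inheritParams state_at
#' @return A `state_timeline`: list with `patient_id`, `intervals` (data frame
#'   `state`, `start_day`, `end_day`) and `death_day` (`NA` unless the
#'   patient's `end_reason` is `"death"`).
#' @examples
#' p <- data.frame(patient_id = "fig", rrms_dx_day = 0, spms_dx_day = 0,
#'                 end_day = 6721, end_reason = "admin_censor")
#' classify_timeline(p, c(-100, 6547))
#' @export
classify_timeline <- function(patient, relapse_days,
                              window = RELAPSE_WINDOW_DAYS) {
  dx <- as.integer(patient$rrms_dx_day)
  end <- as.integer(patient$end_day)
  spms <- patient$spms_dx_day
  spms <- if (length(spms) == 0 || is.na(spms)) NA_integer_ else
    as.integer(spms)
  stopifnot(dx <= end)

  iv <- data.frame(state = character(0), start_day = integer(0),
                   end_day = integer(0), stringsAsFactors = FALSE)
  add <- function(iv, state, s, e) {
    if (s > e) return(iv)
    rbind(iv, data.frame(state = state, start_day = s, end_day = e,
                         stringsAsFactors = FALSE))
  }

  if (is.na(spms)) {
    iv <- add(iv, "RRMS", dx, end)
  } else {
    iv <- add(iv, "RRMS", dx, spms - 1L)
    r <- sort(as.integer(relapse_days))
    r <- r[r <= end]
    # relapsing cover: union of [r, r+window-1], clipped to [spms, end]
    cov_s <- integer(0); cov_e <- integer(0)
    for (ri in r) {
      s <- max(ri, spms); e <- min(ri + window - 1L, end)
      if (s > e) next
      if (length(cov_s) && s <= cov_e[length(cov_e)] + 1L) {
        cov_e[length(cov_e)] <- max(cov_e[length(cov_e)], e)
      } else {
        cov_s <- c(cov_s, s); cov_e <- c(cov_e, e)
      }
    }
    cur <- spms
    k <- 1L
    while (cur <= end) {
      if (k <= length(cov_s) && cov_s[k] == cur) {
        iv <- add(iv, "rSPMS", cov_s[k], cov_e[k])
        cur <- cov_e[k] + 1L
        k <- k + 1L
      } else {
        nxt <- if (k <= length(cov_s)) cov_s[k] - 1L else end
        iv <- add(iv, "nrSPMS", cur, nxt)
        cur <- nxt + 1L
      }
    }
  }
  rownames(iv) <- NULL
  death_day <- if (identical(patient$end_reason, "death")) end else NA_integer_
  structure(list(patient_id = as.character(patient$patient_id %||% ""),
                 intervals = iv, death_day = death_day),
            class = "state_timeline")
}

#' @export
print.state_timeline <- function(x, ...) {
  cat("State timeline for patient", x$patient_id, "\n")
  print(x$intervals, row.names = FALSE)
  if (!is.na(x$death_day)) cat("Death at day", x$death_day, "\n")
  invisible(x)
}

#' Lookup the state of a timeline at given days
#'
#' @param timeline A `state_timeline`.
#' @param t Integer day(s) within the timeline's span.
#' @return Character state vector.
#' @export
timeline_state_at <- function(timeline, t) {
  iv <- timeline$intervals
  idx <- findInterval(as.integer(t), iv$start_day)
  if (any(idx < 1) || any(t > iv$end_day[nrow(iv)])) {
    stop("day outside timeline span", call. = FALSE)
  }
  iv$state[idx]
}

#' Sequence of SPMS-phase labels of a timeline
#'
#' Concatenates the labels of the SPMS-phase intervals (rSPMS/nrSPMS) in
#' order, e.g. `"rSPMS→nrSPMS→rSPMS"`. Used to tabulate transition
#' patterns over a cohort of SPMS patients.
#'
#' @param timeline A `state_timeline` containing at least one SPMS interval.
#' @return A single string; adjacent labels always differ.
#' @export
transition_pattern <- function(timeline) {
  lab <- timeline$intervals$state
  lab <- lab[lab != "RRMS"]
  if (!length(lab)) stop("no SPMS phase in timeline", call. = FALSE)
  paste(lab, collapse = "→")
}

#' Tabulate SPMS transition patterns over a cohort
#'
#' @param timelines List of `state_timeline`s.
#' @return Data frame `pattern`, `n`, sorted by decreasing frequency.
#' @export
pattern_table <- function(timelines) {
  has_spms <- vapply(timelines, function(tl) {
    any(tl$intervals$state != "RRMS")
  }, logical(1))
  pats <- vapply(timelines[has_spms], transition_pattern, character(1))
  if (!length(pats)) {
    return(data.frame(pattern = character(0), n = integer(0)))
  }
  tab <- sort(table(pats), decreasing = TRUE)
  data.frame(pattern = names(tab), n = as.integer(tab), row.names = NULL)
}

#' Build panel observations for the multi-state model
#'
#' Evaluates the phenotype state and the model covariates at each scheduled
#' observation day of one patient. Covariates: `sex_female` indicator, `age`
#' in years (anchored to age at onset), cumulative years on high- and
#' moderate-efficacy DMT (`hedmt_years`, `medmt_years`), `edss` carried
#' forward from the most recent observation (with a 365-day look-ahead
#' fallback before the first visit), `dx_year` (calendar year of RRMS
#' diagnosis, in years since the day-0 epoch), `cum_relapses` (relapses since
#' RRMS diagnosis, exclusive of pre-diagnosis relapses), and
#' `disease_duration` at RRMS diagnosis in years. If the patient died, a
#' final exactly-observed death record is appended at `end_day`.
#'
#' @param patient Single-row patient data frame (needs `age_at_onset`).
#' @param relapse_days Integer vector of relapse days.
#' @param edss Data frame `obs_day`, `edss` for this patient (may be empty).
#' @param episodes Treatment episodes for this patient (may be `NULL`).
#' @param schedule Integer days within follow-up at which the state is
#'   observed; deduplicated and sorted internally.
#' @param window Classification window in days.
#' @return Data frame of panel observations (`patient_id`, `obs_day`,
#'   `state`, `state_num`, `obs_type`, covariate columns). If EDSS could not
#'   be imputed at some day, the attribute `"missing_edss"` is `TRUE`.
#' @export
build_panel <- function(patient, relapse_days, edss = NULL, episodes = NULL,
                        schedule, window = RELAPSE_WINDOW_DAYS) {
  schedule <- sort(unique(as.integer(schedule)))
  if (!length(schedule)) stop("empty observation schedule", call. = FALSE)
  if (any(schedule < patient$rrms_dx_day | schedule > patient$end_day)) {
    stop("schedule outside follow-up for patient ", patient$patient_id,
         call. = FALSE)
  }
  tl <- classify_timeline(patient, relapse_days, window)
  st <- timeline_state_at(tl, schedule)

  dx <- as.integer(patient$rrms_dx_day)
  onset <- as.integer(patient$onset_day)
  aao <- patient$age_at_onset
  age <- if (is.null(aao) || is.na(aao)) rep(NA_real_, length(schedule)) else
    aao + (schedule - onset) / DAYS_PER_YEAR

  edss_at <- rep(NA_real_, length(schedule))
  if (!is.null(edss) && nrow(edss)) {
    eo <- edss[order(edss$obs_day), , drop = FALSE]
    idx <- findInterval(schedule, eo$obs_day)
    has_prior <- idx >= 1
    edss_at[has_prior] <- eo$edss[idx[has_prior]]
    # look-ahead fallback: first later score within 365 days
    for (i in which(!has_prior)) {
      nxt <- which(eo$obs_day > schedule[i] &
                     eo$obs_day <= schedule[i] + 365L)
      if (length(nxt)) edss_at[i] <- eo$edss[nxt[1]]
    }
  }

  hed <- cumulative_exposure(episodes, schedule, "high")
  med <- cumulative_exposure(episodes, schedule, "moderate")
  post_dx_relapses <- sort(relapse_days[relapse_days > dx])
  cumrel <- findInterval(schedule, post_dx_relapses)

  out <- data.frame(
    patient_id = as.character(patient$patient_id),
    obs_day = schedule,
    state = st,
    state_num = match(st, PHENOTYPE_STATES),
    obs_type = "panel",
    sex_female = as.numeric(patient$sex == "female"),
    age = age,
    hedmt_years = hed,
    medmt_years = med,
    edss = edss_at,
    dx_year = dx / DAYS_PER_YEAR,
    cum_relapses = as.numeric(cumrel),
    disease_duration = (dx - onset) / DAYS_PER_YEAR,
    stringsAsFactors = FALSE
  )

  if (identical(patient$end_reason, "death")) {
    last <- out[nrow(out), , drop = FALSE]
    if (last$obs_day < patient$end_day) {
      dth <- last
      dth$obs_day <- as.integer(patient$end_day)
      dth$state <- "Death"
      dth$state_num <- 4L
      dth$obs_type <- "exact_death"
      if (!is.na(aao)) {
        dth$age <- aao + (patient$end_day - onset) / DAYS_PER_YEAR
      }
      dth$hedmt_years <- cumulative_exposure(episodes, patient$end_day, "high")
      dth$medmt_years <- cumulative_exposure(episodes, patient$end_day,
                                             "moderate")
      dth$cum_relapses <- length(post_dx_relapses)
      out <- rbind(out, dth)
    } else {
      out$state[nrow(out)] <- "Death"
      out$state_num[nrow(out)] <- 4L
      out$obs_type[nrow(out)] <- "exact_death"
    }
  }
  rownames(out) <- NULL
  attr(out, "missing_edss") <- anyNA(out$edss)
  out
}

#' Build the panel for a whole cohort
#'
#' Applies [build_panel()] to each patient with the default observation
#' schedule: the patient's EDSS visit days, plus the RRMS and SPMS diagnosis
#' days, deduplicated and clipped to follow-up. Patients with fewer than two
#' observations or with unimputable EDSS are dropped with a warning (their
#' ids are attached as attribute `"dropped"`).
#'
#' @param cohort An `ms_cohort`.
#' @param schedule_fn Optional function(patient row) returning observation
#'   days; defaults to the visit-based schedule above.
#' @param window Classification window in days.
#' @return Panel data frame over all retained patients.
#' @export
build_panel_cohort <- function(cohort, schedule_fn = NULL,
                               window = RELAPSE_WINDOW_DAYS) {
  stopifnot(inherits(cohort, "ms_cohort"))
  rel_by <- split(cohort$relapses$relapse_day, cohort$relapses$patient_id)
  edss_by <- split(cohort$edss, cohort$edss$patient_id)
  trt_by <- split(cohort$treatments, cohort$treatments$patient_id)
  dropped <- character(0)
  panels <- vector("list", nrow(cohort$patients))
  for (i in seq_len(nrow(cohort$patients))) {
    p <- cohort$patients[i, , drop = FALSE]
    pid <- p$patient_id
    ed <- edss_by[[pid]]
    if (is.null(schedule_fn)) {
      sched <- c(p$rrms_dx_day, p$spms_dx_day,
                 if (!is.null(ed)) ed$obs_day)
      sched <- sched[!is.na(sched)]
      sched <- sched[sched >= p$rrms_dx_day & sched <= p$end_day]
    } else {
      sched <- schedule_fn(p)
    }
    if (length(sched) < 2 && p$end_reason != "death") {
      dropped <- c(dropped, pid)
      next
    }
    pan <- build_panel(p, rel_by[[pid]] %||% integer(0), ed, trt_by[[pid]],
                       sched, window)
    if (isTRUE(attr(pan, "missing_edss"))) {
      dropped <- c(dropped, pid)
      next
    }
    panels[[i]] <- pan
  }
  out <- do.call(rbind, panels)
  rownames(out) <- NULL
  if (length(dropped)) {
    warning(length(dropped),
            " patient(s) dropped from panel (too few observations or ",
            "unimputable EDSS)", call. = FALSE)
  }
  attr(out, "dropped") <- dropped
  out
}
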