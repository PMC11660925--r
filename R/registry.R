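# Registry domain model: four delimited tables (patients, relapses, edss,
# treatments) with day-offset dates, validated into an "ms_cohort" object.

HIGH_EFFICACY_DMTS <- c(
  "alemtuzumab", "cladribine", "daclizumab", "fingolimod", "natalizumab",
  "ocrelizumab", "ofatumumab", "ozanimod", "rituximab", "siponimod"
)

MODERATE_EFFICACY_DMTS <- c(
  "dimethyl fumarate", "diroximel fumarate", "glatiramer acetate",
  "teriflunomide"
)

END_REASONS <- c("death", "emigration", "discontinuation", "admin_censor")

PHENOTYPE_STATES <- c("RRMS", "nrSPMS", "rSPMS", "Death")

#' Classify a disease-modifying therapy by efficacy class
#'
#' Drugs are assigned to the high-efficacy class (alemtuzumab, cladribine,
#' daclizumab, fingolimod, natalizumab, ocrelizumab, ofatumumab, ozanimod,
#' rituximab, siponimod) or the moderate-efficacy class (dimethyl fumarate,
#' diroximel fumarate, glatiramer acetate, the interferon-beta family
#' including pegylated interferon, and teriflunomide). Matching is
#' case-insensitive and whitespace-tolerant; interferon products match by
#' substring so that spelling variants ("interferon beta-1a", "peginterferon")
#' are recognised. Anything else is `"unclassified"` and contributes to
#' neither cumulative-exposure covariate.
#'
#' @param drug_name Character vector of drug names.
#' @return Character vector in `c("high", "moderate", "unclassified")`.
#' @examples
#' classify_dmt(c("Natalizumab", "teriflunomide", "ibuprofen"))
#' @export
classify_dmt <- function(drug_name) {
  x <- tolower(trimws(as.character(drug_name)))
  x <- gsub("[[:space:]]+", " ", x)
  out <- rep("unclassified", length(x))
  out[x %in% HIGH_EFFICACY_DMTS] <- "high"
  out[x %in% MODERATE_EFFICACY_DMTS] <- "moderate"
  out[grepl("interferon", x, fixed = TRUE)] <- "moderate"
  out
}

#' Construct a validated registry cohort
#'
#' Bundles the four registry tables into an `ms_cohort` after checking every
#' record-level invariant: follow-up ordering (`onset_day <= rrms_dx_day <=
#' end_day`, SPMS diagnosis inside follow-up), relapses not after end of
#' follow-up, EDSS on the half-point 0--10 grid, treatment episodes with
#' positive duration. Repairs applied on construction (and reported in the
#' `"repairs"` attribute): duplicate relapse days per patient collapsed to one
#' event, open treatment episodes clipped at the patient's `end_day`, and
#' overlapping or abutting episodes of the same efficacy class merged.
#'
#' @param patients Data frame with columns `patient_id`, `sex`
#'   (`"female"`/`"male"`), `onset_day`, `rrms_dx_day`, `spms_dx_day`
#'   (`NA` if never diagnosed SPMS), `end_day`, `end_reason` (one of
#'   `"death"`, `"emigration"`, `"discontinuation"`, `"admin_censor"`), and
#'   optionally `age_at_onset` in years (used as the age anchor).
#' @param relapses Data frame with columns `patient_id`, `relapse_day`.
#' @param edss Data frame with columns `patient_id`, `obs_day`, `edss`.
#' @param treatments Data frame with columns `patient_id`, `drug_name`,
#'   `start_day`, `stop_day` (`NA` = ongoing, clipped at `end_day`).
#' @return An `ms_cohort`: a list of the four cleaned tables (treatments gain
#'   an `efficacy_class` column) with a repair report attached.
#' @export
ms_cohort <- function(patients, relapses = NULL, edss = NULL,
                      treatments = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    df
  }
  if (is.null(relapses)) relapses <- empty(c("patient_id", "relapse_day"))
  if (is.null(edss)) edss <- empty(c("patient_id", "obs_day", "edss"))
  if (is.null(treatments)) {
    treatments <- empty(c("patient_id", "drug_name", "start_day", "stop_day"))
  }

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing required column(s): %s",
                   what, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(patients, c("patient_id", "sex", "onset_day", "rrms_dx_day",
                   "spms_dx_day", "end_day", "end_reason"), "patients")
  need(relapses, c("patient_id", "relapse_day"), "relapses")
  need(edss, c("patient_id", "obs_day", "edss"), "edss")
  need(treatments, c("patient_id", "drug_name", "start_day", "stop_day"),
       "treatments")

  patients <- as.data.frame(patients)
  relapses <- as.data.frame(relapses)
  edss <- as.data.frame(edss)
  treatments <- as.data.frame(treatments)

  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table: ",
         patients$patient_id[duplicated(patients$patient_id)][1],
         call. = FALSE)
  }
  for (col in c("onset_day", "rrms_dx_day", "spms_dx_day", "end_day")) {
    patients[[col]] <- as.integer(patients[[col]])
  }
  bad <- !(patients$sex %in% c("female", "male"))
  if (any(bad)) {
    stop("invalid sex for patient ", patients$patient_id[bad][1],
         call. = FALSE)
  }
  bad <- !(patients$end_reason %in% END_REASONS)
  if (any(bad)) {
    stop("invalid end_reason for patient ", patients$patient_id[bad][1],
         call. = FALSE)
  }
  bad <- !(patients$onset_day <= patients$rrms_dx_day &
             patients$rrms_dx_day <= patients$end_day)
  if (any(bad)) {
    stop("follow-up ordering violated (onset <= RRMS dx <= end) for patient ",
         patients$patient_id[bad][1], call. = FALSE)
  }
  has_spms <- !is.na(patients$spms_dx_day)
  bad <- has_spms & !(patients$spms_dx_day >= patients$rrms_dx_day &
                        patients$spms_dx_day <= patients$end_day)
  if (any(bad)) {
    stop("spms_dx_day outside [rrms_dx_day, end_day] for patient ",
         patients$patient_id[bad][1], call. = FALSE)
  }
  if (!"age_at_onset" %in% names(patients)) patients$age_at_onset <- NA_real_
  patients$age_at_onset <- as.numeric(patients$age_at_onset)

  repairs <- list()
  end_of <- setNames(patients$end_day, patients$patient_id)

  # relapses
  relapses$patient_id <- as.character(relapses$patient_id)
  relapses$relapse_day <- as.integer(relapses$relapse_day)
  unknown <- !(relapses$patient_id %in% patients$patient_id)
  if (any(unknown)) {
    stop("relapse row for unknown patient ", relapses$patient_id[unknown][1],
         call. = FALSE)
  }
  if (nrow(relapses)) {
    bad <- relapses$relapse_day > end_of[relapses$patient_id]
    if (any(bad)) {
      stop("relapse after end of follow-up for patient ",
           relapses$patient_id[bad][1], call. = FALSE)
    }
    dup <- duplicated(relapses[c("patient_id", "relapse_day")])
    repairs$relapses_deduplicated <- sum(dup)
    relapses <- relapses[!dup, , drop = FALSE]
    relapses <- relapses[order(relapses$patient_id, relapses$relapse_day), ,
                         drop = FALSE]
  } else {
    repairs$relapses_deduplicated <- 0L
  }

  # EDSS
  edss$patient_id <- as.character(edss$patient_id)
  edss$obs_day <- as.integer(edss$obs_day)
  edss$edss <- as.numeric(edss$edss)
  unknown <- !(edss$patient_id %in% patients$patient_id)
  if (any(unknown)) {
    stop("EDSS row for unknown patient ", edss$patient_id[unknown][1],
         call. = FALSE)
  }
  if (nrow(edss)) {
    on_grid <- edss$edss >= 0 & edss$edss <= 10 &
      abs(edss$edss * 2 - round(edss$edss * 2)) < 1e-9
    if (any(!on_grid)) {
      stop("EDSS off the 0-10 half-point grid for patient ",
           edss$patient_id[!on_grid][1], call. = FALSE)
    }
    dup <- duplicated(edss[c("patient_id", "obs_day")])
    repairs$edss_deduplicated <- sum(dup)
    edss <- edss[!dup, , drop = FALSE]
    edss <- edss[order(edss$patient_id, edss$obs_day), , drop = FALSE]
  } else {
    repairs$edss_deduplicated <- 0L
  }

  # treatments
  treatments$patient_id <- as.character(treatments$patient_id)
  treatments$drug_name <- as.character(treatments$drug_name)
  treatments$start_day <- as.integer(treatments$start_day)
  treatments$stop_day <- as.integer(treatments$stop_day)
  unknown <- !(treatments$patient_id %in% patients$patient_id)
  if (any(unknown)) {
    stop("treatment row for unknown patient ",
         treatments$patient_id[unknown][1], call. = FALSE)
  }
  if (nrow(treatments)) {
    open <- is.na(treatments$stop_day)
    repairs$episodes_clipped <- sum(open)
    treatments$stop_day[open] <- end_of[treatments$patient_id[open]]
    bad <- treatments$start_day >= treatments$stop_day
    if (any(bad)) {
      stop("treatment episode with non-positive duration for patient ",
           treatments$patient_id[bad][1], call. = FALSE)
    }
    treatments$efficacy_class <- classify_dmt(treatments$drug_name)
    merged <- merge_episodes(treatments)
    repairs$episodes_merged <- nrow(treatments) - nrow(merged)
    treatments <- merged
  } else {
    treatments$efficacy_class <- character(0)
    repairs$episodes_clipped <- 0L
    repairs$episodes_merged <- 0L
  }

  out <- list(patients = patients, relapses = relapses, edss = edss,
              treatments = treatments)
  attr(out, "repairs") <- repairs
  class(out) <- "ms_cohort"
  out
}

# Merge overlapping/abutting episodes within (patient, efficacy_class),
# keeping the first drug name of each merged run.
merge_episodes <- function(tr) {
  if (!nrow(tr)) return(tr)
  tr <- tr[order(tr$patient_id, tr$efficacy_class, tr$start_day,
                 tr$stop_day), , drop = FALSE]
  key <- paste(tr$patient_id, tr$efficacy_class, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(tr)), key), function(idx) {
    sub <- tr[idx, , drop = FALSE]
    keep_start <- sub$start_day[1]
    keep_stop <- sub$stop_day[1]
    out <- sub[1, , drop = FALSE]
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        if (sub$start_day[i] <= keep_stop) {
          keep_stop <- max(keep_stop, sub$stop_day[i])
          out$stop_day[nrow(out)] <- keep_stop
        } else {
          out <- rbind(out, sub[i, , drop = FALSE])
          keep_start <- sub$start_day[i]
          keep_stop <- sub$stop_day[i]
        }
      }
    }
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$patient_id, out$start_day), , drop = FALSE]
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat("Registry cohort:", nrow(x$patients), "patients,",
      nrow(x$relapses), "relapses,", nrow(x$edss), "EDSS observations,",
      nrow(x$treatments), "treatment episodes\n")
  n_spms <- sum(!is.na(x$patients$spms_dx_day))
  cat("  SPMS diagnoses:", n_spms,
      "| deaths:", sum(x$patients$end_reason == "death"), "\n")
  rep <- attr(x, "repairs")
  if (length(rep) && any(unlist(rep) > 0)) {
    cat("  repairs on load:",
        paste(names(rep)[unlist(rep) > 0], unlist(rep)[unlist(rep) > 0],
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Read and write registry cohorts as delimited files
#'
#' A cohort is stored as four UTF-8 comma-delimited files with header rows:
#' `patients.csv`, `relapses.csv`, `edss.csv`, `treatments.csv`. Empty fields
#' are missing values. Loading re-validates every invariant via [ms_cohort()],
#' so `read_registry(write_registry(x))` is the identity on valid cohorts.
#'
#' @param dir Directory containing (or to receive) the four files.
#' @param cohort An `ms_cohort`.
#' @return `read_registry()` returns an `ms_cohort`; `write_registry()`
#'   returns `dir` invisibly.
#' @export
read_registry <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("patients.csv", "relapses.csv", "edss.csv", "treatments.csv")) {
    if (!file.exists(path(f))) stop("missing registry file: ", f, call. = FALSE)
  }
  rd <- function(f) read.csv(path(f), stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  ms_cohort(rd("patients.csv"), rd("relapses.csv"), rd("edss.csv"),
            rd("treatments.csv"))
}

#' @rdname read_registry
#' @export
write_registry <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ms_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE,
                                  na = "")
  wr(cohort$patients, "patients.csv")
  wr(cohort$relapses, "relapses.csv")
  wr(cohort$edss, "edss.csv")
  tr <- cohort$treatments
  tr$efficacy_class <- NULL  # derived on load
  wr(tr, "treatments.csv")
  invisible(dir)
}

#' Cumulative years on therapy of a given efficacy class
#'
#' Total time, in years, spent on treatment episodes of one efficacy class up
#' to (and including) day `t`. Episodes are merged within class before
#' summation, so overlaps are not double-counted; the result is
#' piecewise-linear and non-decreasing in `t`.
#'
#' @param episodes Data frame of treatment episodes for one patient with
#'   columns `start_day`, `stop_day` and `efficacy_class` (as produced by
#'   [ms_cohort()]; an `efficacy_class` column is derived from `drug_name`
#'   if absent).
#' @param t Integer day (vectorised) at which exposure is evaluated.
#' @param class `"high"` or `"moderate"`.
#' @return Non-negative numeric vector of years, `length(t)`.
#' @examples
#' eps <- data.frame(start_day = 0, stop_day = 730, efficacy_class = "high")
#' cumulative_exposure(eps, 730, "high")  # 730/365.25
#' @export
cumulative_exposure <- function(episodes, t, class = c("high", "moderate")) {
  class <- match.arg(class)
  if (is.null(episodes) || !nrow(episodes)) return(numeric(length(t)))
  if (!"efficacy_class" %in% names(episodes)) {
    episodes$efficacy_class <- classify_dmt(episodes$drug_name)
  }
  eps <- episodes[episodes$efficacy_class == class, , drop = FALSE]
  if (!nrow(eps)) return(numeric(length(t)))
  if (!"patient_id" %in% names(eps)) eps$patient_id <- "x"
  eps <- merge_episodes(eps)
  vapply(t, function(tt) {
    sum(pmax(0, pmin(eps$stop_day, tt) - eps$start_day)) / DAYS_PER_YEAR
  }, numeric(1))
}
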