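# End-to-end orchestration: simulate (optional) -> classify -> descriptive
# tables -> cumulative incidence -> Cox milestones -> relapse rates ->
# multi-state Markov fit -> hazard ratios, predicted probabilities,
# prevalence goodness of fit. Every artifact is a CSV; a manifest records
# the configuration hash and seed for reproducibility.

#' Configuration for a full analysis run
#'
#' @param input_dir Directory with the four registry CSVs, or `NULL` to
#'   simulate a cohort.
#' @param sim_params A [cohort_params()] used when `input_dir` is `NULL`.
#' @param out_dir Output directory for the report bundle.
#' @param window_days Retrospective relapse window (days).
#' @param horizons Prediction horizons in years.
#' @param n_draws Parameter draws for prediction intervals.
#' @param seed Integer seed governing every stochastic stage.
#' @param markov_covariates Per-transition covariate spec for the Markov fit
#'   (default [ms_default_covariates()]).
#' @param fit_control Control list passed to [fit_msm()].
#' @param min_spms Minimum number of SPMS patients required to attempt the
#'   SPMS-specific stages and the Markov fit.
#' @return A `run_config` list.
#' @export
msphase_config <- function(input_dir = NULL,
                           sim_params = cohort_params(),
                           out_dir = tempfile("msphase_run_"),
                           window_days = 730L,
                           horizons = c(5, 10, 15),
                           n_draws = 100L,
                           seed = 1L,
                           markov_covariates = ms_default_covariates(),
                           fit_control = list(),
                           min_spms = 10L) {
  cfg <- list(input_dir = input_dir, sim_params = sim_params,
              out_dir = out_dir, window_days = as.integer(window_days),
              horizons = horizons, n_draws = as.integer(n_draws),
              seed = as.integer(seed),
              markov_covariates = markov_covariates,
              fit_control = fit_control, min_spms = as.integer(min_spms))
  stopifnot(cfg$window_days > 0, all(cfg$horizons > 0), cfg$n_draws > 0)
  class(cfg) <- "run_config"
  cfg
}

# Stable hash of the semantic configuration fields (output paths excluded).
config_hash <- function(config) {
  sem <- config[setdiff(names(config), "out_dir")]
  sem <- sem[order(names(sem))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(sem, control = c("keepNA", "niceNames", "showAttributes")),
             tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  message("[msphase] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the complete analysis sequence on a registry cohort (loaded from
#' `config$input_dir` or simulated from `config$sim_params`) and writes a
#' report bundle of CSV tables plus `MANIFEST.json`. Deterministic given the
#' configuration and seed. If the cohort has fewer SPMS patients than
#' `config$min_spms`, the SPMS-specific stages (milestones, SPMS incidence,
#' Markov fit) are skipped with an explicit notice in the manifest.
#'
#' @param config A [msphase_config()].
#' @return Invisibly, a list of the in-memory results (`cohort`,
#'   `timelines`, `panel`, `fit`, tables) with the manifest attached.
#' @export
run_msphase <- function(config = msphase_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  notices <- character(0)
  wr <- function(df, name) {
    write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  }

  cohort <- stage("load", {
    if (!is.null(config$input_dir)) {
      read_registry(config$input_dir)
    } else {
      sp <- config$sim_params
      sp$seed <- config$seed
      simulate_cohort(sp)
    }
  })

  timelines <- stage("classify", {
    rel <- split(cohort$relapses$relapse_day, cohort$relapses$patient_id)
    lapply(seq_len(nrow(cohort$patients)), function(i) {
      p <- cohort$patients[i, , drop = FALSE]
      classify_timeline(p, rel[[p$patient_id]] %||% integer(0),
                        config$window_days)
    })
  })
  tl_df <- do.call(rbind, lapply(timelines, function(tl) {
    cbind(patient_id = tl$patient_id, tl$intervals)
  }))
  wr(tl_df, "timelines.csv")

  p <- cohort$patients
  rel_split <- split(cohort$relapses$relapse_day, cohort$relapses$patient_id)
  spms_idx <- which(!is.na(p$spms_dx_day))
  group <- setNames(rep("RRMS", nrow(p)), p$patient_id)
  for (i in spms_idx) {
    group[p$patient_id[i]] <- state_at(
      p[i, ], rel_split[[p$patient_id[i]]] %||% integer(0),
      p$spms_dx_day[i], config$window_days)
  }

  stage("descriptives", {
    wr(make_descriptives(cohort, group), "table_descriptives.csv")
    wr(pattern_table(timelines), "transition_patterns.csv")
    wr(arr_before_diagnosis(cohort, group), "arr_prediagnosis.csv")
  })

  n_spms <- length(spms_idx)
  has_spms <- n_spms >= config$min_spms
  if (!has_spms) {
    notices <- c(notices, sprintf(
      "only %d SPMS patients (< %d): milestone, incidence and Markov stages skipped",
      n_spms, config$min_spms))
  }

  fit <- NULL; panel <- NULL
  cif_tabs <- list()
  if (has_spms) {
    stage("cumulative_incidence", {
      cif_tabs <- cohort_cifs(cohort, group, config$window_days)
      for (nm in names(cif_tabs)) {
        wr(cif_to_df(cif_tabs[[nm]]), paste0("cif_", nm, ".csv"))
      }
    })
    stage("cox_milestones", {
      ms <- edss_milestones(cohort, window = config$window_days)
      tab <- do.call(rbind, lapply(names(ms), function(nm) {
        cbind(milestone = nm, ms[[nm]]$hr,
              n_events = attr(ms[[nm]], "n_events"))
      }))
      wr(tab, "cox_milestones.csv")
    })
    stage("gee_arr", {
      tab <- relapse_age_table(cohort, config$window_days)
      g <- gee_poisson_arr(tab)
      wr(g$arr, "gee_arr_trajectories.csv")
      wr(g$irr, "gee_irr.csv")
    })
    stage("markov_fit", {
      panel <- suppressWarnings(
        build_panel_cohort(cohort, window = config$window_days))
      fit <- suppressWarnings(
        fit_msm(panel, covariates = config$markov_covariates,
                control = config$fit_control))
      hr <- hazard_ratios(fit)
      wr(hr, "markov_hazard_ratios.csv")
      wr(make_hr_table(fit), "table_hr_formatted.csv")
    })
    stage("markov_predictions", {
      prof <- typical_profile(panel, fit$covnames)
      probs <- predicted_probabilities(fit, prof,
                                       horizons = config$horizons,
                                       n_draws = config$n_draws,
                                       seed = config$seed + 1L,
                                       ridge = 1e-8)
      wr(probs, "markov_transition_probs.csv")
      wr(make_probability_table(probs), "table_probs_formatted.csv")
    })
    stage("prevalence_gof", {
      span <- max(tapply(panel$obs_day, panel$patient_id,
                         function(d) diff(range(d)))) / DAYS_PER_YEAR
      prev <- expected_prevalence(fit, panel,
                                  grid = seq(0, span, length.out = 21))
      wr(as.data.frame(prev), "prevalence_gof.csv")
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("msphase")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(config),
    n_patients = nrow(p),
    n_spms = n_spms,
    notices = notices)
  jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, timelines = timelines, group = group,
                 panel = panel, fit = fit, cifs = cif_tabs,
                 manifest = manifest, out_dir = config$out_dir))
}

# median covariate profile at first observation, used for predictions
typical_profile <- function(panel, covnames) {
  if (!length(covnames)) return(NULL)
  first <- panel[!duplicated(panel$patient_id), covnames, drop = FALSE]
  vapply(first, median, numeric(1))
}

cif_to_df <- function(cif) {
  df <- data.frame(time = cif$times, surv = cif$surv,
                   at_risk = cif$at_risk)
  for (tp in cif$types) df[[paste0("cif_", tp)]] <- cif$cif[, tp]
  df
}

# The three cumulative-incidence analyses: (i) RRMS diagnosis to first SPMS
# classification (split by sub-phenotype at diagnosis) with death competing;
# (ii) nrSPMS-at-diagnosis patients to first relapsing phase; (iii)
# rSPMS-at-diagnosis patients to first non-relapsing phase.
cohort_cifs <- function(cohort, group, window = RELAPSE_WINDOW_DAYS) {
  p <- cohort$patients
  yrs <- function(d0, d1) pmax(d1 - d0, 0.5) / DAYS_PER_YEAR

  ev <- ifelse(!is.na(p$spms_dx_day), paste0("spms_", unname(group[p$patient_id])),
               ifelse(p$end_reason == "death", "death", "censored"))
  exit_day <- ifelse(!is.na(p$spms_dx_day), p$spms_dx_day, p$end_day)
  recs1 <- data.frame(entry_time = 0,
                      exit_time = yrs(p$rrms_dx_day, exit_day),
                      event = ev)
  out <- list(rrms_to_spms = aalen_johansen(recs1))

  rel <- split(cohort$relapses$relapse_day, cohort$relapses$patient_id)
  sub_cif <- function(start_group, target_state) {
    idx <- which(!is.na(p$spms_dx_day) &
                   unname(group[p$patient_id]) == start_group)
    if (length(idx) < 3) return(NULL)
    recs <- lapply(idx, function(i) {
      tl <- classify_timeline(p[i, ], rel[[p$patient_id[i]]] %||% integer(0),
                              window)
      iv <- tl$intervals
      hit <- iv$start_day[iv$state == target_state &
                            iv$start_day >= p$spms_dx_day[i]]
      hit <- hit[hit > p$spms_dx_day[i]]
      if (length(hit)) {
        data.frame(entry_time = 0,
                   exit_time = yrs(p$spms_dx_day[i], min(hit)),
                   event = target_state)
      } else {
        data.frame(entry_time = 0,
                   exit_time = yrs(p$spms_dx_day[i], p$end_day[i]),
                   event = if (p$end_reason[i] == "death") "death" else
                     "censored")
      }
    })
    aalen_johansen(do.call(rbind, recs))
  }
  c1 <- sub_cif("nrSPMS", "rSPMS")
  if (!is.null(c1)) out$nrspms_to_rspms <- c1
  c2 <- sub_cif("rSPMS", "nrSPMS")
  if (!is.null(c2)) out$rspms_to_nrspms <- c2
  out
}

#' Descriptive characteristics table
#'
#' Frequency/percentage and mean (SD) or median (IQR) summaries of the
#' cohort at RRMS diagnosis, per phenotype group (patients who remained
#' RRMS, and the SPMS sub-phenotypes at SPMS diagnosis).
#'
#' @param cohort An `ms_cohort`.
#' @param group Named vector `patient_id -> group label`.
#' @return Data frame with one row per characteristic and one column per
#'   group.
#' @export
make_descriptives <- function(cohort, group) {
  p <- cohort$patients
  g <- unname(group[p$patient_id])
  rel <- split(cohort$relapses$relapse_day, cohort$relapses$patient_id)
  pre_dx <- vapply(seq_len(nrow(p)), function(i) {
    r <- rel[[p$patient_id[i]]]
    if (is.null(r)) 0L else
      sum(r > p$rrms_dx_day[i] - RELAPSE_WINDOW_DAYS & r <= p$rrms_dx_day[i])
  }, integer(1))
  fu_years <- (p$end_day - p$rrms_dx_day) / DAYS_PER_YEAR
  one_group <- function(sel) {
    n <- sum(sel)
    c(`N` = as.character(n),
      `Female, n (%)` = sprintf("%d (%.1f)", sum(p$sex[sel] == "female"),
                                100 * mean(p$sex[sel] == "female")),
      `Age at onset, mean (SD)` = sprintf(
        "%.1f (%.1f)", mean(p$age_at_onset[sel], na.rm = TRUE),
        sd(p$age_at_onset[sel], na.rm = TRUE)),
      `Relapses 2y before diagnosis: 0, n (%)` = sprintf(
        "%d (%.1f)", sum(pre_dx[sel] == 0), 100 * mean(pre_dx[sel] == 0)),
      `Relapses 2y before diagnosis: 1, n (%)` = sprintf(
        "%d (%.1f)", sum(pre_dx[sel] == 1), 100 * mean(pre_dx[sel] == 1)),
      `Relapses 2y before diagnosis: >1, n (%)` = sprintf(
        "%d (%.1f)", sum(pre_dx[sel] > 1), 100 * mean(pre_dx[sel] > 1)),
      `Follow-up years, median (IQR)` = sprintf(
        "%.1f (%.1f-%.1f)", median(fu_years[sel]),
        quantile(fu_years[sel], 0.25), quantile(fu_years[sel], 0.75)))
  }
  groups <- intersect(c("RRMS", "rSPMS", "nrSPMS"), unique(g))
  cols <- lapply(groups, function(gr) one_group(g == gr))
  out <- data.frame(characteristic = names(cols[[1]]),
                    stringsAsFactors = FALSE)
  for (k in seq_along(groups)) out[[groups[k]]] <- unname(cols[[k]])
  out
}

# ---- formatting ----------------------------------------------------------

#' Format estimates with confidence intervals
#'
#' Renders `"est (lower-upper)"` cells using an en dash, e.g.
#' `"1.044 (1.035-1.053)"` at 3 decimals, or `"94.6 (94.1-95.0)"` for
#' percentages at 1 decimal with `scale = 100`.
#'
#' @param est,lower,upper Numeric vectors.
#' @param digits Decimal places.
#' @param scale Multiplier applied before formatting (100 for percentages).
#' @return Character vector.
#' @export
fmt_est_ci <- function(est, lower, upper, digits = 3, scale = 1) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f–%.", digits, "f)"),
          est * scale, lower * scale, upper * scale)
}

#' Hazard-ratio table in per-transition column layout
#'
#' One row per covariate, one column per transition; cells are
#' `"HR (lower-upper)"` at 3 decimals and covariates not included in a
#' transition's model are rendered `"not included"`.
#'
#' @param fit An `msm_fit`.
#' @return Data frame.
#' @export
make_hr_table <- function(fit) {
  hr <- hazard_ratios(fit)
  covs <- unique(hr$covariate)
  trans <- fit$model$structure$labels
  trans <- trans[vapply(fit$model$covariate_spec[trans], length,
                        integer(1)) > 0]
  out <- data.frame(covariate = covs, stringsAsFactors = FALSE)
  for (tr in trans) {
    col <- vapply(covs, function(cv) {
      row <- hr[hr$transition == tr & hr$covariate == cv, ]
      if (!nrow(row)) return("not included")
      fmt_est_ci(row$hr, row$lower, row$upper, digits = 3)
    }, character(1))
    out[[tr]] <- unname(col)
  }
  out
}

#' Transition-probability table in percent
#'
#' @param probs Output of [predicted_probabilities()].
#' @param from,to Optional state filters.
#' @return Data frame with `"est (lower-upper)"` percentage cells at 1
#'   decimal, rows = from-state, columns = to-state, per horizon.
#' @export
make_probability_table <- function(probs, from = NULL, to = NULL) {
  if (!is.null(from)) probs <- probs[probs$from %in% from, ]
  if (!is.null(to)) probs <- probs[probs$to %in% to, ]
  probs$cell <- fmt_est_ci(probs$estimate, probs$lower, probs$upper,
                           digits = 1, scale = 100)
  out <- list()
  for (h in unique(probs$horizon)) {
    sub <- probs[probs$horizon == h, ]
    wide <- data.frame(horizon = h, from = unique(sub$from),
                       stringsAsFactors = FALSE)
    for (st in unique(sub$to)) {
      wide[[st]] <- sub$cell[match(paste(wide$from, st),
                                   paste(sub$from, sub$to))]
    }
    out[[as.character(h)]] <- wide
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
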