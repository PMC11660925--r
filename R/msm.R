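# Continuous-time multi-state Markov model for panel data. Transition
# intensities are log-linear in covariates, q_rs(z) = exp(log_q0_rs +
# beta_rs . z_rs), with a transition-specific covariate subset z_rs.
# Covariates are held piecewise-constant at each observation interval's left
# endpoint; interval transition probabilities are matrix exponentials.

WALD_Z <- 1.959964

#' Define a multi-state transition structure
#'
#' @param states Ordered character vector of state labels.
#' @param allowed Data frame (or 2-column matrix) of allowed instantaneous
#'   transitions with columns `from`, `to` (state labels).
#' @param absorbing Character vector of absorbing states (no outgoing
#'   transitions allowed).
#' @return An `msm_structure` list with elements `states`, `allowed`,
#'   `absorbing` and the transition labels `"from->to"`.
#' @export
ms_structure <- function(states, allowed, absorbing = character(0)) {
  allowed <- as.data.frame(allowed, stringsAsFactors = FALSE)
  names(allowed) <- c("from", "to")
  stopifnot(all(allowed$from %in% states), all(allowed$to %in% states),
            all(absorbing %in% states))
  if (any(allowed$from %in% absorbing)) {
    stop("absorbing state has an outgoing transition", call. = FALSE)
  }
  if (any(allowed$from == allowed$to)) {
    stop("self-transitions are implicit and may not be listed", call. = FALSE)
  }
  structure(list(states = states, allowed = allowed, absorbing = absorbing,
                 labels = paste0(allowed$from, "->", allowed$to)),
            class = "msm_structure")
}

#' Four-state phenotype transition structure
#'
#' The default disease model: three transient phenotype states (RRMS, nrSPMS,
#' rSPMS) and absorbing Death. RRMS can progress to either SPMS sub-phenotype
#' (SPMS assignment is irreversible, so RRMS has no incoming transitions);
#' the SPMS sub-phenotypes can alternate; every transient state can die.
#'
#' @return An `msm_structure`.
#' @export
ms_default_structure <- function() {
  ms_structure(
    states = PHENOTYPE_STATES,
    allowed = data.frame(
      from = c("RRMS", "RRMS", "nrSPMS", "rSPMS", "RRMS", "nrSPMS", "rSPMS"),
      to = c("nrSPMS", "rSPMS", "rSPMS", "nrSPMS", "Death", "Death", "Death"),
      stringsAsFactors = FALSE),
    absorbing = "Death")
}

#' Default per-transition covariate sets
#'
#' The RRMS exit transitions carry the full covariate set (sex, age,
#' cumulative high- and moderate-efficacy DMT years, EDSS, calendar year of
#' RRMS diagnosis, cumulative relapses since RRMS diagnosis, disease duration
#' at RRMS diagnosis); transitions between the SPMS sub-phenotypes carry only
#' sex, age, DMT exposures and EDSS; death transitions carry age and sex.
#'
#' @return Named list mapping transition labels to covariate-name vectors.
#' @export
ms_default_covariates <- function() {
  full <- c("sex_female", "age", "hedmt_years", "medmt_years", "edss",
            "dx_year", "cum_relapses", "disease_duration")
  spms <- c("sex_female", "age", "hedmt_years", "medmt_years", "edss")
  death <- c("age", "sex_female")
  list("RRMS->nrSPMS" = full, "RRMS->rSPMS" = full,
       "nrSPMS->rSPMS" = spms, "rSPMS->nrSPMS" = spms,
       "RRMS->Death" = death, "nrSPMS->Death" = death,
       "rSPMS->Death" = death)
}

#' Construct a proportional-intensity model
#'
#' @param structure An `msm_structure`.
#' @param covariates Named list mapping transition labels (`"from->to"`) to
#'   character vectors of covariate names; transitions absent from the list
#'   carry no covariates. `NULL` means no covariates anywhere.
#' @param log_q0 Named numeric of baseline log intensities (log 1/year), one
#'   per allowed transition; defaults to `log(0.1)` everywhere.
#' @param beta Named list of named numeric coefficient vectors per
#'   transition; defaults to zeros.
#' @return An `msm_model`.
#' @export
msm_model <- function(structure, covariates = NULL, log_q0 = NULL,
                      beta = NULL) {
  stopifnot(inherits(structure, "msm_structure"))
  labs <- structure$labels
  if (is.null(covariates)) covariates <- setNames(vector("list", 0), NULL)
  bad <- setdiff(names(covariates), labs)
  if (length(bad)) {
    stop("covariate spec refers to disallowed transition(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cov_spec <- setNames(lapply(labs, function(l) {
    v <- covariates[[l]]
    if (is.null(v)) character(0) else as.character(v)
  }), labs)
  if (is.null(log_q0)) log_q0 <- setNames(rep(log(0.1), length(labs)), labs)
  stopifnot(all(labs %in% names(log_q0)))
  log_q0 <- log_q0[labs]
  if (is.null(beta)) {
    beta <- setNames(lapply(labs, function(l) {
      setNames(rep(0, length(cov_spec[[l]])), cov_spec[[l]])
    }), labs)
  } else {
    beta <- setNames(lapply(labs, function(l) {
      b <- beta[[l]]
      if (is.null(b)) b <- setNames(rep(0, length(cov_spec[[l]])),
                                    cov_spec[[l]])
      stopifnot(length(b) == length(cov_spec[[l]]))
      setNames(as.numeric(b), cov_spec[[l]])
    }), labs)
  }
  structure(list(structure = structure, covariate_spec = cov_spec,
                 log_q0 = log_q0, beta = beta),
            class = "msm_model")
}

# All covariate names used anywhere in the model, in stable order.
model_covnames <- function(model) {
  unique(unlist(model$covariate_spec, use.names = FALSE))
}

# Pack parameters into a single vector (log intensities then coefficients)
# and build the 0-based transition map consumed by the C++ core.
pack_params <- function(model) {
  labs <- model$structure$labels
  theta <- unname(model$log_q0)
  names(theta) <- paste0("logq(", labs, ")")
  q0_idx <- seq_along(labs)
  beta_idx <- vector("list", length(labs))
  for (k in seq_along(labs)) {
    b <- model$beta[[k]]
    if (length(b)) {
      idx <- length(theta) + seq_along(b)
      theta <- c(theta, setNames(unname(b),
                                 paste0(labs[k], ":", names(b))))
      beta_idx[[k]] <- idx
    } else {
      beta_idx[[k]] <- integer(0)
    }
  }
  list(theta = theta, q0_idx = q0_idx, beta_idx = beta_idx)
}

unpack_params <- function(model, theta) {
  labs <- model$structure$labels
  K <- length(labs)
  model$log_q0[] <- theta[seq_len(K)]
  pos <- K
  for (k in seq_len(K)) {
    nb <- length(model$beta[[k]])
    if (nb) {
      model$beta[[k]][] <- theta[pos + seq_len(nb)]
      pos <- pos + nb
    }
  }
  model
}

transition_map <- function(model, covnames) {
  st <- model$structure
  pp <- pack_params(model)
  K <- nrow(st$allowed)
  z_cols <- lapply(seq_len(K), function(k) {
    match(model$covariate_spec[[k]], covnames) - 1L
  })
  if (any(vapply(z_cols, function(v) anyNA(v), logical(1)))) {
    miss <- setdiff(unlist(model$covariate_spec), covnames)
    stop("covariate(s) missing from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  list(theta = pp$theta,
       tr_from = match(st$allowed$from, st$states) - 1L,
       tr_to = match(st$allowed$to, st$states) - 1L,
       q0_idx = pp$q0_idx - 1L,
       beta_idx = lapply(pp$beta_idx, function(v) as.integer(v - 1L)),
       z_cols = lapply(z_cols, as.integer),
       n_states = length(st$states),
       death_state = if (length(st$absorbing))
         match(st$absorbing[1], st$states) - 1L else -1L)
}

#' Matrix exponential
#'
#' Scaling-and-squaring Pade matrix exponential (dense, suitable for the
#' small generator matrices used here; does not assume diagonalisability).
#'
#' @param A Square numeric matrix.
#' @return `expm(A)`.
#' @export
expm_pade <- function(A) {
  cpp_expm(as.matrix(A))
}

#' Transition intensity matrix at a covariate value
#'
#' @param model An `msm_model`.
#' @param z Named numeric vector containing every covariate named in the
#'   model's covariate spec.
#' @return Square generator matrix `Q` (units 1/year): `Q[r,s] =
#'   exp(log_q0_rs + beta_rs . z_rs)` for allowed transitions, zero for
#'   disallowed off-diagonals, and diagonal entries set so rows sum to zero.
#' @export
intensity_matrix <- function(model, z = NULL) {
  st <- model$structure
  n <- length(st$states)
  need <- model_covnames(model)
  if (length(need)) {
    miss <- setdiff(need, names(z))
    if (length(miss)) {
      stop("missing covariate: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  Q <- matrix(0, n, n, dimnames = list(st$states, st$states))
  for (k in seq_along(st$labels)) {
    covs <- model$covariate_spec[[k]]
    lp <- model$log_q0[[k]] +
      if (length(covs)) sum(model$beta[[k]] * z[covs]) else 0
    Q[st$allowed$from[k], st$allowed$to[k]] <-
      Q[st$allowed$from[k], st$allowed$to[k]] + exp(lp)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over an interval
#'
#' Probability of occupying each state at `t1` given the state at `t0`, under
#' a piecewise-constant covariate path: the product of interval matrix
#' exponentials `expm(Q(z_k) * dt_k)` over the path segments, in time order.
#'
#' @param model An `msm_model`.
#' @param path Either `NULL` (no covariates), a named covariate vector held
#'   constant, or a data frame with a `time` column (years) and one column
#'   per covariate, each row giving the covariate values from that time until
#'   the next row. The path must start at or before `t0`.
#' @param t0,t1 Interval endpoints in years, `t0 <= t1`.
#' @return Stochastic matrix `P(t0, t1)` (rows sum to 1).
#' @export
transition_probability <- function(model, path = NULL, t0 = 0, t1) {
  stopifnot(t1 >= t0)
  n <- length(model$structure$states)
  P <- diag(n)
  dimnames(P) <- list(model$structure$states, model$structure$states)
  if (t1 == t0) return(P)
  if (is.null(path)) {
    path <- data.frame(time = t0)
  } else if (is.null(dim(path))) {
    path <- as.data.frame(c(list(time = t0), as.list(path)))
  }
  path <- path[order(path$time), , drop = FALSE]
  if (path$time[1] > t0) {
    stop("covariate path does not cover the start of the interval",
         call. = FALSE)
  }
  bounds <- c(path$time, Inf)
  for (k in seq_len(nrow(path))) {
    s <- max(bounds[k], t0)
    e <- min(bounds[k + 1], t1)
    if (e <= s) next
    z <- unlist(path[k, setdiff(names(path), "time"), drop = FALSE])
    Q <- intensity_matrix(model, z)
    P <- P %*% cpp_expm(Q * (e - s))
  }
  dimnames(P) <- list(model$structure$states, model$structure$states)
  P
}

# Turn a panel data frame into the interval arrays the C++ core consumes.
# Covariates are taken from the left endpoint of each interval.
prepare_intervals <- function(panel, covnames, structure) {
  stopifnot(all(c("patient_id", "obs_day", "state_num") %in% names(panel)))
  if (!"obs_type" %in% names(panel)) panel$obs_type <- "panel"
  miss <- setdiff(covnames, names(panel))
  if (length(miss)) {
    stop("covariate(s) missing from panel: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  panel <- panel[order(panel$patient_id, panel$obs_day), , drop = FALSE]
  id <- panel$patient_id
  n <- nrow(panel)
  same <- id[-n] == id[-1]
  i1 <- which(same)          # left endpoint rows
  i2 <- i1 + 1L              # right endpoint rows
  dt <- (panel$obs_day[i2] - panel$obs_day[i1]) / DAYS_PER_YEAR
  from <- panel$state_num[i1]
  to <- panel$state_num[i2]
  is_death <- as.integer(panel$obs_type[i2] == "exact_death")
  Z <- if (length(covnames)) {
    as.matrix(panel[i1, covnames, drop = FALSE])
  } else {
    matrix(0, length(i1), 0)
  }
  keep <- dt > 0
  if (any(!keep & from != to)) {
    stop("zero-length interval with a state change in panel", call. = FALSE)
  }
  Z <- Z[keep, , drop = FALSE]
  dt <- dt[keep]; from <- from[keep]; to <- to[keep]
  is_death <- is_death[keep]
  pid <- id[i1][keep]
  if (anyNA(Z) || anyNA(dt)) {
    stop("non-finite covariate or time in panel", call. = FALSE)
  }
  # group identical (covariate row, interval length) combinations so each
  # matrix exponential is computed once per likelihood evaluation
  key <- do.call(paste, c(as.data.frame(cbind(Z, dt)), sep = "\r"))
  first <- !duplicated(key)
  comb <- match(key, key[first])
  list(Zu = Z[first, , drop = FALSE], dtu = dt[first],
       comb = as.integer(comb - 1L), from = as.integer(from - 1L),
       to = as.integer(to - 1L), is_death = is_death, patient_id = pid,
       n_intervals = length(dt))
}

loglik_from_intervals <- function(theta, iv, map) {
  cpp_panel_loglik(theta, iv$Zu, iv$dtu, iv$comb, iv$from, iv$to,
                   iv$is_death, map$tr_from, map$tr_to, map$q0_idx,
                   map$beta_idx, map$z_cols, map$n_states, map$death_state)
}

#' Panel log-likelihood of a multi-state model
#'
#' Sum over consecutive observation pairs of the log transition probability,
#' with covariates fixed at each interval's left endpoint. An exactly
#' observed death at the interval end contributes a density term (transition
#' to any transient state followed by the instantaneous death intensity)
#' rather than a panel probability. A zero-probability observed transition
#' yields `-Inf` with a diagnostic attribute listing the offending pairs.
#'
#' @param model An `msm_model` (its current parameter values are used).
#' @param panel Panel data frame with `patient_id`, `obs_day`, `state_num`,
#'   optionally `obs_type`, and the model's covariate columns.
#' @return The log-likelihood (scalar). Attribute `"bad_pairs"` lists
#'   zero-probability transitions if any.
#' @export
panel_loglik <- function(model, panel) {
  covnames <- model_covnames(model)
  iv <- prepare_intervals(panel, covnames, model$structure)
  map <- transition_map(model, covnames)
  contrib <- loglik_from_intervals(map$theta, iv, map)
  ll <- sum(contrib)
  if (any(!is.finite(contrib))) {
    bad <- which(!is.finite(contrib))
    attr(ll, "bad_pairs") <- data.frame(
      patient_id = iv$patient_id[bad],
      from = model$structure$states[iv$from[bad] + 1L],
      to = model$structure$states[iv$to[bad] + 1L])
  }
  ll
}

# Crude initial rates: observed apparent jumps r->s divided by person-years
# observed in r (0.5 pseudo-jumps for unobserved allowed transitions).
crude_init <- function(iv, structure) {
  states <- structure$states
  py <- tapply(iv$dtu[iv$comb + 1L], states[iv$from + 1L], sum)
  labs <- structure$labels
  out <- numeric(length(labs))
  for (k in seq_along(labs)) {
    f <- structure$allowed$from[k]; t <- structure$allowed$to[k]
    n_jump <- sum(states[iv$from + 1L] == f & states[iv$to + 1L] == t)
    pyr <- py[f]
    if (is.na(pyr) || pyr <= 0) pyr <- 1
    out[k] <- log(max(n_jump, 0.5) / pyr)
  }
  setNames(out, labs)
}

num_hessian <- function(fn, theta) {
  p <- length(theta)
  h <- 1e-4 * pmax(1, abs(theta))
  H <- matrix(0, p, p)
  f0 <- fn(theta)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    for (j in i:p) {
      ej <- numeric(p); ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / h[i]^2
      } else {
        H[i, j] <- (fn(theta + ei + ej) - fn(theta + ei - ej) -
                      fn(theta - ei + ej) + fn(theta - ei - ej)) /
          (4 * h[i] * h[j])
        H[j, i] <- H[i, j]
      }
    }
  }
  (H + t(H)) / 2
}

#' Fit the multi-state Markov model to panel data
#'
#' Maximum-likelihood estimation of baseline log transition intensities and
#' per-transition covariate effects from panel-observed state data, by
#' quasi-Newton (BFGS) optimisation of the matrix-exponential panel
#' likelihood. Baseline intensities are initialised at crude rates (observed
#' apparent jumps over person-years at risk), coefficients at zero. The
#' covariance matrix is the inverse of the numerically differenced observed
#' information at the optimum (central differences, step
#' `1e-4 * max(1, |theta|)`).
#'
#' @param panel Panel data frame (see [build_panel()] /
#'   [simulate_panel_ctmc()]): columns `patient_id`, `obs_day`, `state_num`,
#'   optionally `obs_type`, plus covariate columns.
#' @param structure An `msm_structure` (default [ms_default_structure()]).
#' @param covariates Named list of per-transition covariate names (default
#'   [ms_default_covariates()]); `NULL` for an intensities-only model.
#' @param init Optional `msm_model` supplying starting values.
#' @param control List: `maxit` (default 200), `reltol` (1e-9), `hessian`
#'   (TRUE), `trace` (0), `center` (TRUE: covariates are centred internally
#'   for optimiser conditioning and the estimates mapped back to the
#'   uncentred parameterisation, leaving coefficients and hazard ratios
#'   unchanged).
#' @return An object of class `msm_fit` with components `model` (at the
#'   estimates), `estimates`, `vcov`, `loglik`, `converged`,
#'   `n_transitions_observed`, and bookkeeping. Methods: `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `plot`, `simulate`; see also
#'   [hazard_ratios()], [predicted_probabilities()], [expected_prevalence()].
#' @export
fit_msm <- function(panel, structure = ms_default_structure(),
                    covariates = ms_default_covariates(), init = NULL,
                    control = list()) {
  ctl <- modifyList(list(maxit = 200, reltol = 1e-9, hessian = TRUE,
                         trace = 0, center = TRUE), control)
  model <- if (!is.null(init)) init else msm_model(structure, covariates)
  structure <- model$structure
  covnames <- model_covnames(model)
  iv <- prepare_intervals(panel, covnames, structure)

  states <- structure$states
  counts <- table(factor(states[iv$from + 1L], levels = states),
                  factor(states[iv$to + 1L], levels = states))
  for (k in seq_along(structure$labels)) {
    f <- structure$allowed$from[k]; t <- structure$allowed$to[k]
    if (counts[f, t] == 0) {
      warning("allowed transition ", structure$labels[k],
              " never observed; its intensity is weakly identified",
              call. = FALSE)
    }
  }

  if (is.null(init)) {
    model$log_q0[] <- crude_init(iv, structure)
  }
  map <- transition_map(model, covnames)

  # optional covariate centring: optimise on centred covariates, then map
  # the baseline log intensities back (a linear reparameterisation; the
  # coefficients are unaffected)
  z_means <- rep(0, length(covnames))
  iv_orig <- iv
  if (isTRUE(ctl$center) && length(covnames)) {
    z_means <- colMeans(iv$Zu[iv$comb + 1L, , drop = FALSE])
    iv$Zu <- sweep(iv$Zu, 2, z_means)
  }
  # theta_uncentred = A %*% theta_centred
  A <- diag(length(map$theta))
  for (k in seq_along(map$q0_idx)) {
    bi <- map$beta_idx[[k]] + 1L
    zc <- map$z_cols[[k]] + 1L
    if (length(bi)) A[map$q0_idx[k] + 1L, bi] <- -z_means[zc]
  }
  # starting values on the centred scale: shift the baselines accordingly
  theta0 <- drop(solve(A, map$theta))
  names(theta0) <- names(map$theta)

  nll <- function(theta) {
    v <- sum(loglik_from_intervals(theta, iv, map))
    if (!is.finite(v)) return(1e10)
    -v
  }
  if (nll(theta0) >= 1e10) {
    stop("log-likelihood not finite at the starting values; supply an ",
         "`init` model with crude-rate intensities", call. = FALSE)
  }
  opt <- optim(theta0, nll, method = "BFGS",
               control = list(maxit = ctl$maxit, reltol = ctl$reltol,
                              trace = ctl$trace))
  theta_cen <- opt$par
  theta_hat <- setNames(drop(A %*% theta_cen), names(map$theta))
  loglik <- -opt$value
  converged <- opt$convergence == 0 && is.finite(loglik)

  vc <- NULL
  if (isTRUE(ctl$hessian)) {
    H <- num_hessian(nll, theta_cen)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(vc))) {
      warning("observed information is singular; using pseudo-inverse",
              call. = FALSE)
      vc <- MASS::ginv(H)
    }
    vc <- A %*% vc %*% t(A)
    vc <- (vc + t(vc)) / 2
    dimnames(vc) <- list(names(theta_hat), names(theta_hat))
  }

  fit <- list(model = unpack_params(model, theta_hat),
              estimates = theta_hat, vcov = vc, loglik = loglik,
              converged = converged,
              n_transitions_observed = counts,
              n_patients = length(unique(iv$patient_id)),
              n_intervals = iv$n_intervals,
              intervals = iv_orig, covnames = covnames,
              optim = opt[c("convergence", "counts", "message")],
              call = match.call())
  class(fit) <- "msm_fit"
  fit
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Multi-state Markov model fit\n")
  cat(sprintf("  %d patients, %d observation intervals, log-likelihood %.3f%s\n",
              x$n_patients, x$n_intervals, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  Baseline intensities (per year):\n")
  q0 <- exp(x$estimates[seq_len(nrow(x$model$structure$allowed))])
  names(q0) <- x$model$structure$labels
  print(round(q0, 4))
  invisible(x)
}

#' @export
coef.msm_fit <- function(object, ...) object$estimates

#' @export
vcov.msm_fit <- function(object, ...) object$vcov

#' @export
logLik.msm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates), class = "logLik")
}

#' @export
summary.msm_fit <- function(object, ...) {
  out <- list(fit = object, hr = hazard_ratios(object))
  class(out) <- "summary.msm_fit"
  out
}

#' @export
print.summary.msm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nHazard ratios (95% Wald CI):\n")
  hr <- x$hr
  hr$`HR (95% CI)` <- fmt_est_ci(hr$hr, hr$lower, hr$upper, digits = 3)
  print(hr[, c("transition", "covariate", "HR (95% CI)")], row.names = FALSE)
  invisible(x)
}

#' Hazard ratios with Wald confidence intervals
#'
#' One row per (transition, covariate) pair: `exp(beta)` with the 95% Wald
#' interval `exp(beta +/- 1.959964 * SE)`.
#'
#' @param fit A converged `msm_fit` with a covariance matrix.
#' @return Data frame `transition`, `covariate`, `loghr`, `se`, `hr`,
#'   `lower`, `upper`.
#' @export
hazard_ratios <- function(fit) {
  stopifnot(inherits(fit, "msm_fit"))
  if (is.null(fit$vcov)) stop("fit has no covariance matrix", call. = FALSE)
  labs <- fit$model$structure$labels
  rows <- list()
  for (k in seq_along(labs)) {
    covs <- fit$model$covariate_spec[[k]]
    for (cv in covs) {
      nm <- paste0(labs[k], ":", cv)
      b <- fit$estimates[[nm]]
      se <- sqrt(fit$vcov[nm, nm])
      rows[[length(rows) + 1L]] <- data.frame(
        transition = labs[k], covariate = cv, loghr = b, se = se,
        hr = exp(b), lower = exp(b - WALD_Z * se),
        upper = exp(b + WALD_Z * se), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predicted transition probabilities with sampled confidence intervals
#'
#' Point estimates are transition probabilities at the fitted parameters for
#' a covariate profile held at given values; uncertainty comes from `n_draws`
#' samples of the full parameter vector (log intensities and coefficients)
#' from its asymptotic normal distribution, each mapped through the
#' transition-probability matrix, with percentile 95% intervals.
#'
#' @param fit A converged `msm_fit`.
#' @param profile Named covariate vector (held constant) or a
#'   piecewise-constant path data frame as in [transition_probability()].
#' @param horizons Prediction horizons in years (default 5, 10, 15).
#' @param n_draws Number of parameter draws (default 100).
#' @param seed Optional integer seed for reproducible draws.
#' @param ridge Non-negative eigenvalue floor applied to a covariance matrix
#'   that is not positive semi-definite (as can happen when some transition
#'   is weakly identified and the numerically differenced information is
#'   noisy). Off (0) by default: a non-PSD covariance is then an error.
#' @return Data frame `horizon`, `from`, `to`, `estimate`, `lower`, `upper`
#'   (probabilities), of class `msm_probs`.
#' @export
predicted_probabilities <- function(fit, profile = NULL,
                                    horizons = c(5, 10, 15), n_draws = 100,
                                    seed = NULL, ridge = 0) {
  stopifnot(inherits(fit, "msm_fit"))
  vc <- fit$vcov
  if (is.null(vc)) stop("fit has no covariance matrix", call. = FALSE)
  eg <- eigen(vc, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1e-12)) {
    if (ridge > 0) {
      eg$values <- pmax(eg$values, ridge)
      vc <- eg$vectors %*% diag(eg$values) %*% t(eg$vectors)
      dimnames(vc) <- dimnames(fit$vcov)
    } else {
      stop("covariance matrix is not positive semi-definite; consider the ",
           "`ridge` eigenvalue repair", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  vc_psd <- vc
  ev <- eigen(vc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) vc_psd <- vc + diag(-min(ev) + 1e-12, nrow(vc))
  draws <- MASS::mvrnorm(n_draws, mu = fit$estimates, Sigma = vc_psd)
  states <- fit$model$structure$states
  out <- list()
  for (h in horizons) {
    P0 <- transition_probability(fit$model, profile, 0, h)
    Pd <- array(NA_real_, c(n_draws, length(states), length(states)))
    n_failed <- 0L
    for (d in seq_len(n_draws)) {
      md <- unpack_params(fit$model, draws[d, ])
      Pdraw <- tryCatch(transition_probability(md, profile, 0, h),
                        error = function(e) NULL)
      if (is.null(Pdraw)) {
        n_failed <- n_failed + 1L
      } else {
        # numerical truncation: an extreme draw can leave [0, 1] slightly
        Pd[d, , ] <- pmin(pmax(Pdraw, 0), 1)
      }
    }
    if (n_failed > 0) {
      warning(n_failed, " of ", n_draws, " parameter draws were too ",
              "extreme to propagate (weakly identified transitions); ",
              "intervals use the remaining draws", call. = FALSE)
    }
    for (i in seq_along(states)) {
      for (j in seq_along(states)) {
        qs <- quantile(Pd[, i, j], c(0.025, 0.975), names = FALSE,
                       na.rm = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          horizon = h, from = states[i], to = states[j],
          estimate = P0[i, j], lower = qs[1], upper = qs[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("msm_probs", "data.frame")
  res
}

#' @export
predict.msm_fit <- function(object, profile = NULL, horizons = c(5, 10, 15),
                            n_draws = 100, seed = NULL, ...) {
  predicted_probabilities(object, profile, horizons, n_draws, seed)
}

#' Observed versus model-expected state prevalence
#'
#' Goodness-of-fit summary: at each grid time (years since each patient's
#' first observation) the observed prevalence carries each patient's state
#' forward from their last observation at or before that time, among
#' patients still under observation (death is terminal and persists);
#' expected prevalence averages each contributing patient's model transition
#' probability row from their first observation, using their own
#' piecewise-constant covariate path.
#'
#' @param fit An `msm_fit`.
#' @param panel The panel the model was fitted to (or comparable data).
#' @param grid Numeric vector of times in years since first observation.
#' @return Data frame of class `msm_prevalence`: `time`, `state`, `observed`,
#'   `expected`, `n_at_risk`. Has a `plot()` method.
#' @export
expected_prevalence <- function(fit, panel, grid) {
  if (!length(grid)) stop("empty prevalence grid", call. = FALSE)
  grid <- sort(unique(as.numeric(grid)))
  states <- fit$model$structure$states
  covnames <- fit$covnames
  panel <- panel[order(panel$patient_id, panel$obs_day), , drop = FALSE]
  split_panel <- split(panel, panel$patient_id)
  nG <- length(grid)
  obs_counts <- matrix(0, nG, length(states),
                       dimnames = list(NULL, states))
  exp_sum <- matrix(0, nG, length(states), dimnames = list(NULL, states))
  n_risk <- numeric(nG)
  for (pp in split_panel) {
    if (nrow(pp) < 1) next
    t0 <- pp$obs_day[1]
    tt <- (pp$obs_day - t0) / DAYS_PER_YEAR
    last_t <- tt[nrow(pp)]
    died <- pp$obs_type[nrow(pp)] == "exact_death"
    s0 <- pp$state_num[1]
    # walk the grid accumulating the matrix product along this patient's path
    P <- diag(length(states))
    cur_t <- 0
    seg <- 1L
    z_of <- function(k) {
      if (!length(covnames)) return(NULL)
      unlist(pp[k, covnames, drop = FALSE])
    }
    for (g in seq_len(nG)) {
      tg <- grid[g]
      in_risk <- tg <= last_t || died
      if (!in_risk) break
      # observed: state carried forward from last observation <= tg
      k_obs <- findInterval(min(tg, last_t), tt)
      obs_counts[g, pp$state_num[k_obs]] <-
        obs_counts[g, pp$state_num[k_obs]] + 1
      # expected: advance the product from cur_t to tg
      while (cur_t < tg) {
        seg_end <- if (seg < nrow(pp)) tt[seg + 1L] else Inf
        e <- min(seg_end, tg)
        if (e > cur_t) {
          Q <- intensity_matrix(fit$model, z_of(seg))
          P <- P %*% cpp_expm(Q * (e - cur_t))
          cur_t <- e
        }
        if (cur_t >= seg_end && seg < nrow(pp)) seg <- seg + 1L
      }
      exp_sum[g, ] <- exp_sum[g, ] + P[s0, ]
      n_risk[g] <- n_risk[g] + 1
    }
  }
  keep <- n_risk > 0
  out <- do.call(rbind, lapply(which(keep), function(g) {
    data.frame(time = grid[g], state = states,
               observed = obs_counts[g, ] / n_risk[g],
               expected = exp_sum[g, ] / n_risk[g],
               n_at_risk = n_risk[g], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("msm_prevalence", "data.frame")
  out
}

#' @export
plot.msm_prevalence <- function(x, ...) {
  states <- unique(x$state)
  old <- graphics::par(mfrow = c(1, length(states)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in states) {
    sub <- x[x$state == s, ]
    graphics::plot(sub$time, sub$observed, type = "s", ylim = c(0, 1),
                   xlab = "Years since first observation",
                   ylab = "Prevalence", main = s)
    graphics::lines(sub$time, sub$expected, lty = 2, col = 2)
  }
  invisible(x)
}

#' @export
plot.msm_fit <- function(x, panel, grid = NULL, ...) {
  if (is.null(grid)) {
    span <- max(tapply(panel$obs_day, panel$patient_id,
                       function(d) diff(range(d)))) / DAYS_PER_YEAR
    grid <- seq(0, span, length.out = 21)
  }
  plot(expected_prevalence(x, panel, grid), ...)
}

#' @export
simulate.msm_fit <- function(object, nsim = 1, seed = NULL, n = NULL,
                             t_max = 10, dt_obs = 1, ...) {
  if (is.null(n)) n <- object$n_patients
  covnames <- object$covnames
  iv <- object$intervals
  Zpool <- iv$Zu[iv$comb + 1L, , drop = FALSE][!duplicated(iv$patient_id), ,
                                               drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  cov_fn <- function(i) {
    z <- if (length(covnames)) {
      Zpool[sample.int(nrow(Zpool), 1), , drop = TRUE]
    } else numeric(0)
    as.data.frame(c(list(time = 0), as.list(z)))
  }
  simulate_panel_ctmc(object$model, covariate_fn = cov_fn, n = n,
                      schedule = seq(0, t_max, by = dt_obs), seed = NULL)
}
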