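# Generalised estimating equations for Poisson counts with a log link and
# log-exposure offset. Working correlation: independence, exchangeable, or
# unstructured (requires clusters observed on a common, aligned set of time
# bins). Robust (sandwich) covariance throughout. Written here because the
# estimating-equation machinery is part of the package's estimator surface.

gee_working_cor <- function(resid_std, id, timeidx, corstr, phi, p) {
  ids <- unique(id)
  if (corstr == "independence") {
    return(list(type = "independence", alpha = NULL, R = NULL))
  }
  if (corstr == "exchangeable") {
    num <- 0; den <- 0
    for (g in ids) {
      r <- resid_std[id == g]
      ni <- length(r)
      if (ni < 2) next
      num <- num + (sum(r)^2 - sum(r^2)) / 2
      den <- den + ni * (ni - 1) / 2
    }
    alpha <- if (den > p) num / (phi * (den - p)) else 0
    alpha <- max(min(alpha, 0.95), -0.95)
    return(list(type = "exchangeable", alpha = alpha, R = NULL))
  }
  # unstructured: average cross-products per (bin j, bin k)
  Tn <- max(timeidx)
  S <- matrix(0, Tn, Tn)
  N <- matrix(0, Tn, Tn)
  for (g in ids) {
    sel <- id == g
    r <- resid_std[sel]
    tt <- timeidx[sel]
    S[tt, tt] <- S[tt, tt] + outer(r, r)
    N[tt, tt] <- N[tt, tt] + 1
  }
  R <- S / (phi * pmax(N - p, 1))
  diag(R) <- 1
  R[N == 0] <- 0
  # ensure positive definiteness of the working matrix
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-6)
  R <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
  d <- sqrt(diag(R))
  R <- R / outer(d, d)
  list(type = "unstructured", alpha = NULL, R = R)
}

#' GEE Poisson regression with log link and offset
#'
#' Solves the generalised estimating equations for clustered Poisson counts:
#' log mean = `X beta + offset`, cluster-robust sandwich covariance, and a
#' selectable working correlation (`"independence"`, `"exchangeable"`, or
#' `"unstructured"`). Unstructured correlation needs every cluster's rows
#' aligned on a shared time-bin index; if bins are unbalanced across
#' clusters in a way that leaves some correlation entries unestimable, the
#' solver falls back to exchangeable with a warning. With the independence
#' working correlation and one row per cluster, the estimates coincide with
#' the Poisson GLM.
#'
#' @param y Integer response counts.
#' @param X Model matrix (including intercept column).
#' @param offset Numeric offset (e.g. log exposure), length of `y`.
#' @param id Cluster identifier.
#' @param timeidx Integer time-bin index per row (needed for unstructured).
#' @param corstr Working correlation structure.
#' @param maxit,tol Iteration control.
#' @return List with `coefficients`, `vcov_robust`, `se`, `alpha` or `R`
#'   (estimated working correlation), `phi` (dispersion), `corstr`,
#'   `converged`, `n_clusters`; classed `gee_fit`.
#' @export
gee_poisson <- function(y, X, offset = rep(0, length(y)), id,
                        timeidx = NULL,
                        corstr = c("independence", "exchangeable",
                                   "unstructured"),
                        maxit = 100, tol = 1e-10) {
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  p <- ncol(X)
  id <- as.character(id)
  if (is.null(timeidx)) {
    timeidx <- stats::ave(seq_along(y), id, FUN = seq_along)
  }
  timeidx <- as.integer(timeidx)
  if (corstr == "unstructured") {
    # alignment check: no duplicate bins within a cluster
    dup <- tapply(timeidx, id, anyDuplicated)
    if (any(unlist(dup) > 0)) {
      warning("duplicate time bins within a cluster; falling back to ",
              "exchangeable working correlation", call. = FALSE)
      corstr <- "exchangeable"
    } else {
      # a bin pair never observed jointly makes R unestimable
      Tn <- max(timeidx)
      joint <- matrix(0L, Tn, Tn)
      for (g in unique(id)) {
        tt <- timeidx[id == g]
        joint[tt, tt] <- joint[tt, tt] + 1L
      }
      need <- table(timeidx)
      present <- as.integer(names(need))
      if (any(joint[present, present] == 0)) {
        warning("time bins unbalanced across clusters; falling back to ",
                "exchangeable working correlation", call. = FALSE)
        corstr <- "exchangeable"
      }
    }
  }

  beta <- coef(glm.fit(X, y, offset = offset, family = poisson()))
  ids <- unique(id)
  converged <- FALSE
  wc <- list(type = "independence", alpha = NULL, R = NULL)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    rstd <- (y - mu) / sqrt(mu)
    phi <- sum(rstd^2) / max(length(y) - p, 1)
    wc <- gee_working_cor(rstd, id, timeidx, corstr, phi, p)
    U <- numeric(p)
    Hm <- matrix(0, p, p)
    for (g in ids) {
      sel <- which(id == g)
      Xi <- X[sel, , drop = FALSE]
      mui <- mu[sel]
      yi <- y[sel]
      ni <- length(sel)
      Ri <- switch(wc$type,
                   independence = diag(ni),
                   exchangeable = {
                     R <- matrix(wc$alpha, ni, ni); diag(R) <- 1; R
                   },
                   unstructured = wc$R[timeidx[sel], timeidx[sel],
                                       drop = FALSE])
      A_half <- sqrt(mui)
      Vi <- (Ri * outer(A_half, A_half))  # phi cancels in the update
      Vinv <- solve(Vi)
      Di <- Xi * mui
      U <- U + drop(t(Di) %*% Vinv %*% (yi - mui))
      Hm <- Hm + t(Di) %*% Vinv %*% Di
    }
    delta <- solve(Hm, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  # sandwich covariance at the solution
  eta <- drop(X %*% beta) + offset
  mu <- exp(eta)
  B <- matrix(0, p, p)
  Hm <- matrix(0, p, p)
  for (g in ids) {
    sel <- which(id == g)
    Xi <- X[sel, , drop = FALSE]
    mui <- mu[sel]
    yi <- y[sel]
    ni <- length(sel)
    Ri <- switch(wc$type,
                 independence = diag(ni),
                 exchangeable = {
                   R <- matrix(wc$alpha, ni, ni); diag(R) <- 1; R
                 },
                 unstructured = wc$R[timeidx[sel], timeidx[sel],
                                     drop = FALSE])
    A_half <- sqrt(mui)
    Vinv <- solve(Ri * outer(A_half, A_half))
    Di <- Xi * mui
    gi <- drop(t(Di) %*% Vinv %*% (yi - mui))
    B <- B + outer(gi, gi)
    Hm <- Hm + t(Di) %*% Vinv %*% Di
  }
  Hinv <- solve(Hm)
  vc <- Hinv %*% B %*% Hinv
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 vcov_robust = vc, se = sqrt(diag(vc)),
                 alpha = wc$alpha, R = wc$R, phi = phi, corstr = corstr,
                 converged = converged, n_clusters = length(ids)),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE Poisson fit (", x$corstr, " working correlation, ",
      x$n_clusters, " clusters)\n", sep = "")
  tab <- data.frame(term = names(x$coefficients),
                    estimate = x$coefficients, se = x$se)
  tab$`ratio (95% CI)` <- fmt_est_ci(exp(tab$estimate),
                                     exp(tab$estimate - WALD_Z * tab$se),
                                     exp(tab$estimate + WALD_Z * tab$se),
                                     digits = 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' GEE relapse-rate trajectories by phenotype group
#'
#' Fits the relapse-trajectory model to the age-binned count table from
#' [relapse_age_table()]: Poisson counts with log-exposure offset, and
#' explanatory terms for age (polynomial of selectable degree, default
#' linear), sex, phenotype group, and the group-by-age interaction, with the
#' patient as the cluster and an unstructured working correlation by
#' default. Marginal adjusted annualised relapse rates per group are
#' predicted at specified ages.
#'
#' @param tab Output of [relapse_age_table()] (columns `patient_id`,
#'   `group`, `sex_female`, `age`, `count`, `exposure_years`).
#' @param age_degree Polynomial degree for the age effect (default 1).
#' @param corstr Working correlation (default `"unstructured"`).
#' @param predict_ages Ages at which adjusted ARRs are predicted (default
#'   the quartiles of the observed ages).
#' @return List with the `gee_fit`, the adjusted rate table `arr`
#'   (`group`, `sex`, `age`, `arr`), and the incidence-rate-ratio table
#'   `irr` comparing groups at the mean age; classed `gee_arr`.
#' @export
gee_poisson_arr <- function(tab, age_degree = 1,
                            corstr = "unstructured",
                            predict_ages = NULL) {
  stopifnot(all(c("patient_id", "group", "sex_female", "age", "count",
                  "exposure_years") %in% names(tab)))
  tab <- tab[order(tab$patient_id, tab$age), , drop = FALSE]
  tab$group <- factor(tab$group)
  age_c <- tab$age - mean(tab$age)
  Xl <- list(`(Intercept)` = rep(1, nrow(tab)))
  for (d in seq_len(age_degree)) Xl[[paste0("age", d)]] <- age_c^d
  Xl$sex_female <- tab$sex_female
  glev <- levels(tab$group)
  for (g in glev[-1]) Xl[[paste0("group", g)]] <- as.numeric(tab$group == g)
  for (g in glev[-1]) {
    Xl[[paste0("group", g, ":age")]] <- as.numeric(tab$group == g) * age_c
  }
  X <- do.call(cbind, Xl)
  colnames(X) <- names(Xl)
  timeidx <- tab$age - min(tab$age) + 1L
  fit <- gee_poisson(tab$count, X, offset = log(tab$exposure_years),
                     id = tab$patient_id, timeidx = timeidx,
                     corstr = corstr)
  if (is.null(predict_ages)) {
    predict_ages <- unname(round(quantile(tab$age, c(0.25, 0.5, 0.75))))
  }
  newrow <- function(g, sexf, a) {
    v <- setNames(numeric(ncol(X)), colnames(X))
    v["(Intercept)"] <- 1
    ac <- a - mean(tab$age)
    for (d in seq_len(age_degree)) v[paste0("age", d)] <- ac^d
    v["sex_female"] <- sexf
    if (g != glev[1]) {
      v[paste0("group", g)] <- 1
      v[paste0("group", g, ":age")] <- ac
    }
    v
  }
  arr <- do.call(rbind, lapply(glev, function(g) {
    do.call(rbind, lapply(c(0, 1), function(sexf) {
      do.call(rbind, lapply(predict_ages, function(a) {
        v <- newrow(g, sexf, a)
        est <- sum(v * fit$coefficients)
        se <- sqrt(drop(t(v) %*% fit$vcov_robust %*% v))
        data.frame(group = g, sex = if (sexf == 1) "female" else "male",
                   age = a, arr = exp(est),
                   lower = exp(est - WALD_Z * se),
                   upper = exp(est + WALD_Z * se))
      }))
    }))
  }))
  rownames(arr) <- NULL
  irr <- do.call(rbind, lapply(glev[-1], function(g) {
    v <- newrow(g, 0, round(mean(tab$age))) - newrow(glev[1], 0,
                                                     round(mean(tab$age)))
    est <- sum(v * fit$coefficients)
    se <- sqrt(drop(t(v) %*% fit$vcov_robust %*% v))
    data.frame(comparison = paste(g, "vs", glev[1]), irr = exp(est),
               lower = exp(est - WALD_Z * se),
               upper = exp(est + WALD_Z * se))
  }))
  rownames(irr) <- NULL
  structure(list(fit = fit, arr = arr, irr = irr), class = "gee_arr")
}

#' @export
print.gee_arr <- function(x, ...) {
  cat("Adjusted annualised relapse rates (GEE Poisson):\n")
  a <- x$arr
  a$`ARR (95% CI)` <- fmt_est_ci(a$arr, a$lower, a$upper, digits = 3)
  print(a[, c("group", "sex", "age", "ARR (95% CI)")], row.names = FALSE)
  invisible(x)
}
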