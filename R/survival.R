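# Lung-transplant-free survival: endpoint construction, Kaplan-Meier
# product-limit curves with Greenwood variance, the log-rank test, and a
# Newton-Raphson Cox partial-likelihood fitter with Efron (default) or
# Breslow tie handling. survival::coxph/survfit/survdiff serve as independent
# cross-checks in the test suite, never as the computation path.

#' Build transplant-free survival records from a cohort
#'
#' The composite endpoint counts both death and lung transplantation as
#' events; subjects alive at last follow-up are censored. Records with
#' non-positive follow-up are dropped with a message.
#'
#' @param cohort Cohort data frame (needs `patient_id`, `followup_months`,
#'   `status`; covariate columns are carried through when present).
#' @param cutoff Density cutoff used to derive the `p16_high` covariate when
#'   a `density` column is present and `p16_high` is not.
#' @return Data frame with `patient_id`, `time` (months), `event` (logical)
#'   and available covariates (`p16_high`, `antifibrotic`, `age`, `sex_male`,
#'   `bmi`, `fvc_pct`, `dlco_pct`).
#' @export
ltx_free_records <- function(cohort, cutoff = 2.1) {
  keep <- !is.na(cohort$followup_months) & cohort$followup_months > 0
  if (any(!keep)) {
    message(sprintf("dropping %d record(s) with non-positive or missing follow-up",
                    sum(!keep)))
  }
  cohort <- cohort[keep, , drop = FALSE]
  rec <- data.frame(patient_id = cohort$patient_id,
                    time = cohort$followup_months,
                    event = cohort$status %in% c("died", "transplanted"),
                    stringsAsFactors = FALSE)
  if ("p16_high" %in% names(cohort)) {
    rec$p16_high <- as.numeric(cohort$p16_high)
  } else if ("density" %in% names(cohort)) {
    rec$p16_high <- as.numeric(classify_density(cohort$density, cutoff) == "high")
  }
  if ("treatment" %in% names(cohort)) {
    rec$antifibrotic <- as.numeric(cohort$treatment == "antifibrotic")
  } else if ("antifibrotic" %in% names(cohort)) {
    rec$antifibrotic <- as.numeric(cohort$antifibrotic)
  }
  if ("age" %in% names(cohort)) rec$age <- cohort$age
  if ("sex" %in% names(cohort)) rec$sex_male <- as.numeric(cohort$sex == "M")
  for (f in c("bmi", "fvc_pct", "dlco_pct")) {
    if (f %in% names(cohort)) rec[[f]] <- cohort[[f]]
  }
  rec
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records Data frame with `time` and `event` columns.
#' @return A `km_curve` list: `time` (distinct event times), `n_risk`,
#'   `n_events`, `survival` and Greenwood standard errors.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1, all(records$time > 0))
  time <- records$time
  event <- as.logical(records$event)
  times <- sort(unique(time[event]))
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_ev <- vapply(times, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - n_ev / n_risk)
  # Greenwood: var(S) = S^2 * sum d / (n (n - d))
  gw <- cumsum(n_ev / (n_risk * (n_risk - n_ev)))
  se <- surv * sqrt(gw)
  se[!is.finite(se)] <- NA_real_
  structure(list(time = times, n_risk = n_risk, n_events = n_ev,
                 survival = surv, greenwood_se = se),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km A [km_estimate()] result.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    idx <- which(km$time <= ti)
    if (length(idx)) km$survival[max(idx)] else 1
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events in group A over pooled distinct event
#' times, with the hypergeometric variance; 1 degree of freedom.
#'
#' @param group_a,group_b Data frames with `time` and `event` columns.
#' @return List with `statistic`, `p_value`, `observed`, `expected`,
#'   `variance`.
#' @export
logrank_test <- function(group_a, group_b) {
  stopifnot(nrow(group_a) >= 1, nrow(group_b) >= 1)
  ta <- group_a$time; ea <- as.logical(group_a$event)
  tb <- group_b$time; eb <- as.logical(group_b$event)
  times <- sort(unique(c(ta[ea], tb[eb])))
  if (length(times) == 0) {
    stop("log-rank test undefined: no events in either group", call. = FALSE)
  }
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t); n <- n1 + n2
    d1 <- sum(ta == t & ea); d <- d1 + sum(tb == t & eb)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E, variance = V)
}

# --- Cox proportional hazards ---------------------------------------------

# Partial log-likelihood, gradient and information at beta.
# Fast vectorized path for untied event times; general per-event-time loop
# with Efron or Breslow correction otherwise.
cox_lp_parts <- function(beta, time, event, X, ties = "efron") {
  n <- length(time)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)  # guard exp overflow; the shift cancels exactly
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)  # risk set = prefix in this order
  tS <- time[ord]; eS <- event[ord]; wS <- w[ord]
  XS <- X[ord, , drop = FALSE]
  etaS <- eta[ord]

  ev_times <- tS[eS]
  tied <- anyDuplicated(ev_times) > 0

  S0 <- cumsum(wS)
  S1 <- apply(XS * wS, 2, cumsum)
  if (p == 1) S1 <- matrix(S1, ncol = 1)
  # S2 stored as lower-triangle columns (p small in this setting)
  pairs <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  S2 <- sapply(seq_len(nrow(pairs)), function(k) {
    cumsum(XS[, pairs[k, 1]] * XS[, pairs[k, 2]] * wS)
  })
  if (nrow(pairs) == 1) S2 <- matrix(S2, ncol = 1)
  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(pairs[, 1], pairs[, 2])] <- v
    M[cbind(pairs[, 2], pairs[, 1])] <- v
    M
  }

  if (!tied) {
    # each event's risk set ends at its own (last tied-time) position; with
    # censoring ties at an event time, subjects censored at t stay at risk
    idx <- which(eS)
    # include any rows with the same time value below the event row
    last_at_time <- vapply(idx, function(i) {
      j <- as.integer(i)
      while (j < n && tS[j + 1] == tS[i]) j <- j + 1L
      j
    }, integer(1))
    s0 <- S0[last_at_time]
    mu <- S1[last_at_time, , drop = FALSE] / s0
    ll <- sum(etaS[idx]) - sum(log(s0))
    grad <- colSums(XS[idx, , drop = FALSE]) - colSums(mu)
    s2 <- S2[last_at_time, , drop = FALSE] / s0
    info <- unpack(colSums(s2)) - t(mu) %*% mu
    return(list(loglik = ll, grad = grad, info = info))
  }

  # general tied-data loop; risk-set prefix ends precomputed from the
  # run-length structure of the descending-sorted times
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  runs <- rle(tS)
  run_ends <- cumsum(runs$lengths)
  ut <- unique(tS[eS])
  prefix_end <- run_ends[match(ut, runs$values)]
  D_by_time <- split(which(eS), match(tS[eS], ut))
  for (k in seq_along(ut)) {
    at_risk_last <- prefix_end[k]
    D <- D_by_time[[k]]
    d <- length(D)
    s0R <- S0[at_risk_last]
    s1R <- S1[at_risk_last, ]
    s2R <- unpack(S2[at_risk_last, ])
    wD <- wS[D]
    s0D <- sum(wD)
    s1D <- colSums(XS[D, , drop = FALSE] * wD)
    s2D <- t(XS[D, , drop = FALSE] * wD) %*% XS[D, , drop = FALSE]
    ll <- ll + sum(etaS[D])
    grad <- grad + colSums(XS[D, , drop = FALSE])
    for (l in seq_len(d) - 1) {
      frac <- if (ties == "efron") l / d else 0
      s0l <- s0R - frac * s0D
      s1l <- s1R - frac * s1D
      s2l <- s2R - frac * s2D
      mul <- s1l / s0l
      ll <- ll - log(s0l)
      grad <- grad - mul
      info <- info + s2l / s0l - tcrossprod(mul)
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the partial likelihood with Efron tie
#' correction by default (Breslow available for cross-checking). Convergence
#' when the maximal absolute score component falls below `tol` or after
#' `max_iter` iterations; divergent coefficient paths (monotone likelihood /
#' perfect separation) are flagged, not silently returned.
#'
#' @param records Data frame with `time`, `event` and covariate columns.
#' @param covariates Character vector naming covariate columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Score convergence tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return A `cox_fit` list: `coefficients`, `hazard_ratios`, `se`,
#'   `wald_ci_95` (HR scale), `p_values`, `log_partial_likelihood`,
#'   `n`, `n_events`, `converged`, `n_iterations`, `ties`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 50) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(records)))
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    stop(sprintf("covariate(s) not in records: %s",
                 paste(missing_cov, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(records[, covariates, drop = FALSE])
  if (anyNA(X) || anyNA(records$time) || anyNA(records$event)) {
    stop("missing values are not allowed in survival model fits", call. = FALSE)
  }
  const <- covariates[apply(X, 2, function(x) length(unique(x)) < 2)]
  if (length(const)) {
    stop(sprintf("constant covariate(s): %s", paste(const, collapse = ", ")),
         call. = FALSE)
  }
  time <- records$time
  event <- as.logical(records$event)
  if (sum(event) < 2) stop("at least 2 events required", call. = FALSE)

  p <- ncol(X)
  beta <- numeric(p)
  parts <- cox_lp_parts(beta, time, event, X, ties)
  converged <- FALSE
  diverged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(parts$info, parts$grad),
                     error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    new_beta <- beta + step
    new_parts <- cox_lp_parts(new_beta, time, event, X, ties)
    halvings <- 0
    while (new_parts$loglik < parts$loglik - 1e-12 && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_parts <- cox_lp_parts(new_beta, time, event, X, ties)
      halvings <- halvings + 1
    }
    beta <- new_beta
    parts <- new_parts
    if (any(abs(beta) > 20)) { diverged <- TRUE; break }
    if (max(abs(parts$grad)) < tol) { converged <- TRUE; break }
  }
  if (diverged) {
    warning("Cox fit did not converge (possible monotone likelihood / separation)",
            call. = FALSE)
  }
  vcov <- tryCatch(solve(parts$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- beta / se
  names(beta) <- names(se) <- covariates
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- covariates
  structure(list(coefficients = beta,
                 hazard_ratios = exp(beta),
                 se = se,
                 wald_ci_95 = ci,
                 p_values = 2 * stats::pnorm(-abs(z)),
                 log_partial_likelihood = parts$loglik,
                 n = length(time),
                 n_events = sum(event),
                 converged = converged && !diverged,
                 n_iterations = iter,
                 ties = ties),
            class = "cox_fit")
}

#' Cox partial log-likelihood at a given coefficient vector
#'
#' Exposed for likelihood-based diagnostics and oracle tests.
#'
#' @inheritParams cox_fit
#' @param beta Coefficient vector.
#' @return Scalar partial log-likelihood (up to an additive constant shared
#'   across `beta` values for the same data).
#' @export
cox_loglik <- function(beta, records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(records[, covariates, drop = FALSE])
  cox_lp_parts(beta, records$time, as.logical(records$event), X, ties)$loglik
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients,
                    HR = x$hazard_ratios,
                    lower95 = x$wald_ci_95[, "lower"],
                    upper95 = x$wald_ci_95[, "upper"],
                    p = x$p_values)
  cat(sprintf("Cox proportional hazards (%s ties), %d subjects, %d events%s\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(tab, 4))
  invisible(x)
}
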