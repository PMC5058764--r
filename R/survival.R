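# Kaplan-Meier, log-rank and Cox proportional hazards (Breslow ties),
# implemented directly so the recurrence analyses are self-contained and can
# be validated against brute-force oracles.

surv_inputs <- function(data, time, event) {
  t <- dplyr::pull(data, {{ time }})
  e <- as_flag(dplyr::pull(data, {{ event }}))
  check_numeric(t, "time", min = 0)
  if (anyNA(e)) stop_tpsad("`event` contains missing values.", "tpsad_validation_error")
  list(time = t, event = e)
}

rev_cumsum <- function(v) rev(cumsum(rev(v)))

#' Kaplan-Meier curve
#'
#' Product-limit estimate of event-free survival. Censored-only times change
#' the at-risk counts but not the estimate.
#'
#' @param data Data frame of one row per subject.
#' @param time Column of follow-up times (months, >= 0); unquoted.
#' @param event Column of event indicators (logical or 0/1); unquoted.
#' @return An object of class `km_curve`. `tidy()` returns the step table
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `survival`); `autoplot()`
#'   draws the step function.
#' @export
km_curve <- function(data, time = time, event = event) {
  s <- surv_inputs(data, {{ time }}, {{ event }})
  if (length(s$time) < 1) stop_tpsad("Need at least one subject.", "tpsad_validation_error")
  n <- length(s$time)
  steps <- tibble::tibble(time = s$time, event = s$event) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(n_event = sum(.data$event), n_censor = sum(!.data$event), .groups = "drop") |>
    dplyr::arrange(.data$time) |>
    dplyr::mutate(
      n_risk = n - dplyr::lag(cumsum(.data$n_event + .data$n_censor), default = 0L),
      survival = cumprod(1 - .data$n_event / .data$n_risk)
    ) |>
    dplyr::select("time", "n_risk", "n_event", "n_censor", "survival")
  structure(list(steps = steps, n = n, n_events = sum(s$event)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: %d subjects, %d events, %d distinct times>\n",
              x$n, x$n_events, nrow(x$steps)))
  print(x$steps, n = 6)
  invisible(x)
}

#' @rdname km_curve
#' @param x A `km_curve` object.
#' @param ... Unused.
#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) x$steps

#' @rdname km_curve
#' @param object A `km_curve` object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object$steps[, c("time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Event-free survival") +
    ggplot2::theme_minimal()
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square comparing the event
#' experience of two or more groups, with `groups - 1` degrees of freedom.
#'
#' @inheritParams km_curve
#' @param group Column of group labels; unquoted. At least two non-empty
#'   groups are required.
#' @return An object of class `logrank_test` with `statistic`, `df`,
#'   `p_value` and a per-group observed/expected table. `glance()` returns a
#'   one-row tibble.
#' @export
logrank_test <- function(data, time = time, event = event, group = group) {
  s <- surv_inputs(data, {{ time }}, {{ event }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2) stop_tpsad("Log-rank needs at least two groups.", "tpsad_validation_error")

  et <- sort(unique(s$time[s$event]))
  O <- E <- stats::setNames(numeric(k), levels(g))
  V <- matrix(0, k - 1, k - 1)
  for (tt in et) {
    at <- s$time >= tt
    n_tot <- sum(at)
    nj <- tabulate(g[at], nbins = k)
    dj <- tabulate(g[s$event & s$time == tt], nbins = k)
    d <- sum(dj)
    O <- O + dj
    E <- E + d * nj / n_tot
    if (n_tot > 1) {
      p <- (nj / n_tot)[seq_len(k - 1)]
      V <- V + d * (n_tot - d) / (n_tot - 1) * (diag(p, nrow = k - 1) - tcrossprod(p))
    }
  }
  diff <- (O - E)[seq_len(k - 1)]
  chi2 <- drop(t(diff) %*% safe_solve(V, diff))
  structure(
    list(statistic = chi2, df = k - 1,
         p_value = stats::pchisq(chi2, k - 1, lower.tail = FALSE),
         table = tibble::tibble(group = levels(g), observed = as.numeric(O),
                                expected = as.numeric(E))),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

# Breslow partial-likelihood pieces at a given beta; data pre-sorted by time.
cox_pieces <- function(beta, t, e, X) {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  first <- !duplicated(t)
  grp <- cumsum(first)
  gidx <- which(first)
  S0g <- rev_cumsum(w)[gidx]
  S1g <- apply(X, 2, function(col) rev_cumsum(w * col))[gidx, , drop = FALSE]
  idx <- which(e)
  gi <- grp[idx]
  S0e <- S0g[gi]
  S1e <- S1g[gi, , drop = FALSE]
  xbar <- S1e / S0e
  loglik <- sum(eta[idx] - log(S0e))
  U <- colSums(X[idx, , drop = FALSE] - xbar)
  I <- matrix(0, p, p)
  for (a in seq_len(p)) {
    for (b in a:p) {
      S2ab <- rev_cumsum(w * X[, a] * X[, b])[gidx][gi]
      I[a, b] <- I[b, a] <- sum(S2ab / S0e - xbar[, a] * xbar[, b])
    }
  }
  list(loglik = loglik, U = U, I = I)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with step
#' halving. Convergence is declared when every component of the score is
#' below `tol` (default 1e-8), up to `max_iter` (default 50) iterations.
#' Wald 95% confidence intervals use z = 1.959964. A monotone likelihood
#' (perfect separation) or failure to converge is flagged on the fit and
#' raised as a warning, never silently ignored.
#'
#' @inheritParams km_curve
#' @param covariates Character vector of covariate column names; numeric or
#'   logical/0-1 columns, none constant.
#' @param ties Tie handling; only `"breslow"` is implemented.
#' @param max_iter,tol Newton-Raphson controls.
#' @return An object of class `cox_fit`. `tidy()` gives per-term estimates
#'   (log hazard scale), standard errors, hazard ratios with 95% CI and Wald
#'   p-values; `glance()` gives fit-level summaries including the score test
#'   at beta = 0; `autoplot()` draws a forest plot of hazard ratios.
#' @export
cox_fit <- function(data, covariates, time = time, event = event,
                    ties = "breslow", max_iter = 50, tol = 1e-8) {
  ties <- match.arg(ties)
  s <- surv_inputs(data, {{ time }}, {{ event }})
  check_columns(data, covariates, "`data`")
  X <- as.matrix(as.data.frame(lapply(data[covariates], function(col) {
    if (is.logical(col)) as.numeric(col) else col
  })))
  if (!is.numeric(X) || anyNA(X)) {
    stop_tpsad("Covariates must be numeric (or logical) and complete.", "tpsad_validation_error")
  }
  if (sum(s$event) < ncol(X)) {
    stop_tpsad("Fewer events than covariates; the model is not identifiable.", "tpsad_validation_error")
  }
  csd <- apply(X, 2, stats::sd)
  if (any(csd == 0)) {
    stop_tpsad(sprintf("Constant covariate(s): %s.",
                       paste(covariates[csd == 0], collapse = ", ")), "tpsad_validation_error")
  }

  ord <- order(s$time)
  t <- s$time[ord]; e <- s$event[ord]; X <- X[ord, , drop = FALSE]
  p <- ncol(X)
  beta <- rep(0, p)

  pieces <- cox_pieces(beta, t, e, X)
  loglik_null <- pieces$loglik
  score_chisq <- sum(pieces$U * drop(safe_solve(pieces$I, pieces$U)))

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(pieces$U)) < tol) { converged <- TRUE; break }
    delta <- drop(safe_solve(pieces$I, pieces$U))
    # step halving if the proposal decreases the partial likelihood
    step <- 1
    repeat {
      cand <- cox_pieces(beta + step * delta, t, e, X)
      if (cand$loglik >= pieces$loglik - 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    beta <- beta + step * delta
    pieces <- cand
  }
  if (!converged && max(abs(pieces$U)) < tol) converged <- TRUE
  monotone <- any(abs(beta) > 15)
  if (!converged || monotone) {
    warn(paste0("Cox fit did not converge cleanly",
                if (monotone) " (monotone likelihood / perfect separation suspected)",
                "; inspect `converged` before use."))
    converged <- FALSE
  }

  se <- sqrt(diag(safe_solve(pieces$I)))
  z <- stats::qnorm(0.975)
  coef_tbl <- tibble::tibble(
    term = covariates,
    estimate = beta,
    std_error = se,
    hazard_ratio = exp(beta),
    conf_low = exp(beta - z * se),
    conf_high = exp(beta + z * se),
    statistic = beta / se,
    p_value = 2 * stats::pnorm(-abs(beta / se))
  )
  structure(
    list(coefficients = coef_tbl, loglik = pieces$loglik, loglik_null = loglik_null,
         n = length(t), n_events = sum(e), iterations = iter, converged = converged,
         score_chisq = score_chisq, score_df = p, ties = ties),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): %d subjects, %d events%s\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$coefficients)
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `cox_fit` object.
#' @param ... Unused.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) x$coefficients

#' @rdname cox_fit
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, loglik = x$loglik, loglik_null = x$loglik_null,
    iterations = x$iterations, converged = x$converged,
    score_chisq = x$score_chisq, score_df = x$score_df,
    score_p = stats::pchisq(x$score_chisq, x$score_df, lower.tail = FALSE)
  )
}

#' @rdname cox_fit
#' @param object A `cox_fit` object.
#' @method autoplot cox_fit
#' @export
autoplot.cox_fit <- function(object, ...) {
  df <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hazard_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Quintile strata
#'
#' Assigns each value to one of five strata cut at the 20/40/60/80th
#' percentiles (linear interpolation between order statistics); a value equal
#' to a cut point goes to the lower stratum. If cut points coincide the
#' collapsed strata are merged with a warning (all-equal input yields a
#' single stratum).
#'
#' @param values Numeric vector with at least 5 finite values.
#' @return Integer strata labels (1 = lowest).
#' @export
quintile_strata <- function(values) {
  check_numeric(values, "values")
  if (sum(is.finite(values)) < 5) {
    stop_tpsad("Need at least 5 finite values for quintiles.", "tpsad_validation_error")
  }
  qs <- stats::quantile(values, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  breaks <- unique(qs)
  if (length(breaks) < 4) {
    warn("Quintile cut points coincide; collapsed strata were merged.")
  }
  as.integer(cut(values, breaks = c(-Inf, breaks, Inf), labels = FALSE, right = TRUE))
}

#' Two-group or multi-group location comparison
#'
#' Two-sided pooled-variance Student t-test for two groups; one-way
#' fixed-effects ANOVA (equal variances) for three or more.
#'
#' @param data Data frame.
#' @param value Numeric outcome column; unquoted.
#' @param group Grouping column; unquoted.
#' @param test `"auto"` (default: t-test for 2 groups, ANOVA otherwise),
#'   `"ttest"` or `"anova"`.
#' @return A one-row tibble: `method`, `statistic`, `df1`, `df2`, `p_value`,
#'   `n_groups`.
#' @export
group_compare <- function(data, value, group, test = c("auto", "ttest", "anova")) {
  test <- match.arg(test)
  v <- dplyr::pull(data, {{ value }})
  g <- droplevels(factor(dplyr::pull(data, {{ group }})))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2 || any(table(g) < 2)) {
    stop_tpsad("Need >= 2 groups with >= 2 values each.", "tpsad_validation_error")
  }
  if (test == "auto") test <- if (k == 2) "ttest" else "anova"
  if (test == "ttest") {
    if (k != 2) stop_tpsad("t-test requires exactly 2 groups.", "tpsad_validation_error")
    ht <- stats::t.test(v ~ g, var.equal = TRUE)
    tibble::tibble(method = "Student t (pooled)", statistic = unname(ht$statistic),
                   df1 = 1, df2 = unname(ht$parameter), p_value = ht$p.value, n_groups = 2L)
  } else {
    ht <- stats::oneway.test(v ~ g, var.equal = TRUE)
    tibble::tibble(method = "One-way ANOVA", statistic = unname(ht$statistic),
                   df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
                   p_value = ht$p.value, n_groups = k)
  }
}
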