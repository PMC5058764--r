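library(survival)

sim_surv <- function(n, beta = 0.7, seed = 1) {
  withr::with_seed(seed, {
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.02 * exp(beta * x))
    cens <- runif(n, 20, 120)
    tibble::tibble(time = pmin(t, cens), event = t <= cens, x = x)
  })
}

test_that("Kaplan-Meier reproduces hand-computed product limits", {
  none <- km_curve(tibble::tibble(time = c(3, 6, 9), event = c(FALSE, FALSE, FALSE)))
  expect_true(all(tidy(none)$survival == 1))

  km <- km_curve(tibble::tibble(time = c(1, 2, 3), event = c(TRUE, TRUE, FALSE)))
  expect_equal(tidy(km)$survival, c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(tidy(km)$n_risk, c(3L, 2L, 1L))

  # all-event, distinct times: steps of 1/n (1 - empirical CDF)
  d <- tibble::tibble(time = c(5, 1, 4, 2, 3), event = TRUE)
  expect_equal(tidy(km_curve(d))$survival, seq(0.8, 0, by = -0.2))
  expect_error(km_curve(tibble::tibble(time = -1, event = TRUE)),
               class = "tpsad_validation_error")
})

test_that("Kaplan-Meier agrees with the survival package on censored data", {
  d <- sim_surv(300, seed = 2)
  km <- tidy(km_curve(d))
  sf <- summary(survfit(Surv(time, event) ~ 1, data = d), times = km$time)
  expect_equal(km$survival, sf$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, sf$n.risk)
})

test_that("log-rank is null for identical groups and matches survdiff", {
  same <- tibble::tibble(time = rep(c(1, 3, 5, 7), 2),
                         event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
                         group = rep(c("a", "b"), each = 4))
  expect_lt(logrank_test(same, time, event, group)$statistic, 1e-10)

  d <- sim_surv(400, seed = 3)
  lr <- logrank_test(d, time, event, x)
  sd_ <- survdiff(Surv(time, event) ~ x, data = d)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(sd_$chisq, 1, lower.tail = FALSE), tolerance = 1e-10)

  # strong separation at large n
  far <- tibble::tibble(time = c(rexp(150, 1), rexp(150, 0.05)),
                        event = TRUE, group = rep(1:2, each = 150))
  expect_lt(logrank_test(far, time, event, group)$p_value, 1e-3)
  expect_error(logrank_test(dplyr::mutate(d, g = 1), time, event, g),
               class = "tpsad_validation_error")
})

test_that("asymptotic log-rank p tracks the exhaustive permutation null on tiny samples", {
  # the exhaustive null on 8 subjects (4 + 4) has only 70 support points, so
  # the continuous chi-square can track it no closer than the atom width:
  # expect agreement within ~0.1 and a consistent ordering across datasets
  withr::with_seed(4, {
    p_asym <- p_perm <- numeric(5)
    for (i in 1:5) {
      n <- 8
      d <- tibble::tibble(
        time = round(rexp(n, 0.1), 2),
        event = runif(n) < 0.8,
        g = rep(0:1, each = n / 2)
      )
      p_asym[i] <- logrank_test(d, time, event, g)$p_value
      p_perm[i] <- logrank_perm_oracle(d$time, d$event, d$g)
    }
    # the chi-square p is anti-conservative on tiny samples, never by more
    # than the discreteness envelope, and orders datasets consistently
    expect_true(all(p_perm >= p_asym - 1e-9))
    expect_lt(max(p_perm - p_asym), 0.2)
    expect_gt(cor(p_asym, p_perm, method = "spearman"), 0.7)
  })
})

test_that("multi-group log-rank matches survdiff", {
  d <- sim_surv(300, seed = 5)
  d$g3 <- sample(c("p", "q", "r"), nrow(d), replace = TRUE)
  lr <- logrank_test(d, time, event, g3)
  sd_ <- survdiff(Surv(time, event) ~ g3, data = d)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-10)
  expect_equal(lr$df, 2)
})

test_that("Cox fit maximizes the written-out Breslow partial likelihood", {
  d <- small_surv_fixture()
  fit <- cox_fit(d, "x")
  beta_grid <- cox_grid_oracle(d$time, d$event, d$x)
  expect_lt(abs(tidy(fit)$estimate - beta_grid), 1e-3)
  # and agrees with survival::coxph under Breslow ties
  cf <- coxph(Surv(time, event) ~ x, data = d, ties = "breslow")
  expect_equal(tidy(fit)$estimate, unname(coef(cf)), tolerance = 1e-8)
  expect_equal(tidy(fit)$std_error, unname(sqrt(vcov(cf)[1, 1])), tolerance = 1e-6)
})

test_that("Cox results agree with survival::coxph on a censored multi-covariate fit", {
  d <- sim_surv(500, seed = 6)
  d$z <- withr::with_seed(7, rnorm(500))
  fit <- cox_fit(d, c("x", "z"))
  cf <- coxph(Surv(time, event) ~ x + z, data = d, ties = "breslow")
  expect_equal(tidy(fit)$estimate, unname(coef(cf)), tolerance = 1e-7)
  expect_equal(tidy(fit)$std_error, unname(sqrt(diag(vcov(cf)))), tolerance = 1e-6)
  expect_true(fit$converged)
  g <- glance(fit)
  expect_equal(g$n_events, sum(d$event))
  # HR and CI are consistent transforms of the coefficient
  td <- tidy(fit)
  expect_equal(td$hazard_ratio, exp(td$estimate))
  expect_equal(td$conf_low, exp(td$estimate - qnorm(0.975) * td$std_error))
})

test_that("a covariate independent of outcome has HR near 1", {
  d <- sim_surv(2000, beta = 0, seed = 8)
  fit <- cox_fit(d, "x")
  expect_equal(tidy(fit)$hazard_ratio, 1, tolerance = 0.15)
  expect_gt(tidy(fit)$p_value, 0.001)
})

test_that("two-group exponential data recovers the event-rate-ratio MLE", {
  withr::with_seed(9, {
    n <- 500
    t1 <- rexp(n, 0.05); t2 <- rexp(n, 0.015)
    d <- tibble::tibble(time = c(t1, t2), event = TRUE, x = rep(c(1, 0), each = n))
    fit <- cox_fit(d, "x")
    hr_mle <- (n / sum(t1)) / (n / sum(t2))
    expect_equal(tidy(fit)$hazard_ratio, hr_mle, tolerance = 0.05)
  })
})

test_that("the score test at beta = 0 equals the log-rank chi-square", {
  d <- sim_surv(300, seed = 10)
  fit <- cox_fit(d, "x")
  lr <- logrank_test(d, time, event, x)
  expect_equal(glance(fit)$score_chisq, lr$statistic, tolerance = 1e-6)
})

test_that("Cox validation and separation handling are explicit", {
  d <- sim_surv(50, seed = 11)
  d$const <- 1
  expect_error(cox_fit(d, "const"), class = "tpsad_validation_error")
  # perfectly separating covariate: flagged, not silent
  sep <- tibble::tibble(time = c(1, 2, 3, 4, 10, 11, 12, 13),
                        event = TRUE, x = rep(c(1, 0), each = 4))
  expect_warning(fit <- cox_fit(sep, "x"), "converge")
  expect_false(fit$converged)
})

test_that("planted log-hazard-ratios are recovered within Wald coverage", {
  # 100 seeded cohorts at the published size; each planted effect should lie
  # within 2 SE of its estimate in >= 93% of replicates
  truth <- c(epe = log(1.68), svi = log(1.90), positive_margins = log(2.12),
             grade_intermediate = log(1.97), grade_high = log(5.28))
  covs <- names(truth)
  hits <- matrix(FALSE, 100, length(truth), dimnames = list(NULL, covs))
  for (r in 1:100) {
    co <- simulate_cohort(1108, seed = 3000 + r)
    co$grade <- grade_group(co$gleason_primary, co$gleason_secondary)
    co$grade_intermediate <- co$grade == "intermediate"
    co$grade_high <- co$grade == "high"
    td <- tidy(cox_fit(co, covs, time = followup_time, event = recurrence))
    hits[r, ] <- abs(td$estimate - truth) < 2 * td$std_error
  }
  expect_true(all(colMeans(hits) >= 0.93))
})

test_that("quintile strata cut at interpolated percentiles with ties going low", {
  expect_equal(quintile_strata(1:10), rep(1:5, each = 2))
  expect_warning(s <- quintile_strata(rep(2, 6)), "coincide")
  expect_equal(unique(s), 1L)
  withr::with_seed(12, {
    z <- rnorm(1000)
    expect_equal(as.integer(table(quintile_strata(z))), rep(200L, 5))
  })
  expect_error(quintile_strata(c(1, 2, 3)), class = "tpsad_validation_error")
})

test_that("group comparison reproduces the textbook t and F tests", {
  same <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  out <- group_compare(same, v, g)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  d <- tibble::tibble(v = c(1, 2, 3, 6, 7, 11), g = rep(c("a", "b"), each = 3))
  out2 <- group_compare(d, v, g)
  m <- tapply(d$v, d$g, mean); s2 <- tapply(d$v, d$g, var)
  sp <- sqrt(mean(s2)) # equal group sizes
  t_hand <- unname((m[1] - m[2]) / (sp * sqrt(2 / 3)))
  expect_equal(out2$statistic, t_hand)
  expect_equal(out2$df2, 4)

  d3 <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6, 7, 8, 9), g = rep(letters[1:3], each = 3))
  out3 <- group_compare(d3, v, g)
  expect_equal(out3$method, "One-way ANOVA")
  expect_equal(out3$df1, 2)
  expect_error(group_compare(d3, v, g, test = "ttest"), class = "tpsad_validation_error")
})

test_that("the ANOVA null p-value distribution is uniform", {
  withr::with_seed(13, {
    ps <- replicate(300, {
      d <- tibble::tibble(v = rnorm(30), g = rep(letters[1:3], each = 10))
      group_compare(d, v, g)$p_value
    })
    expect_gt(ks.test(ps, "punif")$p.value, 0.001)
    expect_equal(mean(ps), 0.5, tolerance = 0.06)
  })
})
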