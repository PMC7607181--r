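test_that("filter_survival removes only deaths inside the window", {
  rec <- data.frame(time = c(0.5, 0.5, 1.0, 2, 13),
                    event = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  out <- filter_survival(rec)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_removed"), 2)
  expect_true(all(!(out$event & out$time <= 1)))
  # censored record inside the window is retained
  expect_true(any(out$time == 0.5 & !out$event))
  expect_equal(nrow(filter_survival(rec[0, ])), 0)
})

test_that("KM equals the empirical survival with no censoring", {
  km <- km_estimate(c(2, 5, 7, 9), rep(TRUE, 4))
  expect_equal(km$surv, c(3, 2, 1, 0) / 4)
  expect_equal(km$n_risk, 4:1)
  # all censored -> flat at 1 (no event rows)
  km0 <- km_estimate(c(1, 2, 3), rep(FALSE, 3))
  expect_equal(nrow(km0), 0)
  # hand-computed: death at t=5 with risk set 1 (other censored at 3)
  km1 <- km_estimate(c(3, 5), c(FALSE, TRUE))
  expect_equal(km1$surv, 0)
  expect_equal(km1$n_risk, 1L)
})

test_that("KM with Greenwood CI matches survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(5)
  d <- sim_surv(120)
  km <- km_estimate(d$time, d$event)
  o <- survival::survfit(survival::Surv(d$time, d$event) ~ 1,
                         conf.type = "log")
  oev <- o$n.event > 0
  expect_equal(km$surv, o$surv[oev], tolerance = 1e-12)
  expect_equal(km$lower, o$lower[oev], tolerance = 1e-10)
  expect_equal(km$upper, o$upper[oev], tolerance = 1e-10)
  # curve properties
  expect_true(all(diff(km$surv) <= 1e-15))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
})

test_that("logrank is 0 for identical groups and label-invariant", {
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- rep(TRUE, 8)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(tm, ev, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1, tolerance = 1e-12)
  set.seed(8)
  d <- sim_surv(80, hr = 2)
  g2 <- factor(c("x", "y")[1 + d$x])
  a <- logrank_test(d$time, d$event, g2)
  b <- logrank_test(d$time, d$event, factor(c("y", "x")[1 + d$x]))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$df, 1)
  # O - E sums to zero across the two groups
  expect_equal(sum(a$observed - a$expected), 0, tolerance = 1e-10)
})

test_that("logrank matches survival::survdiff for 2 and 4 groups", {
  skip_if_not_installed("survival")
  set.seed(11)
  d <- sim_surv(200, hr = 1.6)
  g <- factor(c("lo", "hi")[1 + d$x])
  mine <- logrank_test(d$time, d$event, g)
  ref <- survival::survdiff(survival::Surv(d$time, d$event) ~ g)
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)
  g4 <- factor(sample(letters[1:4], 200, TRUE))
  mine4 <- logrank_test(d$time, d$event, g4)
  ref4 <- survival::survdiff(survival::Surv(d$time, d$event) ~ g4)
  expect_equal(mine4$statistic, ref4$chisq, tolerance = 1e-10)
  expect_equal(mine4$df, 3)
})

test_that("logrank has power against HR = 2 (simulation oracle)", {
  set.seed(19)
  rej <- replicate(200, {
    d <- sim_surv(1000, hazard = 0.08, hr = 2, cens_max = 30)
    logrank_test(d$time, d$event, factor(d$x))$p.value < 0.05
  })
  expect_gte(mean(rej), 0.95)
})

test_that("Cox coefficient matches brute-force partial likelihood (<= 6 records)", {
  tm <- c(2, 4, 6, 8, 10, 12)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  x <- c(1, 0, 1, 1, 0, 0)
  # written-out Breslow partial log-likelihood, maximized on a grid +
  # golden-section (independent of the Newton-Raphson path)
  pll <- function(b) {
    eta <- b * x
    sum(sapply(which(ev), function(i) {
      eta[i] - log(sum(exp(eta[tm >= tm[i]])))
    }))
  }
  bhat_ref <- optimize(pll, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  fit <- cox_ph(tm, ev, cbind(x = x))
  expect_true(fit$converged)
  expect_equal(fit$coefficients$coef, bhat_ref, tolerance = 1e-6)
})

test_that("Cox matches survival::coxph under both tie methods", {
  skip_if_not_installed("survival")
  set.seed(23)
  n <- 250
  x <- rbinom(n, 1, 0.4); z <- rnorm(n)
  d <- sim_surv(n, hazard = 0.05, hr = 2, x = x)
  X <- cbind(x = x, z = z)
  for (tie in c("breslow", "efron")) {
    tt <- if (tie == "breslow") d$time else ceiling(d$time)  # force ties
    fit <- cox_ph(tt, d$event, X, ties = tie)
    ref <- survival::coxph(survival::Surv(tt, d$event) ~ x + z, ties = tie)
    expect_equal(fit$coefficients$coef, unname(coef(ref)),
                 tolerance = 1e-7)
    expect_equal(fit$coefficients$se,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
  }
})

test_that("Cox flags separation instead of emitting estimates", {
  # monotone likelihood: the covariate perfectly orders deaths
  tm <- c(1, 2, 3, 10, 11, 12)
  ev <- rep(TRUE, 6)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_ph(tm, ev, cbind(x = x))
  expect_false(fit$converged)
  expect_null(fit$coefficients)
})

test_that("Cox CI covers a null covariate about 95% of the time", {
  set.seed(29)
  cover <- replicate(150, {
    d <- sim_surv(150, hazard = 0.06)
    z <- rnorm(150)
    fit <- cox_ph(d$time, d$event, cbind(z = z))
    if (!fit$converged) return(NA)
    fit$coefficients$hr_lower <= 1 && fit$coefficients$hr_upper >= 1
  })
  expect_gt(mean(cover, na.rm = TRUE), 0.90)
})

test_that("median_split uses the strict-above rule with ties to low", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s), c("low", "low", "high", "high"))
  s2 <- median_split(c(1, 2, 2, 3))
  expect_equal(as.character(s2), c("low", "low", "low", "high"))
  expect_error(median_split(c(5, 5, 5)), class = "ihcmet_param_error")
  expect_error(median_split(1), class = "ihcmet_param_error")
})
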