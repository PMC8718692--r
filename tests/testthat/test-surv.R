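# Kaplan-Meier, log-rank, univariate Cox and the maximally selected
# cutpoint search.

test_that("the product-limit estimator matches hand computation", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))$all
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # all censored: survival stays at 1
  km2 <- km_fit(c(1, 2, 3), c(0, 0, 0))$all
  expect_true(all(km2$surv == 1))

  # single subject with an event: step to 0
  km3 <- km_fit(5, 1)$all
  expect_equal(km3$surv, 0)
  expect_equal(km3$time, 5)

  # without censoring KM equals the empirical survival function
  set.seed(31)
  tm <- rexp(40)
  km4 <- km_fit(tm, rep(1, 40))$all
  emp <- vapply(km4$time, function(t) mean(tm > t), numeric(1))
  expect_equal(km4$surv, emp)

  expect_error(km_fit(c(1, 2), c(1, 1), c("a", "a")), NA)
  expect_equal(km_rate_at(km4, Inf), 0)
})

test_that("log-rank is exactly zero for mirrored groups and matches survdiff", {
  tm <- c(2, 4, 6, 8, 10); ev <- c(1, 0, 1, 1, 0)
  lt <- logrank_test(c(tm, tm), c(ev, ev), rep(c("g1", "g2"), each = 5))
  expect_equal(lt$chisq, 0)
  expect_equal(lt$p_value, 1)
  expect_equal(lt$df, 1L)

  # the internal U/V agrees with survdiff's chi-square
  set.seed(32)
  tm <- rexp(60); ev <- rbinom(60, 1, 0.7); g <- rbinom(60, 1, 0.5) == 1
  uv <- m6ascore:::logrank_uv(tm, ev, g)
  expect_equal(unname(uv["U"]^2 / uv["V"]),
               survival::survdiff(survival::Surv(tm, ev) ~ g)$chisq)

  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("three separated hazard groups give a decisive log-rank", {
  set.seed(33)
  n <- 100
  tm <- c(rexp(n, 0.02 * 2), rexp(n, 0.02), rexp(n, 0.02 * 0.5))
  cens <- runif(3 * n, 0, 120)
  lt <- logrank_test(pmin(tm, cens), as.integer(tm <= cens),
                     rep(c("hr2", "hr1", "hr0.5"), each = n))
  expect_lt(lt$p_value, 0.001)
})

test_that("Cox regression handles the null covariate and recovers parameters", {
  set.seed(34)
  fit0 <- cox_univariate(rexp(20), rbinom(20, 1, 0.8), rep(0, 20))
  expect_equal(fit0$beta, 0)
  expect_equal(fit0$hr, 1)

  xv <- rnorm(500)
  tm <- rexp(500, rate = 0.05 * exp(0.7 * xv))
  fit <- cox_univariate(tm, rep(1, 500), xv)
  expect_true(abs(fit$beta - 0.7) < 3 * fit$se)
  expect_true(fit$converged)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)

  # invariances: affine time rescale, covariate shift; se scales as 1/c
  fit_t <- cox_univariate(3.7 * tm, rep(1, 500), xv)
  expect_equal(fit_t$beta, fit$beta, tolerance = 1e-8)
  fit_s <- cox_univariate(tm, rep(1, 500), xv + 100)
  expect_equal(fit_s$beta, fit$beta, tolerance = 1e-6)
  fit_c <- cox_univariate(tm, rep(1, 500), 2 * xv)
  expect_equal(fit_c$beta, fit$beta / 2, tolerance = 1e-6)
  expect_equal(fit_c$se, fit$se / 2, tolerance = 1e-4)
})

test_that("Efron handling matches the brute-force partial likelihood at tiny n", {
  tm <- c(1, 1, 2, 3, 3, 4); ev <- c(1, 1, 1, 0, 1, 1)
  xv <- c(0.5, -1, 2, 0, 1, -0.5)
  fit <- cox_univariate(tm, ev, xv)
  bf <- stats::optimize(function(b) -oracle_cox_loglik(b, tm, ev, xv),
                        interval = c(-5, 5))$minimum
  expect_equal(fit$beta, bf, tolerance = 1e-4)

  # duplicated cohort: still the argmax of the brute-force Efron partial
  # likelihood (duplication shifts the estimate because tie multiplicities
  # double; both routes must agree on the shifted value)
  fit2 <- cox_univariate(rep(tm, 2), rep(ev, 2), rep(xv, 2))
  bf2 <- stats::optimize(function(b) -oracle_cox_loglik(b, rep(tm, 2), rep(ev, 2), rep(xv, 2)),
                         interval = c(-5, 5))$minimum
  expect_equal(fit2$beta, bf2, tolerance = 1e-4)
})

test_that("perfect separation is flagged as non-converged", {
  tm <- c(1, 2, 3, 10, 11, 12); ev <- rep(1, 6)
  xv <- c(1, 1, 1, 0, 0, 0)  # early deaths all at covariate 1
  fit <- suppressWarnings(cox_univariate(tm, ev, xv))
  expect_false(fit$converged)
})

test_that("cutpoint search equals the brute-force scan and handles edge cases", {
  set.seed(36)
  for (i in 1:5) {
    n <- sample(20:50, 1)
    sc <- rnorm(n)
    tm <- rexp(n, exp(0.8 * sc) * 0.1)
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 3) next
    cp <- max_sel_cutpoint(tm, ev, sc, minprop = 0.1)
    bf <- oracle_cutpoint(tm, ev, sc, minprop = 0.1)
    expect_equal(cp$cutpoint, bf$cutpoint)
    expect_equal(cp$statistic, bf$statistic, tolerance = 1e-8)
    expect_gte(cp$n_low, ceiling(0.1 * n))
    expect_gte(cp$n_high, ceiling(0.1 * n))
  }
  expect_error(max_sel_cutpoint(rexp(10), rep(1, 10), rep(2, 10)), "constant")
  expect_error(max_sel_cutpoint(rexp(4), rep(1, 4), c(1, 1, 1, 2), minprop = 0.49),
               "no candidate")
})

test_that("a score separating a 2x hazard at its median is found near the median", {
  set.seed(37)
  n <- 200
  sc <- rnorm(n)
  hi <- sc > median(sc)
  tm <- rexp(n, ifelse(hi, 0.01, 0.02))
  cp <- max_sel_cutpoint(tm, rep(1, n), sc, minprop = 0.1)
  grid <- sort(unique(sc))
  step <- which.min(abs(grid - median(sc)))
  expect_lte(abs(cp$cutpoint - median(sc)),
             abs(grid[min(step + 2, n)] - grid[max(step - 2, 1)]))
})
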