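test_that("fit_cox matches brute-force Efron partial-likelihood maximization on toy data", {
  for (fx in cox_toy_fixtures()) {
    d <- data.frame(os_time = fx$time, os_event = fx$event)
    X <- if (is.null(dim(fx$X))) matrix(fx$X, ncol = 1, dimnames = list(NULL, "x1")) else fx$X
    for (j in seq_len(ncol(X))) d[[colnames(X)[j]]] <- X[, j]
    fit <- fit_cox(d, colnames(X))
    oracle <- maximize_efron(fx$time, fx$event, X)
    expect_equal(fit$terms$coef, unname(oracle), tolerance = 1e-6)
    # model-level invariants
    expect_equal(fit$terms$hr, exp(fit$terms$coef))
    expect_equal(fit$terms$lower, exp(fit$terms$coef - 1.96 * fit$terms$se))
    expect_equal(fit$aic, -2 * fit$loglik + 2 * nrow(fit$terms))
  }
})

test_that("fit_cox handles the null covariate, weights, and degenerate inputs", {
  set.seed(42)
  n <- 2000
  d <- data.frame(os_time = rexp(n), os_event = rbinom(n, 1, 0.8),
                  x = rbinom(n, 1, 0.5))
  fit <- fit_cox(d, "x")
  expect_lt(abs(fit$terms$coef), 3 * fit$terms$se)  # HR ~ 1 under the null

  # rescaling all weights by a constant leaves the fit unchanged
  fit_s <- fit_cox(d, "x", weights = rep(2, n))
  expect_equal(fit_s$terms$coef, fit$terms$coef, tolerance = 1e-8)
  # duplicating every record at weight 0.5 reproduces the unweighted fit up
  # to the Efron correction for the ties the duplication itself introduces
  d2 <- rbind(d, d)
  fit_w <- fit_cox(d2, "x", weights = rep(0.5, 2 * n))
  expect_equal(fit_w$terms$coef, fit$terms$coef, tolerance = 0.05)

  # constant covariates are dropped with a message, zero events error
  d$z <- 1
  expect_message(fit2 <- fit_cox(d, c("x", "z")), "constant covariate")
  expect_identical(fit2$covariates, "x")
  d0 <- data.frame(os_time = 1:5, os_event = rep(0, 5), x = rnorm(5))
  expect_error(fit_cox(d0, "x"), "no events")
})

test_that("fast-backward elimination produces a strictly decreasing AIC trace", {
  set.seed(7)
  n <- 600
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  t <- rexp(n, rate = 0.1 * exp(1.0 * d$x1))
  cens <- rexp(n, rate = 0.02)
  d$os_time <- pmin(t, cens); d$os_event <- as.integer(t <= cens)
  fb <- fast_backward_aic(d, c("x1", "x2", "x3", "x4"))
  expect_true(all(diff(fb$trace$aic) < 0))
  expect_lte(fb$fit$aic, fb$full_fit$aic)
  expect_true("x1" %in% fb$retained)  # the strong covariate survives

  # all-noise model: elimination may empty the model entirely
  set.seed(8)
  d2 <- data.frame(os_time = rexp(100), os_event = rbinom(100, 1, 0.7),
                   z1 = rnorm(100), z2 = rnorm(100))
  fb2 <- fast_backward_aic(d2, c("z1", "z2"))
  expect_true(all(diff(fb2$trace$aic) < 0))
  if (length(fb2$retained) == 0) expect_identical(nrow(fb2$fit$terms), 0L)
})

test_that("Kaplan-Meier estimates match hand-computed product-limit values", {
  # all events, no censoring: S = 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$all$surv, c(2/3, 1/3, 0))

  # all censored: S stays at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$all$surv == 1))

  # mixed toy with censoring and a tie
  t <- c(1, 2, 2, 4, 5, 7); e <- c(1, 1, 0, 1, 0, 1)
  km3 <- km_estimate(t, e)
  hand <- km_by_hand(t, e)
  got <- km3$all[km3$all$n_event > 0, ]
  expect_equal(got$surv, hand$surv)
  # with one group and no censoring, S equals 1 - ECDF at event times
  t4 <- c(3, 1, 4, 2, 6, 5); e4 <- rep(1, 6)
  km4 <- km_estimate(t4, e4)
  expect_equal(km4$all$surv, 1 - ecdf(t4)(sort(t4)))
  expect_true(all(diff(km4$all$surv) <= 0))
})

test_that("log-rank matches the O-E/V hand formula and is symmetric", {
  t <- c(6, 7, 10, 15, 19, 25, 6, 6, 10, 12, 9, 14)
  e <- c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  g <- rep(c("a", "b"), each = 6)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$statistic, logrank_by_hand(t, e, g), tolerance = 1e-10)
  # label swap leaves the statistic unchanged
  lr2 <- logrank_test(t, e, ifelse(g == "a", "b", "a"))
  expect_equal(lr2$statistic, lr$statistic)
  # duplicated groups: statistic 0, p 1
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 12))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-8)
  expect_error(logrank_test(t, e, rep("a", 12)), ">= 2 groups")
})

test_that("Wilcoxon matches exact enumeration and detects large shifts", {
  x <- c(1.2, 3.4, 0.7, 2.2); y <- c(5.1, 2.9, 4.4, 3.8)
  wt <- wilcoxon_ranksum(x, y)
  expect_equal(wt$p, wilcoxon_exact_enum(x, y), tolerance = 1e-12)

  set.seed(5)
  a <- rnorm(50); b <- rnorm(50) + 10
  expect_lt(wilcoxon_ranksum(a, b)$p, 1e-6)

  same <- c(2, 2, 2, 2)
  expect_equal(wilcoxon_ranksum(same, same)$p, 1)
})

test_that("Pearson categories respect the strict 0.3/0.8 cuts", {
  x <- seq_len(20)
  expect_identical(pearson_with_category(x, x)$category, "strong")
  res <- pearson_with_category(x, -x)
  expect_equal(res$r, -1)
  expect_identical(res$category, "strong")

  # construct pairs with known |r|
  set.seed(2)
  u <- scale(seq_len(40))[, 1]
  v0 <- scale(residuals(lm(rnorm(40) ~ u)))[, 1]
  make_r <- function(r) r * u + sqrt(1 - r^2) * v0
  for (case in list(c(0.5, "moderate"), c(0.2, "weak"), c(0.95, "strong"))) {
    got <- pearson_with_category(u, make_r(as.numeric(case[1])))
    expect_equal(abs(got$r), as.numeric(case[1]), tolerance = 1e-8)
    expect_identical(got$category, case[2])
  }

  # boundary values belong to the lower category (strict inequalities):
  # set the cut exactly to the realized |r|
  y <- make_r(0.6)
  r_obs <- abs(cor(u, y))
  expect_identical(pearson_with_category(u, y, thresholds = c(0.3, r_obs))$category,
                   "moderate")
  expect_identical(pearson_with_category(u, y, thresholds = c(r_obs, 0.9))$category,
                   "weak")

  expect_error(pearson_with_category(rep(1, 5), 1:5), "constant")
})
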