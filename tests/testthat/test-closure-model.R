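test_that("logistic MLE reproduces closed-form and grid-search oracles", {
  # balanced 2x2 data: the fitted OR is the cross-product ratio and the
  # intercept recovers the reference-cell proportion
  d22 <- data.frame(
    closed_by_followup = rep(c(1L, 0L, 1L, 0L), c(10, 5, 5, 10)),
    live_births = rep(c(1, 1, 0, 0), c(10, 5, 5, 10))
  )
  fit <- fit_logistic(d22, regression_spec(covariates = "live_births"))
  or_x <- fit$table$or[fit$table$term == "live_births"]
  expect_equal(or_x, (10 * 10) / (5 * 5), tolerance = 1e-6)  # cross-product ratio
  int <- fit$table$estimate[fit$table$term == "(Intercept)"]
  expect_equal(plogis(int), 5 / 15, tolerance = 1e-6)

  # <= 8 observations, <= 2 binary covariates: progressive-zoom grid search
  for (s in 1:5) {
    set.seed(400 + s)
    repeat {
      n <- 8L
      x1 <- rbinom(n, 1, .5); x2 <- rbinom(n, 1, .5)
      y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
      X <- cbind(1, x1, x2)
      ok <- tryCatch({
        f <- fit_logistic(
          data.frame(closed_by_followup = y, live_births = x1,
                     fertility_rate = x2),
          regression_spec(covariates = c("live_births", "fertility_rate")))
        max(abs(f$table$estimate)) < 4  # keep the MLE inside the search box
      }, error = function(e) FALSE)  # separated draws are re-drawn
      if (ok) break
    }
    beta_hat <- f$table$estimate
    beta_grid <- grid_logistic_mle(X, y)
    expect_lt(max(abs(unname(beta_hat) - unname(beta_grid))), 1e-4)
    expect_gte(logistic_loglik(beta_hat, X, y),
               logistic_loglik(beta_grid, X, y) - 1e-8)
  }
})

test_that("separation and rank deficiency are refused with diagnostics", {
  sep <- data.frame(closed_by_followup = c(0, 0, 0, 1, 1, 1),
                    live_births = c(1, 2, 3, 10, 11, 12))
  expect_error(
    suppressWarnings(fit_logistic(sep, regression_spec(covariates = "live_births"))),
    "separation.*live_births")
  coh <- toy_cohort(80, seed = 14)
  coh$dup <- coh$live_births
  expect_error(
    fit_logistic(coh, regression_spec(covariates = c("live_births", "dup"))),
    "aliased.*dup")
})

test_that("odds ratios, CIs and adjusted p-values are mutually consistent", {
  coh <- toy_cohort(400, seed = 15)
  fit <- fit_logistic(coh)
  tab <- fit$table
  expect_true(all(tab$ci_low < tab$or & tab$or < tab$ci_high))
  expect_true(all(tab$or > 0))
  nonint <- tab$term != "(Intercept)"
  expect_true(all(tab$p_adj[nonint] >= tab$p_raw[nonint] - 1e-12))
  expect_equal(tab$p_adj[nonint], bh_adjust(tab$p_raw[nonint]))
  expect_equal(tab$or, exp(tab$estimate))
  expect_equal(tab$ci_low, exp(tab$estimate - qnorm(.975) * tab$se))
  expect_lte(fit$stats$deviance, fit$stats$null_deviance)
})

test_that("GVIF matches the closed-form VIF and is 1 under orthogonality", {
  # two standardized predictors with empirical correlation exactly 0.8
  set.seed(16)
  n <- 200
  z1 <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ z1)); e <- scale(e)[, 1]
  x2 <- 0.8 * z1 + sqrt(1 - 0.64) * e
  y <- rnorm(n)
  m <- lm(y ~ z1 + x2)
  gv <- gvif(m)
  expect_equal(gv$gvif, rep(1 / (1 - 0.8^2), 2), tolerance = 1e-6)

  # exactly orthogonal balanced design, linear model -> VIF exactly 1
  x1 <- rep(c(-1, 1), each = 50)
  x2o <- rep(c(-1, 1), times = 50)
  m2 <- lm(rnorm(100) ~ x1 + x2o)
  expect_equal(gvif(m2)$gvif, c(1, 1), tolerance = 1e-10)

  # single-predictor model: no collinearity by construction
  coh <- toy_cohort(100, seed = 17)
  f1 <- fit_logistic(coh, regression_spec(covariates = "live_births"))
  expect_equal(gvif(f1)$gvif, 1)
  expect_equal(gvif(f1, "live_births"), 1)
})

test_that("the logit-linearity check has correct null and power behaviour", {
  nulls <- vapply(1:20, function(s) {
    set.seed(500 + s)
    x <- runif(600, 1, 100)
    y <- rbinom(600, 1, plogis(-2 + 0.02 * x))
    d <- data.frame(closed_by_followup = y, live_births = x)
    check_logit_linearity(d, "live_births")$linear
  }, NA)
  expect_gte(mean(nulls), 0.9)  # fail-to-reject under a truly linear logit

  rejects <- vapply(1:10, function(s) {
    set.seed(600 + s)
    x <- runif(2000, 0, 10)
    y <- rbinom(2000, 1, plogis(-4 + 1.6 * x - 0.16 * x^2))
    d <- data.frame(closed_by_followup = y, live_births = x)
    !check_logit_linearity(d, "live_births")$linear
  }, NA)
  expect_gte(mean(rejects), 0.9)  # strong curvature is detected

  const <- data.frame(closed_by_followup = rbinom(50, 1, .5), live_births = 7)
  expect_error(check_logit_linearity(const, "live_births"), "distinct")
})

test_that("Benjamini-Hochberg adjustment matches step-up enumeration", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(18)
  for (i in 1:10) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])  # order invariance
    expect_true(all(adj >= p & adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))     # monotone in the ranks
  }
})

test_that("fit statistics satisfy their defining identities", {
  coh <- toy_cohort(120, seed = 19)
  fit <- fit_logistic(coh, regression_spec(covariates = c("live_births",
                                                          "has_pediatrics")))
  st <- model_fit_stats(fit)
  k_all <- nrow(fit$table)
  expect_equal(st$aic, -2 * st$loglik + 2 * k_all, tolerance = 1e-9)
  expect_equal(st$bic, -2 * st$loglik + log(st$n) * k_all, tolerance = 1e-9)

  # direct log-likelihood summation oracle on a 6-observation example
  d6 <- data.frame(closed_by_followup = c(0L, 1L, 0L, 1L, 1L, 0L),
                   live_births = c(1, 2, 3, 4, 5, 2.5))
  f6 <- fit_logistic(d6, regression_spec(covariates = "live_births"))
  X <- cbind(1, d6$live_births)
  expect_equal(f6$stats$loglik,
               logistic_loglik(f6$table$estimate, X, d6$closed_by_followup),
               tolerance = 1e-8)

  # adjusted McFadden penalizes an information-free model below zero
  ll0 <- f6$stats$null_deviance / -2
  k <- 1
  expect_lte(1 - (ll0 - k) / ll0, 0)
})

test_that("backward stepwise elimination keeps signal and drops noise", {
  hits <- vapply(1:30, function(s) {
    set.seed(700 + s)
    n <- 1000
    x <- rnorm(n); noise <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 1.2 * x))
    d <- data.frame(closed_by_followup = y, live_births = x,
                    fertility_rate = noise)
    sel <- backward_stepwise_aic(
      d, regression_spec(covariates = c("live_births", "fertility_rate")))
    ("live_births" %in% sel$retained) && !("fertility_rate" %in% sel$retained)
  }, NA)
  expect_gte(mean(hits), 0.8)

  # a single informative term is retained, with a complete trace
  set.seed(20)
  x <- rnorm(400)
  d1 <- data.frame(closed_by_followup = rbinom(400, 1, plogis(-1 + 1.5 * x)),
                   live_births = x)
  sel1 <- backward_stepwise_aic(d1, regression_spec(covariates = "live_births"))
  expect_equal(sel1$retained, "live_births")
  expect_equal(sel1$trace$aic[1], sel1$full_aic)
  expect_lte(sel1$final_aic, sel1$full_aic + 1e-9)
})

test_that("LOWESS curves track the generating risk function", {
  flat <- data.frame(closed_by_followup = 0L,
                     live_births = seq(100, 2000, length.out = 80),
                     has_pediatrics = FALSE)
  c0 <- lowess_curve(flat, stratify_by_pediatrics = FALSE)
  expect_true(all(c0$y == 0))

  # wide-plateau step function: the smooth stays near each plateau level
  set.seed(21)
  x <- sort(runif(6000, 0, 100))
  y <- as.integer(x < 50) * rbinom(6000, 1, .4)  # closure risk .4 then 0
  d <- data.frame(closed_by_followup = y, live_births = x,
                  has_pediatrics = FALSE)
  cv <- lowess_curve(d, stratify_by_pediatrics = FALSE, span = 0.25)
  lowband <- cv$x < 30
  highband <- cv$x > 70
  expect_lt(max(abs(cv$y[lowband] - 0.4)), 0.05)
  expect_lt(max(abs(cv$y[highband] - 0)), 0.05)

  # a protective pediatrics effect orders the stratified curves
  set.seed(22)
  n <- 4000
  births <- round(runif(n, 100, 2500))
  ped <- runif(n) < .4
  yy <- rbinom(n, 1, plogis(-0.5 - 0.002 * births - 1.2 * ped))
  dd <- data.frame(closed_by_followup = yy, live_births = births,
                   has_pediatrics = ped)
  cs <- lowess_curve(dd)
  common <- range(cs$x[cs$stratum == "pediatrics"])
  pc <- cs[cs$stratum == "pediatrics", ]
  nc <- cs[cs$stratum == "no_pediatrics" &
             cs$x >= common[1] & cs$x <= common[2], ]
  pn <- approx(pc$x, pc$y, xout = nc$x, rule = 2)$y
  expect_gt(mean(nc$y > pn), 0.9)

  tiny <- dd[1:25, ]; tiny$has_pediatrics[1:3] <- TRUE
  tiny$has_pediatrics[4:25] <- FALSE
  expect_warning(lowess_curve(tiny), "skipped")
})

test_that("multicollinearity screening removes offending terms and keeps others", {
  coh <- toy_cohort(300, seed = 23)
  # an almost-duplicate of live_births forces a huge GVIF
  set.seed(123)
  coh$births_copy <- coh$live_births + rnorm(300, 0, 1)
  sp <- regression_spec(covariates = c("live_births", "births_copy",
                                       "has_pediatrics"))
  sc <- screen_multicollinearity(coh, sp)
  expect_true(length(sc$removed) >= 1)
  expect_true(all(sc$fit$term_gvif$gvif_adj <= sp$gvif_threshold))
  clean <- screen_multicollinearity(coh, regression_spec(
    covariates = c("live_births", "has_pediatrics")))
  expect_length(clean$removed, 0)
})
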