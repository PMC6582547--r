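test_that("Spearman correlation handles monotone transforms, reversals and ties", {
  x <- c(2, 5, 1, 9, 4, 7, 3)
  expect_equal(spearman_mwda_dda(x, exp(x)), 1.0)
  expect_equal(spearman_mwda_dda(x, -x^3), -1.0)
  for (s in 1:20) {
    set.seed(s)
    a <- sample(1:6, 30, replace = TRUE)  # heavy ties
    b <- a + rnorm(30)
    expect_equal(spearman_mwda_dda(a, b), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearman_mwda_dda(rep(1, 5), 1:5)))
  expect_error(spearman_mwda_dda(1:4, 1:3), "equal length")
  expect_error(spearman_mwda_dda(1:2, 2:1), "at least 3")
})

test_that("noise sigma is the stated percentile of the pooled measure", {
  expect_equal(compute_sigma(1:100, "high"), 50.5)   # interpolated median
  expect_equal(compute_sigma(rep(3, 10), "low"), 3)
  expect_equal(compute_sigma(rep(3, 10), "high"), 3)
  for (s in 1:10) {
    set.seed(s)
    v <- rexp(57)
    expect_equal(compute_sigma(v, "low"), oracle_percentile(v, 0.01))
    expect_equal(compute_sigma(v, "moderate"), oracle_percentile(v, 0.10))
    expect_equal(compute_sigma(v, "high"), oracle_percentile(v, 0.50))
  }
})

test_that("response simulation adds calibrated Gaussian noise", {
  m <- c(0.2, 0.4, 0.6)
  expect_equal(simulate_response(m, 0)$y, m)
  r1 <- simulate_response(m, 0.1, seed = 5)
  r2 <- simulate_response(m, 0.1, seed = 5)
  expect_identical(r1$y, r2$y)
  big <- simulate_response(rep(0, 1e4), 0.5, seed = 6)
  # sample variance of the residuals within 3 SEs of sigma^2
  se <- 0.25 * sqrt(2 / (1e4 - 1))
  expect_lt(abs(stats::var(big$y) - 0.25), 3 * se)
  expect_error(simulate_response(m, -1), "non-negative")
})

test_that("univariate fits recover exact lines and match the likelihood oracle", {
  x <- 1:10
  f <- fit_univariate(2 * x + 1, x)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_error(fit_univariate(1:10, rep(1, 10)), "constant")
  expect_error(fit_univariate(1:3, 1:3), "more than 3")

  set.seed(21)
  x1 <- rnorm(40); x2 <- rnorm(40)
  y <- x1 + rnorm(40, 0, 0.5)
  f1 <- fit_univariate(y, x1); f2 <- fit_univariate(y, x2)
  # AIC differences equal the full Gaussian log-likelihood computation
  want <- -2 * oracle_gauss_loglik(y, x1) + 2 * oracle_gauss_loglik(y, x2)
  expect_equal(f1$aic - f2$aic, want, tolerance = 1e-9)
  # null case: independent covariate explains nothing at large n
  set.seed(22)
  f0 <- fit_univariate(rnorm(5000), rnorm(5000))
  expect_lt(f0$r_squared, 0.01)
})

test_that("scale selection is exact without noise and breaks ties to the smaller radius", {
  set.seed(23)
  for (s in 1:10) {
    cand <- list(`100` = rnorm(30), `500` = rnorm(30), `1500` = rnorm(30))
    truth <- sample(names(cand), 1)
    sel <- select_scale(cand[[truth]], cand,
                        true_radius = as.numeric(truth))
    expect_equal(sel$chosen_radius, as.numeric(truth))
    expect_true(sel$correct)
  }
  x <- rnorm(25)
  tie <- select_scale(x + rnorm(25), list(`500` = x, `100` = x))
  expect_equal(tie$chosen_radius, 100)
  expect_error(select_scale(1:10, list(`1` = 1:10)), "at least 2")
})

test_that("AIC and BIC rank candidate scales identically", {
  # with k and n fixed the two criteria differ by a constant
  set.seed(24)
  for (s in 1:8) {
    x <- replicate(4, rnorm(35))
    y <- x[, 1] + rnorm(35, 0, runif(1, 0.1, 2))
    cand <- setNames(lapply(1:4, function(i) x[, i]), c(1, 2, 3, 4))
    fits <- select_scale(y, cand)$fits
    expect_identical(order(fits$aic), order(fits$bic))
    expect_equal(stats::var(fits$bic - fits$aic), 0)
  }
})

test_that("logit-proportion regression recovers known coefficients", {
  set.seed(25)
  n <- 400
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  eta <- 0.5 + 1.2 * d$a - 0.7 * d$b + 0.4 * d$a * d$b
  d$y <- plogis(eta)
  # noiseless proportions strictly inside (0,1): clamp adjustment is inert
  fit <- suppressWarnings( # summary.lm flags the intentionally perfect fit
    logit_proportion_model(d, "y", c("a", "b"),
                           interactions = list(c("a", "b")),
                           adjust = "clamp", eps = 1e-12))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[, "Estimate"]),
               c(0.5, 1.2, -0.7, 0.4), tolerance = 1e-6)

  # noisy parameter recovery within 3 SEs
  d$y2 <- plogis(eta + rnorm(n, 0, 0.8))
  fit2 <- logit_proportion_model(d, "y2", c("a", "b"),
                                 interactions = list(c("a", "b")),
                                 adjust = "clamp", eps = 1e-12)
  est <- fit2$coefficients[, "Estimate"]
  se <- fit2$coefficients[, "Std. Error"]
  expect_true(all(abs(est - c(0.5, 1.2, -0.7, 0.4)) < 3 * se))

  # proportions at the boundary require adjustment, and ranges are checked
  d$y3 <- c(0, 1, runif(n - 2))
  expect_silent(logit_proportion_model(d, "y3", "a"))
  d$bad <- d$a
  expect_error(logit_proportion_model(d, "bad", "b"), "proportions")
})
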