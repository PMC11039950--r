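test_that("Wald ratios follow the ratio formula and reject zero exposure effects", {
  set <- make_set(gamma = 0.1, sigma_x = 0.02, Gamma = 0.05, sigma_y = 0.01)
  wr <- wald_ratio(set$records[1, ])
  expect_equal(wr$beta_ratio, 0.5)
  expect_equal(wr$se_ratio, 0.1)
  expect_equal(wr$weight, 100)

  set0 <- make_set(0.1, 0.02, 0, 0.01)
  expect_equal(wald_ratio(set0$records[1, ])$beta_ratio, 0)

  bad <- make_set(c(0, 0.1), c(0.02, 0.02), c(0.01, 0.01), c(0.01, 0.01))
  expect_error(wald_ratio(bad$records[1, ]), class = "mrbiome_degenerate_error")
})

test_that("IVW reproduces the hand-computed weighted mean of two ratios", {
  # ratios 0.5 (se 0.1) and 0.3 (se 0.2): weights 100 and 25
  set <- set_from_ratios(c(0.5, 0.3), c(100, 25))
  est <- mr_ivw(set, "fixed")
  expect_equal(est$beta, 0.46, tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 125), tolerance = 1e-12)
  expect_equal(est$pvalue, 2 * pnorm(-0.46 / sqrt(1 / 125)), tolerance = 1e-12)

  one <- make_set(0.1, 0.02, 0.05, 0.01)
  expect_error(mr_ivw(one), class = "mrbiome_insufficient_error")
})

test_that("IVW agrees with an independent fixed-effect meta-analysis", {
  skip_if_not_installed("metafor")
  set.seed(31)
  J <- 12
  set <- make_set(gamma = rnorm(J, 0.1, 0.03), sigma_x = runif(J, 0.005, 0.02),
                  Gamma = rnorm(J, 0.02, 0.01), sigma_y = runif(J, 0.005, 0.02))
  r <- set$records
  yi <- r$Gamma / r$gamma
  vi <- (r$sigma_y / abs(r$gamma))^2
  fe <- metafor::rma(yi = yi, vi = vi, method = "FE")
  est <- mr_ivw(set, "fixed")
  expect_equal(est$beta, as.numeric(fe$beta), tolerance = 1e-9)
  expect_equal(est$se, as.numeric(fe$se), tolerance = 1e-9)
})

test_that("IVW is invariant to record order and joint sign flips", {
  set.seed(32)
  J <- 10
  set <- make_set(rnorm(J, 0.1, 0.03), runif(J, 0.005, 0.02),
                  rnorm(J, -0.03, 0.01), runif(J, 0.005, 0.02))
  base <- mr_ivw(set, "fixed")
  perm <- sample(J)
  expect_equal(mr_ivw(subset_set(set, perm), "fixed")$beta, base$beta)
  flip <- set
  idx <- c(2, 5, 7)
  flip$records$gamma[idx] <- -flip$records$gamma[idx]
  flip$records$Gamma[idx] <- -flip$records$Gamma[idx]
  expect_equal(mr_ivw(flip, "fixed")$beta, base$beta, tolerance = 1e-12)

  # the J -> 1 limit of the IVW formula is the Wald ratio: second record
  # with vanishing weight
  lim <- make_set(c(0.1, 0.2), c(0.02, 0.02), c(0.05, 0.01), c(0.01, 1e6))
  expect_equal(mr_ivw(lim, "fixed")$beta,
               wald_ratio(lim$records[1, ])$beta_ratio, tolerance = 1e-6)
})

test_that("random-effects IVW never reports a smaller SE than fixed", {
  set.seed(33)
  for (i in 1:10) {
    set <- make_set(rnorm(8, 0.1, 0.02), runif(8, 0.005, 0.02),
                    rnorm(8, 0.03, 0.03), runif(8, 0.005, 0.02))
    expect_gte(mr_ivw(set, "random")$se, mr_ivw(set, "fixed")$se)
    expect_equal(mr_ivw(set, "random")$beta, mr_ivw(set, "fixed")$beta)
  }
})

test_that("Egger regression matches closed-form WLS and detects exact fits", {
  # equal weights: plain normal equations give slope 0.2, intercept 0.01
  set <- make_set(gamma = c(0.1, 0.2, 0.3), sigma_x = rep(0.01, 3),
                  Gamma = c(0.03, 0.05, 0.07), sigma_y = rep(0.02, 3))
  eg <- mr_egger(set)
  expect_equal(eg$slope$beta, 0.2, tolerance = 1e-9)
  expect_equal(eg$intercept$intercept, 0.01, tolerance = 1e-9)

  # data generated exactly as Gamma = c * gamma: intercept 0, slope c
  set2 <- make_set(gamma = c(0.05, 0.1, 0.2, 0.4), sigma_x = rep(0.01, 4),
                   Gamma = 0.3 * c(0.05, 0.1, 0.2, 0.4), sigma_y = rep(0.02, 4))
  eg2 <- mr_egger(set2)
  expect_equal(eg2$slope$beta, 0.3, tolerance = 1e-9)
  expect_equal(eg2$intercept$intercept, 0, tolerance = 1e-9)

  # with the intercept constrained to zero, the WLS slope is the IVW estimate
  set.seed(34)
  set3 <- make_set(abs(rnorm(9, 0.1, 0.05)), runif(9, 0.005, 0.02),
                   rnorm(9, 0.03, 0.02), runif(9, 0.005, 0.02))
  r <- set3$records
  constrained <- lm(Gamma ~ 0 + gamma, data = r, weights = 1 / r$sigma_y^2)
  expect_equal(mr_ivw(set3, "fixed")$beta, unname(coef(constrained)),
               tolerance = 1e-9)

  expect_error(mr_egger(set_from_ratios(c(0.1, 0.2), c(1, 1))),
               class = "mrbiome_insufficient_error")
})

test_that("Egger is invariant to the allele coding of individual records", {
  set.seed(35)
  set <- make_set(rnorm(10, 0, 0.1), runif(10, 0.005, 0.02),
                  rnorm(10, 0, 0.03), runif(10, 0.005, 0.02))
  base <- mr_egger(set)
  flip <- set
  idx <- c(1, 4, 9)
  flip$records$gamma[idx] <- -flip$records$gamma[idx]
  flip$records$Gamma[idx] <- -flip$records$Gamma[idx]
  flipped <- mr_egger(flip)
  expect_equal(flipped$slope$beta, base$slope$beta, tolerance = 1e-12)
  expect_equal(flipped$intercept$intercept, base$intercept$intercept,
               tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative weight distribution", {
  # sorted ratios (0.2, 0.5, 0.9), normalized weights (0.2, 0.3, 0.5):
  # breakpoints (0.10, 0.35, 0.75) bracket 0.5 -> estimate 0.65
  set <- set_from_ratios(c(0.2, 0.5, 0.9), c(2, 3, 5))
  est <- mr_weighted_median(set, estimator_config(n_boot = 100, seed = 1))
  expect_equal(est$beta, 0.65, tolerance = 1e-12)

  # equal weights equal the interpolated simple median
  set2 <- set_from_ratios(c(0.9, 0.2, 0.5), c(1, 1, 1))
  est2 <- mr_weighted_median(set2, estimator_config(n_boot = 100, seed = 1))
  expect_equal(est2$beta, 0.5, tolerance = 1e-12)

  # identical ratios collapse to the common value with a small bootstrap SE
  set3 <- make_set(rep(0.2, 4), rep(0.001, 4), rep(0.06, 4), rep(0.002, 4))
  est3 <- mr_weighted_median(set3, estimator_config(n_boot = 200, seed = 2))
  expect_equal(est3$beta, 0.3, tolerance = 1e-12)
  expect_lt(est3$se, 0.05)
})

test_that("weighted mode finds the dominant ratio cluster", {
  # three tightly clustered ratios carrying 90% of the weight dominate
  set <- set_from_ratios(c(0.5, 0.5, 0.5, 2.0), c(30, 30, 30, 10))
  cfg <- estimator_config(n_boot = 100, seed = 3)
  est <- mr_weighted_mode(set, cfg)
  r <- set$records$Gamma
  w <- 1 / set$records$sigma_y^2
  # the MAD degenerates (3 identical ratios), so the bandwidth falls back to
  # the SD; the argmax sits within one bandwidth plus a grid step of 0.5
  h <- 0.9 * sd(r) * 4^(-1 / 5)
  grid_step <- (diff(range(r)) + 6 * h) / 511
  expect_lt(abs(est$beta - 0.5), h + grid_step)
  expect_equal(est$beta, wmode_oracle(r, w), tolerance = 1e-12)

  # all ratios identical -> exactly that value
  set2 <- make_set(rep(0.1, 3), rep(0.001, 3), rep(0.04, 3), rep(0.002, 3))
  expect_equal(mr_weighted_mode(set2, cfg)$beta, 0.4, tolerance = 1e-12)
})

test_that("stochastic estimators are reproducible and preserve the RNG stream", {
  sim <- simulate_pair(synthetic_config(J = 10, beta0 = 0.2, seed = 36))
  set <- build_instrument_set(sim$exposure, sim$outcome)
  cfg <- estimator_config(n_boot = 150, seed = 99)
  a <- mr_weighted_median(set, cfg)
  b <- mr_weighted_median(set, cfg)
  expect_identical(a, b)
  expect_identical(mr_weighted_mode(set, cfg), mr_weighted_mode(set, cfg))
  expect_identical(mr_presso(set, cfg)$global_pvalue,
                   mr_presso(set, cfg)$global_pvalue)

  # a seeded estimator must not disturb the caller's RNG stream
  set.seed(123)
  x1 <- rnorm(1)
  set.seed(123)
  invisible(mr_weighted_median(set, cfg))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("odds-ratio conversion matches exp-transformed Wald intervals", {
  o <- to_odds_ratio(0, 0.1)
  expect_equal(o$or, 1)
  expect_equal(o$ci_low * o$ci_high, 1, tolerance = 1e-12)

  # a published protective estimate: log-OR -0.4780 (se 0.1359)
  o2 <- to_odds_ratio(-0.4780, 0.1359)
  expect_equal(round(o2$or, 3), 0.620)
  expect_equal(round(o2$ci_low, 3), 0.475)
  expect_equal(round(o2$ci_high, 3), 0.809)

  # inverting a printed OR + CI recovers the standard error
  implied_se <- (log(0.891) - log(0.624)) / (2 * qnorm(0.975))
  o3 <- to_odds_ratio(log(0.746), implied_se)
  expect_equal(round(o3$ci_low, 3), 0.624)
  expect_equal(round(o3$ci_high, 3), 0.891)
  expect_error(to_odds_ratio(0.1, -0.01), class = "mrbiome_usage_error")
})
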