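test_that("batch-means MCSE behaves on iid, autocorrelated and constant chains", {
  set.seed(1)
  x <- rnorm(1e4)
  expect_lt(abs(mcse_batch(x) / (1 / sqrt(1e4)) - 1), 0.3)

  # AR(1): asymptotic sd of the mean = sd * sqrt((1+phi)/(1-phi)) / sqrt(n)
  phi <- 0.9
  n <- 1e4
  ar <- as.numeric(arima.sim(list(ar = phi), n, sd = 1))
  theory <- sd(ar) * sqrt((1 + phi) / (1 - phi)) / sqrt(n)
  expect_lt(abs(mcse_batch(ar) / theory - 1), 0.3)

  expect_equal(mcse_batch(rep(2, 1000)), 0)
  expect_error(mcse_batch(rnorm(50)), "at least 100")
  expect_error(mcse_batch(rnorm(200), n_batches = 5), "10 batches")
})

test_that("stage-2 posterior means hit the OLS limit under a flat prior", {
  set.seed(2)
  g <- rep(c("0", "1"), each = 300)
  y <- rnorm(600, ifelse(g == "1", 3, 0), 2)
  fit <- fit_maternal_model(y, g, gibbs_config(4000, 500, seed = 3,
                                               fixed_sigma_e = 4))
  cs <- contrast_summary(fit, "1")
  dm <- mean(y[g == "1"]) - mean(y[g == "0"])
  expect_lt(abs(cs$mean - dm), 3 * cs$mcse)

  # flat-by-large-variance: two prior magnitudes agree with group means
  for (v in c(1e6, 1e10)) {
    f <- fit_maternal_model(y, g, gibbs_config(4000, 500, seed = 4),
                            prior_var = v)
    expect_lt(abs(contrast_summary(f, "1")$mean - dm),
              4 * contrast_summary(f, "1")$mcse + 0.01)
  }

  expect_error(fit_maternal_model(y, factor(g, levels = c("0", "1", "2"))),
               "zero observations")
})

test_that("stage-2 recovers planted group effects and the null", {
  set.seed(5)
  m <- c(0, -18, -47, -91)
  g <- sample(0:3, 4000, TRUE, prob = c(.36, .31, .2, .13))
  y <- m[g + 1] + rnorm(4000, 0, 5)
  fit <- fit_maternal_model(y, g, gibbs_config(4000, 500, seed = 6))
  cs <- all_contrasts(fit)
  expect_lt(max(abs(cs$mean - c(-18, -47, -91))), 1)
  expect_true(all(cs$prob_neg > 0.999))
  expect_true(all(cs$hpd_low <= cs$mean & cs$mean <= cs$hpd_high))

  y0 <- rnorm(4000, 0, 5)
  f0 <- fit_maternal_model(y0, g, gibbs_config(3000, 500, seed = 7))
  cs0 <- all_contrasts(f0)
  n_l <- tabulate(g + 1)
  se <- 5 * sqrt(1 / n_l[-1] + 1 / n_l[1])
  expect_true(all(abs(cs0$mean) < 3 * se))
})

test_that("contrast summaries: identities, quantiles, sign probabilities", {
  samples <- matrix(rnorm(3000), 1000, 3,
                    dimnames = list(NULL, c("mu", "m_0", "m_1")))
  samples[, "m_1"] <- samples[, "m_0"]     # identical chains
  fit <- structure(list(samples = cbind(samples, sigma2 = 1),
                        levels = c("0", "1")),
                   class = c("stage2_fit", "list"))
  cs <- contrast_summary(fit, "1")
  expect_equal(cs$mean, 0)
  expect_equal(c(cs$hpd_low, cs$hpd_high), c(0, 0))

  # location invariance: a common shift of all level effects cancels
  sh <- samples
  sh[, c("m_0", "m_1")] <- sh[, c("m_0", "m_1")] + rnorm(1000)
  fit2 <- structure(list(samples = cbind(sh, sigma2 = 1),
                         levels = c("0", "1")),
                    class = c("stage2_fit", "list"))
  expect_equal(contrast_summary(fit2, "1")$mean, cs$mean)

  # iid Normal(delta, 1) contrast samples: equal-tail interval ~ delta +/- 1.96
  set.seed(8)
  d <- rnorm(9000, 2, 1)
  big <- structure(list(samples = cbind(mu = 0, m_0 = 0, m_1 = d,
                                        sigma2 = 1),
                        levels = c("0", "1")),
                   class = c("stage2_fit", "list"))
  cb <- contrast_summary(big, "1")
  expect_lt(abs(cb$hpd_low - (2 - 1.96)), 0.08)
  expect_lt(abs(cb$hpd_high - (2 + 1.96)), 0.08)
  # sign probability equals the empirical fraction exactly
  expect_equal(cb$prob_neg, mean(d < 0))
  expect_equal(cb$prob_pos, mean(d > 0))

  expect_error(contrast_summary(big, "1", reference = "1"), "itself")
  expect_error(contrast_summary(big, "9"), "not in the fitted factor")
})

test_that("merit-stratified linear model matches OLS closed forms", {
  set.seed(9)
  ids <- sprintf("c%04d", 1:400)
  conc <- rep(c(0L, 1L), 200)
  circ <- data.frame(cow_id = ids, lact_group = conc * 2L,
                     yield_group = 0L, mastitis = 0L)
  y <- setNames(-90 * conc + rnorm(400, 0, 4), ids)
  sets <- list(top = ids[1:200], bottom = ids[201:400])
  fit <- merit_stratified_fit(y, circ, sets)
  for (s in 1:2) {
    idx <- sets[[fit$stratum[s]]]
    dm <- mean(y[idx][conc[match(idx, ids)] == 1]) -
      mean(y[idx][conc[match(idx, ids)] == 0])
    expect_equal(fit$estimate[s], dm)     # balanced design: diff of means
  }
  expect_lt(abs(fit$estimate[1] + 90), 3 * fit$se[1])

  y0 <- setNames(rnorm(400, 0, 4), ids)
  f0 <- merit_stratified_fit(y0, circ, sets)
  expect_true(all(abs(f0$estimate) < 3 * f0$se))

  one_level <- circ
  one_level$lact_group[match(sets$top, ids)] <- 2L
  expect_error(merit_stratified_fit(y, one_level, sets),
               "single concurrence level")
})
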