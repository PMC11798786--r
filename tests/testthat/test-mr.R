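test_that("wald_ratio arithmetic and error handling", {
  e <- wald_ratio(0.1, 0.01, 0.02, 0.005)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.05)
  expect_equal(wald_ratio(1, 0.01, 0.1515, 0.05)$beta, 0.1515)
  expect_equal(wald_ratio(-0.1, 0.01, 0.02, 0.005)$beta, -0.2)
  expect_error(wald_ratio(0, 0.01, 0.02, 0.005), "null instrument")
  # second-order SE >= first-order
  e2 <- wald_ratio(0.1, 0.02, 0.02, 0.005, second_order = TRUE)
  expect_gt(e2$se, e$se)
})

test_that("IVW matches hand-computed weighted least squares", {
  h <- harmonized_set(gamma = c(0.1, 0.2), se_gamma = c(0.01, 0.01),
                      big_gamma = c(0.02, 0.03),
                      se_big_gamma = c(0.01, 0.01))
  est <- mr_ivw(h, variance_mode = "fixed")
  # weights 100 and 400, ratios 0.2 and 0.15
  expect_equal(est$beta, 0.16)
  expect_equal(est$se, 1 / sqrt(500))
  # generic WLS oracle: regression through the origin, weights 1/se_G^2
  fit <- lm(big_gamma ~ gamma + 0, data = h, weights = 1 / h$se_big_gamma^2)
  expect_equal(est$beta, unname(coef(fit)[1]))
  # single SNP degrades to the Wald ratio
  expect_message(one <- mr_ivw(h[1, ]), "Wald ratio")
  expect_equal(one$beta, wald_ratio(0.1, 0.01, 0.02, 0.01)$beta)
})

test_that("IVW multiplicative random effects never deflates the SE", {
  h <- sim_hset(k = 15, effect = 0.1, seed = 8)
  fixed <- mr_ivw(h, "fixed")
  mre <- mr_ivw(h, "multiplicative_random")
  expect_equal(fixed$beta, mre$beta)
  expect_gte(mre$se, fixed$se)
})

test_that("IVW recovers a simulated true effect", {
  reps <- 200
  est <- vapply(seq_len(reps), function(i) {
    s <- simulate_study(sim_config(
      n_snps = 20, n_instruments = 20, n_exposure = 50000,
      n_outcome = 50000, beta1_true = 0, beta2_true = 0,
      direct_true = 0.15, seed = 6000L + i))
    mr_ivw(harmonize(s$exposure, s$outcome))$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.15), 2 * sd(est) / sqrt(reps))
})

test_that("IVW is invariant to reordering and joint sign flips", {
  h <- sim_hset(k = 12, effect = 0.2, seed = 3)
  b0 <- mr_ivw(h, "fixed")$beta
  expect_equal(mr_ivw(h[sample(12), ], "fixed")$beta, b0)
  hf <- h
  hf$gamma <- -h$gamma; hf$big_gamma <- -h$big_gamma
  expect_equal(mr_ivw(hf, "fixed")$beta, b0)
})

test_that("Egger fits an exact line and constrained Egger reproduces IVW", {
  g <- c(0.05, 0.1, 0.15, 0.2)
  h <- harmonized_set(gamma = g, se_gamma = rep(0.01, 4),
                      big_gamma = 0.01 + 0.5 * g,
                      se_big_gamma = rep(0.01, 4))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.5)
  expect_equal(e$intercept, 0.01)
  expect_lt(e$residual_scale, 1e-20)
  # oracle equivalence on random sets: zero-intercept weighted regression
  # of oriented Gamma on gamma equals the IVW slope
  for (i in 1:20) {
    hr <- sim_hset(k = 10, effect = 0.1, seed = 100 + i)
    flip <- sign(hr$gamma)
    fit <- lm(I(flip * hr$big_gamma) ~ I(flip * hr$gamma) + 0,
              weights = 1 / hr$se_big_gamma^2)
    expect_equal(unname(coef(fit)[1]), mr_ivw(hr, "fixed")$beta)
  }
  expect_error(mr_egger(h[1:2, ]), "insufficient")
})

test_that("Egger slope is less biased than IVW under directional pleiotropy", {
  reps <- 100
  bias <- vapply(seq_len(reps), function(i) {
    s <- simulate_study(sim_config(
      n_snps = 30, n_instruments = 30, n_exposure = 50000,
      n_outcome = 50000, beta1_true = 0, beta2_true = 0,
      direct_true = 0.1, gamma_sd = 0.15,
      pleiotropy_mode = "directional", pleiotropy_sd = 0.02,
      seed = 7000L + i))
    h <- harmonize(s$exposure, s$outcome)
    c(mr_egger(h)$beta, mr_ivw(h)$beta)
  }, numeric(2))
  expect_lt(abs(mean(bias[1, ]) - 0.1), abs(mean(bias[2, ]) - 0.1))
})

test_that("weighted median interpolates the weighted quantile function", {
  h3 <- harmonized_set(gamma = c(1, 1, 1), se_gamma = rep(0.01, 3),
                       big_gamma = c(0.1, 0.2, 0.3),
                       se_big_gamma = rep(1, 3))
  expect_equal(mr_weighted_median(h3, n_boot = 50, seed = 1)$beta, 0.2)
  # weights {1,1,2} via se_big_gamma: w = 1/se^2
  h4 <- harmonized_set(gamma = c(1, 1, 1), se_gamma = rep(0.01, 3),
                       big_gamma = c(0.1, 0.2, 0.3),
                       se_big_gamma = c(1, 1, 1 / sqrt(2)))
  est <- mr_weighted_median(h4, n_boot = 50, seed = 1)
  # brute-force oracle over the piecewise-linear quantile function
  r <- c(0.1, 0.2, 0.3); w <- c(1, 1, 2) / 4
  p <- cumsum(w) - w / 2
  expect_equal(est$beta, approx(p, r, xout = 0.5)$y)
  expect_equal(est$beta, 0.2 + 0.1 * (0.5 - 0.375) / (0.75 - 0.375))
  # equal weights, odd k: equals the sample median of ratios
  h5 <- sim_hset(k = 9, effect = 0.1, seed = 5)
  h5$se_big_gamma <- rep(0.01, 9)
  h5$gamma <- abs(h5$gamma); h5$gamma[] <- 0.1  # equalize weights
  expect_equal(mr_weighted_median(h5, n_boot = 50, seed = 2)$beta,
               median(h5$big_gamma / h5$gamma))
})

test_that("weighted median resists 30% invalid instruments better than IVW", {
  reps <- 100
  est <- vapply(seq_len(reps), function(i) {
    s <- simulate_study(sim_config(
      n_snps = 20, n_instruments = 20, n_exposure = 50000,
      n_outcome = 50000, beta1_true = 0, beta2_true = 0,
      direct_true = 0.1, gamma_sd = 0.15,
      pleiotropy_mode = "directional", pleiotropy_sd = 0.05,
      pleiotropy_frac = 0.3, seed = 8000L + i))
    h <- harmonize(s$exposure, s$outcome)
    c(mr_weighted_median(h, n_boot = 1, seed = 1)$beta, mr_ivw(h)$beta)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.1), abs(mean(est[2, ]) - 0.1))
})

test_that("mode estimators follow the kernel-density oracle", {
  hc <- harmonized_set(gamma = rep(1, 4), se_gamma = rep(0.01, 4),
                       big_gamma = rep(0.25, 4), se_big_gamma = rep(0.1, 4))
  expect_equal(mr_mode(hc, n_boot = 10, seed = 1)$beta, 0.25)
  # the mode ignores a lone outlier
  ho <- harmonized_set(gamma = rep(1, 4), se_gamma = rep(0.01, 4),
                       big_gamma = c(0.1, 0.1, 0.1, 0.9),
                       se_big_gamma = rep(0.1, 4))
  est <- mr_mode(ho, n_boot = 10, seed = 1)
  expect_lt(abs(est$beta - 0.1), 0.05)
  # grid-search oracle over the explicit kernel density, using the
  # documented bandwidth rule (modified Silverman with sd fallback when
  # the mad collapses to zero)
  r <- c(0.1, 0.1, 0.1, 0.9)
  h <- 0.9 * min(sd(r), mad(r)) * 4^(-1 / 5)
  if (h <= 0) h <- 0.9 * sd(r) * 4^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- sapply(grid, function(x) sum(dnorm((x - r) / h)))
  expect_equal(est$beta, grid[which.max(dens)])
  # weighted mode is pulled to a dominant weight
  hw <- harmonized_set(gamma = rep(1, 4), se_gamma = rep(0.01, 4),
                       big_gamma = c(0.1, 0.2, 0.3, 0.6),
                       se_big_gamma = c(1, 1, 1, 0.001))
  expect_lt(abs(mr_mode(hw, weighted = TRUE, n_boot = 10, seed = 1)$beta -
                  0.6), 0.05)
  expect_error(mr_mode(hc[1:2, ]), "insufficient")
})

test_that("Cochran's Q matches hand arithmetic and is zero for equal ratios", {
  heq <- harmonized_set(gamma = rep(1, 3), se_gamma = rep(0.01, 3),
                        big_gamma = rep(0.2, 3), se_big_gamma = rep(0.1, 3))
  q <- cochran_q(heq)
  expect_equal(q$q, 0)
  expect_equal(q$q_pvalue, 1)
  h2 <- harmonized_set(gamma = c(1, 1), se_gamma = rep(0.01, 2),
                       big_gamma = c(0, 1), se_big_gamma = c(1, 1))
  q2 <- cochran_q(h2, beta_ref = 0.5)
  expect_equal(q2$q, 0.5)
  expect_equal(q2$q_df, 1L)
})

test_that("Q p-values are approximately uniform under the null", {
  reps <- 300
  pvals <- vapply(seq_len(reps), function(i) {
    s <- simulate_study(sim_config(
      n_snps = 15, n_instruments = 15, n_exposure = 50000,
      n_outcome = 50000, beta1_true = 0, beta2_true = 0,
      direct_true = 0.1, seed = 9000L + i))
    cochran_q(harmonize(s$exposure, s$outcome))$q_pvalue
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("leave-one-out isolates a gross outlier", {
  h <- sim_hset(k = 10, effect = 0.1, seed = 21)
  loo0 <- leave_one_out(h)
  expect_equal(nrow(loo0), 10L)
  expect_equal(loo0$snp_id, h$snp_id)
  # identical SNPs: every row equals the full estimate
  hi <- harmonized_set(gamma = rep(0.1, 5), se_gamma = rep(0.01, 5),
                       big_gamma = rep(0.02, 5), se_big_gamma = rep(0.01, 5))
  looi <- leave_one_out(hi)
  expect_true(all(abs(looi$beta - mr_ivw(hi)$beta) < 1e-12))
  # inject an outlier into an equal-weight set: its removal moves the
  # estimate the most
  set.seed(14)
  ho <- harmonized_set(gamma = rep(0.1, 10), se_gamma = rep(0.01, 10),
                       big_gamma = rnorm(10, 0.01, 0.002),
                       se_big_gamma = rep(0.002, 10))
  ho$big_gamma[4] <- ho$big_gamma[4] + 20 * ho$se_big_gamma[4]
  full <- mr_ivw(ho)$beta
  loo <- leave_one_out(ho)
  expect_equal(which.max(abs(loo$beta - full)), 4L)
})

test_that("odds-ratio transform reproduces the published worked examples", {
  expect_equal(round(to_odds_ratio(0.1515, 0)$or, 4), 1.1636)
  expect_equal(round(to_odds_ratio(0.1464, 0)$or, 4), 1.1577)
  o <- to_odds_ratio(0, 0.1)
  expect_equal(o$or, 1)
  expect_equal(o$ci_low * o$ci_high, 1)  # symmetric on the log scale
})

test_that("bootstrap estimators are bit-reproducible given a seed", {
  h <- sim_hset(k = 8, effect = 0.1, seed = 33)
  expect_identical(mr_weighted_median(h, n_boot = 200, seed = 5),
                   mr_weighted_median(h, n_boot = 200, seed = 5))
  expect_identical(mr_mode(h, weighted = TRUE, n_boot = 200, seed = 5),
                   mr_mode(h, weighted = TRUE, n_boot = 200, seed = 5))
})

test_that("mr_all emits the five methods in the results schema", {
  h <- sim_hset(k = 10, effect = 0.1, seed = 2)
  tab <- mr_all(h, n_boot = 50, seed = 1)
  expect_setequal(tab$method, c("ivw", "egger", "weighted_median",
                                "simple_mode", "weighted_mode"))
  expect_true(all(c("exposure", "outcome", "method", "n_snps", "beta", "se",
                    "pvalue", "ci_low", "ci_high", "or", "or_ci_low",
                    "or_ci_high") %in% names(tab)))
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
  expect_equal(tab$or, exp(tab$beta))
})
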