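test_that("decomposition reproduces the worked-example arithmetic exactly", {
  d <- decompose_mediation(beta_all = 0.1515, se_all = 0.064,
                           beta1 = 0.17, se1 = 0.03,
                           beta2 = 0.12, se2 = 0.04)
  expect_equal(d$beta12, 0.17 * 0.12)           # 0.0204, exact identity
  expect_equal(d$direct_effect, 0.1515 - 0.0204)  # 0.1311
  expect_equal(d$proportion, 100 * 0.0204 / 0.1515)
  expect_false(d$directions_inconsistent)
  # beta2 = 0 collapses the indirect path
  d0 <- decompose_mediation(0.2, 0.05, 0.17, 0.03, 0, 0.04)
  expect_equal(d0$beta12, 0)
  expect_equal(d0$direct_effect, 0.2)
  expect_equal(d0$proportion, 0)
})

test_that("delta-method SE matches the formula and a Monte-Carlo oracle", {
  d <- decompose_mediation(0.5, 0.1, 0.5, 0.1, 0.4, 0.2)
  expect_equal(d$se12, sqrt(0.16 * 0.01 + 0.25 * 0.04))  # 0.1077
  # MC oracle: sd of the product of two independent normals
  set.seed(1)
  draws <- rnorm(1e6, 0.5, 0.1) * rnorm(1e6, 0.4, 0.2)
  expect_equal(d$se12, sd(draws), tolerance = 0.02)
})

test_that("footnote rules: spanning CI suppresses the proportion CI, inconsistent directions the proportion", {
  # CI spans zero: proportion present, CI absent
  d1 <- decompose_mediation(0.1515, 0.06, 0.1, 0.03, 0.132, 0.08)
  expect_true(d1$ci_spans_zero)
  expect_false(is.na(d1$proportion))
  expect_true(is.na(d1$prop_ci_low) && is.na(d1$prop_ci_high))
  # inconsistent directions: no proportion at all
  d2 <- decompose_mediation(0.1464, 0.05, 0.1, 0.01, -0.15, 0.01)
  expect_true(d2$directions_inconsistent)
  expect_true(is.na(d2$proportion))
  # zero total effect with a proportion requested -> flagged, absent
  d3 <- decompose_mediation(0, 0.05, 0.1, 0.01, 0.1, 0.01)
  expect_true(d3$directions_inconsistent)
  expect_true(is.na(d3$proportion))
  # tight consistent pathway: CI present and covering the point estimate
  d4 <- decompose_mediation(0.15, 0.01, 0.17, 0.005, 0.12, 0.005)
  expect_false(d4$ci_spans_zero)
  expect_true(d4$prop_ci_low < d4$proportion &&
                d4$proportion < d4$prop_ci_high)
})

test_that("exact identities hold to machine precision on random inputs", {
  set.seed(7)
  for (i in 1:50) {
    b <- rnorm(3); s <- abs(rnorm(3, 0.05, 0.01))
    d <- decompose_mediation(b[1], s[1], b[2], s[2], b[3], s[3])
    expect_identical(d$beta12, b[2] * b[3])
    expect_identical(d$direct_effect, b[1] - b[2] * b[3])
  }
})

test_that("snp_exclusion equals unadjusted IVW when instrument sets are disjoint", {
  s <- simulate_study(sim_config(
    n_snps = 60, n_instruments = 15, n_instruments_mediator = 15,
    n_exposure = 50000, n_mediator = 50000, n_outcome = 50000,
    gamma_sd = 0.15, med_gamma_sd = 0.15, seed = 90L))
  est <- adjusted_step2(s$mediator, s$outcome, s$exposure, ld = s$ld)
  adj <- attr(est, "adjustment")
  expect_equal(adj$mode, "snp_exclusion")
  # unadjusted IVW on the same instrument set
  sel <- select_instruments(s$mediator, ld = s$ld)
  keep <- sel$instruments$snp_id[
    !(sel$instruments$snp_id %in% select_candidates(s$exposure, 1e-5)$snp_id)]
  h <- harmonize(s$mediator[s$mediator$snp_id %in% keep, ], s$outcome)
  expect_equal(est$beta, mr_ivw(h)$beta)
  # if no mediator instrument touches the exposure, nothing is removed
  if (adj$n_before == adj$n_after)
    expect_equal(est$beta,
                 mr_ivw(harmonize(s$mediator[s$mediator$snp_id %in%
                                               sel$instruments$snp_id, ],
                                  s$outcome))$beta)
})

test_that("a shared exposure/mediator instrument is excluded in snp_exclusion mode", {
  s <- simulate_study(sim_config(
    n_snps = 60, n_instruments = 15, n_instruments_mediator = 15,
    n_exposure = 50000, n_mediator = 50000, n_outcome = 50000,
    gamma_sd = 0.15, med_gamma_sd = 0.15, seed = 91L))
  # make one mediator instrument also a strong exposure hit
  shared <- s$truth$mediator_instrument_ids[1]
  i <- match(shared, s$exposure$snp_id)
  s$exposure$beta[i] <- 0.2
  s$exposure$pvalue[i] <- 1e-30
  est <- adjusted_step2(s$mediator, s$outcome, s$exposure, ld = s$ld)
  adj <- attr(est, "adjustment")
  expect_lt(adj$n_after, adj$n_before)
})

test_that("mvmr recovers beta2 and a null exposure coefficient on chains with no direct effect", {
  reps <- 50
  coefs <- vapply(seq_len(reps), function(i) {
    s <- simulate_study(sim_config(
      n_snps = 60, n_instruments = 15, n_instruments_mediator = 15,
      n_exposure = 50000, n_mediator = 50000, n_outcome = 50000,
      beta1_true = 0.3, beta2_true = 0.2, direct_true = 0,
      gamma_sd = 0.15, med_gamma_sd = 0.15, seed = 1200L + i))
    est <- adjusted_step2(s$mediator, s$outcome, s$exposure, mode = "mvmr",
                          ld = s$ld)
    c(med = est$beta, exp = est$exposure_beta)
  }, numeric(2))
  mc2 <- 2 * apply(coefs, 1, sd) / sqrt(reps)
  expect_lt(abs(mean(coefs["med", ]) - 0.2), mc2["med"] + 0.01)
  expect_lt(abs(mean(coefs["exp", ])), mc2["exp"] + 0.01)
})

test_that("underidentified step 2 errors", {
  s <- simulate_study(sim_config(
    n_snps = 30, n_instruments = 14, n_instruments_mediator = 2,
    n_exposure = 50000, n_mediator = 50000, n_outcome = 50000,
    gamma_sd = 0.15, med_gamma_sd = 0.15, seed = 92L))
  # every mediator instrument is also exposure-associated via beta1 and the
  # exposure instruments; force removal of all by marking them exposure hits
  for (id in s$truth$mediator_instrument_ids) {
    i <- match(id, s$exposure$snp_id)
    s$exposure$beta[i] <- 0.2
    s$exposure$pvalue[i] <- 1e-30
  }
  expect_error(adjusted_step2(s$mediator, s$outcome, s$exposure, ld = s$ld),
               "underidentified")
})

test_that("mediation_scan recovers the true pathway and honors contracts", {
  s <- simulate_study(sim_config(
    n_snps = 80, n_instruments = 20, n_instruments_mediator = 20,
    n_exposure = 50000, n_mediator = 50000, n_outcome = 50000,
    beta1_true = 0.3, beta2_true = 0.2, direct_true = 0.1,
    gamma_sd = 0.15, med_gamma_sd = 0.15, seed = 93L))
  # a decoy mediator with its own instruments but no causal role: permute
  # the mediator's true association away by regenerating under a null chain
  s_null <- simulate_study(sim_config(
    n_snps = 80, n_instruments = 20, n_instruments_mediator = 20,
    n_exposure = 50000, n_mediator = 50000, n_outcome = 50000,
    beta1_true = 0, beta2_true = 0, direct_true = 0.1,
    gamma_sd = 0.15, med_gamma_sd = 0.15, seed = 94L))
  tab <- mediation_scan(exposures = list(lipid = s$exposure),
                        mediators = list(metab = s$mediator,
                                         decoy = s_null$mediator),
                        outcome = s$outcome, ld = s$ld)
  expect_true("metab" %in% tab$mediator)
  expect_false("decoy" %in% tab$mediator)  # fails the step-1 filter
  expect_true(all(c("exposure", "mediator", "outcome", "beta_all", "direct",
                    "beta12", "ci12_low", "ci12_high", "pvalue",
                    "proportion", "prop_ci_low", "prop_ci_high", "flags",
                    "adjustment_mode") %in% names(tab)))
  row <- tab[tab$mediator == "metab", ]
  expect_equal(row$direct, row$beta_all - row$beta12)
  # empty candidate sets: empty table with a warning
  expect_warning(empty <- mediation_scan(list(), list(), s$outcome), "empty")
  expect_equal(nrow(empty), 0L)
})
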