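# Shared fixture builders; everything is generated in code.

make_sumstats <- function(snp_id, beta, se, eaf = 0.3, n = 10000,
                          effect_allele = "A", other_allele = "G",
                          chrom = "1", pos = NULL) {
  k <- length(snp_id)
  if (is.null(pos)) pos <- seq_len(k) * 100000
  data.frame(snp_id = snp_id, chrom = rep_len(chrom, k), pos = pos,
             effect_allele = rep_len(effect_allele, k),
             other_allele = rep_len(other_allele, k),
             eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
             pvalue = 2 * pnorm(-abs(beta / rep_len(se, k))),
             n = rep_len(n, k), stringsAsFactors = FALSE)
}

# A small strong-instrument study: returns a harmonized_set with k SNPs,
# true slope `effect`, optional per-SNP pleiotropy added to the outcome.
sim_hset <- function(k = 20, effect = 0.15, n_exp = 50000, n_out = 50000,
                     gamma_sd = 0.1, alpha = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maf <- runif(k, 0.1, 0.5)
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * n_exp)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_out)
  gamma_true <- rnorm(k, 0, gamma_sd)
  alpha <- rep_len(alpha, k)
  gamma_hat <- rnorm(k, gamma_true, se_x)
  big_hat <- rnorm(k, effect * gamma_true + alpha, se_y)
  harmonized_set(gamma_hat, se_x, big_hat, se_y,
                 n_exposure = n_exp, n_outcome = n_out)
}

expect_same_hset <- function(a, b) {
  expect_equal(a$snp_id, b$snp_id)
  expect_equal(a$gamma, b$gamma)
  expect_equal(a$big_gamma, b$big_gamma)
  expect_equal(a$se_gamma, b$se_gamma)
  expect_equal(a$se_big_gamma, b$se_big_gamma)
}
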