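#' Simulation configuration for a three-trait summary-statistics study
#'
#' Defines the generative model of a synthetic exposure -> mediator ->
#' outcome study at the summary-statistics level. Traits are standardized
#' (unit variance), so the sampling SE of a per-SNP effect is
#' `1 / sqrt(2 * maf * (1 - maf) * N)` and no individual-level data is
#' simulated. Defaults emulate the shape of a lipid -> metabolite -> fatty
#' liver disease study: sample sizes 7,174 / 8,299 / 778,614 and a causal
#' chain with total effect 0.1515 of which ~13.5% is mediated.
#'
#' @param n_snps Total SNPs simulated.
#' @param n_instruments SNPs causal for the exposure (the first
#'   `n_instruments` SNPs).
#' @param n_instruments_mediator SNPs with mediator-specific effects,
#'   disjoint from the exposure instruments (the next block of SNPs).
#'   Default equals `n_instruments`.
#' @param maf_range Uniform sampling range of minor-allele frequencies,
#'   within (0, 0.5].
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (>= 100).
#' @param beta1_true Exposure -> mediator causal effect.
#' @param beta2_true Mediator -> outcome causal effect.
#' @param direct_true Exposure -> outcome direct effect.
#' @param gamma_sd SD of per-SNP true exposure effects.
#' @param med_gamma_sd SD of per-SNP mediator-specific effects.
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (zero-mean normal
#'   direct outcome effects) or `"directional"` (half-normal magnitude,
#'   oriented with the sign of the SNP's exposure effect, i.e. pushing the
#'   outcome in the direction of the exposure-increasing allele).
#' @param pleiotropy_sd SD of the per-SNP pleiotropic outcome effect
#'   `alpha_j`.
#' @param pleiotropy_frac Fraction of exposure instruments carrying a
#'   pleiotropic effect (default 1 = all).
#' @param ld_blocks List of `c(size, r)` pairs: consecutive SNPs are grouped
#'   into blocks with pairwise correlation `r` (the clumping threshold is on
#'   `r^2`). SNPs beyond the blocks are independent.
#' @param seed Integer seed; the whole study derives from one stream.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_snps = 120, n_instruments = 23,
                       n_instruments_mediator =
                         min(n_instruments, n_snps - n_instruments),
                       maf_range = c(0.05, 0.5),
                       n_exposure = 7174, n_mediator = 8299,
                       n_outcome = 778614,
                       beta1_true = 0.17, beta2_true = 0.12,
                       direct_true = 0.1311,
                       gamma_sd = 0.1, med_gamma_sd = 0.1,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0, pleiotropy_frac = 1,
                       ld_blocks = list(), seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_instruments <= n_snps,
            n_instruments + n_instruments_mediator <= n_snps,
            n_exposure >= 100, n_mediator >= 100, n_outcome >= 100,
            length(maf_range) == 2L, maf_range[1] < maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5,
            pleiotropy_sd >= 0, pleiotropy_frac >= 0, pleiotropy_frac <= 1)
  for (b in ld_blocks) {
    stopifnot(length(b) == 2L, b[1] >= 1)
    if (abs(b[2]) > 1) stop("impossible LD spec: |r| > 1")
  }
  if (sum(vapply(ld_blocks, `[`, numeric(1), 1)) > n_snps)
    stop("LD blocks cover more SNPs than n_snps")
  structure(list(
    n_snps = as.integer(n_snps), n_instruments = as.integer(n_instruments),
    n_instruments_mediator = as.integer(n_instruments_mediator),
    maf_range = maf_range, n_exposure = n_exposure, n_mediator = n_mediator,
    n_outcome = n_outcome, beta1_true = beta1_true, beta2_true = beta2_true,
    direct_true = direct_true, gamma_sd = gamma_sd,
    med_gamma_sd = med_gamma_sd, pleiotropy_mode = pleiotropy_mode,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_frac = pleiotropy_frac,
    ld_blocks = ld_blocks, seed = as.integer(seed)),
    class = "sim_config")
}

# Block-diagonal SNP correlation matrix implied by the config.
ld_correlation <- function(config) {
  n <- config$n_snps
  R <- diag(n)
  at <- 1L
  for (b in config$ld_blocks) {
    size <- as.integer(b[1]); r <- b[2]
    idx <- at:(at + size - 1L)
    R[idx, idx] <- r
    R[cbind(idx, idx)] <- 1
    at <- at + size
  }
  R
}

#' Simulate a three-trait GWAS summary-statistics study
#'
#' Draws per-SNP true effects, then observed effects with sampling noise on
#' the summary-statistics scale. For the `n_instruments` exposure-causal
#' SNPs, joint effects `gamma_j ~ N(0, gamma_sd^2)`; a disjoint block of
#' `n_instruments_mediator` SNPs gets mediator-specific effects
#' `delta_j ~ N(0, med_gamma_sd^2)`. True per-SNP effects are
#' `m_j = beta1 * gamma_j + delta_j` on the mediator and
#' `o_j = direct * gamma_j + beta2 * m_j + alpha_j` on the outcome, where
#' `alpha_j` is the pleiotropy term. Under LD, marginal effects are
#' `R %*%` the joint effects and estimation noise is correlated within
#' blocks with the same `R`. Observed betas are
#' `Normal(truth, se^2)` with `se = 1/sqrt(2*maf*(1-maf)*N)`; p-values are
#' two-sided normal. A fixed seed gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @return List with elements `exposure`, `mediator`, `outcome`
#'   (summary-statistics data.frames), `ld` (the target r-squared matrix with
#'   snp_id dimnames) and `truth` (a `synthetic_truth` list: per-SNP true
#'   effects, the pleiotropy vector, the generative scalars, the total effect
#'   and the true mediation proportion).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snps
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  R <- ld_correlation(config)
  has_ld <- length(config$ld_blocks) > 0L
  # symmetric square root tolerates singular blocks (within-block r = 1)
  L <- if (has_ld) {
    e <- eigen(R, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  } else NULL

  gamma_joint <- numeric(n)
  idx_exp <- seq_len(config$n_instruments)
  gamma_joint[idx_exp] <- stats::rnorm(config$n_instruments, 0, config$gamma_sd)
  delta_joint <- numeric(n)
  idx_med <- if (config$n_instruments_mediator > 0)
    config$n_instruments + seq_len(config$n_instruments_mediator)
  else integer(0)
  delta_joint[idx_med] <- stats::rnorm(length(idx_med), 0, config$med_gamma_sd)

  alpha_joint <- numeric(n)
  if (config$pleiotropy_mode != "none" && config$pleiotropy_sd > 0) {
    n_pl <- round(config$pleiotropy_frac * config$n_instruments)
    pl_idx <- idx_exp[seq_len(n_pl)]
    raw <- stats::rnorm(length(pl_idx), 0, config$pleiotropy_sd)
    if (config$pleiotropy_mode == "directional") {
      # directional = pushes the outcome in the direction of the
      # exposure-increasing allele; with sign-symmetric gamma an
      # allele-agnostic positive shift would cancel instead of biasing
      sgn <- sign(gamma_joint[pl_idx])
      sgn[sgn == 0] <- 1
      raw <- abs(raw) * sgn
    }
    alpha_joint[pl_idx] <- raw
  }

  marg <- function(x) if (has_ld) drop(R %*% x) else x
  gamma_true <- marg(gamma_joint)
  delta_true <- marg(delta_joint)
  alpha <- marg(alpha_joint)
  m_true <- config$beta1_true * gamma_true + delta_true
  o_true <- config$direct_true * gamma_true + config$beta2_true * m_true + alpha

  corr_noise <- function() {
    z <- stats::rnorm(n)
    if (has_ld) drop(L %*% z) else z
  }
  one_trait <- function(truth, N) {
    se <- 1 / sqrt(2 * maf * (1 - maf) * N)
    beta <- truth + se * corr_noise()
    data.frame(
      snp_id = sprintf("rs%05d", seq_len(n)), chrom = "1",
      pos = seq_len(n) * 100000, effect_allele = "A", other_allele = "G",
      eaf = maf, beta = beta, se = se,
      pvalue = 2 * stats::pnorm(-abs(beta / se)), n = N,
      stringsAsFactors = FALSE)
  }
  exposure <- one_trait(gamma_true, config$n_exposure)
  mediator <- one_trait(m_true, config$n_mediator)
  outcome <- one_trait(o_true, config$n_outcome)

  r2 <- R * R
  dimnames(r2) <- list(exposure$snp_id, exposure$snp_id)
  total <- config$direct_true + config$beta1_true * config$beta2_true
  truth <- structure(list(
    gamma = gamma_true, mediator_effect = m_true, outcome_effect = o_true,
    alpha = alpha, delta = delta_true,
    beta1_true = config$beta1_true, beta2_true = config$beta2_true,
    direct_true = config$direct_true,
    total_effect = total,
    mediation_proportion = if (total != 0)
      100 * config$beta1_true * config$beta2_true / total else NA_real_,
    instrument_ids = exposure$snp_id[idx_exp],
    mediator_instrument_ids = exposure$snp_id[idx_med]),
    class = "synthetic_truth")
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       ld = r2, truth = truth)
}

#' True total causal effect of a simulated study
#'
#' The generative identity `total = direct + beta1 * beta2`, used by
#' parameter-recovery tests.
#'
#' @param truth A `synthetic_truth` (from [simulate_study()]).
#' @return The scalar total exposure -> outcome effect.
#' @export
true_total_effect <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  truth$direct_true + truth$beta1_true * truth$beta2_true
}

#' Write a simulated study to an output directory
#'
#' Emits the three summary-statistics TSVs, the LD r-squared matrix as a TSV
#' (square, header = snp_ids) and the generative truth as JSON.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sumstats(study$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(study$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(study$outcome, file.path(dir, "outcome.tsv"))
  ld <- as.data.frame(study$ld)
  utils::write.table(cbind(snp_id = rownames(study$ld), ld),
                     file.path(dir, "ld.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- study$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an LD r-squared matrix written by [write_study()]
#' @param path TSV path.
#' @return Numeric matrix with snp_id dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$snp_id
  storage.mode(m) <- "double"
  m
}
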