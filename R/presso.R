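# Leave-one-out IVW slopes from weight sums; O(k).
loo_slopes <- function(r, w) {
  s_num <- sum(w * r)
  s_den <- sum(w)
  (s_num - w * r) / (s_den - w)
}

presso_rss <- function(big_gamma, gamma, se_big_gamma, slopes) {
  sum((big_gamma - slopes * gamma)^2 / se_big_gamma^2)
}

# Simulate n_sim replicate datasets under the outlier-free model and return
# the per-replicate RSS matrix of squared standardized residuals (n_sim x k).
presso_sim_resid2 <- function(hset, slopes, n_sim) {
  k <- nrow(hset)
  g_star <- matrix(stats::rnorm(n_sim * k, rep(hset$gamma, each = n_sim),
                                rep(hset$se_gamma, each = n_sim)),
                   n_sim, k)
  G_mean <- slopes * hset$gamma
  G_star <- matrix(stats::rnorm(n_sim * k, rep(G_mean, each = n_sim),
                                rep(hset$se_big_gamma, each = n_sim)),
                   n_sim, k)
  w_star <- sweep(g_star^2, 2, hset$se_big_gamma^2, "/")
  r_star <- G_star / g_star
  s_num <- rowSums(w_star * r_star)
  s_den <- rowSums(w_star)
  slopes_star <- (s_num - w_star * r_star) / (s_den - w_star)
  (G_star - slopes_star * g_star)^2 /
    matrix(hset$se_big_gamma^2, n_sim, k, byrow = TRUE)
}

#' MR-PRESSO global pleiotropy test
#'
#' The observed residual sum of squares uses, for each SNP, the IVW slope
#' estimated with that SNP left out: `RSS = sum_j (Gamma_j - beta_(-j) *
#' gamma_j)^2 / se_Gamma_j^2`. Its null distribution is simulated by
#' redrawing `(gamma_j*, Gamma_j*)` from normal sampling distributions
#' centered on the outlier-free model; the p-value uses the add-one rule
#' `(1 + #{RSS* >= RSS_obs}) / (1 + n_sim)`, so the smallest attainable p
#' is `1/(1 + n_sim)`.
#'
#' @param hset A `harmonized_set` with >= 4 SNPs.
#' @param n_sim Simulated replicates (default 1000).
#' @param seed Seed for the simulation.
#' @return List `rss_observed, global_pvalue, n_simulations, seed`.
#' @export
presso_global <- function(hset, n_sim = 1000, seed = NULL) {
  hset <- as_hset(hset)
  k <- nrow(hset)
  if (k < 4L) stop("MR-PRESSO requires >= 4 instruments")
  if (!is.null(seed)) set.seed(seed)
  rw <- ratio_weights(hset)
  slopes <- loo_slopes(rw$r, rw$w)
  rss_obs <- presso_rss(hset$big_gamma, hset$gamma, hset$se_big_gamma, slopes)
  resid2 <- presso_sim_resid2(hset, slopes, n_sim)
  rss_star <- rowSums(resid2)
  p <- (1 + sum(rss_star >= rss_obs)) / (1 + n_sim)
  list(rss_observed = rss_obs, global_pvalue = p, n_simulations = n_sim,
       seed = seed)
}

#' MR-PRESSO outlier test
#'
#' Per-SNP add-one tail probabilities of the simulated squared standardized
#' residual exceeding the observed one; SNPs with `p < alpha / k`
#' (Bonferroni) are flagged as outliers.
#'
#' @param hset A `harmonized_set` with >= 4 SNPs.
#' @param n_sim Simulated replicates (default 1000).
#' @param seed Seed for the simulation.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List `pvalues` (named per-SNP), `outliers` (snp_id character
#'   vector), `alpha_bonferroni`.
#' @export
presso_outlier <- function(hset, n_sim = 1000, seed = NULL, alpha = 0.05) {
  hset <- as_hset(hset)
  k <- nrow(hset)
  if (k < 4L) stop("MR-PRESSO requires >= 4 instruments")
  if (!is.null(seed)) set.seed(seed)
  rw <- ratio_weights(hset)
  slopes <- loo_slopes(rw$r, rw$w)
  obs2 <- (hset$big_gamma - slopes * hset$gamma)^2 / hset$se_big_gamma^2
  resid2 <- presso_sim_resid2(hset, slopes, n_sim)
  pvals <- (1 + colSums(resid2 >= matrix(obs2, n_sim, k, byrow = TRUE))) /
    (1 + n_sim)
  names(pvals) <- hset$snp_id
  thr <- alpha / k
  list(pvalues = pvals, outliers = hset$snp_id[pvals < thr],
       alpha_bonferroni = thr)
}

#' MR-PRESSO distortion test
#'
#' Quantifies how much removing the flagged outliers moves the IVW slope:
#' `coefficient = 100 * (beta_no_outliers - beta_all) / |beta_no_outliers|`.
#' The p-value compares the observed shift with shifts from removing random
#' SNP subsets of the same size.
#'
#' @param hset A `harmonized_set`.
#' @param outliers Character vector of outlier snp_ids (subset of the set).
#' @param n_draw Random subsets drawn for the null (default 1000).
#' @param seed Seed for the draws.
#' @return If `outliers` is empty, `list(applicable = FALSE)`; otherwise
#'   `applicable, distortion_coefficient, pvalue, beta_all,
#'   beta_no_outliers`.
#' @export
presso_distortion <- function(hset, outliers, n_draw = 1000, seed = NULL) {
  hset <- as_hset(hset)
  if (length(outliers) == 0L) return(list(applicable = FALSE))
  stopifnot(all(outliers %in% hset$snp_id))
  if (length(outliers) >= nrow(hset))
    stop("all instruments flagged as outliers")
  if (!is.null(seed)) set.seed(seed)
  rw <- ratio_weights(hset)
  ivw_slope <- function(keep) sum(rw$w[keep] * rw$r[keep]) / sum(rw$w[keep])
  all_idx <- seq_len(nrow(hset))
  beta_all <- ivw_slope(all_idx)
  keep_idx <- all_idx[!(hset$snp_id %in% outliers)]
  beta_no <- ivw_slope(keep_idx)
  d_obs <- beta_no - beta_all
  n_out <- length(outliers)
  d_rand <- vapply(seq_len(n_draw), function(i) {
    drop_i <- sample(all_idx, n_out)
    ivw_slope(setdiff(all_idx, drop_i)) - beta_all
  }, numeric(1))
  p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (1 + n_draw)
  list(applicable = TRUE,
       distortion_coefficient = 100 * d_obs / abs(beta_no),
       pvalue = p, beta_all = beta_all, beta_no_outliers = beta_no)
}

#' Full MR-PRESSO analysis
#'
#' Runs the global, outlier and distortion stages and re-estimates IVW with
#' flagged outliers removed.
#'
#' @param hset A `harmonized_set` with >= 4 SNPs.
#' @param n_sim Simulated replicates per stage (default 1000).
#' @param seed Seed; stages derive sub-seeds deterministically from it.
#' @param alpha Outlier significance level (default 0.05).
#' @return List of class `presso_report`: `rss_observed, global_pvalue,
#'   outlier_pvalues, outliers, distortion, corrected (mr_estimate or NULL),
#'   n_simulations, seed`.
#' @export
mr_presso <- function(hset, n_sim = 1000, seed = NULL, alpha = 0.05) {
  hset <- as_hset(hset)
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL)
  else list(seed, seed + 1L, seed + 2L)
  glob <- presso_global(hset, n_sim, seeds[[1]])
  outl <- presso_outlier(hset, n_sim, seeds[[2]], alpha)
  dist <- presso_distortion(hset, outl$outliers, n_sim, seeds[[3]])
  corrected <- if (length(outl$outliers) > 0L &&
                   length(outl$outliers) < nrow(hset) - 1L)
    mr_ivw(hset[!(hset$snp_id %in% outl$outliers), , drop = FALSE])
  else NULL
  structure(list(rss_observed = glob$rss_observed,
                 global_pvalue = glob$global_pvalue,
                 outlier_pvalues = outl$pvalues, outliers = outl$outliers,
                 distortion = dist, corrected = corrected,
                 n_simulations = n_sim, seed = seed),
            class = "presso_report")
}

#' @export
print.presso_report <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.3f, global p = %.4g (%d simulations)\n",
              x$rss_observed, x$global_pvalue, x$n_simulations))
  if (length(x$outliers) > 0L)
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  else cat("  no outliers detected\n")
  invisible(x)
}
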