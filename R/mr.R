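# Build an MREstimate; CI and OR scale derive from (beta, se).
mr_estimate <- function(method, beta, se, pvalue, n_snps, extra = NULL) {
  ci_low <- beta - 1.96 * se
  ci_high <- beta + 1.96 * se
  est <- list(method = method, beta = beta, se = se, pvalue = pvalue,
              ci_low = ci_low, ci_high = ci_high,
              or = exp(beta), or_ci_low = exp(ci_low),
              or_ci_high = exp(ci_high), n_snps = n_snps)
  est <- c(est, extra)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI %.4f to %.4f, p = %.4g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  cat(sprintf("  OR   = %.4f, 95%% CI %.4f to %.4f\n",
              x$or, x$or_ci_low, x$or_ci_high))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.4g\n",
                x$intercept, x$intercept_se, x$intercept_pvalue))
  invisible(x)
}

#' Wald ratio estimate for a single instrument
#'
#' `beta = Gamma / gamma` with first-order SE `se_Gamma / |gamma|` by
#' default; the second-order form
#' `sqrt(se_Gamma^2/gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)` is available.
#'
#' @param gamma,se_gamma SNP-exposure effect and SE (`gamma != 0`).
#' @param big_gamma,se_big_gamma SNP-outcome effect and SE.
#' @param second_order Use the second-order SE. Default FALSE.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(gamma, se_gamma, big_gamma, se_big_gamma,
                       second_order = FALSE) {
  if (gamma == 0) stop("null instrument: gamma = 0")
  beta <- big_gamma / gamma
  se <- if (second_order)
    sqrt(se_big_gamma^2 / gamma^2 + big_gamma^2 * se_gamma^2 / gamma^4)
  else se_big_gamma / abs(gamma)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate("wald_ratio", beta, se, p, 1L)
}

ratio_weights <- function(hset) {
  list(r = hset$big_gamma / hset$gamma,
       w = hset$gamma^2 / hset$se_big_gamma^2)
}

#' Inverse-variance-weighted estimate
#'
#' Meta-analytic combination of per-SNP Wald ratios with first-order
#' inverse-variance weights `w_j = gamma_j^2 / se_Gamma_j^2`, equivalent to
#' weighted regression of Gamma on gamma through the origin. The default
#' multiplicative random-effects SE inflates the fixed-effect SE by
#' `sqrt(max(1, Q/(k-1)))`, never deflating it below the fixed-effect value.
#'
#' @param hset A `harmonized_set` (>= 2 SNPs; a single SNP degrades to
#'   [wald_ratio()] with a message).
#' @param variance_mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with extra fields `q`, `q_df`, `q_pvalue`.
#' @export
mr_ivw <- function(hset,
                   variance_mode = c("multiplicative_random", "fixed")) {
  variance_mode <- match.arg(variance_mode)
  hset <- as_hset(hset)
  k <- nrow(hset)
  if (k == 0L) stop("empty harmonized set")
  if (k == 1L) {
    message("single SNP: IVW degrades to the Wald ratio")
    return(wald_ratio(hset$gamma, hset$se_gamma, hset$big_gamma,
                      hset$se_big_gamma))
  }
  rw <- ratio_weights(hset)
  beta <- sum(rw$w * rw$r) / sum(rw$w)
  se_fixed <- 1 / sqrt(sum(rw$w))
  q <- sum(rw$w * (rw$r - beta)^2)
  se <- if (variance_mode == "multiplicative_random")
    se_fixed * sqrt(max(1, q / (k - 1))) else se_fixed
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate("ivw", beta, se, p, k,
              extra = list(q = q, q_df = k - 1L,
                           q_pvalue = stats::pchisq(q, k - 1L,
                                                    lower.tail = FALSE),
                           variance_mode = variance_mode))
}

#' MR-Egger regression
#'
#' Weighted regression `Gamma = alpha + beta * gamma` (weights
#' `1/se_Gamma^2`) after orienting every SNP so `gamma_j >= 0`. A non-zero
#' intercept `alpha` signals directional pleiotropy. SEs are inflated by
#' `sqrt(max(1, RSS/(k-2)))` and p-values use the t distribution with k-2
#' degrees of freedom.
#'
#' @param hset A `harmonized_set` with >= 3 SNPs.
#' @return An `mr_estimate` for the slope, with extra fields `intercept`,
#'   `intercept_se`, `intercept_pvalue`.
#' @export
mr_egger <- function(hset) {
  hset <- as_hset(hset)
  k <- nrow(hset)
  if (k < 3L) stop("insufficient instruments for Egger (need >= 3)")
  flip <- sign(hset$gamma)
  flip[flip == 0] <- 1
  g <- hset$gamma * flip
  G <- hset$big_gamma * flip
  w <- 1 / hset$se_big_gamma^2
  X <- cbind(intercept = 1, slope = g)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * G)
  coefs <- drop(solve(XtWX, XtWy))
  resid <- G - drop(X %*% coefs)
  sigma2 <- sum(w * resid^2) / (k - 2)
  vcov <- solve(XtWX) * max(1, sigma2)
  ses <- sqrt(diag(vcov))
  tvals <- coefs / ses
  pvals <- 2 * stats::pt(-abs(tvals), df = k - 2)
  est <- mr_estimate("egger", coefs[["slope"]], ses[["slope"]],
                     pvals[["slope"]], k,
                     extra = list(intercept = coefs[["intercept"]],
                                  intercept_se = ses[["intercept"]],
                                  intercept_pvalue = pvals[["intercept"]],
                                  residual_scale = sigma2))
  # t-based CI for consistency with the reported p-value
  tcrit <- stats::qt(0.975, df = k - 2)
  est$ci_low <- est$beta - tcrit * est$se
  est$ci_high <- est$beta + tcrit * est$se
  est$or_ci_low <- exp(est$ci_low)
  est$or_ci_high <- exp(est$ci_high)
  est
}

weighted_median_core <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- cumsum(w)
  p <- s - w / 2
  if (0.5 <= p[1]) return(r[1])
  k <- length(r)
  if (0.5 >= p[k]) return(r[k])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

boot_resample <- function(hset, n_boot, seed, statistic) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(hset)
  vapply(seq_len(n_boot), function(b) {
    g <- stats::rnorm(k, hset$gamma, hset$se_gamma)
    G <- stats::rnorm(k, hset$big_gamma, hset$se_big_gamma)
    statistic(g, G)
  }, numeric(1))
}

#' Weighted-median estimate
#'
#' Consistent when up to half the instrument weight is invalid. The estimate
#' is the weight-0.5 point of the piecewise-linear quantile function through
#' the ordered Wald ratios at cumulative midpoints `(S_j - w_j/2)/S_k`, with
#' weights from inverse first-order Wald variances. The SE comes from a
#' parametric bootstrap resampling `(gamma_j, Gamma_j)` from their normal
#' sampling distributions.
#'
#' @param hset A `harmonized_set` with >= 3 SNPs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap; required for reproducibility.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = NULL) {
  hset <- as_hset(hset)
  k <- nrow(hset)
  if (k < 3L) stop("insufficient instruments for weighted median (need >= 3)")
  rw <- ratio_weights(hset)
  beta <- weighted_median_core(rw$r, rw$w)
  boots <- boot_resample(hset, n_boot, seed, function(g, G) {
    weighted_median_core(G / g, g^2 / hset$se_big_gamma^2)
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate("weighted_median", beta, se, p, k)
}

mode_core <- function(r, w, phi) {
  if (max(r) - min(r) < .Machine$double.eps * 100) return(r[1])
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(r) * length(r)^(-1 / 5)
  h <- phi * s
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- colSums(w / sum(w) * outer(r, grid, function(ri, x)
    stats::dnorm((x - ri) / h)))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The argmax of a normal-kernel density over the Wald ratios, on a
#' 512-point grid spanning the ratio range plus three bandwidths. Bandwidth
#' is `phi` times the modified Silverman scale
#' `0.9 * min(sd, mad) * k^(-1/5)`. Simple mode uses uniform weights;
#' weighted mode uses inverse-variance weights. SE by parametric bootstrap.
#'
#' @param hset A `harmonized_set` with >= 3 SNPs.
#' @param weighted Use inverse-variance weights (weighted mode). Default
#'   FALSE (simple mode).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate` with method `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mr_mode <- function(hset, weighted = FALSE, phi = 1, n_boot = 1000,
                    seed = NULL) {
  hset <- as_hset(hset)
  k <- nrow(hset)
  if (k < 3L) stop("insufficient instruments for mode estimator (need >= 3)")
  rw <- ratio_weights(hset)
  w0 <- if (weighted) rw$w else rep(1, k)
  beta <- mode_core(rw$r, w0, phi)
  boots <- boot_resample(hset, n_boot, seed, function(g, G) {
    wb <- if (weighted) g^2 / hset$se_big_gamma^2 else rep(1, k)
    mode_core(G / g, wb, phi)
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              beta, se, p, k)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (r_j - beta_ref)^2` with first-order inverse Wald-variance
#' weights; p from chi-square with k-1 df.
#'
#' @param hset A `harmonized_set` with >= 2 SNPs.
#' @param beta_ref Reference estimate (defaults to the fixed-effect IVW).
#' @return List `q, q_df, q_pvalue`.
#' @export
cochran_q <- function(hset, beta_ref = NULL) {
  hset <- as_hset(hset)
  k <- nrow(hset)
  stopifnot(k >= 2L)
  rw <- ratio_weights(hset)
  if (is.null(beta_ref)) beta_ref <- sum(rw$w * rw$r) / sum(rw$w)
  q <- sum(rw$w * (rw$r - beta_ref)^2)
  list(q = q, q_df = k - 1L,
       q_pvalue = stats::pchisq(q, k - 1L, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates IVW dropping each SNP in turn; a row that moves the estimate
#' materially flags a disproportionately influential instrument.
#'
#' @param hset A `harmonized_set` with >= 3 SNPs.
#' @param variance_mode Passed to [mr_ivw()].
#' @return data.frame `snp_id, beta, se, pvalue`, one row per dropped SNP.
#' @export
leave_one_out <- function(hset,
                          variance_mode = c("multiplicative_random",
                                            "fixed")) {
  variance_mode <- match.arg(variance_mode)
  hset <- as_hset(hset)
  k <- nrow(hset)
  stopifnot(k >= 3L)
  rows <- lapply(seq_len(k), function(j) {
    est <- mr_ivw(hset[-j, , drop = FALSE], variance_mode)
    data.frame(snp_id = hset$snp_id[j], beta = est$beta, se = est$se,
               pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert a log-odds effect to the odds-ratio scale
#'
#' @param beta Log-odds effect per SD of exposure.
#' @param se Standard error (>= 0).
#' @return List `or, ci_low, ci_high` with `exp(beta +/- 1.96 se)` bounds.
#' @export
to_odds_ratio <- function(beta, se) {
  stopifnot(se >= 0)
  list(or = exp(beta), ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se))
}

#' Run the five standard estimators on one harmonized set
#'
#' IVW, MR-Egger, weighted median, simple mode, and weighted mode. Egger and
#' the median/mode estimators require >= 3 SNPs and are omitted (with a log
#' attribute) below that.
#'
#' @param hset A `harmonized_set`.
#' @param n_boot,seed Bootstrap controls for the stochastic estimators.
#' @return data.frame `exposure outcome method n_snps beta se pvalue ci_low
#'   ci_high or or_ci_low or_ci_high`.
#' @export
mr_all <- function(hset, n_boot = 1000, seed = NULL) {
  hset <- as_hset(hset)
  k <- nrow(hset)
  ests <- list(mr_ivw(hset))
  if (k >= 3L) {
    ests <- c(ests, list(
      mr_egger(hset),
      mr_weighted_median(hset, n_boot, seed),
      mr_mode(hset, weighted = FALSE, n_boot = n_boot,
              seed = if (is.null(seed)) NULL else seed + 1L),
      mr_mode(hset, weighted = TRUE, n_boot = n_boot,
              seed = if (is.null(seed)) NULL else seed + 2L)))
  }
  rows <- lapply(ests, function(e)
    data.frame(exposure = attr(hset, "exposure_trait") %||% "exposure",
               outcome = attr(hset, "outcome_trait") %||% "outcome",
               method = e$method, n_snps = e$n_snps, beta = e$beta,
               se = e$se, pvalue = e$pvalue, ci_low = e$ci_low,
               ci_high = e$ci_high, or = e$or, or_ci_low = e$or_ci_low,
               or_ci_high = e$or_ci_high, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Heterogeneity, pleiotropy-intercept and leave-one-out sensitivity report
#'
#' @param hset A `harmonized_set` with >= 3 SNPs.
#' @return List with `cochran` (`q, q_df, q_pvalue`), `egger_intercept`
#'   (`estimate, se, pvalue`), `leave_one_out` (data.frame), and `wald`
#'   (per-SNP ratio estimates with SEs, the forest/funnel data).
#' @export
sensitivity_report <- function(hset) {
  hset <- as_hset(hset)
  eg <- mr_egger(hset)
  rw <- ratio_weights(hset)
  wald <- data.frame(snp_id = hset$snp_id, beta = rw$r,
                     se = hset$se_big_gamma / abs(hset$gamma),
                     stringsAsFactors = FALSE)
  list(cochran = cochran_q(hset),
       egger_intercept = list(estimate = eg$intercept,
                              se = eg$intercept_se,
                              pvalue = eg$intercept_pvalue),
       leave_one_out = leave_one_out(hset),
       wald = wald)
}
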