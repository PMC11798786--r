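#' Two-step mediation decomposition with delta-method intervals
#'
#' Decomposes a total exposure -> outcome effect (`beta_all`) into the
#' indirect (mediated) path `beta12 = beta1 * beta2` and the direct effect
#' `beta_all - beta12`. The indirect-effect SE is first-order delta with
#' independent steps: `se12 = sqrt(beta2^2 se1^2 + beta1^2 se2^2)`. The
#' mediation proportion `100 * beta12 / beta_all` is only reported when
#' `beta1 * beta2` and `beta_all` share a sign; its CI (first-order delta on
#' the ratio) is suppressed whenever the indirect-effect CI spans zero,
#' because the proportion's bounds then contradict the direction of the
#' total effect.
#'
#' @param beta_all,se_all Total effect and SE.
#' @param beta1,se1 Exposure -> mediator effect and SE.
#' @param beta2,se2 Adjusted mediator -> outcome effect and SE.
#' @return A `mediation_result` list: `beta1, se1, beta2, se2, beta_all,
#'   se_all, beta12, se12, ci12_low, ci12_high, pvalue12, direct_effect,
#'   proportion, prop_ci_low, prop_ci_high, ci_spans_zero,
#'   directions_inconsistent`.
#' @export
decompose_mediation <- function(beta_all, se_all, beta1, se1, beta2, se2) {
  stopifnot(se_all >= 0, se1 >= 0, se2 >= 0)
  beta12 <- beta1 * beta2
  se12 <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
  ci12 <- beta12 + c(-1.96, 1.96) * se12
  direct <- beta_all - beta12
  p12 <- if (se12 > 0) 2 * stats::pnorm(-abs(beta12 / se12)) else
    as.numeric(beta12 == 0)
  spans_zero <- ci12[1] < 0 && ci12[2] > 0
  inconsistent <- beta_all == 0 || (beta12 != 0 && sign(beta12) != sign(beta_all))
  proportion <- prop_lo <- prop_hi <- NA_real_
  if (!inconsistent) {
    proportion <- 100 * beta12 / beta_all
    if (!spans_zero) {
      se_prop <- 100 * sqrt(se12^2 / beta_all^2 +
                              beta12^2 * se_all^2 / beta_all^4)
      prop_lo <- proportion - 1.96 * se_prop
      prop_hi <- proportion + 1.96 * se_prop
    }
  }
  structure(list(beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 beta_all = beta_all, se_all = se_all,
                 beta12 = beta12, se12 = se12,
                 ci12_low = ci12[1], ci12_high = ci12[2], pvalue12 = p12,
                 direct_effect = direct, proportion = proportion,
                 prop_ci_low = prop_lo, prop_ci_high = prop_hi,
                 ci_spans_zero = spans_zero,
                 directions_inconsistent = inconsistent),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("total %.4f, direct %.4f, mediated %.4f (95%% CI %.4f to %.4f), p = %.4g\n",
              x$beta_all, x$direct_effect, x$beta12, x$ci12_low,
              x$ci12_high, x$pvalue12))
  if (x$directions_inconsistent)
    cat("  proportion not computed (inconsistent effect directions)\n")
  else if (x$ci_spans_zero)
    cat(sprintf("  proportion %.2f%% (CI suppressed: mediated-effect CI spans 0)\n",
                x$proportion))
  else
    cat(sprintf("  proportion %.2f%% (95%% CI %.2f%% to %.2f%%)\n",
                x$proportion, x$prop_ci_low, x$prop_ci_high))
  invisible(x)
}

#' Mediator -> outcome effect adjusted for the exposure
#'
#' Step 2 of the two-step design. In `snp_exclusion` mode (the default),
#' mediator instruments that are associated with the exposure at the
#' instrument threshold, or in LD with any exposure instrument, are removed
#' before an ordinary IVW mediator -> outcome analysis. In `mvmr` mode, the
#' union of exposure and mediator instruments enters a joint weighted
#' regression of the outcome effects on both exposure and mediator effects
#' (through the origin, weights `1/se_Gamma^2`) and the mediator coefficient
#' is reported.
#'
#' @param mediator_stats,outcome_stats,exposure_stats Summary-statistics
#'   data.frames sharing snp_ids.
#' @param mode `"snp_exclusion"` (default) or `"mvmr"`.
#' @param p_threshold Instrument threshold (default 1e-5).
#' @param ld LD r-squared source (see [clump()]).
#' @param r2_max,window_kb Clumping parameters.
#' @return An `mr_estimate` for the adjusted mediator -> outcome effect,
#'   with attribute `adjustment` recording the mode and instrument counts
#'   before/after adjustment.
#' @export
adjusted_step2 <- function(mediator_stats, outcome_stats, exposure_stats,
                           mode = c("snp_exclusion", "mvmr"),
                           p_threshold = 1e-5, ld = NULL, r2_max = 0.001,
                           window_kb = 10000) {
  mode <- match.arg(mode)
  med_sel <- select_instruments(mediator_stats, p_threshold, ld,
                                r2_max, window_kb)
  med_ids <- med_sel$instruments$snp_id
  exp_cand <- tryCatch(select_candidates(exposure_stats, p_threshold),
                       error = function(e) exposure_stats[0, , drop = FALSE])
  if (mode == "snp_exclusion") {
    exp_assoc <- med_ids %in% exp_cand$snp_id
    in_ld <- vapply(med_ids, function(id) {
      any(vapply(exp_cand$snp_id, function(eid)
        id != eid && ld_r2_lookup(ld, id, eid) >= r2_max, logical(1)))
    }, logical(1))
    keep_ids <- med_ids[!exp_assoc & !in_ld]
    if (length(keep_ids) < 2L) stop("underidentified step 2")
    med_sub <- mediator_stats[mediator_stats$snp_id %in% keep_ids, ,
                              drop = FALSE]
    hset <- harmonize(med_sub, outcome_stats,
                      exposure_trait = "mediator", outcome_trait = "outcome")
    est <- mr_ivw(hset)
    attr(est, "adjustment") <- list(mode = mode,
                                    n_before = length(med_ids),
                                    n_after = length(keep_ids))
    return(est)
  }
  # mvmr: union instruments, joint weighted regression through the origin
  exp_sel <- select_instruments(exposure_stats, p_threshold, ld,
                                r2_max, window_kb)
  union_ids <- union(exp_sel$instruments$snp_id, med_ids)
  h_exp <- harmonize(exposure_stats[exposure_stats$snp_id %in% union_ids, ],
                     outcome_stats, exposure_trait = "exposure")
  h_med <- harmonize(mediator_stats[mediator_stats$snp_id %in% union_ids, ],
                     outcome_stats, exposure_trait = "mediator")
  common <- intersect(h_exp$snp_id, h_med$snp_id)
  if (length(common) < 3L) stop("underidentified step 2")
  ie <- match(common, h_exp$snp_id)
  im <- match(common, h_med$snp_id)
  X <- cbind(exposure = h_exp$gamma[ie], mediator = h_med$gamma[im])
  y <- h_exp$big_gamma[ie]
  w <- 1 / h_exp$se_big_gamma[ie]^2
  XtWX <- crossprod(X, w * X)
  coefs <- drop(solve(XtWX, crossprod(X, w * y)))
  resid <- y - drop(X %*% coefs)
  sigma2 <- sum(w * resid^2) / (length(common) - 2)
  vcov <- solve(XtWX) * max(1, sigma2)
  se <- sqrt(diag(vcov))
  p <- 2 * stats::pnorm(-abs(coefs / se))
  est <- mr_estimate("mvmr_mediator", coefs[["mediator"]],
                     se[["mediator"]], p[["mediator"]], length(common),
                     extra = list(exposure_beta = coefs[["exposure"]],
                                  exposure_se = se[["exposure"]],
                                  exposure_pvalue = p[["exposure"]]))
  attr(est, "adjustment") <- list(mode = mode,
                                  n_before = length(union_ids),
                                  n_after = length(common))
  est
}

#' Scan lipid x metabolite pairs for mediated pathways
#'
#' For every (exposure, mediator) pair: estimates the exposure -> mediator
#' effect (step 1, kept when `p < step1_p`), the adjusted mediator ->
#' outcome effect (step 2), and the total exposure -> outcome effect, then
#' decomposes them via [decompose_mediation()]. Rows are sorted by absolute
#' mediated effect, descending.
#'
#' @param exposures Named list of exposure summary-statistics tables.
#' @param mediators Named list of mediator summary-statistics tables.
#' @param outcome Outcome summary-statistics table.
#' @param ld LD r-squared source.
#' @param p_threshold Instrument threshold (default 1e-5).
#' @param step1_p Significance filter on the exposure -> mediator effect
#'   (default 0.05).
#' @param mode Step-2 adjustment mode (see [adjusted_step2()]).
#' @param r2_max,window_kb Clumping parameters.
#' @return data.frame `exposure mediator outcome beta_all direct beta12
#'   ci12_low ci12_high pvalue proportion prop_ci_low prop_ci_high flags
#'   adjustment_mode`, one row per retained pair.
#' @export
mediation_scan <- function(exposures, mediators, outcome, ld = NULL,
                           p_threshold = 1e-5, step1_p = 0.05,
                           mode = c("snp_exclusion", "mvmr"),
                           r2_max = 0.001, window_kb = 10000) {
  mode <- match.arg(mode)
  if (length(exposures) == 0L || length(mediators) == 0L) {
    warning("empty candidate sets: no pathways to scan")
    return(data.frame())
  }
  rows <- list()
  for (en in names(exposures)) {
    exp_stats <- exposures[[en]]
    sel <- tryCatch(select_instruments(exp_stats, p_threshold, ld,
                                       r2_max, window_kb),
                    error = function(e) NULL)
    if (is.null(sel)) next
    exp_inst <- exp_stats[exp_stats$snp_id %in% sel$instruments$snp_id, ]
    h_all <- harmonize(exp_inst, outcome, exposure_trait = en)
    est_all <- mr_ivw(h_all)
    for (mn in names(mediators)) {
      med_stats <- mediators[[mn]]
      h1 <- harmonize(exp_inst, med_stats, exposure_trait = en,
                      outcome_trait = mn)
      est1 <- mr_ivw(h1)
      if (est1$pvalue >= step1_p) next
      est2 <- tryCatch(
        adjusted_step2(med_stats, outcome, exp_stats, mode,
                       p_threshold, ld, r2_max, window_kb),
        error = function(e) NULL)
      if (is.null(est2)) next
      dec <- decompose_mediation(est_all$beta, est_all$se,
                                 est1$beta, est1$se, est2$beta, est2$se)
      flags <- paste(c(if (dec$ci_spans_zero) "ci_spans_zero",
                       if (dec$directions_inconsistent)
                         "directions_inconsistent"), collapse = ";")
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = en, mediator = mn, outcome = "outcome",
        beta_all = dec$beta_all, direct = dec$direct_effect,
        beta12 = dec$beta12, ci12_low = dec$ci12_low,
        ci12_high = dec$ci12_high, pvalue = dec$pvalue12,
        proportion = dec$proportion, prop_ci_low = dec$prop_ci_low,
        prop_ci_high = dec$prop_ci_high, flags = flags,
        adjustment_mode = mode, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    warning("no pathway passed the step-1 filter")
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$beta12)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
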