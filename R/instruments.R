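#' Select candidate instruments by p-value threshold
#'
#' @param stats Validated summary-statistics data.frame.
#' @param p_threshold Significance level; SNPs with `pvalue < p_threshold`
#'   are candidates. Conventional choices are 1e-5 for molecular traits with
#'   few genome-wide hits and 5e-8 for well-powered disease GWAS.
#' @return The candidate rows sorted by ascending p-value (ties broken by
#'   `snp_id`).
#' @export
select_candidates <- function(stats, p_threshold) {
  stopifnot(is.data.frame(stats), p_threshold > 0, p_threshold <= 1)
  keep <- stats[stats$pvalue < p_threshold, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no instruments at threshold ", p_threshold)
  keep <- keep[order(keep$pvalue, keep$snp_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

ld_r2_lookup <- function(ld, a, b) {
  if (is.null(ld)) return(0)
  if (is.function(ld)) return(ld(a, b))
  if (a %in% rownames(ld) && b %in% colnames(ld)) return(ld[a, b])
  0  # missing pair treated as unlinked
}

#' Greedy LD clumping
#'
#' Repeatedly retains the lowest-p unclaimed SNP and discards all unclaimed
#' SNPs on the same chromosome within `window_kb` whose squared correlation
#' with it is at least `r2_max`. Ties on p are broken by lexicographic
#' `snp_id`, making the result invariant to input row order.
#'
#' @param candidates data.frame with `snp_id, chrom, pos, pvalue`.
#' @param ld Square r-squared matrix with snp_id dimnames, or a function
#'   `(id_a, id_b) -> r2`, or NULL (all pairs unlinked). Missing pairs are
#'   treated as r2 = 0.
#' @param r2_max Exclusion threshold on r-squared (default 0.001).
#' @param window_kb Physical window in kilobases (default 10000).
#' @return Character vector of retained snp_ids, in retention order.
#' @export
clump <- function(candidates, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  stopifnot(all(c("snp_id", "chrom", "pos", "pvalue") %in% names(candidates)))
  cand <- candidates[order(candidates$pvalue, candidates$snp_id), ,
                     drop = FALSE]
  unclaimed <- rep(TRUE, nrow(cand))
  retained <- character(0)
  while (any(unclaimed)) {
    i <- which(unclaimed)[1L]
    retained <- c(retained, cand$snp_id[i])
    unclaimed[i] <- FALSE
    for (j in which(unclaimed)) {
      if (cand$chrom[j] != cand$chrom[i]) next
      if (abs(cand$pos[j] - cand$pos[i]) > window_kb * 1000) next
      if (ld_r2_lookup(ld, cand$snp_id[i], cand$snp_id[j]) >= r2_max)
        unclaimed[j] <- FALSE
    }
  }
  retained
}

#' Per-SNP variance explained in the exposure
#'
#' Default form `t^2 / (t^2 + n - 2)` with `t = beta/se` needs only the
#' statistics present in any GWAS table; for standardized traits the
#' EAF-based alternative `2 * eaf * (1 - eaf) * beta^2` is available.
#' Summed over instruments it gives the total R-squared feeding the
#' F-statistic.
#'
#' @param beta,se Effect and standard error (vectorized).
#' @param n Sample size (> 2).
#' @param method `"tstat"` (default) or `"eaf"`.
#' @param eaf Effect-allele frequency, required for `method = "eaf"`.
#' @return Variance-explained fraction in [0, 1).
#' @export
snp_r2 <- function(beta, se, n, method = c("tstat", "eaf"), eaf = NULL) {
  method <- match.arg(method)
  if (method == "eaf") {
    stopifnot(!is.null(eaf))
    return(2 * eaf * (1 - eaf) * beta^2)
  }
  stopifnot(all(se > 0), all(n > 2))
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Instrument-strength F-statistic
#'
#' `F = (N - 2) * R2 / (1 - R2)`; values above 10 are the conventional
#' screen for strong instruments.
#'
#' @param n Sample size (> 2).
#' @param r2 Variance explained, in [0, 1).
#' @return The F value (vectorized).
#' @export
f_statistic <- function(n, r2) {
  stopifnot(all(n > 2))
  if (any(r2 >= 1) || any(r2 < 0)) stop("r2 must lie in [0, 1)")
  (n - 2) * r2 / (1 - r2)
}

#' Steiger direction filtering
#'
#' For each instrument compares the variance explained in the exposure
#' (`r2_x`) with that explained in the outcome (`r2_y`), both via
#' [snp_r2()]. SNPs with `r2_y > r2_x` likely act on the outcome first and
#' are dropped. A two-sided z-test on the difference of Fisher-transformed
#' correlations is reported per SNP as a confidence annotation but does not
#' drive the drop decision.
#'
#' @param hset A `harmonized_set` with `n_exposure` and `n_outcome` present.
#' @return List with `hset` (the filtered set) and `verdicts` (data.frame
#'   `snp_id, r2_exposure, r2_outcome, direction, z, pvalue`).
#' @export
steiger_filter <- function(hset) {
  hset <- as_hset(hset)
  stopifnot(all(is.finite(hset$n_exposure)), all(is.finite(hset$n_outcome)))
  r2x <- snp_r2(hset$gamma, hset$se_gamma, hset$n_exposure)
  r2y <- snp_r2(hset$big_gamma, hset$se_big_gamma, hset$n_outcome)
  forward <- r2y <= r2x
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (hset$n_exposure - 3) + 1 / (hset$n_outcome - 3))
  verdicts <- data.frame(
    snp_id = hset$snp_id, r2_exposure = r2x, r2_outcome = r2y,
    direction = ifelse(forward, "forward", "reverse"),
    z = z, pvalue = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  kept <- hset[forward, , drop = FALSE]
  rownames(kept) <- NULL
  attributes(kept)[c("exposure_trait", "outcome_trait")] <-
    attributes(hset)[c("exposure_trait", "outcome_trait")]
  class(kept) <- class(hset)
  list(hset = kept, verdicts = verdicts)
}

#' Full instrument-selection cascade
#'
#' p-value thresholding, greedy LD clumping, and per-SNP F screening, with
#' audit counts at every stage. Steiger filtering operates on harmonized
#' pairs and is applied separately via [steiger_filter()].
#'
#' @param stats Exposure summary statistics.
#' @param p_threshold Instrument p-value threshold (default 1e-5).
#' @param ld LD r-squared source for [clump()].
#' @param r2_max,window_kb Clumping parameters.
#' @param f_min Minimum per-SNP F-statistic (default 10).
#' @return List with `instruments` (data.frame of retained rows plus `r2`
#'   and `f_stat` columns), `total_r2`, `overall_f` (F from summed r2), and
#'   `audit` (named counts: candidates, removed_clump, removed_f, retained).
#' @export
select_instruments <- function(stats, p_threshold = 1e-5, ld = NULL,
                               r2_max = 0.001, window_kb = 10000,
                               f_min = 10) {
  cand <- select_candidates(stats, p_threshold)
  kept_ids <- clump(cand, ld, r2_max, window_kb)
  inst <- cand[match(kept_ids, cand$snp_id), , drop = FALSE]
  inst$r2 <- snp_r2(inst$beta, inst$se, inst$n)
  inst$f_stat <- f_statistic(inst$n, inst$r2)
  weak <- inst$f_stat <= f_min
  audit <- c(candidates = nrow(cand),
             removed_clump = nrow(cand) - length(kept_ids),
             removed_f = sum(weak), retained = sum(!weak))
  inst <- inst[!weak, , drop = FALSE]
  if (nrow(inst) == 0L) stop("no instruments pass the F screen")
  rownames(inst) <- NULL
  total_r2 <- sum(inst$r2)
  list(instruments = inst, total_r2 = total_r2,
       overall_f = f_statistic(inst$n[1], min(total_r2, 1 - 1e-12)),
       audit = audit)
}
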