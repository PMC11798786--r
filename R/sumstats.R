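# Canonical column order of the summary-statistics dialect.
SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Read GWAS summary statistics
#'
#' Reads a tab- or comma-delimited table of per-SNP association statistics
#' (one row per SNP: identifier, chromosome, position, effect allele, other
#' allele, effect-allele frequency, beta, standard error, p-value, sample
#' size). Rows violating hard invariants (non-ACGT or identical alleles,
#' non-positive SE, frequency outside (0,1), p-value outside (0,1],
#' non-finite beta, non-positive N) are dropped and logged; a p-value that
#' disagrees with the two-sided normal test of beta/se by more than 10%
#' relative tolerance only triggers a warning, since published tables
#' routinely carry rounded p-values.
#'
#' @param path Path to a delimited text file with a header row. The
#'   delimiter (tab or comma) is sniffed from the header line.
#' @param column_map Optional named character vector renaming file columns to
#'   the canonical names, e.g. `c(snp_id = "rsid", pvalue = "p")` maps the
#'   file's `rsid` column to `snp_id`.
#' @return A `data.frame` with columns `snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pvalue, n` and an attribute `drop_log`
#'   (data.frame `snp_id, reason`) recording rejected rows.
#' @seealso [write_sumstats()], [harmonize()]
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty summary-statistics file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      idx <- match(column_map[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }
  missing_cols <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("empty summary-statistics file: ", path)
  df <- df[SUMSTATS_COLS]
  df$chrom <- as.character(df$chrom)
  df$snp_id <- as.character(df$snp_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    df[[col]] <- as.numeric(df[[col]])
  validate_sumstats(df)
}

# Enforce SummaryStatRecord invariants; attach a drop log.
validate_sumstats <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad_allele <- !(df$effect_allele %in% ALLELES) |
    !(df$other_allele %in% ALLELES)
  reason[bad_allele] <- "invalid allele (non-SNP or multi-allelic)"
  same <- !bad_allele & df$effect_allele == df$other_allele
  reason[same] <- "identical alleles"
  reason[is.na(reason) & (!is.finite(df$se) | df$se <= 0)] <- "nonpositive SE"
  reason[is.na(reason) & (!is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1)] <-
    "EAF outside (0,1)"
  reason[is.na(reason) & (!is.finite(df$pvalue) | df$pvalue <= 0 |
                            df$pvalue > 1)] <- "p-value outside (0,1]"
  reason[is.na(reason) & !is.finite(df$beta)] <- "non-finite beta"
  reason[is.na(reason) & (!is.finite(df$n) | df$n < 1)] <- "nonpositive N"
  reason[is.na(reason) & (!is.finite(df$pos) | df$pos < 1)] <- "invalid position"
  drop <- !is.na(reason)
  drop_log <- data.frame(snp_id = df$snp_id[drop], reason = reason[drop],
                         stringsAsFactors = FALSE)
  kept <- df[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  # soft check: p consistent with beta/se under two-sided normal
  if (nrow(kept) > 0L) {
    p_exp <- 2 * stats::pnorm(-abs(kept$beta / kept$se))
    rel <- abs(kept$pvalue - p_exp) / pmax(p_exp, .Machine$double.xmin)
    n_bad <- sum(rel > 0.10 & p_exp > 1e-300)
    if (n_bad > 0L)
      warning(n_bad, " record(s) have p-values inconsistent with beta/se ",
              "beyond 10% relative tolerance (kept; likely rounding)")
  }
  attr(kept, "drop_log") <- drop_log
  kept
}

#' Write GWAS summary statistics
#'
#' Writes the canonical tab-delimited dialect: header
#' `snp_id chrom pos effect_allele other_allele eaf beta se pvalue n`,
#' floats rendered with 6 significant digits. The output is re-readable by
#' [read_sumstats()] and a write/read/write cycle is byte-identical.
#'
#' @param records Validated summary-statistics data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  cols <- SUMSTATS_COLS
  out <- data.frame(matrix(nrow = nrow(records), ncol = 0L))
  for (col in cols) {
    x <- records[[col]]
    out[[col]] <- if (col %in% c("eaf", "beta", "se", "pvalue"))
      formatC(x, digits = 6, format = "g")
    else if (col %in% c("pos", "n")) formatC(x, format = "d")
    else as.character(x)
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to path: ", path))
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0L)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the SNP-outcome associations to the effect allele of the
#' SNP-exposure associations, producing the (gamma_j, Gamma_j) pairs that all
#' MR estimators consume. SNPs are joined strictly on `snp_id`. When the
#' outcome alleles are swapped relative to the exposure, the outcome beta is
#' negated and its EAF replaced by 1 - EAF; when they are the strand
#' complement they are complemented before comparison. Palindromic SNPs (A/T
#' or C/G) carry no strand information in their alleles, so they are aligned
#' by allele frequency and only retained when both EAFs fall outside
#' `[0.5 - window, 0.5 + window]`.
#'
#' @param exposure,outcome Summary-statistics data.frames (see
#'   [read_sumstats()]).
#' @param palindrome_eaf_window Half-width of the ambiguity window around
#'   EAF = 0.5 inside which palindromic SNPs are dropped. Default 0.08.
#' @param exposure_trait,outcome_trait Trait labels stored on the result.
#' @return A `harmonized_set`: a data.frame with columns `snp_id, gamma,
#'   se_gamma, gamma_pvalue, big_gamma, se_big_gamma, eaf, n_exposure,
#'   n_outcome`, plus attributes `exposure_trait`, `outcome_trait` and
#'   `harmonization_log` (data.frame `snp_id, action, reason`).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      exposure_trait = "exposure", outcome_trait = "outcome") {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  if (anyDuplicated(exposure$snp_id) || anyDuplicated(outcome$snp_id))
    stop("duplicated snp_id in input table")
  w <- palindrome_eaf_window
  log_rows <- list()
  note <- function(id, action, reason)
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(snp_id = id, action = action, reason = reason,
                 stringsAsFactors = FALSE)

  only_exp <- setdiff(exposure$snp_id, outcome$snp_id)
  only_out <- setdiff(outcome$snp_id, exposure$snp_id)
  for (id in only_exp) note(id, "dropped", "not in outcome")
  for (id in only_out) note(id, "dropped", "not in exposure")

  common <- intersect(exposure$snp_id, outcome$snp_id)
  ex <- exposure[match(common, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(common, outcome$snp_id), , drop = FALSE]

  keep <- logical(length(common))
  big_gamma <- ou$beta
  for (i in seq_along(common)) {
    e_ea <- ex$effect_allele[i]; e_oa <- ex$other_allele[i]
    o_ea <- ou$effect_allele[i]; o_oa <- ou$other_allele[i]
    id <- common[i]
    if (is_palindromic(e_ea, e_oa)) {
      # letters alone cannot resolve strand; orientation comes from EAF
      swapped <- if (o_ea == e_ea && o_oa == e_oa) FALSE
      else if (o_ea == e_oa && o_oa == e_ea) TRUE
      else { note(id, "dropped", "allele mismatch"); next }
      eaf_out <- if (swapped) 1 - ou$eaf[i] else ou$eaf[i]
      if (abs(ex$eaf[i] - 0.5) <= w || abs(eaf_out - 0.5) <= w) {
        note(id, "dropped", "ambiguous palindromic")
        next
      }
      concordant <- (ex$eaf[i] - 0.5) * (eaf_out - 0.5) > 0
      if (concordant) {
        big_gamma[i] <- if (swapped) -ou$beta[i] else ou$beta[i]
        note(id, if (swapped) "sign-flipped" else "kept",
             "palindromic, EAF-aligned")
      } else {
        big_gamma[i] <- if (swapped) ou$beta[i] else -ou$beta[i]
        note(id, if (swapped) "kept" else "sign-flipped",
             "palindromic, EAF-aligned (opposite strand)")
      }
      keep[i] <- TRUE
    } else {
      c_ea <- unname(COMPLEMENT[o_ea]); c_oa <- unname(COMPLEMENT[o_oa])
      if (o_ea == e_ea && o_oa == e_oa) {
        note(id, "kept", "alleles match")
      } else if (o_ea == e_oa && o_oa == e_ea) {
        big_gamma[i] <- -ou$beta[i]
        note(id, "sign-flipped", "alleles swapped")
      } else if (c_ea == e_ea && c_oa == e_oa) {
        note(id, "strand-flipped", "strand complement")
      } else if (c_ea == e_oa && c_oa == e_ea) {
        big_gamma[i] <- -ou$beta[i]
        note(id, "strand-sign-flipped", "strand complement, swapped")
      } else {
        note(id, "dropped", "allele mismatch")
        next
      }
      keep[i] <- TRUE
    }
  }

  hset <- data.frame(
    snp_id = common[keep],
    gamma = ex$beta[keep], se_gamma = ex$se[keep],
    gamma_pvalue = ex$pvalue[keep],
    big_gamma = big_gamma[keep], se_big_gamma = ou$se[keep],
    eaf = ex$eaf[keep],
    n_exposure = ex$n[keep], n_outcome = ou$n[keep],
    stringsAsFactors = FALSE)
  if (nrow(hset) == 0L) stop("no instruments after harmonization")
  log_df <- do.call(rbind, log_rows)
  rownames(hset) <- NULL
  structure(hset,
            exposure_trait = exposure_trait, outcome_trait = outcome_trait,
            harmonization_log = log_df,
            class = c("harmonized_set", "data.frame"))
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor used by the estimators and in simulations where
#' exposure and outcome tables already share effect alleles.
#'
#' @param gamma,se_gamma SNP-exposure effects and standard errors.
#' @param big_gamma,se_big_gamma SNP-outcome effects and standard errors.
#' @param snp_id Optional SNP identifiers.
#' @param gamma_pvalue Optional SNP-exposure p-values (two-sided normal
#'   recomputed when absent).
#' @param eaf,n_exposure,n_outcome Optional frequency and sample sizes.
#' @param exposure_trait,outcome_trait Trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(gamma, se_gamma, big_gamma, se_big_gamma,
                           snp_id = NULL, gamma_pvalue = NULL, eaf = NA_real_,
                           n_exposure = NA_real_, n_outcome = NA_real_,
                           exposure_trait = "exposure",
                           outcome_trait = "outcome") {
  k <- length(gamma)
  stopifnot(length(se_gamma) == k, length(big_gamma) == k,
            length(se_big_gamma) == k, all(se_gamma > 0),
            all(se_big_gamma > 0), all(is.finite(gamma)),
            all(is.finite(big_gamma)))
  if (is.null(snp_id)) snp_id <- sprintf("snp%03d", seq_len(k))
  if (is.null(gamma_pvalue))
    gamma_pvalue <- 2 * stats::pnorm(-abs(gamma / se_gamma))
  structure(
    data.frame(snp_id = snp_id, gamma = gamma, se_gamma = se_gamma,
               gamma_pvalue = gamma_pvalue, big_gamma = big_gamma,
               se_big_gamma = se_big_gamma, eaf = eaf,
               n_exposure = n_exposure, n_outcome = n_outcome,
               stringsAsFactors = FALSE),
    exposure_trait = exposure_trait, outcome_trait = outcome_trait,
    harmonization_log = NULL,
    class = c("harmonized_set", "data.frame"))
}

#' Harmonization log accessor
#' @param hset A `harmonized_set`.
#' @return data.frame `snp_id, action, reason`, or NULL.
#' @export
harmonization_log <- function(hset) attr(hset, "harmonization_log")

as_hset <- function(x) {
  need <- c("gamma", "se_gamma", "big_gamma", "se_big_gamma")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("expected a harmonized_set (columns gamma, se_gamma, big_gamma, se_big_gamma)")
  x
}
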