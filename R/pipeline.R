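#' Screening configuration
#'
#' Collects the thresholds of the multi-exposure screen. Instrument
#' thresholds default to 1e-5 for molecular exposures and 5e-8 when the
#' disease outcome plays the exposure role (reverse MR). IVW significance
#' gates default to 0.05 for lipids and 0.01 for metabolites; since the
#' field uses both conventions, the screen table carries a flag for each.
#'
#' @param exposures Named list of exposure summary-statistics tables.
#' @param outcome Outcome summary-statistics table.
#' @param classes Character vector (`"lipid"` or `"metabolite"`) parallel to
#'   `exposures`; recycled if length 1.
#' @param ld LD r-squared source (see [clump()]).
#' @param p_instrument Instrument p-threshold (default 1e-5).
#' @param p_instrument_disease Threshold when the disease trait is the
#'   exposure (default 5e-8).
#' @param r2_max,window_kb Clumping parameters (defaults 0.001, 10000).
#' @param f_min Minimum per-SNP F (default 10).
#' @param sig_lipid,sig_metabolite IVW significance gates (0.05, 0.01).
#' @param egger_gate Intercept p-value above which no directional
#'   pleiotropy is declared (default 0.05).
#' @param n_boot Bootstrap replicates for stochastic estimators.
#' @param seed Integer seed; per-exposure sub-seeds derive from it.
#' @param outdir Output directory for [make_report()].
#' @return List of class `screen_config`.
#' @export
screen_config <- function(exposures, outcome, classes = "lipid", ld = NULL,
                          p_instrument = 1e-5, p_instrument_disease = 5e-8,
                          r2_max = 0.001, window_kb = 10000, f_min = 10,
                          sig_lipid = 0.05, sig_metabolite = 0.01,
                          egger_gate = 0.05, n_boot = 1000, seed = 1L,
                          outdir = NULL) {
  stopifnot(is.list(exposures), is.data.frame(outcome) || is.null(outcome))
  if (length(classes) == 1L) classes <- rep(classes, length(exposures))
  stopifnot(length(classes) == length(exposures),
            all(classes %in% c("lipid", "metabolite", "disease")),
            p_instrument > 0, p_instrument <= 1,
            sig_lipid > 0, sig_lipid < 1, sig_metabolite > 0,
            sig_metabolite < 1)
  structure(list(exposures = exposures, outcome = outcome,
                 classes = classes, ld = ld, p_instrument = p_instrument,
                 p_instrument_disease = p_instrument_disease,
                 r2_max = r2_max, window_kb = window_kb, f_min = f_min,
                 sig_lipid = sig_lipid, sig_metabolite = sig_metabolite,
                 egger_gate = egger_gate, n_boot = n_boot,
                 seed = as.integer(seed), outdir = outdir),
            class = "screen_config")
}

screen_one <- function(name, stats, class, config, seed) {
  p_thr <- if (class == "disease") config$p_instrument_disease
  else config$p_instrument
  sel <- select_instruments(stats, p_thr, config$ld, config$r2_max,
                            config$window_kb, config$f_min)
  inst <- stats[stats$snp_id %in% sel$instruments$snp_id, , drop = FALSE]
  hset <- harmonize(inst, config$outcome, exposure_trait = name)
  st <- steiger_filter(hset)
  hset <- st$hset
  k <- nrow(hset)
  ivw <- mr_ivw(hset)
  sens <- if (k >= 3L) sensitivity_report(hset) else NULL
  presso_p <- if (k >= 4L)
    presso_global(hset, config$n_boot, seed)$global_pvalue else NA_real_
  egger_p <- if (!is.null(sens)) sens$egger_intercept$pvalue else NA_real_
  q_p <- if (k >= 2L) cochran_q(hset)$q_pvalue else NA_real_
  sig_thr <- if (class == "metabolite") config$sig_metabolite
  else config$sig_lipid
  row <- data.frame(
    exposure = name, class = class, n_snps = k,
    beta = ivw$beta, se = ivw$se, pvalue = ivw$pvalue,
    ci_low = ivw$ci_low, ci_high = ivw$ci_high,
    or = ivw$or, or_ci_low = ivw$or_ci_low, or_ci_high = ivw$or_ci_high,
    min_f = min(sel$instruments$f_stat), q_pvalue = q_p,
    egger_intercept_pvalue = egger_p, presso_global_pvalue = presso_p,
    steiger_forward = sum(st$verdicts$direction == "forward"),
    pass_significance = ivw$pvalue < sig_thr,
    pass_nominal = ivw$pvalue < 0.05,
    pass_egger_gate = is.na(egger_p) || egger_p > config$egger_gate,
    pass_f_gate = min(sel$instruments$f_stat) > config$f_min,
    stringsAsFactors = FALSE)
  list(row = row, hset = hset, sensitivity = sens, estimates = mr_all(
    hset, n_boot = config$n_boot, seed = seed))
}

#' Run the multi-exposure screen
#'
#' For each exposure: instrument selection, harmonization against the
#' outcome, Steiger filtering, the five estimators, heterogeneity and
#' pleiotropy diagnostics, and pass/fail gates (IVW significance at the
#' class threshold and at the nominal 0.05, Egger-intercept gate, F gate).
#' Exposures failing instrument selection are logged and skipped.
#'
#' @param config A [screen_config()].
#' @return List of class `screen_result` with `table` (one row per screened
#'   exposure), `estimates` (all-method results per exposure), `sensitivity`
#'   (per-exposure sensitivity reports), `skipped` (named reasons).
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  if (length(config$exposures) == 0L) {
    warning("empty exposure list")
    return(structure(list(table = data.frame(), estimates = list(),
                          sensitivity = list(), skipped = character(0),
                          config = config), class = "screen_result"))
  }
  rows <- list(); ests <- list(); sens <- list(); skipped <- character(0)
  for (i in seq_along(config$exposures)) {
    name <- names(config$exposures)[i] %||% paste0("exposure", i)
    res <- tryCatch(
      screen_one(name, config$exposures[[i]], config$classes[i], config,
                 seed = config$seed + i),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[name] <- conditionMessage(res)
      next
    }
    rows[[name]] <- res$row
    ests[[name]] <- res$estimates
    sens[[name]] <- res$sensitivity
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame()
  # nominal thresholds are the field's convention; BH q-values logged for
  # transparency, never used as a gate
  if (nrow(tab) > 0L)
    tab$q_value_bh <- stats::p.adjust(tab$pvalue, method = "BH")
  structure(list(table = tab, estimates = ests, sensitivity = sens,
                 skipped = skipped, config = config),
            class = "screen_result")
}

#' Reverse-direction MR screen
#'
#' Swaps roles: the disease outcome becomes the exposure (instrumented at
#' the genome-wide threshold) and each previously screened trait becomes an
#' outcome. Output schema matches [run_screen()].
#'
#' @param config A [screen_config()]; its `outcome` is instrumented at
#'   `p_instrument_disease`.
#' @param targets Optional character vector restricting which exposures to
#'   test in reverse (default: all).
#' @return A `screen_result`.
#' @export
reverse_mr <- function(config, targets = NULL) {
  stopifnot(inherits(config, "screen_config"))
  nms <- targets %||% names(config$exposures)
  rows <- list(); ests <- list(); sens <- list(); skipped <- character(0)
  for (i in seq_along(nms)) {
    name <- nms[i]
    rev_config <- screen_config(
      exposures = stats::setNames(list(config$outcome), "outcome_trait"),
      outcome = config$exposures[[name]], classes = "disease",
      ld = config$ld, p_instrument = config$p_instrument,
      p_instrument_disease = config$p_instrument_disease,
      r2_max = config$r2_max, window_kb = config$window_kb,
      f_min = config$f_min, sig_lipid = config$sig_lipid,
      sig_metabolite = config$sig_metabolite,
      egger_gate = config$egger_gate, n_boot = config$n_boot,
      seed = config$seed + 1000L + i)
    res <- run_screen(rev_config)
    if (nrow(res$table) > 0L) {
      row <- res$table
      row$exposure <- "outcome_trait"
      row$reverse_outcome <- name
      rows[[name]] <- row
      ests[[name]] <- res$estimates[[1]]
      sens[[name]] <- res$sensitivity[[1]]
    } else skipped[name] <- res$skipped[1] %||% "instrument selection failed"
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame()
  structure(list(table = tab, estimates = ests, sensitivity = sens,
                 skipped = skipped, config = config),
            class = "screen_result")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write the report bundle
#'
#' Emits the data behind the standard MR figures -- volcano (beta and
#' -log10 p per exposure), per-method results, per-SNP forest/funnel data,
#' leave-one-out tables, the mediation table -- plus a JSON run manifest
#' with every threshold and seed. Nothing is recomputed here: every number
#' is copied from an upstream result, so reruns with the same seeds are
#' byte-identical.
#'
#' @param screen A `screen_result` from [run_screen()].
#' @param mediation Optional mediation table from [mediation_scan()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector of files written, invisibly.
#' @export
make_report <- function(screen, mediation = NULL, outdir) {
  stopifnot(inherits(screen, "screen_result"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- c()
  tab <- screen$table
  if (nrow(tab) > 0L) {
    volcano <- data.frame(exposure = tab$exposure, beta = tab$beta,
                          neg_log10_p = -log10(tab$pvalue),
                          stringsAsFactors = FALSE)
    files["volcano"] <- write_tsv(volcano, file.path(outdir, "volcano.tsv"))
    files["screen"] <- write_tsv(tab, file.path(outdir, "screen.tsv"))
  }
  if (length(screen$estimates) > 0L) {
    allm <- do.call(rbind, c(screen$estimates, make.row.names = FALSE))
    files["estimates"] <- write_tsv(allm, file.path(outdir, "estimates.tsv"))
  }
  if (length(screen$sensitivity) > 0L) {
    loo <- list(); wald <- list()
    for (nm in names(screen$sensitivity)) {
      s <- screen$sensitivity[[nm]]
      if (is.null(s)) next
      loo[[nm]] <- cbind(exposure = nm, s$leave_one_out)
      wald[[nm]] <- cbind(exposure = nm, s$wald)
    }
    if (length(loo))
      files["leave_one_out"] <- write_tsv(
        do.call(rbind, c(loo, make.row.names = FALSE)),
        file.path(outdir, "leave_one_out.tsv"))
    if (length(wald))
      files["forest"] <- write_tsv(
        do.call(rbind, c(wald, make.row.names = FALSE)),
        file.path(outdir, "forest_funnel.tsv"))
  }
  if (!is.null(mediation) && nrow(mediation) > 0L)
    files["mediation"] <- write_tsv(mediation,
                                    file.path(outdir, "mediation.tsv"))
  cfg <- screen$config
  manifest <- list(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    thresholds = list(
      p_instrument = cfg$p_instrument,
      p_instrument_disease = cfg$p_instrument_disease,
      clump_r2 = cfg$r2_max, clump_window_kb = cfg$window_kb,
      f_min = cfg$f_min, sig_lipid = cfg$sig_lipid,
      sig_metabolite = cfg$sig_metabolite, egger_gate = cfg$egger_gate),
    n_boot = cfg$n_boot, seed = cfg$seed,
    exposures = names(cfg$exposures), classes = cfg$classes,
    skipped = as.list(screen$skipped))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["manifest"] <- manifest_path
  invisible(files)
}
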