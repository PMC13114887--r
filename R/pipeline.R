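# End-to-end orchestration: read scoring data, obtain the calibration
# curve, quality-control and summarise conditions, screen the
# donor-by-treatment interaction, score substances and render a run report.

#' Configuration of a full analysis run
#'
#' @param scoring_csv Path to the CBMN scoring table (CSV).
#' @param curve_json Path to a calibration-curve JSON (published or fitted);
#'   exactly one of `curve_json` and `calibration_csv` must be given.
#' @param calibration_csv Path to a calibration scoring table to refit the
#'   curve from (columns `dose_mGy`, `mn_count`, `n_bc_scored` as in any
#'   scoring table).
#' @param nominal_dose_mGy Delivered screening dose in mGy.
#' @param alpha_levels Significance tiers for the Tukey table.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in every artifact and used for any
#'   resampling.
#' @param col_map Optional column mapping passed to [read_scoring_table()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(scoring_csv, curve_json = NULL, calibration_csv = NULL,
                       nominal_dose_mGy = 2000,
                       alpha_levels = c(0.001, 0.01, 0.05),
                       out_dir = ".", seed = 1L, col_map = NULL) {
  if (is.null(curve_json) == is.null(calibration_csv)) {
    stop("config error: give exactly one of curve_json or calibration_csv",
         call. = FALSE)
  }
  for (p in c(scoring_csv, curve_json, calibration_csv)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("config error: input path does not exist: ", p, call. = FALSE)
    }
  }
  structure(
    list(scoring_csv = scoring_csv, curve_json = curve_json,
         calibration_csv = calibration_csv,
         nominal_dose_mGy = nominal_dose_mGy, alpha_levels = alpha_levels,
         out_dir = out_dir, seed = as.integer(seed), col_map = col_map),
    class = "run_config"
  )
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full screening analysis pipeline
#'
#' Stages: read the scoring table; obtain the calibration curve (from JSON
#' or refit from a calibration table); summarise conditions with CBPI
#' quality flags; run the donor-by-treatment interaction screen; score every
#' substance x timing arm (MP, equivalent dose, DRF, Tukey-adjusted p,
#' tier, DMSO normalisation); write the artifact set (summary CSV,
#' protection-results CSV, pairwise-comparisons CSV, curve JSON, markdown
#' report). Any stage error propagates with a stage-labelled message.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory results (`records`,
#'   `summary`, `curve`, `donor_screen`, `results`, `comparisons`) and the
#'   paths of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  records <- .stage("read", read_scoring_table(config$scoring_csv,
                                               col_map = config$col_map))
  curve <- .stage("calibrate", {
    if (!is.null(config$curve_json)) {
      read_calibration(config$curve_json)
    } else {
      cal <- read_scoring_table(config$calibration_csv)
      fit_calibration(cal$dose_mGy,
                      mn_frequency_per_500(cal$mn_count, cal$n_bc_scored))
    }
  })
  summary_tab <- .stage("summarize",
                        suppressWarnings(summarize_conditions(records)))
  screen <- .stage("donor_screen", donor_interaction_screen(records))
  results <- .stage("score",
                    score_screening(records, curve,
                                    nominal_dose_mGy = config$nominal_dose_mGy))
  comparisons <- .stage("compare", {
    irr <- records[records$dose_mGy > 0, , drop = FALSE]
    f <- mn_frequency_per_500(irr$mn_count, irr$n_bc_scored)
    arm <- paste(irr$substance, irr$timing, sep = ":")
    groups <- split(f, arm)
    if (length(groups) >= 2L && all(lengths(groups) >= 2L)) {
      tukey_hsd(groups, alpha_levels = config$alpha_levels)
    } else NULL
  })

  paths <- list(
    summary = file.path(config$out_dir, "condition_summary.csv"),
    results = file.path(config$out_dir, "protection_results.csv"),
    comparisons = file.path(config$out_dir, "pairwise_comparisons.csv"),
    curve = file.path(config$out_dir, "calibration_curve.json"),
    report = file.path(config$out_dir, "report.md")
  )
  .stage("write", {
    utils::write.csv(summary_tab, paths$summary, row.names = FALSE)
    utils::write.csv(as.data.frame(results), paths$results,
                     row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.csv(as.data.frame(comparisons), paths$comparisons,
                       row.names = FALSE)
    }
    write_calibration(curve, paths$curve)
    writeLines(make_report(results, curve = curve, donor_screen = screen,
                           summary_tab = summary_tab, seed = config$seed),
               paths$report)
  })
  invisible(list(records = records, summary = summary_tab, curve = curve,
                 donor_screen = screen, results = results,
                 comparisons = comparisons, paths = paths))
}

#' Render the markdown run report
#'
#' Deterministic rendering (no timestamps): the calibration equation in the
#' inverse dosimetry form `D = a + b y`, CBPI quality flags per condition,
#' the donor-interaction screen verdict, and the MP/DRF table with
#' protection tiers after the display rounding rules (MP to integer
#' percent, DRF to one decimal, equivalent dose in Gy truncated to two
#' decimals; infinite DRFs render as a complete-protection flag).
#'
#' @param results A `protection_results` data frame.
#' @param curve The `mn_calibration` used.
#' @param donor_screen Optional `donor_screen` result.
#' @param summary_tab Optional condition summary.
#' @param seed Seed recorded in the artifact.
#' @return Character vector of markdown lines.
#' @export
make_report <- function(results, curve, donor_screen = NULL,
                        summary_tab = NULL, seed = NA_integer_) {
  lines <- c("# CBMN radioprotector screening report", "",
             sprintf("Seed: %s", seed), "")
  lines <- c(lines, "## Calibration curve", "",
             sprintf("`D = %.2f + %.2f y` (D in mGy, y in MN/500 BC; %s)",
                     curve$a, curve$b, curve$provenance))
  if (!is.na(curve$r_squared)) {
    lines <- c(lines, sprintf("Reliability: %.2f%% (R^2 = %.4f)",
                              100 * curve$r_squared, curve$r_squared))
  }
  lines <- c(lines, "")
  if (!is.null(summary_tab) && "cbpi_flag" %in% names(summary_tab)) {
    n_fail <- sum(summary_tab$cbpi_flag == "fail", na.rm = TRUE)
    lines <- c(lines, "## Culture quality (CBPI)", "",
               sprintf("%d of %d conditions outside the 1.3-1.7 CBPI band.",
                       n_fail, nrow(summary_tab)), "")
  }
  if (!is.null(donor_screen)) {
    lines <- c(lines, "## Donor pooling", "", donor_screen$message, "")
  }
  lines <- c(lines, "## Protection endpoints", "")
  if (nrow(results) == 0L) {
    lines <- c(lines, "No substances scored.", "")
    return(lines)
  }
  lines <- c(lines,
             "| substance | timing | MN/500 BC | MP (%) | equiv. dose (Gy) | DRF | tier |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    drf_disp <- if (r$complete_protection) "complete protection" else
      sprintf("%.1f", format_drf(r$drf))
    eq_disp <- if (r$complete_protection) "< baseline" else
      sprintf("%.2f", format_equiv_dose_gy(r$equiv_dose_mGy))
    lines <- c(lines, sprintf(
      "| %s | %s | %.1f | %d | %s | %s | %s |",
      r$substance, r$timing, r$fmn_treated_irr, format_mp(r$mp_percent),
      eq_disp, drf_disp,
      if (is.na(r$tier)) "-" else r$tier))
  }
  c(lines, "")
}
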