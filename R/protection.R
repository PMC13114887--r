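# Substance-level radioprotection endpoints: magnitude of protection (MP),
# equivalent dose and dose reduction factor (DRF), DMSO solvent
# normalisation, genotoxicity assessment and protection tier.

#' Magnitude of protection (MP)
#'
#' Percent reduction of the micronucleus frequency in the treated
#' irradiated arm relative to the irradiated control:
#' `MP = 100 * (f_control - f_treated) / f_control`. Negative values
#' indicate radiosensitisation. The value is returned unrounded; display
#' layers round to the nearest integer percent ([format_mp()]).
#'
#' @param fmn_control_irr Irradiated-control MN/500 BC frequency (> 0).
#' @param fmn_treated_irr Treated irradiated MN/500 BC frequency.
#' @return MP in percent, vectorised over `fmn_treated_irr`.
#' @examples
#' magnitude_of_protection(26, 11) # 57.69..., displayed as 58
#' @export
magnitude_of_protection <- function(fmn_control_irr, fmn_treated_irr) {
  if (any(fmn_control_irr <= 0)) {
    stop("undefined MP: irradiated-control frequency must be > 0",
         call. = FALSE)
  }
  100 * (fmn_control_irr - fmn_treated_irr) / fmn_control_irr
}

#' Dose reduction factor (DRF)
#'
#' The equivalent dose is the gamma dose that would produce the treated
#' arm's MN frequency in untreated cultures, obtained by inverse
#' interpolation on the calibration curve; the DRF is the nominal delivered
#' dose divided by that equivalent dose. DRF > 1 indicates protection.
#' When the equivalent dose clamps to 0 (frequency below the curve's
#' baseline) the DRF is reported as `Inf` with `complete_protection = TRUE`:
#' protection is complete at the resolution of the curve.
#'
#' @param curve An invertible `mn_calibration` object.
#' @param nominal_dose_mGy Delivered dose in mGy (> 0).
#' @param fmn_treated_irr Treated irradiated MN/500 BC frequency
#'   (vectorised).
#' @return A data frame with columns `y`, `equiv_dose_mGy`, `clamped`,
#'   `drf`, `complete_protection`.
#' @examples
#' curve <- from_inverse_coefficients(-429.54, 64.37)
#' dose_reduction_factor(curve, 2000, 11) # DRF 7.18, displayed 7.2
#' @export
dose_reduction_factor <- function(curve, nominal_dose_mGy, fmn_treated_irr) {
  if (!is.finite(nominal_dose_mGy) || nominal_dose_mGy <= 0) {
    stop("nominal dose must be > 0 mGy", call. = FALSE)
  }
  est <- estimate_dose(curve, fmn_treated_irr)
  drf <- ifelse(est$dose_mGy > 0, nominal_dose_mGy / est$dose_mGy, Inf)
  data.frame(
    y = fmn_treated_irr,
    equiv_dose_mGy = est$dose_mGy,
    clamped = est$clamped,
    drf = drf,
    complete_protection = est$dose_mGy == 0
  )
}

#' DMSO solvent normalisation
#'
#' For lipophilic compounds dissolved in DMSO, the solvent's own protective
#' effect is subtracted from the total effect of compound plus solvent:
#' `MP_net = MP_total - MP_dmso`. Both MPs must come from the same timing
#' arm (DMSO protects only when present before irradiation). Negative net
#' values are allowed and indicate net radiosensitisation.
#'
#' @param mp_total_percent MP of compound + DMSO, percent.
#' @param mp_dmso_percent MP of the DMSO-only arm, percent.
#' @param timing_total,timing_dmso Optional timing labels; if both given
#'   they must match.
#' @return Net MP in percent.
#' @export
dmso_normalize <- function(mp_total_percent, mp_dmso_percent,
                           timing_total = NULL, timing_dmso = NULL) {
  if (!is.null(timing_total) && !is.null(timing_dmso) &&
      !identical(timing_total, timing_dmso)) {
    stop("timing mismatch: total and DMSO-only MPs must share the timing arm",
         call. = FALSE)
  }
  mp_total_percent - mp_dmso_percent
}

#' Genotoxicity assessment of an unirradiated treated arm
#'
#' A substance is genotoxic when it raises the MN frequency above the
#' unirradiated control and the difference is significant at the two-tailed
#' 0.05 level.
#'
#' @param fmn_treated_unirr Treated unirradiated MN/500 BC frequency.
#' @param fmn_control_unirr Untreated unirradiated (spontaneous) frequency.
#' @param p_value Two-tailed p-value for the comparison.
#' @param alpha Significance level.
#' @return `"genotoxic"` or `"not_genotoxic"`.
#' @export
assess_genotoxicity <- function(fmn_treated_unirr, fmn_control_unirr,
                                p_value, alpha = 0.05) {
  ifelse(fmn_treated_unirr > fmn_control_unirr & p_value < alpha,
         "genotoxic", "not_genotoxic")
}

#' Classify a substance into a protection tier
#'
#' Tiers follow the marker convention of screening figures: a significant
#' decrease in MN frequency versus the irradiated control at p < 0.001 is a
#' strong protector, at p < 0.01 a moderate protector; a significant
#' increase at p < 0.01 is a radiosensitiser; anything else is not
#' significant.
#'
#' @param p_value Adjusted p-value vs the irradiated control, in \[0, 1\].
#' @param direction Sign of (treated - control): `"decrease"` or
#'   `"increase"` (or the numeric difference, whose sign is used).
#' @return One of `"protector_strong"`, `"protector_moderate"`,
#'   `"radiosensitizer"`, `"not_significant"`.
#' @export
classify_substance <- function(p_value, direction) {
  stopifnot(all(p_value >= 0 & p_value <= 1))
  if (is.numeric(direction)) {
    direction <- ifelse(direction < 0, "decrease",
                        ifelse(direction > 0, "increase", "none"))
  }
  mapply(function(p, d) {
    if (d == "decrease") {
      if (p < 0.001) return("protector_strong")
      if (p < 0.01) return("protector_moderate")
    } else if (d == "increase" && p < 0.01) {
      return("radiosensitizer")
    }
    "not_significant"
  }, p_value, direction, USE.NAMES = FALSE)
}

#' Score a radioprotector screening experiment
#'
#' Orchestrates the substance-level endpoints over every substance-by-timing
#' arm of a screening dataset: condition means, MP against the irradiated
#' control, equivalent dose and DRF on the supplied calibration curve,
#' Tukey-adjusted p-values versus the irradiated control, protection tiers,
#' and DMSO-normalised MP where a solvent-only arm is present for the same
#' timing. All values are unrounded; [format_protection_results()] applies
#' the display rules.
#'
#' @param records A `culture_records` data frame containing an irradiated
#'   control arm (`substance == control_label`, `dose_mGy > 0`) and treated
#'   irradiated arms with `timing` in pre/post.
#' @param curve An invertible `mn_calibration` object.
#' @param nominal_dose_mGy Delivered screening dose in mGy.
#' @param control_label Substance label of the controls.
#' @param dmso_label Substance label of the solvent-only arms.
#' @return A data frame of class `protection_results`, one row per
#'   substance x timing, with columns `substance`, `timing`, `solvent`, `n`,
#'   `fmn_control_irr`, `fmn_treated_irr`, `se_treated`, `mp_percent`,
#'   `mp_dmso_normalized`, `equiv_dose_mGy`, `drf`, `complete_protection`,
#'   `p_vs_irradiated_control`, `tier`.
#' @export
score_screening <- function(records, curve, nominal_dose_mGy = 2000,
                            control_label = "control",
                            dmso_label = "dmso") {
  stopifnot(is.data.frame(records))
  irr <- records$dose_mGy > 0
  is_ctrl <- records$substance == control_label
  if (!any(irr & is_ctrl)) {
    stop("missing irradiated control arm (substance '", control_label,
         "' with dose > 0)", call. = FALSE)
  }
  freq <- mn_frequency_per_500(records$mn_count, records$n_bc_scored)
  irr_rec <- records[irr, , drop = FALSE]
  irr_freq <- freq[irr]
  arm <- ifelse(irr_rec$substance == control_label, "__irr_control__",
                paste(irr_rec$substance, irr_rec$timing, sep = ":"))
  fmn_control <- mean(irr_freq[arm == "__irr_control__"])

  # pairwise Tukey p-values vs the irradiated control, over all irradiated arms
  groups <- split(irr_freq, arm)
  p_vs_ctrl <- rep(NA_real_, length(groups))
  names(p_vs_ctrl) <- names(groups)
  if (length(groups) >= 2L && all(lengths(groups) >= 2L)) {
    # degenerate (all-constant) data leaves the p-values as NA
    tk <- tryCatch(tukey_hsd(groups), error = function(e) NULL)
    if (!is.null(tk)) {
      ctrl_rows <- tk$group_a == "__irr_control__" | tk$group_b == "__irr_control__"
      other <- ifelse(tk$group_a[ctrl_rows] == "__irr_control__",
                      tk$group_b[ctrl_rows], tk$group_a[ctrl_rows])
      p_vs_ctrl[other] <- tk$adjusted_p[ctrl_rows]
    }
  }

  treat_arms <- setdiff(names(groups), "__irr_control__")
  if (length(treat_arms) == 0L) {
    res <- data.frame()
    class(res) <- c("protection_results", "data.frame")
    return(res)
  }
  rows <- lapply(treat_arms, function(a) {
    parts <- strsplit(a, ":", fixed = TRUE)[[1L]]
    subst <- parts[1L]; tim <- parts[2L]
    f <- groups[[a]]
    fmn_treated <- mean(f)
    mp <- magnitude_of_protection(fmn_control, fmn_treated)
    drf <- dose_reduction_factor(curve, nominal_dose_mGy, fmn_treated)
    solv <- unique(irr_rec$solvent[arm == a])[1L]
    p <- unname(p_vs_ctrl[a])
    tier <- if (is.na(p)) NA_character_ else {
      classify_substance(p, fmn_treated - fmn_control)
    }
    data.frame(
      substance = subst, timing = tim, solvent = solv, n = length(f),
      fmn_control_irr = fmn_control, fmn_treated_irr = fmn_treated,
      se_treated = if (length(f) > 1) stats::sd(f) / sqrt(length(f)) else 0,
      mp_percent = mp, mp_dmso_normalized = NA_real_,
      equiv_dose_mGy = drf$equiv_dose_mGy, drf = drf$drf,
      complete_protection = drf$complete_protection,
      p_vs_irradiated_control = p,
      tier = tier,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)

  # DMSO normalisation: subtract the solvent-only MP of the same timing arm
  for (tim in unique(res$timing)) {
    dmso_row <- res$substance == dmso_label & res$timing == tim
    if (any(dmso_row)) {
      mp_dmso <- res$mp_percent[dmso_row][1L]
      idx <- res$timing == tim & res$solvent == "dmso" &
        res$substance != dmso_label
      res$mp_dmso_normalized[idx] <-
        dmso_normalize(res$mp_percent[idx], mp_dmso)
    }
  }
  rownames(res) <- NULL
  attr(res, "nominal_dose_mGy") <- nominal_dose_mGy
  attr(res, "curve") <- curve
  class(res) <- c("protection_results", "data.frame")
  res
}

#' Display rounding for MP values
#'
#' MP is displayed to the nearest integer percent.
#' @param mp_percent Unrounded MP.
#' @return Rounded value.
#' @export
format_mp <- function(mp_percent) round(mp_percent)

#' Display rounding for DRF values
#'
#' DRF is displayed to one decimal; infinite DRFs render as
#' `"complete protection"`.
#' @param drf Unrounded DRF.
#' @return Numeric rounded value (`Inf` preserved).
#' @export
format_drf <- function(drf) round(drf, 1)

#' Display conversion of an equivalent dose to Gy
#'
#' Equivalent doses are displayed in Gy truncated (not rounded) to two
#' decimals, so 278.5 mGy renders as 0.27 Gy.
#' @param dose_mGy Dose in mGy.
#' @return Dose in Gy, truncated to two decimals.
#' @export
format_equiv_dose_gy <- function(dose_mGy) trunc(dose_mGy / 10) / 100

#' @export
print.protection_results <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No substances scored.\n")
    return(invisible(x))
  }
  cat("Radioprotector screening results (nominal dose ",
      attr(x, "nominal_dose_mGy"), " mGy)\n\n", sep = "")
  disp <- data.frame(
    substance = x$substance, timing = x$timing,
    `MN/500BC` = round(x$fmn_treated_irr, 1),
    `MP%` = format_mp(x$mp_percent),
    `MP% (DMSO-adj)` = ifelse(is.na(x$mp_dmso_normalized), "",
                              format_mp(x$mp_dmso_normalized)),
    `equiv Gy` = ifelse(x$complete_protection, "<baseline",
                        sprintf("%.2f", format_equiv_dose_gy(x$equiv_dose_mGy))),
    DRF = ifelse(x$complete_protection, "complete protection",
                 sprintf("%.1f", format_drf(x$drf))),
    p = ifelse(is.na(x$p_vs_irradiated_control), "",
               format.pval(x$p_vs_irradiated_control, digits = 2)),
    tier = ifelse(is.na(x$tier), "", x$tier),
    check.names = FALSE
  )
  print(disp, row.names = FALSE)
  invisible(x)
}
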