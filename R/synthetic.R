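# Seeded synthetic CBMN data generator: emulates a multi-donor
# radioprotector screening study (calibration schedule, 2 Gy screening arm,
# solvent arms) with Poisson or negative-binomial counts and a
# multiplicative log-normal donor effect.

#' Configuration of the synthetic CBMN generative model
#'
#' Defaults emulate the study design the analysis targets: 6 donors by 5
#' independent experiments; a spontaneous frequency of 0.02 MN/BC (10
#' MN/500 BC); a 20-point calibration schedule spanning 0-16,362 mGy with
#' forward slope matching the inverse dosimetry equation
#' `D = -429.54 + 64.37 y` (slope `1/64.37` MN/500 BC per mGy); a 2 Gy
#' (2000 mGy) screening arm whose irradiated control averages 26 MN/500 BC;
#' substance effects expressed as protection fractions `f` so the treated
#' arm mean is `(1 - f) * irradiated_control_mean` (`f < 0` encodes
#' radiosensitisers); and an additive DMSO solvent protection fraction that
#' applies only when the solvent is present before irradiation.
#'
#' Counts per 500 BC are Poisson when `dispersion = 0`, negative binomial
#' with `variance = mean * (1 + dispersion)` otherwise; the donor effect
#' multiplies the arm mean by a mean-one log-normal factor with log-scale
#' SD `donor_sd`.
#'
#' @param baseline_freq Mean MN/500 BC at zero dose.
#' @param slope Forward slope, MN/500 BC per mGy.
#' @param dispersion Overdispersion; 0 gives Poisson counts.
#' @param donor_sd Between-donor SD on the log-mean scale.
#' @param n_donors,n_experiments Design size.
#' @param calibration_doses Dose schedule in mGy.
#' @param nominal_screen_dose Screening dose in mGy.
#' @param irradiated_control_mean Mean MN/500 BC of the irradiated control.
#' @param effects Named list mapping substance to a list with elements
#'   `pre` and/or `post` (protection fractions) and optionally
#'   `solvent` (`"aqueous"`, `"dmso"` or `"undiluted"`, default aqueous).
#' @param dmso_offset Additive solvent protection fraction (pre arm only).
#' @param n_bc_scored Binucleated cells scored per culture.
#' @param cbpi_target Expected CBPI of simulated tallies.
#' @param seed Integer seed; the same seed yields an identical dataset.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(baseline_freq = 10,
                             slope = 1 / 64.37,
                             dispersion = 0,
                             donor_sd = 0.05,
                             n_donors = 6,
                             n_experiments = 5,
                             calibration_doses = round(seq(0, 16362,
                                                           length.out = 20)),
                             nominal_screen_dose = 2000,
                             irradiated_control_mean = 26,
                             effects = list(),
                             dmso_offset = 0.04,
                             n_bc_scored = 500,
                             cbpi_target = 1.65,
                             seed = NULL) {
  cfg <- list(
    baseline_freq = baseline_freq, slope = slope, dispersion = dispersion,
    donor_sd = donor_sd, n_donors = as.integer(n_donors),
    n_experiments = as.integer(n_experiments),
    calibration_doses = calibration_doses,
    nominal_screen_dose = nominal_screen_dose,
    irradiated_control_mean = irradiated_control_mean,
    effects = effects, dmso_offset = dmso_offset,
    n_bc_scored = as.integer(n_bc_scored),
    cbpi_target = cbpi_target, seed = seed
  )
  stopifnot(cfg$baseline_freq >= 0, cfg$dispersion >= 0, cfg$donor_sd >= 0,
            cfg$n_donors >= 1, cfg$n_experiments >= 1,
            all(cfg$calibration_doses >= 0), cfg$nominal_screen_dose > 0,
            cfg$irradiated_control_mean > 0, cfg$n_bc_scored >= 1)
  if (cfg$cbpi_target < 1 || cfg$cbpi_target > 3) {
    stop("cbpi_target must lie in [1, 3]", call. = FALSE)
  }
  for (s in names(cfg$effects)) {
    e <- cfg$effects[[s]]
    bad <- setdiff(names(e), c("pre", "post", "solvent"))
    if (length(bad) > 0L) {
      stop("unknown timing '", bad[1L], "' in effects for ", s, call. = FALSE)
    }
    for (tim in intersect(names(e), c("pre", "post"))) {
      if (e[[tim]] > 1) {
        stop("protection fraction must be <= 1 (substance ", s, ")",
             call. = FALSE)
      }
    }
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# counts with variance = mean * (1 + dispersion); dispersion 0 -> Poisson
.draw_counts <- function(n, mean, dispersion) {
  if (dispersion <= 0) {
    stats::rpois(n, mean)
  } else {
    stats::rnbinom(n, size = mean / dispersion, mu = mean)
  }
}

# mean-one multiplicative log-normal donor factors
.donor_factors <- function(n_donors, donor_sd) {
  if (donor_sd <= 0) return(rep(1, n_donors))
  stats::rlnorm(n_donors, meanlog = -donor_sd^2 / 2, sdlog = donor_sd)
}

.simulate_arm_records <- function(cfg, substance, timing, solvent, dose,
                                  mean_freq, donor_fac) {
  rows <- expand.grid(donor = seq_len(cfg$n_donors),
                      experiment = seq_len(cfg$n_experiments))
  mu_count <- mean_freq * donor_fac[rows$donor] * cfg$n_bc_scored / 500
  if (any(mu_count < 0)) {
    stop("configuration yields a negative mean frequency for ", substance,
         call. = FALSE)
  }
  counts <- .draw_counts(nrow(rows), mu_count, cfg$dispersion)
  tallies <- .cbpi_probs(cfg$cbpi_target)
  tal <- stats::rmultinom(nrow(rows), size = cfg$n_bc_scored, prob = tallies)
  data.frame(
    donor_id = paste0("d", rows$donor),
    experiment_id = paste0("e", rows$experiment),
    substance = substance, timing = timing, solvent = solvent,
    dose_mGy = dose, n_bc_scored = cfg$n_bc_scored, mn_count = counts,
    n_mono = tal[1L, ], n_bi = tal[2L, ], n_multi = tal[3L, ],
    stringsAsFactors = FALSE
  )
}

#' Simulate a calibration dataset
#'
#' One culture per dose x donor x experiment: MN counts per `n_bc_scored`
#' BC drawn from Poisson (or negative binomial when `dispersion > 0`) with
#' mean `baseline_freq + slope * dose`, multiplied by the donor factor.
#' Records carry `timing = "none"` and `substance = "control"`.
#'
#' @param config A `synthetic_config`.
#' @return A `culture_records` data frame with a `truth` attribute carrying
#'   the generating parameters.
#' @export
simulate_calibration_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  donor_fac <- .donor_factors(config$n_donors, config$donor_sd)
  recs <- do.call(rbind, lapply(config$calibration_doses, function(d) {
    .simulate_arm_records(config, "control", "none", "aqueous", d,
                          config$baseline_freq + config$slope * d,
                          donor_fac)
  }))
  out <- culture_records(recs)
  attr(out, "truth") <- list(baseline_freq = config$baseline_freq,
                             slope = config$slope,
                             donor_factors = donor_fac)
  out
}

#' Simulate a screening experiment
#'
#' Emulated arms: unirradiated control, irradiated control at the nominal
#' screening dose, one arm per substance x timing in the effects map, and a
#' solvent-only DMSO arm per timing whenever any substance uses DMSO. The
#' treated arm mean is `(1 - f_total) * irradiated_control_mean`, where
#' `f_total` adds the DMSO offset for DMSO-dissolved substances in the pre
#' arm only (the solvent has no effect after irradiation).
#'
#' @param config A `synthetic_config` with a non-empty or empty `effects`
#'   map.
#' @return A `culture_records` data frame with a `truth` attribute listing
#'   the configured arm means and total protection fractions.
#' @export
simulate_screening_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  donor_fac <- .donor_factors(config$n_donors, config$donor_sd)
  arms <- list(
    list(substance = "control", timing = "none", solvent = "aqueous",
         dose = 0, mean = config$baseline_freq, f_total = NA_real_),
    list(substance = "control", timing = "none", solvent = "aqueous",
         dose = config$nominal_screen_dose,
         mean = config$irradiated_control_mean, f_total = NA_real_)
  )
  any_dmso <- any(vapply(config$effects, function(e) {
    identical(e$solvent, "dmso")
  }, logical(1L)))
  if (any_dmso) {
    for (tim in c("pre", "post")) {
      f_dmso <- if (tim == "pre") config$dmso_offset else 0
      arms[[length(arms) + 1L]] <- list(
        substance = "dmso", timing = tim, solvent = "dmso",
        dose = config$nominal_screen_dose,
        mean = (1 - f_dmso) * config$irradiated_control_mean,
        f_total = f_dmso
      )
    }
  }
  for (s in names(config$effects)) {
    e <- config$effects[[s]]
    solv <- if (is.null(e$solvent)) "aqueous" else e$solvent
    for (tim in intersect(names(e), c("pre", "post"))) {
      f_total <- e[[tim]] +
        if (solv == "dmso" && tim == "pre") config$dmso_offset else 0
      arms[[length(arms) + 1L]] <- list(
        substance = s, timing = tim, solvent = solv,
        dose = config$nominal_screen_dose,
        mean = (1 - f_total) * config$irradiated_control_mean,
        f_total = f_total
      )
    }
  }
  recs <- do.call(rbind, lapply(arms, function(a) {
    .simulate_arm_records(config, a$substance, a$timing, a$solvent,
                          a$dose, a$mean, donor_fac)
  }))
  out <- culture_records(recs)
  attr(out, "truth") <- list(
    arms = do.call(rbind, lapply(arms, function(a) {
      data.frame(substance = a$substance, timing = a$timing,
                 mean_freq = a$mean, f_total = a$f_total,
                 stringsAsFactors = FALSE)
    })),
    donor_factors = donor_fac
  )
  out
}

# cell-class probabilities with expected CBPI equal to the target:
# CBPI = 1 + p_bi + 2 p_multi
.cbpi_probs <- function(target) {
  p_multi <- min(0.05, (target - 1) / 2)
  p_bi <- target - 1 - 2 * p_multi
  c(mono = 1 - p_bi - p_multi, bi = p_bi, multi = p_multi)
}

#' Simulate mono-/bi-/multinucleate cell tallies
#'
#' Multinomial draw over cell classes with probabilities chosen so the
#' expected CBPI equals the target.
#'
#' @param config A `synthetic_config` (uses `cbpi_target` and `seed`).
#' @param n_cells Number of cells to classify.
#' @return Named integer vector `(n_mono, n_bi, n_multi)`.
#' @export
simulate_cbpi_tallies <- function(config, n_cells) {
  stopifnot(inherits(config, "synthetic_config"), n_cells >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- .cbpi_probs(config$cbpi_target)
  draw <- stats::rmultinom(1L, size = n_cells, prob = p)[, 1L]
  c(n_mono = draw[[1L]], n_bi = draw[[2L]], n_multi = draw[[3L]])
}

#' Write a synthetic dataset and its ground truth
#'
#' Writes the scoring table as CSV and the generating truth (arm means,
#' protection fractions, donor factors) as JSON, so downstream tests never
#' re-derive truth from outputs.
#'
#' @param records Records from a `simulate_*` function.
#' @param csv_path,truth_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_synthetic_dataset <- function(records, csv_path, truth_path) {
  write_scoring_table(records, csv_path)
  jsonlite::write_json(attr(records, "truth"), truth_path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(csv_path)
}
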