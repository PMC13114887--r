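# Micronucleus dose-response calibration: forward linear fit, the exact
# inverse used for biological dosimetry, and dose estimation with optional
# bootstrap intervals.

#' Fit a linear micronucleus dose-response calibration curve
#'
#' Ordinary least squares of MN frequency (MN/500 BC) on gamma dose (mGy):
#' `y = c0 + c1 * D`. The fitted object carries both the forward
#' parameterisation `(c0, c1)` and the inverse dosimetry form
#' `D = a + b * y` with `a = -c0/c1`, `b = 1/c1`, together with the
#' coefficient of determination (also reported as percent reliability,
#' `100 * r_squared`) and the residual standard deviation. A Poisson-style
#' weighted fit (weights `1/max(fitted, eps)` iterated once from the
#' unweighted fit) is available for counts whose variance tracks the mean.
#'
#' @param dose_mGy Numeric vector of delivered doses in mGy (>= 0, at least
#'   three distinct values).
#' @param frequency Numeric vector of observed MN/500 BC frequencies.
#' @param weighting `"none"` (default) or `"poisson"`.
#' @return An object of class `mn_calibration`; see [calibration_curve()]
#'   for the fields.
#' @seealso [from_inverse_coefficients()], [estimate_dose()],
#'   [fit_calibration_lq()]
#' @examples
#' d <- seq(0, 16362, length.out = 20)
#' fit <- fit_calibration(d, 6.673 + 0.0155352 * d)
#' coef(fit)
#' @export
fit_calibration <- function(dose_mGy, frequency, weighting = c("none", "poisson")) {
  weighting <- match.arg(weighting)
  stopifnot(length(dose_mGy) == length(frequency))
  if (any(dose_mGy < 0)) stop("doses must be non-negative", call. = FALSE)
  if (length(unique(dose_mGy)) < 3L) {
    stop("singular design: need >= 3 distinct dose points", call. = FALSE)
  }
  dat <- data.frame(dose = dose_mGy, freq = frequency)
  fit <- stats::lm(freq ~ dose, data = dat)
  if (weighting == "poisson") {
    w <- 1 / pmax(stats::fitted(fit), 1e-8)
    fit <- stats::lm(freq ~ dose, data = dat, weights = w)
  }
  cf <- stats::coef(fit)
  c0 <- unname(cf[1L]); c1 <- unname(cf[2L])
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((frequency - mean(frequency))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  curve <- calibration_curve(
    c0 = c0, c1 = c1, n_points = length(dose_mGy),
    r_squared = r2,
    residual_sd = sqrt(ssr / stats::df.residual(fit)),
    provenance = "fit"
  )
  curve$data <- dat
  curve$lm <- fit
  curve
}

#' Construct a calibration curve from its parameters
#'
#' Low-level constructor holding both parameterisations of the same line:
#' the forward curve `y = c0 + c1 * D` and the inverse dosimetry equation
#' `D = a + b * y` with `a = -c0/c1` and `b = 1/c1`. Invertibility requires
#' a positive slope (`c1 > 0`); a non-positive slope yields a curve with
#' inversion disabled.
#'
#' @param c0 Intercept, MN/500 BC at zero dose.
#' @param c1 Slope, MN/500 BC per mGy.
#' @param n_points Number of calibration points behind the fit (NA for
#'   published curves).
#' @param r_squared Coefficient of determination (NA when not available).
#' @param residual_sd Residual SD in MN/500 BC (NA when not available).
#' @param provenance `"fit"` or `"published"`.
#' @return A list of class `mn_calibration` with fields `c0`, `c1`, `a`,
#'   `b`, `invertible`, `n_points`, `r_squared`, `residual_sd`,
#'   `provenance`.
#' @export
calibration_curve <- function(c0, c1, n_points = NA_integer_,
                              r_squared = NA_real_, residual_sd = NA_real_,
                              provenance = c("fit", "published")) {
  provenance <- match.arg(provenance)
  invertible <- is.finite(c1) && c1 > 0
  structure(
    list(
      c0 = c0, c1 = c1,
      a = if (invertible) -c0 / c1 else NA_real_,
      b = if (invertible) 1 / c1 else NA_real_,
      invertible = invertible,
      n_points = n_points,
      r_squared = r_squared,
      residual_sd = residual_sd,
      provenance = provenance
    ),
    class = "mn_calibration"
  )
}

#' Build a calibration curve from a published inverse dosimetry equation
#'
#' Biological dosimetry papers often publish only the inverse form
#' `D = a + b * y` (dose in mGy as a function of MN/500 BC). This
#' constructor takes those coefficients directly, without refitting:
#' `c0 = -a/b`, `c1 = 1/b`; fit diagnostics are marked absent.
#'
#' @param a Inverse intercept in mGy.
#' @param b Inverse slope in mGy per MN/500 BC; must be positive.
#' @return An `mn_calibration` object with provenance `"published"`.
#' @examples
#' from_inverse_coefficients(-429.54, 64.37)
#' @export
from_inverse_coefficients <- function(a, b) {
  if (!is.finite(b) || b <= 0) {
    stop("non-invertible curve: inverse slope b must be > 0", call. = FALSE)
  }
  calibration_curve(c0 = -a / b, c1 = 1 / b, provenance = "published")
}

#' Estimate the gamma dose equivalent to an observed MN frequency
#'
#' Inverse interpolation on the calibration curve: `D = a + b * y`, the
#' dose that would produce the observed frequency in untreated cultures.
#' Frequencies below the curve's zero-dose intercept give a negative raw
#' dose; these are clamped to 0 with `clamped = TRUE` and a warning, since
#' sub-baseline frequencies are expected in strongly protected samples.
#' When the curve was fitted from data, a seeded percentile bootstrap over
#' the calibration points can attach a confidence interval.
#'
#' @param curve An invertible `mn_calibration` object.
#' @param y Observed MN/500 BC frequency (vectorised).
#' @param ci Logical; compute a percentile bootstrap CI (requires a fitted
#'   curve with its data).
#' @param level CI level.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed for the bootstrap.
#' @return A data frame of class `dose_estimate` with columns `y`,
#'   `dose_mGy`, `clamped`, and (if `ci`) `ci_low_mGy`, `ci_high_mGy`.
#' @examples
#' curve <- from_inverse_coefficients(-429.54, 64.37)
#' estimate_dose(curve, 11) # 278.53 mGy
#' @export
estimate_dose <- function(curve, y, ci = FALSE, level = 0.95,
                          n_boot = 2000, seed = NULL) {
  stopifnot(inherits(curve, "mn_calibration"))
  if (!curve$invertible) {
    stop("non-invertible curve: forward slope must be > 0", call. = FALSE)
  }
  raw <- curve$a + curve$b * y
  clamped <- raw < 0
  dose <- ifelse(clamped, 0, raw)
  if (any(clamped)) {
    warning(sum(clamped), " dose estimate(s) below 0 clamped to 0 mGy",
            call. = FALSE)
  }
  out <- data.frame(y = y, dose_mGy = dose, clamped = clamped)
  if (ci) {
    if (is.null(curve$data)) {
      stop("bootstrap CI requires a curve fitted from data", call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    dat <- curve$data
    n <- nrow(dat)
    boots <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      cf <- stats::coef(stats::lm(freq ~ dose, data = dat[idx, ]))
      if (cf[2L] <= 0) return(rep(NA_real_, length(y)))
      pmax(0, -cf[1L] / cf[2L] + y / cf[2L])
    })
    boots <- matrix(boots, nrow = length(y))
    alpha <- (1 - level) / 2
    qs <- apply(boots, 1L, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE)
    out$ci_low_mGy <- pmin(qs[1L, ], out$dose_mGy)
    out$ci_high_mGy <- pmax(qs[2L, ], out$dose_mGy)
  }
  class(out) <- c("dose_estimate", "data.frame")
  out
}

#' Fit a linear-quadratic calibration curve
#'
#' Least-squares fit of `y = c0 + c1 * D + c2 * D^2`, the classical
#' cytogenetic dose-response form, provided for comparison with the linear
#' curve; it is not used in DRF scoring by default. The inverse takes the
#' positive root of the quadratic.
#'
#' @inheritParams fit_calibration
#' @return An object of class `mn_calibration_lq` with fields `c0`, `c1`,
#'   `c2`, `r_squared`, `residual_sd`, `n_points`.
#' @export
fit_calibration_lq <- function(dose_mGy, frequency) {
  stopifnot(length(dose_mGy) == length(frequency))
  if (length(unique(dose_mGy)) < 4L) {
    stop("need >= 4 distinct dose points for a quadratic fit", call. = FALSE)
  }
  dat <- data.frame(dose = dose_mGy, freq = frequency)
  fit <- stats::lm(freq ~ dose + I(dose^2), data = dat)
  cf <- unname(stats::coef(fit))
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((frequency - mean(frequency))^2)
  structure(
    list(c0 = cf[1L], c1 = cf[2L], c2 = cf[3L],
         r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
         residual_sd = sqrt(ssr / stats::df.residual(fit)),
         n_points = length(dose_mGy)),
    class = "mn_calibration_lq"
  )
}

#' Inverse of the linear-quadratic curve
#'
#' Solves `c0 + c1 * D + c2 * D^2 = y` for the non-negative dose; with
#' `c2 = 0` this reduces to the linear inverse.
#'
#' @param curve An `mn_calibration_lq` object.
#' @param y Observed MN/500 BC frequency (vectorised).
#' @return Dose(s) in mGy.
#' @export
estimate_dose_lq <- function(curve, y) {
  stopifnot(inherits(curve, "mn_calibration_lq"))
  vapply(y, function(yi) {
    if (abs(curve$c2) < 1e-12) {
      return((yi - curve$c0) / curve$c1)
    }
    disc <- curve$c1^2 - 4 * curve$c2 * (curve$c0 - yi)
    if (disc < 0) {
      stop("no real dose produces frequency ", yi, " on this curve",
           call. = FALSE)
    }
    (-curve$c1 + sqrt(disc)) / (2 * curve$c2)
  }, numeric(1L))
}

#' @export
print.mn_calibration <- function(x, ...) {
  cat("Micronucleus dose-response calibration curve (",
      x$provenance, ")\n", sep = "")
  cat(sprintf("  forward:  y = %.4f + %.7f * D   (MN/500 BC, D in mGy)\n",
              x$c0, x$c1))
  if (x$invertible) {
    cat(sprintf("  inverse:  D = %.2f + %.2f * y   (mGy)\n", x$a, x$b))
  } else {
    cat("  inverse:  disabled (non-positive slope)\n")
  }
  if (!is.na(x$r_squared)) {
    cat(sprintf("  n = %d points, R^2 = %.4f (reliability %.2f%%), residual SD = %.3f\n",
                x$n_points, x$r_squared, 100 * x$r_squared, x$residual_sd))
  }
  invisible(x)
}

#' @export
coef.mn_calibration <- function(object, ...) {
  c(c0 = object$c0, c1 = object$c1, a = object$a, b = object$b)
}

#' Forward prediction: MN frequency expected at a dose
#'
#' @param object An `mn_calibration` object.
#' @param dose_mGy Dose(s) in mGy.
#' @param ... Unused.
#' @return Predicted MN/500 BC frequency.
#' @export
predict.mn_calibration <- function(object, dose_mGy, ...) {
  object$c0 + object$c1 * dose_mGy
}

#' @export
summary.mn_calibration <- function(object, ...) {
  print(object)
  if (!is.null(object$lm)) {
    cat("\nUnderlying least-squares fit:\n")
    print(summary(object$lm))
  }
  invisible(object)
}

#' @export
plot.mn_calibration <- function(x, ...) {
  if (is.null(x$data)) {
    stop("plot requires a curve fitted from data", call. = FALSE)
  }
  plot(x$data$dose, x$data$freq, xlab = "Dose (mGy)",
       ylab = "MN / 500 BC", main = "MN dose-response calibration", ...)
  graphics::abline(a = x$c0, b = x$c1)
  invisible(x)
}

#' Serialize a calibration curve to JSON
#'
#' Writes both parameterisations, the diagnostics, and the provenance so a
#' published curve and a refit are distinguishable downstream.
#'
#' @param curve An `mn_calibration` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "mn_calibration"))
  doc <- curve[c("c0", "c1", "a", "b", "invertible", "n_points",
                 "r_squared", "residual_sd", "provenance")]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' @param path JSON path produced by [write_calibration()] (or any document
#'   carrying at least the inverse coefficients `a` and `b`).
#' @return An `mn_calibration` object.
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(doc$c0) && !is.null(doc$c1)) {
    curve <- calibration_curve(
      c0 = doc$c0, c1 = doc$c1,
      n_points = if (is.null(doc$n_points)) NA_integer_ else doc$n_points,
      r_squared = if (is.null(doc$r_squared)) NA_real_ else doc$r_squared,
      residual_sd = if (is.null(doc$residual_sd)) NA_real_ else doc$residual_sd,
      provenance = if (is.null(doc$provenance)) "published" else doc$provenance
    )
  } else if (!is.null(doc$a) && !is.null(doc$b)) {
    curve <- from_inverse_coefficients(doc$a, doc$b)
  } else {
    stop("curve JSON must carry (c0, c1) or (a, b)", call. = FALSE)
  }
  curve
}
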