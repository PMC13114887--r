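# Significance machinery: one-way ANOVA across treatment arms, Tukey HSD
# (Tukey-Kramer for unbalanced groups) pairwise comparisons, and the
# donor-by-treatment interaction screen that licenses pooling across donors.

.as_group_list <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  lapply(groups, as.numeric)
}

#' One-way analysis of variance over treatment arms
#'
#' Classical fixed-effects one-way ANOVA on the MN/500 BC scale:
#' `F = MS_between / MS_within`, p-value from the F distribution on
#' (k - 1, N - k) degrees of freedom.
#'
#' @param groups Named list mapping arm label to a numeric vector of
#'   per-culture frequencies; at least two groups of at least two
#'   observations.
#' @return A list of class `mn_anova` with `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `group_means`, `ms_within`.
#' @export
one_way_anova <- function(groups) {
  groups <- .as_group_list(groups)
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1L))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  df_b <- k - 1L
  df_w <- N - k
  if (ssw <= 0) {
    stop("degenerate within-group variance: all groups constant",
         call. = FALSE)
  }
  f <- (ssb / df_b) / (ssw / df_w)
  structure(
    list(f_statistic = f, df_between = df_b, df_within = df_w,
         p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
         group_means = means, ms_within = ssw / df_w),
    class = "mn_anova"
  )
}

#' @export
print.mn_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4f on (%d, %d) df, p = %.4g\n",
              x$f_statistic, x$df_between, x$df_within, x$p_value))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise comparisons among arm means with family-wise control via
#' the studentized range distribution. The statistic is the Tukey-Kramer
#' form `q = |m_a - m_b| / sqrt(MS_w/2 * (1/n_a + 1/n_b))`, which reduces
#' to the classical balanced statistic when group sizes are equal; adjusted
#' p-values come from the studentized range CDF with `k` means and the
#' within degrees of freedom. Significance is flagged at each requested
#' alpha; the flags are nested by construction.
#'
#' @param groups Named list of numeric vectors, as [one_way_anova()].
#' @param alpha_levels Significance tiers to flag.
#' @return A data frame of class `tukey_table` with one row per unordered
#'   pair: `group_a`, `group_b`, `mean_diff`, `q_statistic`, `adjusted_p`,
#'   `significant_at` (`"0.001"`, `"0.01"`, `"0.05"` or `"ns"`).
#' @export
tukey_hsd <- function(groups, alpha_levels = c(0.001, 0.01, 0.05)) {
  groups <- .as_group_list(groups)
  if (length(groups) < 2L) {
    stop("Tukey HSD needs >= 2 groups", call. = FALSE)
  }
  aov_res <- one_way_anova(groups)
  k <- length(groups)
  n <- lengths(groups)
  means <- aov_res$group_means
  msw <- aov_res$ms_within
  dfw <- aov_res$df_within
  labs <- names(groups)
  pairs <- utils::combn(k, 2L)
  alpha_levels <- sort(alpha_levels)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    diff <- means[j] - means[i]
    se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
    sig <- alpha_levels[p < alpha_levels]
    data.frame(group_a = labs[i], group_b = labs[j],
               mean_diff = unname(diff), q_statistic = unname(q),
               adjusted_p = unname(p),
               significant_at = if (length(sig)) format(min(sig)) else "ns",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ms_within") <- msw
  attr(out, "df_within") <- dfw
  attr(out, "n_means") <- k
  class(out) <- c("tukey_table", "data.frame")
  out
}

#' Critical value of the studentized range
#'
#' Convenience wrapper around the studentized range quantile used by the
#' Tukey procedure, e.g. `q(0.05; k = 3, df = 6) ~ 4.34`.
#'
#' @param alpha Upper-tail probability.
#' @param nmeans Number of means `k`.
#' @param df Within-group degrees of freedom.
#' @return The critical value.
#' @export
tukey_critical_q <- function(alpha, nmeans, df) {
  stats::qtukey(alpha, nmeans = nmeans, df = df, lower.tail = FALSE)
}

#' Donor-by-treatment interaction screen
#'
#' Pooling scoring data across donors is legitimate only when the donor and
#' treatment factors do not interact. This screen fits the two-way
#' fixed-effects ANOVA `frequency ~ donor * treatment` on per-culture
#' MN/500 BC values and tests the interaction term; pooling is allowed when
#' the interaction p-value is at least `alpha`. Designs with a single donor
#' or treatment, or without replication within donor-by-treatment cells,
#' cannot be tested and return `pooling_allowed = FALSE` with an advisory
#' message.
#'
#' @param records A `culture_records` data frame; the treatment arm is the
#'   combination of substance, timing and dose.
#' @param alpha Interaction significance threshold.
#' @return A list of class `donor_screen` with `interaction_p`,
#'   `pooling_allowed`, `testable`, `message`, `df_interaction`.
#' @export
donor_interaction_screen <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records))
  freq <- mn_frequency_per_500(records$mn_count, records$n_bc_scored)
  donor <- factor(records$donor_id)
  treatment <- factor(paste(records$substance, records$timing,
                            records$dose_mGy, sep = "|"))
  res <- list(interaction_p = NA_real_, pooling_allowed = FALSE,
              testable = FALSE, df_interaction = NA_integer_,
              message = "")
  class(res) <- "donor_screen"
  if (nlevels(donor) < 2L || nlevels(treatment) < 2L) {
    res$message <- "cannot test: need >= 2 donors and >= 2 treatment arms"
    return(res)
  }
  cell_n <- table(donor, treatment)
  df_resid <- length(freq) - nlevels(donor) * nlevels(treatment)
  if (any(cell_n == 0L) || df_resid < 1L) {
    res$message <-
      "cannot test: unreplicated or incomplete donor-by-treatment design"
    return(res)
  }
  fit <- stats::aov(freq ~ donor * treatment)
  tab <- summary(fit)[[1L]]
  irow <- grep("donor:treatment", trimws(rownames(tab)))
  res$interaction_p <- tab[irow, "Pr(>F)"]
  res$df_interaction <- tab[irow, "Df"]
  res$testable <- TRUE
  res$pooling_allowed <- res$interaction_p >= alpha
  res$message <- if (res$pooling_allowed) {
    sprintf("no significant donor-by-treatment interaction (p = %.3f); pooling across donors allowed",
            res$interaction_p)
  } else {
    sprintf("significant donor-by-treatment interaction (p = %.3f); pooling not advised",
            res$interaction_p)
  }
  res
}

#' @export
print.donor_screen <- function(x, ...) {
  cat("Donor-by-treatment interaction screen\n")
  cat("  ", x$message, "\n", sep = "")
  invisible(x)
}
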