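# Independent numerical oracles used to cross-check the inference code.

# The published inverse dosimetry curve used throughout the worked examples.
paper_curve <- function() from_inverse_coefficients(-429.54, 64.37)

# Small well-formed culture table for I/O tests.
make_records <- function(n = 3, mn = 10, dose = 0, substance = "control",
                         timing = "none", solvent = "aqueous") {
  culture_records(data.frame(
    donor_id = paste0("d", seq_len(n)),
    experiment_id = "e1",
    substance = substance, timing = timing, solvent = solvent,
    dose_mGy = dose, n_bc_scored = 500, mn_count = mn,
    n_mono = 200, n_bi = 275, n_multi = 25
  ))
}

# Permutation-test for the one-way ANOVA F statistic: shuffle group labels
# and recompute F. Independent of the F-distribution route. Small discrete
# fixtures put non-trivial mass exactly at the observed F, so both tail
# conventions are returned: `p_ge` counts ties in the tail, `p_gt` does not;
# a continuous reference p-value should fall inside [p_gt, p_ge].
permutation_anova_p <- function(groups, n_perm = 20000, seed = 7) {
  set.seed(seed)
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  f_of <- function(lab) {
    sp <- split(values, lab)
    k <- length(sp); N <- length(values)
    means <- vapply(sp, mean, numeric(1))
    ssb <- sum(lengths(sp) * (means - mean(values))^2)
    ssw <- sum(vapply(sp, function(g) sum((g - mean(g))^2), numeric(1)))
    (ssb / (k - 1)) / (ssw / (N - k))
  }
  f_obs <- f_of(labels)
  ge <- 0L; gt <- 0L
  for (i in seq_len(n_perm)) {
    f <- f_of(sample(labels))
    if (f >= f_obs - 1e-12) ge <- ge + 1L
    if (f > f_obs + 1e-12) gt <- gt + 1L
  }
  list(p_ge = ge / n_perm, p_gt = gt / n_perm, n_perm = n_perm)
}

# Upper-tail probability of the studentized range by direct double
# quadrature: outer integral over the scale factor s = sqrt(chisq_df / df),
# inner integral the range probability of k standard normals.
ptukey_quadrature <- function(q, nmeans, df, rel.tol = 1e-9) {
  range_cdf <- function(w) {
    # P(range of k iid N(0,1) <= w)
    if (w <= 0) return(0)
    f <- function(z) {
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(nmeans - 1)
    }
    nmeans * stats::integrate(f, -Inf, Inf, rel.tol = rel.tol)$value
  }
  scale_density <- function(s) 2 * df * s * stats::dchisq(df * s^2, df)
  cdf <- stats::integrate(function(s) {
    vapply(s, function(si) scale_density(si) * range_cdf(q * si), numeric(1))
  }, 0, Inf, rel.tol = rel.tol)$value
  1 - cdf
}
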