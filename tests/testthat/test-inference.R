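fixture_groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))

test_that("one-way ANOVA matches the hand-decomposed fixture and base R", {
  res <- one_way_anova(fixture_groups)
  expect_equal(res$f_statistic, 3)          # SSB = 6 on 2 df, SSW = 6 on 6 df
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 6L)
  expect_equal(unname(res$group_means), c(2, 3, 4))
  # independent route: stats::oneway.test with pooled variance
  vals <- unlist(fixture_groups)
  lab <- factor(rep(names(fixture_groups), each = 3))
  ref <- stats::oneway.test(vals ~ lab, var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(one_way_anova(same)$f_statistic, 0)
  expect_equal(one_way_anova(same)$p_value, 1)
  expect_error(one_way_anova(list(a = 1:3)), ">= 2 groups")
  expect_error(one_way_anova(list(a = c(1, 1), b = c(2, 2))),
               "degenerate")
})

test_that("ANOVA p agrees with a seeded permutation test", {
  res <- one_way_anova(fixture_groups)
  perm <- permutation_anova_p(fixture_groups, n_perm = 20000, seed = 7)
  # the fixture's permutation distribution has mass exactly at F = 3, so the
  # continuous F p-value must land inside the tie band, up to MC error
  mc_se <- sqrt(perm$p_ge * (1 - perm$p_ge) / perm$n_perm)
  expect_gt(res$p_value, perm$p_gt - 4 * mc_se)
  expect_lt(res$p_value, perm$p_ge + 4 * mc_se)
})

test_that("ANOVA F is invariant under location shifts and relabeling", {
  set.seed(14)
  g <- list(x = rnorm(6), y = rnorm(5, 1), z = rnorm(7, 2))
  f0 <- one_way_anova(g)$f_statistic
  shifted <- lapply(g, function(v) v + 42)
  expect_equal(one_way_anova(shifted)$f_statistic, f0, tolerance = 1e-10)
  relabeled <- g[c("z", "x", "y")]
  expect_equal(one_way_anova(relabeled)$f_statistic, f0, tolerance = 1e-12)
})

test_that("Tukey HSD reproduces the hand statistic and base TukeyHSD", {
  tk <- tukey_hsd(fixture_groups)
  extreme <- tk[tk$group_a == "a" & tk$group_b == "c", ]
  expect_equal(extreme$q_statistic, 2 / sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(round(extreme$q_statistic, 3), 3.464)

  # independent route: base aov + TukeyHSD adjusted p
  vals <- unlist(fixture_groups)
  lab <- factor(rep(names(fixture_groups), each = 3))
  ref <- stats::TukeyHSD(stats::aov(vals ~ lab))$lab
  expect_equal(sort(tk$adjusted_p), sort(unname(ref[, "p adj"])),
               tolerance = 1e-9)
  expect_error(tukey_hsd(list(a = 1:3)), ">= 2 groups")
})

test_that("Tukey adjusted p matches direct quadrature of the range CDF", {
  tk <- tukey_hsd(fixture_groups)
  extreme <- tk[tk$group_a == "a" & tk$group_b == "c", ]
  p_quad <- ptukey_quadrature(extreme$q_statistic, nmeans = 3, df = 6)
  expect_lt(abs(extreme$adjusted_p - p_quad), 1e-4)
  # published critical value q(0.05; k = 3, df = 6) ~ 4.34
  expect_equal(tukey_critical_q(0.05, 3, 6), 4.34, tolerance = 0.005)
})

test_that("Tukey adjustment is never anti-conservative vs pairwise t-tests", {
  # comparison at the same error-variance estimate: the unadjusted pairwise
  # p is the two-sided t probability of q/sqrt(2) on the pooled within df
  set.seed(33)
  for (i in 1:10) {
    g <- list(a = rnorm(5), b = rnorm(5, 0.5), c = rnorm(6, 1), d = rnorm(4))
    tk <- tukey_hsd(g)
    dfw <- attr(tk, "df_within")
    p_unadj <- 2 * stats::pt(-tk$q_statistic / sqrt(2), dfw)
    expect_true(all(tk$adjusted_p + 1e-10 >= p_unadj))
  }
})

test_that("with two groups F = t^2 and Tukey matches the t-test decision", {
  set.seed(44)
  g <- list(a = rnorm(8), b = rnorm(8, 0.8))
  res <- one_way_anova(g)
  tt <- stats::t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  tk <- tukey_hsd(g)
  expect_equal(tk$adjusted_p, tt$p.value, tolerance = 1e-8)
})

test_that("identical groups yield non-significant Tukey comparisons", {
  g <- list(a = c(1, 2, 3, 2), b = c(2, 1, 3, 2), c = c(2, 3, 1, 2))
  tk <- tukey_hsd(g)
  expect_true(all(tk$adjusted_p > 0.9))
  expect_true(all(tk$significant_at == "ns"))
})

test_that("donor interaction screen licenses pooling only without interaction", {
  sim_records <- function(inter_sd, seed) {
    set.seed(seed)
    grid <- expand.grid(donor = paste0("d", 1:3),
                        trt = c("control", "RA"),
                        rep = 1:5)
    mu <- 26 + ifelse(grid$trt == "RA", -10, 0)
    if (inter_sd > 0) {
      shift <- outer(c(-1, 0, 1), c(-1, 1)) * inter_sd
      mu <- mu + shift[cbind(as.integer(grid$donor),
                             as.integer(factor(grid$trt)))]
    }
    culture_records(data.frame(
      donor_id = grid$donor, experiment_id = paste0("e", grid$rep),
      substance = grid$trt, timing = ifelse(grid$trt == "RA", "pre", "none"),
      solvent = "aqueous", dose_mGy = 2000, n_bc_scored = 500,
      mn_count = pmax(0, round(rnorm(nrow(grid), mu, 2.5)))
    ))
  }
  # null interaction: pooling allowed in >= 90% of replicates
  null_ok <- vapply(1:40, function(s) {
    donor_interaction_screen(sim_records(0, s))$pooling_allowed
  }, logical(1))
  expect_gte(mean(null_ok), 0.9)
  # strong interaction (>= 2 within-cell SDs): detected in >= 80%
  alt_block <- vapply(1:40, function(s) {
    donor_interaction_screen(sim_records(5, 1000 + s))$pooling_allowed
  }, logical(1))
  expect_gte(mean(!alt_block), 0.8)
})

test_that("unreplicated or single-donor designs yield a cannot-test verdict", {
  rec <- make_records(n = 4, mn = c(10, 11, 12, 13))
  rec$donor_id <- "d1"  # single donor
  scr <- donor_interaction_screen(rec)
  expect_false(scr$testable)
  expect_false(scr$pooling_allowed)
  expect_match(scr$message, "cannot test")

  # 2 donors x 2 treatments but one observation per cell: no interaction df
  rec2 <- culture_records(data.frame(
    donor_id = rep(c("d1", "d2"), each = 2),
    experiment_id = "e1",
    substance = rep(c("control", "RA"), 2),
    timing = rep(c("none", "pre"), 2),
    solvent = "aqueous", dose_mGy = 2000, n_bc_scored = 500,
    mn_count = c(26, 11, 25, 12)
  ))
  scr2 <- donor_interaction_screen(rec2)
  expect_false(scr2$testable)
  expect_match(scr2$message, "unreplicated|incomplete")
})
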