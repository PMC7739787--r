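# metrics-level generator for statistics tests: discipline x leg cell means,
# a Gaussian random intercept per skier-session (nested in discipline), and
# Gaussian residuals. Fast, with known truth.
make_metrics <- function(cell_means, n_id_per_disc = 5, n_cycles = 10,
                         id_sd = 3, resid_sd = 4, seed = 1) {
  set.seed(seed)
  disc <- rownames(cell_means)
  out <- list()
  for (d in disc) {
    for (i in seq_len(n_id_per_disc)) {
      u <- rnorm(1, 0, id_sd)
      for (leg in colnames(cell_means)) {
        out[[length(out) + 1]] <- data.frame(
          id = sprintf("%s-%02d", d, i), discipline = d, leg = leg,
          y = cell_means[d, leg] + u + rnorm(n_cycles, 0, resid_sd))
      }
    }
  }
  do.call(rbind, out)
}

cells_null <- matrix(20, 4, 2, dimnames = list(c("SL", "GS", "SG", "DH"),
                                               c("IL", "OL")))

test_that("REML fixed effects equal OLS on balanced data without ID variance", {
  md <- make_metrics(cells_null + outer(c(0, 5, 10, 8), c(0, 4), "+"),
                     id_sd = 0, seed = 2)
  fit <- fit_mixed(md, "y", transform = "none")
  ols <- stats::lm(y ~ discipline * leg,
                   data = transform(md,
                                    discipline = factor(discipline, c("SL", "GS", "SG", "DH")),
                                    leg = factor(leg, c("IL", "OL"))))
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("a null model recovers zero effects and zero ID variance", {
  md <- make_metrics(cells_null, n_id_per_disc = 13, n_cycles = 10,
                     id_sd = 0, resid_sd = 4, seed = 3)   # ~2080 rows
  fit <- fit_mixed(md, "y", transform = "none")
  expect_lt(max(abs(fit$beta[-1])), 1)        # Monte-Carlo error at n~2000
  expect_lt(abs(fit$beta[1] - 20), 1)
  expect_lt(fit$tau2, 0.5)
  expect_gt(min(fit$anova$p), 0.001)          # no spurious strong signal
})

test_that("Satterthwaite df matches the balanced between-session analysis", {
  # one observation level between-ID factor: df should be (#IDs - #groups)
  md <- make_metrics(cells_null + outer(c(0, 6, 12, 10), c(0, 0), "+"),
                     n_id_per_disc = 5, n_cycles = 8, id_sd = 3, seed = 4)
  fit <- fit_mixed(md, "y", fixed = ~ discipline, transform = "none")
  tc <- tukey_contrasts(fit, "discipline")
  expect_equal(tc$df, rep(16, 6), tolerance = 0.02)
  expect_equal(fit$anova$ddf[1], 16, tolerance = 0.5)
})

test_that("mixed-model Cohen's d and effect labels", {
  expect_equal(cohens_d_mixed(8, 9, 55), 1)
  expect_equal(cohens_d_mixed(0, 9, 55), 0)
  expect_error(cohens_d_mixed(1, 0, 0), "variance")
  expect_equal(classify_effect(c(0, 0.19, 0.2, 0.49, 0.5, 0.79, 0.8, 1.16)),
               c("trivial", "trivial", "small", "small", "medium", "medium",
                 "large", "large"))
  expect_error(classify_effect(-0.1))
  # d equals classic pooled-SD Cohen's d when the ID variance vanishes
  md <- make_metrics(cells_null + outer(c(0, 5, 0, 0), c(0, 0), "+"),
                     n_id_per_disc = 8, n_cycles = 25, id_sd = 0, seed = 1)
  fit <- fit_mixed(md, "y", fixed = ~ discipline, transform = "none")
  tc <- tukey_contrasts(fit, "discipline")
  g1 <- md$y[md$discipline == "SL"]; g2 <- md$y[md$discipline == "GS"]
  sp <- sqrt(((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
               (length(g1) + length(g2) - 2))
  d_classic <- abs(mean(g1) - mean(g2)) / sp
  d_mixed <- tc$cohens_d[tc$contrast == "SL - GS"]
  expect_equal(d_mixed, d_classic, tolerance = 0.02)
})

test_that("log transform fires only for clearly non-normal positive data", {
  set.seed(6)
  norm <- maybe_log_transform(rnorm(500, 50, 5))
  expect_equal(norm$transform, "none")
  x <- rlnorm(500, 3, 1)
  logn <- maybe_log_transform(x)
  expect_equal(logn$transform, "log")
  expect_equal(logn$values, log(x))
  expect_lt(logn$p_raw, 0.01)
  cst <- maybe_log_transform(rep(7, 20))
  expect_equal(cst$transform, "none")
  expect_true(cst$degenerate)
  expect_warning(maybe_log_transform(c(rlnorm(300, 0, 2), -1)), "positive")
})

test_that("Tukey adjustment reduces to the t-test for two groups", {
  md <- make_metrics(cells_null[1:2, , drop = FALSE] + outer(c(0, 3), c(0, 0), "+"),
                     n_id_per_disc = 6, n_cycles = 8, id_sd = 2, seed = 7)
  fit <- fit_mixed(md, "y", fixed = ~ discipline, transform = "none")
  tc <- tukey_contrasts(fit, "discipline")
  expect_equal(nrow(tc), 1)
  p_t <- 2 * stats::pt(abs(tc$t), tc$df, lower.tail = FALSE)
  expect_equal(tc$p_adj, p_t, tolerance = 1e-6)
})

test_that("Tukey familywise error on a 4-group null is controlled", {
  # scaled-down null simulation with a seeded stream
  set.seed(99)
  seeds <- sample.int(1e6, 400)
  hits <- vapply(seeds, function(s) {
    md <- make_metrics(cells_null[, 1, drop = FALSE], n_id_per_disc = 6,
                       n_cycles = 6, id_sd = 2, resid_sd = 3, seed = s)
    fit <- fit_mixed(md, "y", fixed = ~ discipline, transform = "none",
                     tests = FALSE)
    any(tukey_contrasts(fit, "discipline")$p_adj < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.07)
})

test_that("contrasts recover a known discipline ordering", {
  md <- make_metrics(cells_null + outer(c(0, 8, 16, 15), c(0, 0), "+"),
                     n_id_per_disc = 5, n_cycles = 10, id_sd = 2, seed = 8)
  fit <- fit_mixed(md, "y", fixed = ~ discipline, transform = "none")
  tc <- tukey_contrasts(fit, "discipline")
  expect_lt(tc$estimate[tc$contrast == "SL - GS"], 0)
  expect_lt(tc$estimate[tc$contrast == "SL - SG"], 0)
  expect_lt(tc$estimate[tc$contrast == "GS - SG"], 0)
})

test_that("the interaction is detected with high power at the stated design", {
  # ISO%(OL) differs by +15 points between SG and SL, ID SD 3 points;
  # scaled-down replicate count, seeded
  cells <- matrix(c(19, 20, 28, 38,     # IL
                    11, 34, 42, 38),    # OL
                  4, 2, dimnames = list(c("SL", "GS", "SG", "DH"),
                                        c("IL", "OL")))
  set.seed(100)
  seeds <- sample.int(1e6, 25)
  pvals <- vapply(seeds, function(s) {
    md <- make_metrics(cells, n_id_per_disc = 5, n_cycles = 20,
                       id_sd = 3, resid_sd = 8, seed = s)
    fit <- fit_mixed(md, "y", transform = "none")
    fit$anova$p[fit$anova$term == "discipline:leg"]
  }, numeric(1))
  expect_gte(mean(pvals < 0.001), 0.95)
})

test_that("ANOVA p-values under a true null are approximately uniform", {
  set.seed(101)
  seeds <- sample.int(1e6, 150)
  pvals <- vapply(seeds, function(s) {
    md <- make_metrics(cells_null[, 1, drop = FALSE], n_id_per_disc = 4,
                       n_cycles = 6, id_sd = 2, resid_sd = 3, seed = s)
    fit <- fit_mixed(md, "y", fixed = ~ discipline, transform = "none")
    fit$anova$p[1]
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("d is invariant to affine rescaling of the response", {
  md <- make_metrics(cells_null + outer(c(0, 6, 3, 1), c(0, 2), "+"),
                     n_id_per_disc = 4, n_cycles = 6, id_sd = 2, seed = 9)
  f1 <- fit_mixed(md, "y", transform = "none")
  md$y2 <- 100 + 7 * md$y
  f2 <- fit_mixed(md, "y2", transform = "none")
  t1 <- tukey_contrasts(f1, "discipline", by = "leg")
  t2 <- tukey_contrasts(f2, "discipline", by = "leg")
  expect_equal(t1$cohens_d, t2$cohens_d, tolerance = 1e-6)
})

test_that("model fitting validates its inputs", {
  md <- make_metrics(cells_null, n_id_per_disc = 1, seed = 10)
  expect_error(fit_mixed(md[md$discipline == "SL", ], "y"), "2 levels")
  md2 <- make_metrics(cells_null, n_id_per_disc = 5, seed = 10)
  md2$y <- -abs(md2$y)
  expect_error(fit_mixed(md2, "y", transform = "log"), "positive")
})
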