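test_that("with no random levels the fit is exact inverse-variance GLS", {
  # single effect: one-observation GLS
  es1 <- data.frame(yi = 0.5, vi = 0.04, comparison_id = "c1")
  f1 <- fit_reml(es1, spec = meta_spec("SMD", ~1, random = character(0)))
  expect_equal(unname(f1$beta), 0.5)
  expect_equal(unname(f1$se), 0.2)

  # equal variances: arithmetic mean with SE = sqrt(v/k)
  set.seed(3)
  y <- rnorm(12)
  esk <- data.frame(yi = y, vi = 0.15, comparison_id = paste0("c", 1:12))
  fk <- fit_reml(esk, spec = meta_spec("SMD", ~1, random = character(0)))
  expect_equal(unname(fk$beta), mean(y))
  expect_equal(unname(fk$se), sqrt(0.15 / 12))

  # unequal variances: exact weighted mean
  vi <- runif(9, 0.02, 0.4)
  es <- data.frame(yi = rnorm(9), vi = vi, comparison_id = paste0("c", 1:9))
  f <- fit_reml(es, spec = meta_spec("SMD", ~1, random = character(0)))
  expect_equal(unname(f$beta), sum(es$yi / vi) / sum(1 / vi))
  expect_equal(unname(f$se), sqrt(1 / sum(1 / vi)))
  expect_equal(unname(f$tau2), c(0, 0, 0), ignore_attr = TRUE)
})

test_that("REML estimates agree with an exhaustive grid-search oracle", {
  # random toy instances, one exchangeable random level
  set.seed(2718)
  for (i in 1:30) {
    k <- sample(4:6, 1)
    # at least two distinct studies, otherwise tau2 is unidentifiable
    # (the study intercept aliases the fixed intercept)
    repeat {
      study <- paste0("S", sample(1:3, k, replace = TRUE))
      if (length(unique(study)) >= 2L) break
    }
    es <- data.frame(yi = rnorm(k, 0, 1), vi = runif(k, 0.05, 0.3),
                     comparison_id = paste0("c", 1:k), study_id = study)
    X <- matrix(1, k, 1)
    ref <- grid_fit_ref(es$yi, X, diag(es$vi), study)
    fit <- fit_reml(es, spec = meta_spec("SMD", ~1, random = "study"))
    expect_equal(unname(fit$beta), unname(ref$beta), tolerance = 1e-4)
    expect_lt(abs(fit$tau2[["study"]] - ref$tau2), 1e-4)
  }
})

test_that("the multilevel fit matches metafor on synthetic data", {
  skip_if_not_installed("metafor")
  d <- generate_dataset(synth_config(n_studies = 25, seed = 77))
  es <- compute_effects(d$comparisons, kind = "SMD")
  v <- build_vcv(es)
  # rho = 1 collapses the compound-symmetric experiment level to an
  # exchangeable experiment intercept
  fit <- fit_reml(es, vcv = v, spec = meta_spec("SMD", ~1,
                                                random = c("study",
                                                           "experiment")),
                  rho_fixed = 1)
  mf <- metafor::rma.mv(yi, V = v$matrix,
                        random = list(~1 | study_id, ~1 | experiment_id),
                        data = es, method = "REML",
                        control = list(rel.tol = 1e-12))
  expect_equal(unname(fit$beta), as.numeric(mf$b), tolerance = 1e-5)
  expect_equal(unname(fit$se), as.numeric(mf$se), tolerance = 1e-5)
  expect_equal(unname(fit$tau2[c("study", "experiment")]),
               as.numeric(mf$sigma2), tolerance = 1e-4)
  expect_equal(fit$loglik_reml, as.numeric(stats::logLik(mf)),
               tolerance = 1e-8)

  # compound symmetry with the within-experiment correlation held fixed
  fit2 <- fit_reml(es, vcv = v,
                   spec = meta_spec("SMD", ~1,
                                    random = c("study", "experiment")),
                   rho_fixed = 0.5)
  mf2 <- metafor::rma.mv(yi, V = v$matrix,
                         random = list(~1 | study_id,
                                       ~comparison_id | experiment_id),
                         struct = "CS", rho = 0.5, data = es,
                         method = "REML", control = list(rel.tol = 1e-12))
  expect_equal(unname(fit2$beta), as.numeric(mf2$b), tolerance = 1e-5)
  expect_equal(unname(fit2$tau2[["experiment"]]), as.numeric(mf2$tau2),
               tolerance = 1e-4)
  expect_equal(fit2$loglik_reml, as.numeric(stats::logLik(mf2)),
               tolerance = 1e-8)
})

test_that("rank-deficient designs are refused with the aliased columns", {
  d <- generate_dataset(synth_config(n_studies = 6, seed = 10))
  es <- compute_effects(d$comparisons, kind = "SMD")
  es$dup <- es$host_range  # perfectly collinear moderator
  expect_error(
    fit_reml(es, spec = meta_spec("SMD", ~ host_range + dup)),
    "aliased")
})

test_that("I-squared decomposition follows the typical-sampling-variance rule", {
  es <- data.frame(yi = rnorm(10), vi = 0.1,
                   comparison_id = paste0("c", 1:10),
                   study_id = paste0("S", 1:10))
  f <- fit_reml(es, spec = meta_spec("SMD", ~1, random = "study"))
  # equal vi: typical v equals v, components sum to the total
  expect_equal(attr(f$i2, "typical_v"), 0.1)
  expect_equal(sum(f$i2[c("study", "genus", "experiment")]),
               f$i2[["total"]])

  # hand value: tau2 = 0.3 against vbar = 0.1 gives 75%
  f2 <- f
  f2$tau2 <- c(study = 0.3, genus = 0, experiment = 0)
  i2 <- i2_decompose(f2)
  expect_equal(i2[["study"]], 75)
  expect_equal(i2[["total"]], 75)

  # no heterogeneity: all components zero
  f3 <- f
  f3$tau2 <- c(study = 0, genus = 0, experiment = 0)
  expect_equal(unname(i2_decompose(f3)[c("study", "total")]), c(0, 0))
})

test_that("QM is the Wald chi-square and rejects degenerate contrasts", {
  es <- data.frame(yi = c(rnorm(6, 0), rnorm(6, 0.8)), vi = 0.05,
                   comparison_id = paste0("c", 1:12),
                   study_id = paste0("S", rep(1:6, 2)),
                   grp = rep(c("a", "b"), each = 6))
  f <- fit_reml(es, spec = meta_spec("SMD", ~ 0 + grp, random = "study"))
  q <- qm_test(f, coefficients = 2)
  expect_equal(q$QM, (f$beta[2] / f$se[2])^2, ignore_attr = TRUE)
  expect_equal(q$df, 1)
  expect_equal(q$pval, pchisq(q$QM, 1, lower.tail = FALSE))

  # QM of a zero coefficient is 0 with p = 1
  fz <- f; fz$beta[1] <- 0
  expect_equal(qm_test(fz, coefficients = 1)$QM, 0)
  expect_equal(qm_test(fz, coefficients = 1)$pval, 1)

  expect_error(qm_test(f, L = rbind(c(1, -1), c(1, -1))), "rank deficient")
})

test_that("linear contrasts reproduce coefficients and combine variances", {
  es <- data.frame(yi = rnorm(14, 0.3), vi = runif(14, 0.02, 0.2),
                   comparison_id = paste0("c", 1:14),
                   study_id = paste0("S", rep(1:7, 2)),
                   grp = rep(c("a", "b"), 7))
  f <- fit_reml(es, spec = meta_spec("SMD", ~ 0 + grp, random = "study"))

  # selection contrast reproduces the coefficient
  c1 <- contrast(f, c(1, 0))
  expect_equal(c1$estimate, unname(f$beta[1]))
  expect_equal(c1$se, unname(f$se[1]))

  # difference of two coefficients: se = sqrt(v1 + v2 - 2cov)
  c2 <- contrast(f, c(1, -1))
  expect_equal(c2$se,
               sqrt(f$cov_beta[1, 1] + f$cov_beta[2, 2] -
                      2 * f$cov_beta[1, 2]))

  expect_error(contrast(f, c(0, 0)), "zero weight")
  expect_error(contrast(f, c(1, 0, 0)), "length")
})

test_that("Holm adjustment applies the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(c(0.2, 0.2, 0.2)), c(0.6, 0.6, 0.6))
  # componentwise >= input, <= 1, order-preserving with the input
  set.seed(9)
  p <- runif(6)
  a <- holm_adjust(p)
  expect_true(all(a >= p) && all(a <= 1))
  expect_equal(order(a), order(holm_adjust(p)))
  expect_equal(a[order(p)], cummax(a[order(p)]))  # monotone step-down
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("prediction intervals widen the CI by the summed heterogeneity", {
  es <- data.frame(yi = rnorm(8), vi = 0.1, comparison_id = paste0("c", 1:8),
                   study_id = paste0("S", 1:8))
  f <- fit_reml(es, spec = meta_spec("SMD", ~1, random = "study"))
  f$tau2 <- c(study = 0.03, genus = 0, experiment = 0)
  f$se[1] <- 0.1
  pi <- prediction_interval(f)
  expect_equal(unname(diff(pi)) / 2, qnorm(0.975) * sqrt(0.04))
  expect_equal(unname(diff(pi)) / 2, 0.392, tolerance = 1e-3)

  # no heterogeneity: prediction interval equals the confidence interval
  f$tau2 <- c(study = 0, genus = 0, experiment = 0)
  pi0 <- prediction_interval(f)
  expect_equal(unname(pi0),
               unname(c(f$beta[1] - qnorm(0.975) * f$se[1],
                        f$beta[1] + qnorm(0.975) * f$se[1])))

  # width is non-decreasing in each component
  f$tau2 <- c(study = 0.1, genus = 0, experiment = 0)
  expect_gt(diff(prediction_interval(f)), diff(pi0))
})

test_that("moderator cross-tabulation reports integer row percentages", {
  rec <- data.frame(
    parasite_genetic_diversity = rep(c("high", "low"), c(4, 4)),
    laboratory = c("no", "no", "no", "yes", rep("yes", 4)))
  ct <- collinearity_crosstab(rec, "parasite_genetic_diversity",
                              "laboratory")
  expect_equal(unname(ct$counts["high", c("no", "yes")]), c(3, 1))
  expect_equal(unname(ct$row_percent["high", c("no", "yes")]), c(75, 25))
  expect_equal(unname(ct$row_percent["low", c("no", "yes")]), c(0, 100))
  expect_error(collinearity_crosstab(rec, "nope", "laboratory"),
               "unknown moderator")
})
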