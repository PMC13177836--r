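low_ <- function(m, s, n) group_summary(m, s, n, diversity_level = "low")
high_ <- function(m, s, n) group_summary(m, s, n, diversity_level = "high")

test_that("SMD matches the Hedges-corrected hand calculation", {
  e <- effect_smd(low_(10, 2, 10), high_(8, 2, 10))
  J <- 1 - 3 / 71
  expect_equal(e$yi, -J)
  expect_equal(e$yi, -0.9577, tolerance = 1e-4)
  expect_equal(e$vi, 0.2 + J^2 / 40)
  expect_equal(e$vi, 0.2229, tolerance = 1e-3)

  # identical groups: g = 0 and variance reduces to (nH+nL)/(nH nL)
  e0 <- effect_smd(low_(5, 1.3, 10), high_(5, 1.3, 10))
  expect_equal(e0$yi, 0)
  expect_equal(e0$vi, 0.2)

  # antisymmetry under swapping the groups
  a <- effect_smd(low_(10, 2, 12), high_(7, 3, 9))
  b <- effect_smd(low_(7, 3, 9), high_(10, 2, 12))
  expect_equal(b$yi, -a$yi)
  expect_equal(b$vi, a$vi)

  expect_error(effect_smd(low_(1, 0, 10), high_(2, 0, 10)), "pooled SD")
  expect_error(effect_smd(low_(1, 1, 1), high_(2, 1, 10)), "n >= 2")
})

test_that("lnCVR matches the hand calculation with independence variance", {
  e <- effect_lncvr(low_(10, 2, 10), high_(10, 4, 10))
  expect_equal(e$yi, log(2))
  expect_equal(e$vi, 0.004 + 1 / 18 + 0.016 + 1 / 18)
  expect_equal(e$vi, 0.1311, tolerance = 1e-3)

  # equal CVs and equal n cancel exactly
  expect_equal(effect_lncvr(low_(5, 1, 8), high_(15, 3, 8))$yi, 0)

  # antisymmetry under swapping
  a <- effect_lncvr(low_(10, 2, 10), high_(8, 3, 10))
  b <- effect_lncvr(low_(8, 3, 10), high_(10, 2, 10))
  expect_equal(b$yi, -a$yi)
  expect_equal(b$vi, a$vi)

  # scale invariance: rescaling both groups by the same constant
  s1 <- effect_lncvr(low_(10, 2, 10), high_(8, 3, 12))
  s2 <- effect_lncvr(low_(10 * 7.3, 2 * 7.3, 10), high_(8 * 7.3, 3 * 7.3, 12))
  expect_equal(s2$yi, s1$yi)

  expect_error(effect_lncvr(low_(0, 1, 10), high_(1, 1, 10)), "non-positive")
})

test_that("effect formulas agree with metafor's escalc", {
  skip_if_not_installed("metafor")
  set.seed(101)
  for (i in 1:20) {
    mL <- runif(1, 2, 20); mH <- runif(1, 2, 20)
    sL <- runif(1, 0.5, 5); sH <- runif(1, 0.5, 5)
    nL <- sample(5:40, 1); nH <- sample(5:40, 1)
    es <- effect_smd(low_(mL, sL, nL), high_(mH, sH, nH))
    ref <- metafor::escalc(measure = "SMD", m1i = mH, sd1i = sH, n1i = nH,
                           m2i = mL, sd2i = sL, n2i = nL)
    # escalc applies the exact gamma-ratio small-sample correction; the
    # 1 - 3/(4m - 1) approximation used here agrees to ~1e-5 relative
    expect_equal(es$yi, as.numeric(ref$yi), tolerance = 2e-4)
    expect_equal(es$vi, as.numeric(ref$vi), tolerance = 2e-4)
    ec <- effect_lncvr(low_(mL, sL, nL), high_(mH, sH, nH))
    rc <- metafor::escalc(measure = "CVR", m1i = mH, sd1i = sH, n1i = nH,
                          m2i = mL, sd2i = sL, n2i = nL)
    expect_equal(ec$yi, as.numeric(rc$yi), tolerance = 1e-10)
    expect_equal(ec$vi, as.numeric(rc$vi), tolerance = 1e-10)
  }
})

test_that("compute_effects applies the offset and matches the pair functions", {
  rec <- toy_records(4)
  rec$mean_low[1] <- 0; rec$sd_low[1] <- 0  # zero summary needs the offset
  es <- compute_effects(rec, kind = c("SMD", "lnCVR"))
  expect_equal(nrow(es), 8)
  expect_equal(attr(es, "offset"), 0.001)
  i <- which(es$kind == "SMD")[2]
  manual <- effect_smd(
    apply_offset(low_(rec$mean_low[2], rec$sd_low[2], rec$n_low[2])),
    apply_offset(high_(rec$mean_high[2], rec$sd_high[2], rec$n_high[2])))
  expect_equal(es$yi[i], manual$yi)
  expect_equal(es$vi[i], manual$vi)

  # zeros-only sensitivity switch leaves non-zero rows untouched
  ez <- compute_effects(rec, kind = "SMD", offset_zero_only = TRUE)
  plain <- effect_smd(low_(rec$mean_low[2], rec$sd_low[2], rec$n_low[2]),
                      high_(rec$mean_high[2], rec$sd_high[2], rec$n_high[2]))
  expect_equal(ez$yi[2], plain$yi)
})

test_that("sampling variances are calibrated on noise-only synthetic data", {
  # tau2 = 0, single cell: empirical variance of computed effects should
  # match the analytic formulas (3 sigma Monte-Carlo bands on the variance
  # ratio, plus a small allowance for the large-sample approximation)
  cells <- diversity_uncertainty_cells()
  cells$smd <- c(-0.5, -0.5, -0.5, -0.5)
  cells$lncvr <- 0.3
  cfg <- synth_config(n_studies = 2000, experiments_per_study = 1,
                      comparisons_per_experiment = 1,
                      cell_effects = cells,
                      tau2_study = 0, tau2_genus = 0, tau2_experiment = 0,
                      n_per_group = 50, shared_control_fraction = 0,
                      seed = 404)
  d <- generate_dataset(cfg)
  es <- compute_effects(d$comparisons, kind = "SMD", offset = 0)
  v_analytic <- 2 / 50 + mean(d$truth$true_smd)^2 / 200
  ratio <- var(es$yi) / v_analytic
  band <- 3 * sqrt(2 / (nrow(es) - 1)) + 0.03
  expect_lt(abs(ratio - 1), band)
  ec <- compute_effects(d$comparisons, kind = "lnCVR", offset = 0)
  cvL <- 0.3; cvH <- 0.3 * exp(0.3)
  v_cvr <- cvL^2 / 50 + 1 / 98 + cvH^2 / 50 + 1 / 98
  expect_lt(abs(var(ec$yi) / v_cvr - 1), band)
})

test_that("shared-control VCV blocks follow the requested construction", {
  rec <- toy_records(4)
  es <- compute_effects(rec, kind = "SMD")
  # no shared controls: diagonal
  v <- build_vcv(es)
  expect_equal(v$matrix, diag(es$vi, 4), ignore_attr = TRUE)

  # fixed_r: v1 = v2 = 0.2 -> off-diagonal exactly 0.1
  es2 <- es[1:2, ]
  es2$vi <- c(0.2, 0.2)
  es2$shared_control_key <- "blockA"
  v2 <- build_vcv(es2, r = 0.5)
  expect_equal(v2$matrix[1, 2], 0.1)
  expect_equal(diag(v2$matrix), es2$vi, ignore_attr = TRUE)

  # exact_smd at g = 0: cov = 1/n_C with N = 30
  es3 <- es2
  es3$yi <- c(0, 0)
  es3$n_low <- 10; es3$n_high <- 10
  v3 <- build_vcv(es3, mode = "exact_smd")
  expect_equal(v3$matrix[1, 2], 0.1)

  expect_error(build_vcv(compute_effects(rec, kind = "lnCVR"),
                         mode = "exact_smd"), "SMD effects only")
  # invalid correlation must be refused, not repaired
  expect_error(build_vcv(es2, r = 1.2), "in \\(0, 1\\)")
})

test_that("VCV construction is permutation-equivariant", {
  d <- generate_dataset(synth_config(n_studies = 10, seed = 5,
                                     shared_control_fraction = 1))
  es <- compute_effects(d$comparisons, kind = "SMD")
  v <- build_vcv(es)
  set.seed(14)
  perm <- sample(nrow(es))
  vp <- build_vcv(es[perm, ])
  expect_equal(vp$ordering, v$ordering[perm])
  expect_equal(vp$matrix, v$matrix[perm, perm], ignore_attr = TRUE)
})
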