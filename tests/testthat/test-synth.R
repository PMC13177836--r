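test_that("the preset encodes the diversity-uncertainty sign structure", {
  cfg <- diversity_uncertainty_preset()
  ce <- cfg$cell_effects
  pick <- function(hr, pd)
    ce[ce$host_range == hr & ce$parasite_genetic_diversity == pd, ]
  expect_lt(pick("specialist", "low")$lncvr, 0)
  expect_gt(pick("specialist", "high")$lncvr, 0)
  expect_true(all(ce$smd <= 0))
  # generalist cells attenuated toward zero relative to specialist cells
  expect_true(all(abs(pick("generalist", "low")$lncvr) <
                    abs(pick("specialist", "low")$lncvr)))
  expect_lt(abs(pick("generalist", "high")$smd),
            abs(pick("specialist", "high")$smd))
})

test_that("invalid configurations are refused with the offending field", {
  expect_error(synth_config(tau2_study = -1), "tau2_study")
  expect_error(synth_config(rho_experiment = 1.5), "rho_experiment")
  expect_error(synth_config(shared_control_fraction = 2),
               "shared_control_fraction")
  expect_error(synth_config(n_per_group = 1), "n_per_group")
  bad_cells <- diversity_uncertainty_cells()[1:3, ]
  expect_error(synth_config(cell_effects = bad_cells), "cell_effects")
  mm <- default_moderator_marginals()
  mm$host_type <- c(invertebrate = 0.7, vertebrate = 0.7)
  expect_error(synth_config(moderator_marginals = mm),
               "moderator_marginals")
})

test_that("generation is deterministic: same config, identical CSV bytes", {
  cfg <- synth_config(n_studies = 6, seed = 99)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_comparisons(generate_dataset(cfg)$comparisons, f1)
  write_comparisons(generate_dataset(cfg)$comparisons, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
  # and the caller's RNG stream is left untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_dataset(cfg))
  expect_identical(.Random.seed, before)
})

test_that("identifiers form a strict 3-level nesting", {
  d <- generate_dataset(synth_config(n_studies = 12, seed = 3))
  cmp <- d$comparisons
  expect_false(anyDuplicated(cmp$comparison_id) > 0)
  # every experiment maps to exactly one study
  m <- unique(cmp[, c("study_id", "experiment_id")])
  expect_false(anyDuplicated(m$experiment_id) > 0)
  # truth table aligns row-for-row with the comparisons
  expect_identical(d$truth$comparison_id, cmp$comparison_id)
  # moderators come from the closed vocabularies
  ml <- moderator_levels()
  for (mod in names(ml)) expect_true(all(cmp[[mod]] %in% ml[[mod]]))
})

test_that("the noise-free limit reproduces the cell effects exactly", {
  cells <- diversity_uncertainty_cells()
  cells$smd <- -0.5
  cells$lncvr <- 0.25
  cfg <- synth_config(n_studies = 8, cell_effects = cells,
                      tau2_study = 0, tau2_genus = 0, tau2_experiment = 0,
                      sampling_noise = FALSE, seed = 17)
  d <- generate_dataset(cfg)
  es <- compute_effects(d$comparisons, kind = "SMD", offset = 0,
                        hedges_correct = FALSE)
  expect_equal(es$yi, rep(-0.5, nrow(es)))
  ec <- compute_effects(d$comparisons, kind = "lnCVR", offset = 0)
  expect_equal(ec$yi, rep(0.25, nrow(ec)))
})

test_that("computed lnCVR is Monte-Carlo consistent with its target", {
  # 1000 independent comparisons in one cell, true lnCVR = ln 2, n = 50
  cells <- diversity_uncertainty_cells()
  cells$smd <- 0
  cells$lncvr <- 0.6931
  cfg <- synth_config(n_studies = 1000, experiments_per_study = 1,
                      comparisons_per_experiment = 1, cell_effects = cells,
                      cell_probs = c(1, 0, 0, 0),
                      tau2_study = 0, tau2_genus = 0, tau2_experiment = 0,
                      n_per_group = 50, shared_control_fraction = 0,
                      seed = 2024)
  d <- generate_dataset(cfg)
  ec <- compute_effects(d$comparisons, kind = "lnCVR", offset = 0)
  mc_se <- sd(ec$yi) / sqrt(nrow(ec))
  expect_lt(abs(mean(ec$yi) - 0.6931), 3 * mc_se)
})

test_that("shared-control experiments reuse one observed low group", {
  d <- generate_dataset(synth_config(n_studies = 20, seed = 8,
                                     shared_control_fraction = 1,
                                     comparisons_per_experiment = c(2, 3)))
  cmp <- d$comparisons
  expect_true(any(!is.na(cmp$shared_control_key)))
  for (key in unique(na.omit(cmp$shared_control_key))) {
    blk <- cmp[!is.na(cmp$shared_control_key) &
                 cmp$shared_control_key == key, ]
    expect_gte(nrow(blk), 2)
    expect_equal(length(unique(blk$mean_low)), 1L)
    expect_equal(length(unique(blk$sd_low)), 1L)
  }
})

test_that("replicate-level generation honours the sampling distributions", {
  cfg <- synth_config(seed = 55)
  # degenerate probability: all proportion replicates are zero
  r0 <- generate_replicates(cfg, "proportion", prob = 0,
                            n_populations = 5)
  expect_true(all(r0$value == 0))

  # Poisson mean-variance identity at lambda = 4 over 10,000 replicates
  rp <- generate_replicates(cfg, "count", n_populations = 100,
                            replicates_per_population = 100, lambda = 4)
  ratio <- var(rp$value) / mean(rp$value)
  expect_lt(abs(ratio - 1), 3 * sqrt(2 / nrow(rp)) + 0.01)

  # continuous kind is reproducible under the config seed
  r1 <- generate_replicates(cfg, "continuous")
  r2 <- generate_replicates(cfg, "continuous")
  expect_identical(r1, r2)

  # and flows through harmonisation to a two-group comparison
  pops <- summarise_replicates(r1)
  split <- dichotomise_continuous(pops)
  expect_equal(split$low$n, split$high$n)
})
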