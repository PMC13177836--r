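# Seeded evaluation: all stochastic operations run in a named, versioned
# RNG stream and restore the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

.cell_key <- function(host_range, parasite_genetic_diversity) {
  paste(host_range, parasite_genetic_diversity, sep = ":")
}

#' Configuration of the synthetic comparison-table generator
#'
#' Fully parameterises a synthetic dataset with the statistical structure the
#' meta-analysis assumes: a strict 3-level nesting (comparisons within
#' experiments within studies), a 2x2 parasite-genetic-diversity by
#' host-range cell structure with cell-specific true SMD and lnCVR,
#' study/genus/experiment heterogeneity, within-experiment correlation, and
#' shared low-diversity control groups.
#'
#' @param n_studies Number of studies.
#' @param experiments_per_study Count, or range `c(lo, hi)` sampled uniformly
#'   per study.
#' @param comparisons_per_experiment Count or range, sampled per experiment.
#' @param cell_effects Data.frame with columns `host_range`,
#'   `parasite_genetic_diversity`, `smd`, `lncvr`, covering all four cells
#'   exactly once. The `smd` is the population standardised mean difference
#'   (the estimand of Hedges' g); `lncvr` the population log CV ratio.
#' @param tau2_study,tau2_genus,tau2_experiment Variance components (>= 0) of
#'   the study, host-genus and experiment-level random deviations of the true
#'   effects.
#' @param rho_experiment Within-experiment correlation of comparison-level
#'   deviations, in \[-1, 1\] (compound symmetry).
#' @param control_mean,control_cv Population mean and coefficient of
#'   variation of the low-diversity (reference) group.
#' @param n_per_group Replicate-population count per group, count or range.
#' @param shared_control_fraction Probability that a multi-comparison
#'   experiment reports all its high-diversity groups against one shared
#'   low-diversity group, in \[0, 1\].
#' @param cell_probs Probabilities of the four cells (order of
#'   `cell_effects` rows); studies are assigned to cells.
#' @param moderator_marginals Named list of per-moderator category
#'   probability vectors (the eight contextual moderators; see
#'   [moderator_levels()]).
#' @param genus_dup_fraction Fraction of studies sharing a host genus with an
#'   earlier study (exercises the genus random effect).
#' @param sampling_noise If `FALSE`, observed group summaries equal their
#'   population values (analytic limit mode, for exactness checks).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   config.
#' @return An object of class `synth_config` (validated list).
#' @seealso [diversity_uncertainty_preset()], [generate_dataset()]
#' @export
synth_config <- function(n_studies = 48,
                         experiments_per_study = c(1, 4),
                         comparisons_per_experiment = c(1, 3),
                         cell_effects = diversity_uncertainty_cells(),
                         tau2_study = 0.5,
                         tau2_genus = 0.02,
                         tau2_experiment = 0.05,
                         rho_experiment = 0.5,
                         control_mean = 10,
                         control_cv = 0.3,
                         n_per_group = c(8, 40),
                         shared_control_fraction = 0.3,
                         cell_probs = c(0.25, 0.25, 0.25, 0.25),
                         moderator_marginals = default_moderator_marginals(),
                         genus_dup_fraction = 0.1,
                         sampling_noise = TRUE,
                         seed = 1L) {
  cfg <- list(n_studies = n_studies,
              experiments_per_study = experiments_per_study,
              comparisons_per_experiment = comparisons_per_experiment,
              cell_effects = cell_effects,
              tau2_study = tau2_study, tau2_genus = tau2_genus,
              tau2_experiment = tau2_experiment,
              rho_experiment = rho_experiment,
              control_mean = control_mean, control_cv = control_cv,
              n_per_group = n_per_group,
              shared_control_fraction = shared_control_fraction,
              cell_probs = cell_probs,
              moderator_marginals = moderator_marginals,
              genus_dup_fraction = genus_dup_fraction,
              sampling_noise = sampling_noise,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("synth_config: invalid field '%s': %s", field, why),
         call. = FALSE)
  count_or_range <- function(x, field, min = 1) {
    if (!is.numeric(x) || !length(x) %in% 1:2 || any(x < min) ||
        any(x != floor(x)) || (length(x) == 2 && x[2] < x[1]))
      bad(field, "must be a count or an increasing integer range")
  }
  if (!is.numeric(cfg$n_studies) || cfg$n_studies < 1)
    bad("n_studies", "must be >= 1")
  count_or_range(cfg$experiments_per_study, "experiments_per_study")
  count_or_range(cfg$comparisons_per_experiment, "comparisons_per_experiment")
  count_or_range(cfg$n_per_group, "n_per_group", min = 2)
  for (f in c("tau2_study", "tau2_genus", "tau2_experiment"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) bad(f, "variance must be >= 0")
  if (abs(cfg$rho_experiment) > 1)
    bad("rho_experiment", "must lie in [-1, 1]")
  if (cfg$shared_control_fraction < 0 || cfg$shared_control_fraction > 1)
    bad("shared_control_fraction", "must lie in [0, 1]")
  if (cfg$control_mean <= 0 || cfg$control_cv <= 0)
    bad("control_mean/control_cv", "must be positive")
  ce <- cfg$cell_effects
  need <- c("host_range", "parasite_genetic_diversity", "smd", "lncvr")
  if (!is.data.frame(ce) || !all(need %in% names(ce)))
    bad("cell_effects", paste("needs columns", paste(need, collapse = ", ")))
  keys <- .cell_key(ce$host_range, ce$parasite_genetic_diversity)
  want <- .cell_key(rep(c("specialist", "generalist"), each = 2),
                    rep(c("high", "low"), 2))
  if (nrow(ce) != 4L || !setequal(keys, want) || anyDuplicated(keys))
    bad("cell_effects", "must cover each of the four 2x2 cells exactly once")
  if (length(cfg$cell_probs) != 4L || any(cfg$cell_probs < 0) ||
      abs(sum(cfg$cell_probs) - 1) > 1e-8)
    bad("cell_probs", "must be 4 probabilities summing to 1")
  ml <- moderator_levels()
  mm <- cfg$moderator_marginals
  for (m in names(mm)) {
    if (!m %in% names(ml)) bad("moderator_marginals", paste("unknown moderator", m))
    p <- mm[[m]]
    if (is.null(names(p)) || !all(names(p) %in% ml[[m]]) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-8)
      bad("moderator_marginals",
          paste0(m, ": named probabilities over its levels, summing to 1"))
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("synth_config: %d studies, tau2 (study/genus/experiment) = ",
                     "%.3g/%.3g/%.3g, rho = %.2g, seed = %d\n"),
              x$n_studies, x$tau2_study, x$tau2_genus, x$tau2_experiment,
              x$rho_experiment, x$seed))
  print(x$cell_effects, row.names = FALSE)
  invisible(x)
}

#' Default contextual-moderator marginals
#'
#' Category probabilities for the eight contextual moderators, loosely
#' reflecting the composition typical of host-parasite diversity experiments
#' (mostly invertebrate hosts, microparasites, lab and field roughly split).
#' @return Named list of named probability vectors.
#' @export
default_moderator_marginals <- function() {
  list(
    metric_of_success = c(prevalence = 0.40, load = 0.30, virulence = 0.25,
                          other = 0.05),
    host_type = c(invertebrate = 0.70, vertebrate = 0.30),
    parasite_type = c(microparasite = 0.75, macroparasite = 0.25),
    source_of_diversity = c(relatedness = 0.30, genotypes = 0.40,
                            natural = 0.30),
    scale_of_diversity = c(discrete = 0.60, continuous = 0.40),
    host_reproduction = c(sexual = 0.60, asexual = 0.15, mixed = 0.25),
    host_mortality = c(yes = 0.55, no = 0.45),
    laboratory = c(yes = 0.55, no = 0.45)
  )
}

#' Cell effects of the diversity-uncertainty scenario
#'
#' True effect signs follow the diversity-uncertainty reasoning for
#' matching-alleles-like specificity: higher host genetic diversity lowers
#' mean parasite success in every cell (all SMD <= 0), most strongly for
#' specialist (single-host) parasites; it lowers variability when parasite
#' genetic diversity is low but raises it when parasite diversity is high
#' (specialist cells), while generalist cells are attenuated to zero.
#' Magnitudes are illustrative and configurable.
#'
#' @return Data.frame of the four cells with `smd` and `lncvr` columns.
#' @export
diversity_uncertainty_cells <- function() {
  data.frame(
    host_range = c("specialist", "specialist", "generalist", "generalist"),
    parasite_genetic_diversity = c("low", "high", "low", "high"),
    smd = c(-0.54, -0.76, -0.42, -0.23),
    lncvr = c(-0.54, 0.61, 0.00, 0.00)
  )
}

#' Preset configuration encoding the diversity-uncertainty scenario
#'
#' Returns the default [synth_config()] whose cell effects follow the 2x2
#' diversity-uncertainty sign structure (see
#' [diversity_uncertainty_cells()]), with heterogeneity dominated by the
#' study level and only a small genus component.
#'
#' @param ... Overrides passed to [synth_config()] (e.g. `n_studies`,
#'   `seed`).
#' @return A `synth_config`.
#' @examples
#' cfg <- diversity_uncertainty_preset(seed = 7)
#' subset(cfg$cell_effects, host_range == "specialist")
#' @export
diversity_uncertainty_preset <- function(...) {
  synth_config(...)
}

.draw_count <- function(x, n) {
  if (length(x) == 1L) rep.int(as.integer(x), n)
  else sample(seq.int(x[1L], x[2L]), n, replace = TRUE)
}

.draw_cat <- function(p, n) {
  sample(names(p), n, replace = TRUE, prob = p)
}

# Observed summaries of a positive-valued metric: sample mean ~
# Normal(mu, sigma^2/n), sample SD ~ sigma * sqrt(ChiSq(n-1)/(n-1)),
# redrawn in the rare event of a non-positive mean (parasite-success
# summaries are positive by definition; the truncation mass is negligible
# at the default CV regime).
.sample_summary <- function(mu, sigma, n) {
  for (i in 1:1000) {
    m <- rnorm(1, mu, sigma / sqrt(n))
    if (m > 0) break
  }
  if (m <= 0) m <- mu * 1e-3
  c(m, sigma * sqrt(rchisq(1, n - 1) / (n - 1)))
}

# Solve mu_H for mu_H = mu_L + theta * s_pool(mu_H) with s_H = cv_H * mu_H,
# s_pool^2 = wL sd_L^2 + wH (cv_H mu_H)^2. Squaring gives the quadratic
# (1 - t^2 c2) mu^2 - 2 mu_L mu + (mu_L^2 - t^2 A) = 0 with A = wL sd_L^2,
# c2 = wH cv_H^2; the valid root has sign(mu - mu_L) = sign(theta) and
# mu > 0. Returns c(mu_H, sd_H, clamped); clamped flags the (rare) absence
# of a valid positive root at extreme effect/CV combinations.
.solve_high_group <- function(mu_L, sd_L, cv_H, theta, nL, nH) {
  wL <- (nL - 1) / (nH + nL - 2)
  wH <- (nH - 1) / (nH + nL - 2)
  A <- wL * sd_L^2
  c2 <- wH * cv_H^2
  if (theta == 0) return(c(mu_L, cv_H * mu_L, 0))
  t2 <- theta^2
  q <- 1 - t2 * c2
  D <- t2 * (c2 * mu_L^2 + A * q)
  mu <- NA_real_
  if (D >= 0 && abs(q) > 1e-12) {
    cand <- c(mu_L + sqrt(D), mu_L - sqrt(D)) / q
    ok <- cand > 0 & sign(cand - mu_L) == sign(theta)
    cand <- cand[ok]
    if (length(cand)) mu <- cand[which.min(abs(cand - mu_L))]
  } else if (D >= 0) {  # q == 0: linear case
    cand <- (mu_L^2 - t2 * A) / (2 * mu_L)
    if (cand > 0 && sign(cand - mu_L) == sign(theta)) mu <- cand
  }
  clamped <- is.na(mu)
  if (clamped) mu <- 0.02 * mu_L
  c(mu, cv_H * mu, clamped)
}

#' Generate a synthetic comparison table with known truth
#'
#' Draws a full hierarchical dataset under `config`: per-comparison true
#' effects are the cell effect plus study, genus and experiment-level random
#' deviations (experiment deviations compound-symmetric with correlation
#' `rho_experiment`); the low-diversity group has population mean
#' `control_mean` and CV `control_cv`; the high-diversity group's population
#' parameters are implied by the true SMD and lnCVR. Observed group summaries
#' are then sampled with the exact Gaussian sampling distributions, i.e.
#' sample mean ~ Normal(mu, sigma^2/n) and sample variance ~
#' sigma^2 ChiSq(n-1)/(n-1), which makes the analytic SMD/lnCVR sampling
#' variances exactly correct. Shared-control experiments reuse one observed
#' low-diversity summary across their comparisons and are tagged with a
#' `shared_control_key`.
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_dataset`: list with `comparisons` (the
#'   canonical comparison table, see [comparison_columns()]), `truth`
#'   (per-comparison realised true SMD/lnCVR and random-effect draws),
#'   `config` and `seed`. Regeneration from the same config is
#'   bit-identical.
#' @examples
#' d <- generate_dataset(synth_config(n_studies = 4, seed = 42))
#' head(d$comparisons)
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, {
    S <- config$n_studies
    ce <- config$cell_effects
    cell_of_study <- sample(nrow(ce), S, replace = TRUE,
                            prob = config$cell_probs)

    # genus map: default one genus per study, a fraction duplicated
    genus <- paste0("G", formatC(seq_len(S), width = 2, flag = "0"))
    if (S > 1 && config$genus_dup_fraction > 0) {
      dup <- which(runif(S) < config$genus_dup_fraction & seq_len(S) > 1)
      for (i in dup) genus[i] <- genus[sample.int(i - 1L, 1L)]
    }

    u_study <- matrix(rnorm(2 * S, 0, sqrt(config$tau2_study)), ncol = 2)
    gset <- unique(genus)
    u_genus <- matrix(rnorm(2 * length(gset), 0, sqrt(config$tau2_genus)),
                      ncol = 2, dimnames = list(gset, NULL))

    mods_study <- lapply(config$moderator_marginals, .draw_cat, n = S)
    n_exp <- .draw_count(config$experiments_per_study, S)

    # preallocated column vectors (grown geometrically if needed)
    cap <- sum(n_exp) * max(config$comparisons_per_experiment)
    chr <- function() character(cap); num <- function() numeric(cap)
    col_sid <- chr(); col_eid <- chr(); col_cid <- chr(); col_gen <- chr()
    col_mL <- num(); col_sL <- num(); col_nL <- num()
    col_mH <- num(); col_sH <- num(); col_nH <- num()
    col_metric <- chr(); col_key <- chr()
    col_cell_i <- integer(cap); col_study_i <- integer(cap)
    t_smd <- num(); t_cvr <- num(); t_ue_s <- num(); t_ue_c <- num()
    t_clamp <- logical(cap)
    ri <- 0L
    te <- config$tau2_experiment; rho <- config$rho_experiment
    for (s in seq_len(S)) {
      sid <- paste0("S", formatC(s, width = 2, flag = "0"))
      cell <- ce[cell_of_study[s], ]
      for (e in seq_len(n_exp[s])) {
        eid <- paste0(sid, ".E", e)
        m <- .draw_count(config$comparisons_per_experiment, 1L)
        shared <- m >= 2L && runif(1) < config$shared_control_fraction
        # compound-symmetric experiment deviations, one pair of shared
        # components per experiment plus idiosyncratic comparison parts
        # (generation supports rho in [0, 1]; negative rho has no such
        # decomposition)
        rho_g <- max(rho, 0)
        b_exp <- rnorm(2, 0, sqrt(rho_g * te))
        n_grp <- .draw_count(config$n_per_group, 1L)
        mu_L <- config$control_mean
        sd_L <- config$control_cv * mu_L
        if (shared) {
          if (config$sampling_noise) {
            o <- .sample_summary(mu_L, sd_L, n_grp)
            obs_mL <- o[1]; obs_sL <- o[2]
          } else { obs_mL <- mu_L; obs_sL <- sd_L }
        }
        for (cc in seq_len(m)) {
          cid <- paste0(eid, ".C", cc)
          idio <- rnorm(2, 0, sqrt((1 - rho_g) * te))
          dev_exp <- b_exp + idio
          th_smd <- cell$smd + u_study[s, 1] + u_genus[genus[s], 1] +
            dev_exp[1]
          th_cvr <- cell$lncvr + u_study[s, 2] + u_genus[genus[s], 2] +
            dev_exp[2]
          cv_H <- config$control_cv * exp(th_cvr)
          hg <- .solve_high_group(mu_L, sd_L, cv_H, th_smd, n_grp, n_grp)
          mu_H <- hg[1]; sd_H <- hg[2]
          sp <- sqrt(((n_grp - 1) * sd_H^2 + (n_grp - 1) * sd_L^2) /
                       (2 * n_grp - 2))
          true_smd <- (mu_H - mu_L) / sp
          true_cvr <- log((sd_H / mu_H) / (sd_L / mu_L))

          if (!shared) {
            if (config$sampling_noise) {
              o <- .sample_summary(mu_L, sd_L, n_grp)
              obs_mL <- o[1]; obs_sL <- o[2]
            } else { obs_mL <- mu_L; obs_sL <- sd_L }
          }
          if (config$sampling_noise) {
            o <- .sample_summary(mu_H, sd_H, n_grp)
            obs_mH <- o[1]; obs_sH <- o[2]
          } else { obs_mH <- mu_H; obs_sH <- sd_H }

          ri <- ri + 1L
          col_sid[ri] <- sid; col_eid[ri] <- eid; col_cid[ri] <- cid
          col_gen[ri] <- genus[s]
          col_mL[ri] <- obs_mL; col_sL[ri] <- obs_sL; col_nL[ri] <- n_grp
          col_mH[ri] <- obs_mH; col_sH[ri] <- obs_sH; col_nH[ri] <- n_grp
          col_metric[ri] <- .draw_cat(
            config$moderator_marginals$metric_of_success, 1L)
          col_key[ri] <- if (shared) eid else NA_character_
          col_cell_i[ri] <- cell_of_study[s]; col_study_i[ri] <- s
          t_smd[ri] <- true_smd; t_cvr[ri] <- true_cvr
          t_ue_s[ri] <- dev_exp[1]; t_ue_c[ri] <- dev_exp[2]
          t_clamp[ri] <- hg[3] > 0
        }
      }
    }
    idx <- seq_len(ri)
    si <- col_study_i[idx]; ci <- col_cell_i[idx]
    comparisons <- data.frame(
      study_id = col_sid[idx], experiment_id = col_eid[idx],
      comparison_id = col_cid[idx], host_genus = col_gen[idx],
      mean_low = col_mL[idx], sd_low = col_sL[idx], n_low = col_nL[idx],
      mean_high = col_mH[idx], sd_high = col_sH[idx], n_high = col_nH[idx],
      metric_of_success = col_metric[idx],
      host_type = mods_study$host_type[si],
      parasite_type = mods_study$parasite_type[si],
      source_of_diversity = mods_study$source_of_diversity[si],
      scale_of_diversity = mods_study$scale_of_diversity[si],
      host_reproduction = mods_study$host_reproduction[si],
      host_mortality = mods_study$host_mortality[si],
      laboratory = mods_study$laboratory[si],
      parasite_genetic_diversity = ce$parasite_genetic_diversity[ci],
      host_range = ce$host_range[ci],
      shared_control_key = col_key[idx],
      stringsAsFactors = FALSE)
    truth <- data.frame(
      comparison_id = col_cid[idx], study_id = col_sid[idx],
      experiment_id = col_eid[idx],
      cell = .cell_key(ce$host_range[ci], ce$parasite_genetic_diversity[ci]),
      cell_smd = ce$smd[ci], cell_lncvr = ce$lncvr[ci],
      true_smd = t_smd[idx], true_lncvr = t_cvr[idx],
      u_study_smd = u_study[si, 1], u_study_lncvr = u_study[si, 2],
      u_genus_smd = u_genus[col_gen[idx], 1],
      u_genus_lncvr = u_genus[col_gen[idx], 2],
      u_exp_smd = t_ue_s[idx], u_exp_lncvr = t_ue_c[idx],
      clamped = t_clamp[idx], stringsAsFactors = FALSE)
    structure(list(comparisons = comparisons, truth = truth,
                   config = config, seed = config$seed),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("synth_dataset: %d comparisons, %d experiments, %d studies (seed %d)\n",
              nrow(x$comparisons), length(unique(x$comparisons$experiment_id)),
              length(unique(x$comparisons$study_id)), x$seed))
  invisible(x)
}

#' Generate replicate-level raw observations
#'
#' Emits per-population replicate observations of a parasite-success metric
#' plus a continuous diversity score per population, suitable as input to the
#' harmonisation stage ([summarise_replicates()] then
#' [dichotomise_continuous()]). Replicates are Normal for continuous metrics,
#' scaled Binomial for proportions, Poisson for counts; the metric trends
#' with the diversity score at rate `trend` (on the link scale).
#'
#' @param config A [synth_config()] (supplies `control_mean`, `control_cv`
#'   and the seed).
#' @param metric_kind `"continuous"`, `"proportion"` or `"count"`.
#' @param n_populations Number of host populations.
#' @param replicates_per_population Replicate observations per population;
#'   defaults to the config's `n_per_group`.
#' @param trend Slope of the metric against the (0, 1) diversity score:
#'   identity scale for continuous, logit for proportions, log for counts.
#' @param prob Baseline proportion (proportion kind).
#' @param trials Binomial denominator per replicate (proportion kind).
#' @param lambda Baseline Poisson mean (count kind).
#' @return Data.frame with columns `population_id`, `diversity_score`,
#'   `replicate`, `value`, `metric_kind`.
#' @export
generate_replicates <- function(config,
                                metric_kind = c("continuous", "proportion",
                                                "count"),
                                n_populations = 10,
                                replicates_per_population = NULL,
                                trend = 0, prob = 0.5, trials = 20,
                                lambda = 4) {
  metric_kind <- match.arg(metric_kind)
  validate_synth_config(config)
  if (is.null(replicates_per_population))
    replicates_per_population <- max(config$n_per_group)
  R <- replicates_per_population
  with_seed(config$seed, {
    score <- runif(n_populations)
    rows <- lapply(seq_len(n_populations), function(i) {
      value <- switch(metric_kind,
        continuous = rnorm(R, config$control_mean * (1 + trend * score[i]),
                           config$control_cv * config$control_mean),
        proportion = {
          p <- if (prob <= 0) 0 else if (prob >= 1) 1 else
            stats::plogis(stats::qlogis(prob) + trend * score[i])
          rbinom(R, trials, p) / trials
        },
        count = rpois(R, lambda * exp(trend * score[i])))
      data.frame(population_id = sprintf("P%03d", i),
                 diversity_score = score[i],
                 replicate = seq_len(R), value = value,
                 metric_kind = metric_kind, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
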