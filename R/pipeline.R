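#' Read and validate a canonical comparison table
#'
#' Reads the comparison-table CSV (schema in [comparison_columns()]),
#' validating every row: numeric group summaries, sd >= 0, n >= 1, moderator
#' values from the closed vocabularies. All row-level problems are collected
#' and reported together with their line numbers; nothing is silently
#' dropped. Unknown extra columns are preserved as passthrough.
#'
#' @param path CSV file path.
#' @return Validated data.frame of comparison records.
#' @export
read_comparisons <- function(path) {
  if (!file.exists(path)) stop("read_comparisons: no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(comparison_columns(), "shared_control_key")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("read_comparisons: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"shared_control_key" %in% names(df))
    df$shared_control_key <- NA_character_
  df$shared_control_key <- as.character(df$shared_control_key)

  errs <- character(0)
  note <- function(row, msg)
    errs <<- c(errs, sprintf("row %d: %s", row, msg))
  for (cl in .numeric_columns) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(v))
    for (r in bad) note(r, paste0("non-numeric ", cl, " ('", df[[cl]][r], "')"))
    df[[cl]] <- v
  }
  for (r in seq_len(nrow(df))) {
    if (is.finite(df$sd_low[r]) && df$sd_low[r] < 0) note(r, "sd_low < 0")
    if (is.finite(df$sd_high[r]) && df$sd_high[r] < 0) note(r, "sd_high < 0")
    if (is.finite(df$n_low[r]) && df$n_low[r] < 1) note(r, "n_low < 1")
    if (is.finite(df$n_high[r]) && df$n_high[r] < 1) note(r, "n_high < 1")
  }
  ml <- moderator_levels()
  for (m in names(ml)) {
    bad <- which(!df[[m]] %in% ml[[m]])
    for (r in bad)
      note(r, sprintf("unknown %s level '%s'", m, df[[m]][r]))
  }
  if (length(errs))
    stop("read_comparisons: validation failed:\n  ",
         paste(errs, collapse = "\n  "))
  df
}

#' Write a comparison table / effects table / VCV to CSV
#'
#' `write_comparisons()` and `write_effects()` write plain CSVs;
#' `write_vcv()` writes the sampling VCV as a labelled square CSV.
#'
#' @param records,effects,vcv Objects to write.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_comparisons <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparisons
#' @export
write_effects <- function(effects, path) {
  write.csv(effects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparisons
#' @export
write_vcv <- function(vcv, path) {
  m <- if (inherits(vcv, "sampling_vcv")) vcv$matrix else as.matrix(vcv)
  write.csv(data.frame(comparison_id = rownames(m), m,
                       check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param input A [synth_config()] (synthetic run) or a path to a canonical
#'   comparison-table CSV.
#' @param kinds Effect kinds to analyse.
#' @param vcv_mode,vcv_r Shared-control VCV construction ([build_vcv()]).
#' @param moderators Moderators for the single-moderator analyses (default:
#'   the eight contextual moderators).
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @param seed Integer seed (overrides the synth config's seed if given).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = diversity_uncertainty_preset(),
                       kinds = c("SMD", "lnCVR"),
                       vcv_mode = "fixed_r", vcv_r = 0.5,
                       moderators = setdiff(names(moderator_levels()),
                                            c("parasite_genetic_diversity",
                                              "host_range")),
                       output_dir = NULL, seed = NULL) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (!inherits(input, "synth_config") &&
      !(is.character(input) && length(input) == 1L))
    stop("run_config: input must be a synth_config or a CSV path")
  unknown <- setdiff(moderators, names(moderator_levels()))
  if (length(unknown))
    stop("run_config: unknown moderator(s): ", paste(unknown, collapse = ", "))
  structure(list(input = input, kinds = kinds, vcv_mode = vcv_mode,
                 vcv_r = vcv_r, moderators = moderators,
                 output_dir = output_dir, seed = seed),
            class = "run_config")
}

.fit_to_list <- function(fit) {
  list(coefficients = data.frame(term = names(fit$beta),
                                 estimate = unname(fit$beta),
                                 se = unname(fit$se),
                                 zval = unname(fit$zval),
                                 pval = unname(fit$pval),
                                 ci.lb = unname(fit$ci.lb),
                                 ci.ub = unname(fit$ci.ub)),
       tau2 = as.list(fit$tau2), rho_exp = fit$rho_exp,
       i2 = as.list(fit$i2), k = fit$k, loglik_reml = fit$loglik_reml)
}

# cell-mean contrasts for the parasite-diversity x host-range interaction
.rq2_contrasts <- function(fit) {
  nm <- names(fit$beta)
  pick <- function(hr, pd) {
    i <- which(grepl(hr, nm, fixed = TRUE) & grepl(pd, nm, fixed = TRUE))
    if (length(i) != 1L) return(NA_integer_)
    i
  }
  idx <- c(sl = pick("specialist", "low"), sh = pick("specialist", "high"),
           gl = pick("generalist", "low"), gh = pick("generalist", "high"))
  if (anyNA(idx)) {
    warning("rq2: incomplete cell structure; contrasts skipped")
    return(NULL)
  }
  unit <- function(i) replace(numeric(fit$p), i, 1)
  L <- rbind(
    (unit(idx["sl"]) + unit(idx["sh"])) / 2 -
      (unit(idx["gl"]) + unit(idx["gh"])) / 2,
    unit(idx["sh"]) - unit(idx["sl"]),
    unit(idx["gh"]) - unit(idx["gl"]))
  contrast_family(fit, L, labels = c(
    "specialist - generalist (mean over parasite diversity)",
    "specialist: high - low parasite diversity",
    "generalist: high - low parasite diversity"))
}

# single-moderator fit: cell means per level + all pairwise contrasts (Holm)
.rq3_one <- function(effects, vcv, kind, moderator, random) {
  lev <- unique(effects[[moderator]])
  if (length(lev) < 2L) {
    warning("rq3: moderator '", moderator,
            "' has a single observed level; contrasts skipped")
    return(NULL)
  }
  f <- stats::as.formula(paste0("~ 0 + ", moderator))
  fit <- fit_reml(effects, vcv = vcv,
                  spec = meta_spec(kind, f, random = random))
  pairs <- utils::combn(seq_len(fit$p), 2L)
  L <- t(apply(pairs, 2L, function(ij)
    replace(replace(numeric(fit$p), ij[1L], 1), ij[2L], -1)))
  labels <- apply(pairs, 2L, function(ij)
    paste(names(fit$beta)[ij[1L]], "-", names(fit$beta)[ij[2L]]))
  list(fit = .fit_to_list(fit),
       qm = qm_test(fit, L = t(apply(pairs[, seq_len(fit$p - 1L),
                                           drop = FALSE], 2L, function(ij)
         replace(replace(numeric(fit$p), ij[1L], 1), ij[2L], -1)))),
       contrasts = contrast_family(fit, L, labels))
}

# orchard-style plot-ready table: per-effect points scaled by inverse SE,
# plus model means, CIs and prediction intervals per coefficient
.orchard_table <- function(effects, fit) {
  pts <- data.frame(comparison_id = effects$comparison_id,
                    study_id = effects$study_id,
                    yi = effects$yi, se = sqrt(effects$vi),
                    point_scale = 1 / sqrt(effects$vi))
  pis <- t(vapply(seq_len(fit$p), function(i) prediction_interval(fit, i),
                  numeric(2)))
  means <- data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                      ci.lb = unname(fit$ci.lb), ci.ub = unname(fit$ci.ub),
                      pi.lb = pis[, 1L], pi.ub = pis[, 2L],
                      k = fit$k)
  list(points = pts, means = means)
}

#' Run the full meta-analysis pipeline
#'
#' Chains the stages: obtain the comparison table (synthetic generation or
#' CSV), compute SMD/lnCVR effect sizes with the log-safety offset, build
#' shared-control sampling VCVs, and fit, per effect kind:
#' \describe{
#'   \item{rq1}{the overall effect (intercept-only multilevel model) with
#'     I-squared decomposition and prediction interval;}
#'   \item{rq2}{the parasite-genetic-diversity x host-range cell-means model
#'     with both directional contrast families (specialist vs generalist;
#'     high vs low parasite diversity within host range), Holm-adjusted;}
#'   \item{rq3}{each contextual moderator singly (cell means, omnibus QM,
#'     all pairwise Holm-adjusted contrasts);}
#'   \item{bias}{funnel table and effect-SE association;}
#'   \item{loo}{leave-one-study-out and leave-one-set-out sensitivity
#'     summaries;}
#' } plus the parasite-diversity x laboratory collinearity cross-tab and a
#' run manifest. If `output_dir` is set, CSV/JSON outputs and the manifest
#' are written there; outputs are regenerable bit-identically from the
#' manifest (seeded generation, deterministic fits).
#'
#' @param config A [run_config()].
#' @return A result bundle (list) with components `data`, `truth` (synthetic
#'   runs), per-kind `effects`, `vcv`, `rq1`, `rq2`, `rq3`, `bias`, `loo`,
#'   `orchard`, plus `collinearity` and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  bundle <- list()
  res <- try({
    if (inherits(config$input, "synth_config")) {
      sc <- config$input
      if (!is.null(config$seed)) sc$seed <- as.integer(config$seed)
      ds <- generate_dataset(sc)
      records <- ds$comparisons
      bundle$truth <- ds$truth
      input_desc <- sprintf("synthetic (seed %d)", sc$seed)
    } else {
      records <- read_comparisons(config$input)
      input_desc <- config$input
    }
    bundle$data <- records

    rand <- names(.level_column)[vapply(.level_column, `%in%`,
                                        logical(1), names(records))]
    for (kind in config$kinds) {
      stage <- paste0("effects/", kind)
      es <- compute_effects(records, kind = kind)
      vcv <- build_vcv(es, mode = config$vcv_mode, r = config$vcv_r)
      bundle$effects[[kind]] <- es
      bundle$vcv[[kind]] <- vcv

      stage <- paste0("rq1/", kind)
      fit1 <- fit_reml(es, vcv = vcv, spec = meta_spec(kind, ~1, rand))
      bundle$rq1[[kind]] <- c(.fit_to_list(fit1),
                              list(prediction_interval =
                                     as.list(prediction_interval(fit1))))
      bundle$orchard[[kind]] <- .orchard_table(es, fit1)

      stage <- paste0("rq2/", kind)
      f2 <- ~ 0 + host_range:parasite_genetic_diversity
      fit2 <- fit_reml(es, vcv = vcv, spec = meta_spec(kind, f2, rand))
      bundle$rq2[[kind]] <- list(fit = .fit_to_list(fit2),
                                 contrasts = .rq2_contrasts(fit2))

      stage <- paste0("rq3/", kind)
      bundle$rq3[[kind]] <- lapply(
        setNames(config$moderators, config$moderators),
        function(m) .rq3_one(es, vcv, kind, m, rand))

      stage <- paste0("bias/", kind)
      bundle$bias[[kind]] <- list(
        egger = egger_association(es),
        funnel = funnel_table(es, fit1))

      stage <- paste0("loo/", kind)
      spec1 <- meta_spec(kind, ~1, rand)
      bundle$loo[[kind]] <- list(
        study = leave_one_out(es, vcv, spec1, unit = "study"),
        set = leave_one_out(es, vcv, spec1, unit = "comparison_set"))
    }

    stage <- "collinearity"
    bundle$collinearity <- collinearity_crosstab(
      bundle$effects[[1L]], "parasite_genetic_diversity", "laboratory")

    stage <- "manifest"
    bundle$manifest <- list(
      package = "divmeta",
      version = as.character(utils::packageVersion("divmeta")),
      input = input_desc,
      seed = if (!is.null(config$seed)) config$seed
             else if (inherits(config$input, "synth_config"))
               config$input$seed else NA,
      kinds = config$kinds, vcv_mode = config$vcv_mode, vcv_r = config$vcv_r,
      n_comparisons = nrow(records),
      n_studies = length(unique(records$study_id)),
      input_checksum = .data_checksum(records))
    NULL
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("run_pipeline: stage '", stage, "' failed: ",
         attr(res, "condition")$message, call. = FALSE)

  if (!is.null(config$output_dir)) .write_bundle(bundle, config$output_dir)
  bundle
}

.data_checksum <- function(records) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(records, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_comparisons(bundle$data, file.path(dir, "comparisons.csv"))
  if (!is.null(bundle$truth))
    write.csv(bundle$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  for (kind in names(bundle$effects)) {
    write_effects(bundle$effects[[kind]],
                  file.path(dir, paste0("effects_", kind, ".csv")))
    write_vcv(bundle$vcv[[kind]], file.path(dir, paste0("vcv_", kind, ".csv")))
    write.csv(bundle$loo[[kind]]$study$iterations,
              file.path(dir, paste0("loo_study_", kind, ".csv")),
              row.names = FALSE)
    loo_avg <- rbind(bundle$loo[[kind]]$study$averaged,
                     bundle$loo[[kind]]$set$averaged)
    write.csv(loo_avg, file.path(dir, paste0("loo_summary_", kind, ".csv")),
              row.names = FALSE)
    write.csv(bundle$orchard[[kind]]$points,
              file.path(dir, paste0("orchard_points_", kind, ".csv")),
              row.names = FALSE)
    write.csv(bundle$orchard[[kind]]$means,
              file.path(dir, paste0("orchard_means_", kind, ".csv")),
              row.names = FALSE)
  }
  for (part in c("rq1", "rq2", "rq3", "bias")) {
    jsonlite::write_json(bundle[[part]],
                         file.path(dir, paste0(part, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
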