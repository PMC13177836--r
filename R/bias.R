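#' Effect-size / standard-error association (publication-bias check)
#'
#' Small-study (publication-bias) diagnostic reported as a correlation: the
#' Pearson correlation between effect values and their standard errors, with
#' Fisher-z 95% confidence interval and two-sided p-value. A classical
#' weighted Egger regression (standardised effect on precision; bias = the
#' intercept) is available via `method = "regression"`.
#'
#' @param effects Effects data.frame with `yi`, `vi` (single kind).
#' @param method `"correlation"` (default) or `"regression"`.
#' @return For `"correlation"`: list with `r`, `ci` (length 2), `pval`, `k`.
#'   For `"regression"`: list with `intercept`, `se`, `zval`, `pval`, `k`.
#' @export
egger_association <- function(effects, method = c("correlation",
                                                  "regression")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(effects), all(c("yi", "vi") %in% names(effects)))
  yi <- effects$yi
  sei <- sqrt(effects$vi)
  k <- length(yi)
  if (k < 4L) stop("egger_association: need at least 4 effects")
  if (stats::sd(sei) == 0)
    stop("egger_association: standard errors are constant; ",
         "association undefined")
  if (method == "correlation") {
    if (stats::sd(yi) == 0)  # constant effects: no association by definition
      return(list(r = 0, ci = c(NA_real_, NA_real_), pval = 1, k = k))
    ct <- cor.test(yi, sei, method = "pearson")
    list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
         pval = ct$p.value, k = k)
  } else {
    prec <- 1 / sei
    fit <- stats::lm(I(yi / sei) ~ prec)
    sm <- summary(fit)$coefficients
    list(intercept = sm[1, 1], se = sm[1, 2],
         zval = sm[1, 1] / sm[1, 2],
         pval = 2 * pnorm(-abs(sm[1, 1] / sm[1, 2])), k = k)
  }
}

#' Funnel-plot table
#'
#' Plot-ready table of effects against their precision: one row per effect
#' with its standard error (plotted inverted by convention, captured by the
#' `se_rank` ordering column), plus the model mean and 95% CI of an
#' intercept-only fit so any front-end can draw the funnel.
#'
#' @param effects Effects data.frame (single kind).
#' @param fit Optional intercept-only [fit_reml()] on the same data; fitted
#'   here (with whatever random-effect columns are available) if omitted.
#' @return Data.frame with columns `comparison_id` (if present), `yi`, `se`,
#'   `se_rank`, `model_mean`, `ci.lb`, `ci.ub`. Empty input gives an empty
#'   table.
#' @export
funnel_table <- function(effects, fit = NULL) {
  if (is.null(effects) || nrow(effects) == 0L) {
    return(data.frame(yi = numeric(0), se = numeric(0),
                      se_rank = integer(0), model_mean = numeric(0),
                      ci.lb = numeric(0), ci.ub = numeric(0)))
  }
  if (is.null(fit)) {
    rand <- names(.level_column)[vapply(.level_column, `%in%`,
                                        logical(1), names(effects))]
    kind <- if ("kind" %in% names(effects)) effects$kind[1L] else "SMD"
    fit <- fit_reml(effects,
                    spec = meta_spec(kind, ~1, random = rand))
  }
  se <- sqrt(effects$vi)
  out <- data.frame(yi = effects$yi, se = se,
                    se_rank = rank(-se, ties.method = "first"),
                    model_mean = unname(fit$beta[1L]),
                    ci.lb = unname(fit$ci.lb[1L]),
                    ci.ub = unname(fit$ci.ub[1L]))
  if ("comparison_id" %in% names(effects))
    out <- cbind(comparison_id = effects$comparison_id, out)
  out
}

# independent-comparison-set membership: effects sharing a low-diversity
# control group form one set; others are their own set
.comparison_sets <- function(effects) {
  key <- if ("shared_control_key" %in% names(effects))
    as.character(effects$shared_control_key) else rep(NA_character_,
                                                      nrow(effects))
  ifelse(!is.na(key) & key != "", paste0("set:", key),
         paste0("cmp:", as.character(effects$comparison_id)))
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the model with one unit omitted at a time — either one study or
#' one set of independent comparisons (high-diversity groups sharing a
#' low-diversity control group count as a single set) — and summarises the
#' focal coefficient across iterations by unweighted arithmetic means of
#' estimate, SE, z, p and CI bounds (a precision-weighted mean estimate is
#' exported alongside).
#'
#' @param effects Effects data.frame (single kind).
#' @param vcv Optional sampling VCV for the full data; subset per iteration.
#' @param spec A [meta_spec()] (typically intercept-only).
#' @param unit `"study"` or `"comparison_set"`.
#' @param coef_index Coefficient summarised across refits (default 1, the
#'   intercept).
#' @return Object of class `loo_result`: `iterations` (one row per omitted
#'   unit; failed refits carry NA and are flagged), `averaged` (one-row
#'   summary with columns Method, ES, Estimate, SE, z, p, ci.lb, ci.ub plus
#'   `Estimate_wtd`), `unit`.
#' @export
leave_one_out <- function(effects, vcv = NULL, spec = meta_spec(),
                          unit = c("study", "comparison_set"),
                          coef_index = 1L) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(effects))
  grp <- if (unit == "study") as.character(effects$study_id)
         else .comparison_sets(effects)
  units <- unique(grp)
  if (length(units) < 3L)
    stop("leave_one_out: need at least 3 distinct units")
  Vfull <- if (is.null(vcv)) NULL
           else if (inherits(vcv, "sampling_vcv")) vcv$matrix else as.matrix(vcv)

  rows <- lapply(units, function(u) {
    keep <- grp != u
    sub <- effects[keep, , drop = FALSE]
    Vsub <- if (is.null(Vfull)) NULL else Vfull[keep, keep, drop = FALSE]
    fit <- tryCatch(fit_reml(sub, vcv = Vsub, spec = spec),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("leave_one_out: refit failed omitting '", u, "': ",
              conditionMessage(fit))
      return(data.frame(omitted = u, k = sum(keep), estimate = NA_real_,
                        se = NA_real_, zval = NA_real_, pval = NA_real_,
                        ci.lb = NA_real_, ci.ub = NA_real_, failed = TRUE))
    }
    i <- coef_index
    data.frame(omitted = u, k = sum(keep),
               estimate = unname(fit$beta[i]), se = unname(fit$se[i]),
               zval = unname(fit$zval[i]), pval = unname(fit$pval[i]),
               ci.lb = unname(fit$ci.lb[i]), ci.ub = unname(fit$ci.ub[i]),
               failed = FALSE)
  })
  iters <- do.call(rbind, rows)
  ok <- iters[!iters$failed, , drop = FALSE]
  if (nrow(ok) == 0L) stop("leave_one_out: every refit failed")
  method <- if (unit == "study") "Leave1studyout" else "Leave1setout"
  averaged <- data.frame(
    Method = method,
    ES = spec$effect_kind,
    Estimate = mean(ok$estimate), SE = mean(ok$se), z = mean(ok$zval),
    p = mean(ok$pval), ci.lb = mean(ok$ci.lb), ci.ub = mean(ok$ci.ub),
    Estimate_wtd = sum(ok$estimate / ok$se^2) / sum(1 / ok$se^2))
  structure(list(iterations = iters, averaged = averaged, unit = unit),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out (%s): %d iterations (%d failed)\n",
              x$unit, nrow(x$iterations), sum(x$iterations$failed)))
  print(round(x$averaged[, c("Estimate", "SE", "z", "p", "ci.lb", "ci.ub")],
              4), row.names = FALSE)
  invisible(x)
}
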