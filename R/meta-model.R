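#' Specification of a multilevel meta-regression model
#'
#' @param effect_kind `"SMD"` or `"lnCVR"` (which effect sizes the model is
#'   fitted to; mean and variability are analysed in separate models).
#' @param fixed One-sided formula for the fixed (moderator) part, e.g. `~ 1`
#'   (overall effect), `~ 0 + parasite_genetic_diversity:host_range` (cell
#'   means), `~ 0 + parasite_type`.
#' @param random Character vector of random-effect levels, a subset of
#'   `c("study", "genus", "experiment")`. Study and genus are exchangeable
#'   intercepts; the experiment level is compound-symmetric across the
#'   comparisons of an experiment with estimated correlation `rho`.
#' @param vcv_mode,vcv_r Shared-control VCV construction to use when the
#'   pipeline builds the sampling covariance (see [build_vcv()]).
#' @return An object of class `meta_spec`.
#' @export
meta_spec <- function(effect_kind = c("SMD", "lnCVR"), fixed = ~1,
                      random = c("study", "genus", "experiment"),
                      vcv_mode = "fixed_r", vcv_r = 0.5) {
  effect_kind <- match.arg(effect_kind)
  stopifnot(inherits(fixed, "formula"))
  if (length(random))
    random <- match.arg(random, c("study", "genus", "experiment"),
                        several.ok = TRUE)
  structure(list(effect_kind = effect_kind, fixed = fixed, random = random,
                 vcv_mode = vcv_mode, vcv_r = vcv_r),
            class = "meta_spec")
}

.level_column <- c(study = "study_id", genus = "host_genus",
                   experiment = "experiment_id")

# connected components of the grouping structure (union-find); two effects
# are linked if they share any active random-effect level or a nonzero
# sampling covariance.
.residual_components <- function(factors, V) {
  k <- nrow(V)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (f in factors) {
    for (idx in split(seq_len(k), f)) {
      if (length(idx) > 1L) for (j in idx[-1L]) unite(idx[1L], j)
    }
  }
  nz <- which(V != 0 & row(V) < col(V), arr.ind = TRUE)
  if (nrow(nz)) for (r in seq_len(nrow(nz))) unite(nz[r, 1L], nz[r, 2L])
  comp <- vapply(seq_len(k), find, integer(1))
  split(seq_len(k), comp)
}

.same_matrix <- function(f, idx) {
  fi <- f[idx]
  outer(fi, fi, `==`) * 1
}

#' Fit a multilevel random-effects meta-regression by REML
#'
#' Maximises the restricted log-likelihood
#' \deqn{\ell_R = -\tfrac12\left[\ln|\Sigma| + \ln|X'\Sigma^{-1}X|
#'   + r'\Sigma^{-1}r\right] + \mathrm{const},}
#' with marginal covariance
#' \eqn{\Sigma = V + \tau^2_{study} Z_s Z_s' + \tau^2_{genus} Z_g Z_g' +
#' \tau^2_{exp}[(1-\rho)I + \rho Z_e Z_e']}: the sampling (co)variance plus
#' exchangeable study and host-genus intercepts and compound-symmetric
#' experiment-level effects. Variance components are bounded below at zero
#' (log-scale search), \eqn{\rho \in [0, 0.999]}; optimisation uses a
#' bounded quasi-Newton method from several dispersed starts, and the
#' returned fit carries the gradient norm at the solution. Fixed-effect
#' inference is Wald-normal (z), matching standard meta-analytic practice.
#' With `random = character(0)` the fit reduces exactly to generalised least
#' squares (inverse-variance weighting).
#'
#' @param effects Effects data.frame from [compute_effects()] (single kind),
#'   with columns `yi`, `vi`, identifiers and moderators.
#' @param vcv Optional [build_vcv()] result (or plain matrix) giving the
#'   sampling VCV; defaults to `diag(vi)`.
#' @param spec A [meta_spec()].
#' @param n_starts Number of dispersed optimisation starts (>= 1).
#' @param rho_fixed Optionally fix the experiment-level correlation instead
#'   of estimating it.
#' @return An object of class `meta_fit` with elements `beta`, `se`, `zval`,
#'   `pval`, `ci.lb`, `ci.ub`, `cov_beta`, `tau2` (named per level),
#'   `rho_exp`, `k`, `p`, `loglik_reml`, `i2` (multilevel I-squared, percent),
#'   `conv` (convergence diagnostics), and the data needed by downstream
#'   operations.
#' @examples
#' d <- generate_dataset(synth_config(n_studies = 8, seed = 1))
#' es <- compute_effects(d$comparisons, kind = "SMD")
#' fit <- fit_reml(es, spec = meta_spec("SMD", ~1, random = "study"))
#' fit
#' @export
fit_reml <- function(effects, vcv = NULL, spec = meta_spec(),
                     n_starts = 5, rho_fixed = NULL) {
  stopifnot(is.data.frame(effects), all(c("yi", "vi") %in% names(effects)))
  if ("kind" %in% names(effects) && length(unique(effects$kind)) > 1L)
    stop("fit_reml: effects must be of a single kind; filter first")
  y <- effects$yi
  k <- length(y)

  X <- stats::model.matrix(spec$fixed, data = effects)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("fit_reml: rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  # variance components need residual degrees of freedom; pure GLS does not
  k_min <- if (length(spec$random)) p + 1L else p
  if (k < k_min)
    stop("fit_reml: need at least ", k_min, " effects (k = ", k,
         ") for ", p, " coefficient(s)")

  if (is.null(vcv)) {
    V <- diag(effects$vi, k, k)
  } else {
    Vm <- if (inherits(vcv, "sampling_vcv")) vcv$matrix else as.matrix(vcv)
    ord <- if (inherits(vcv, "sampling_vcv")) vcv$ordering else rownames(Vm)
    if (!is.null(ord) && "comparison_id" %in% names(effects)) {
      m <- match(as.character(effects$comparison_id), ord)
      if (anyNA(m)) stop("fit_reml: vcv ordering does not cover all effects")
      V <- Vm[m, m, drop = FALSE]
    } else V <- Vm
    if (nrow(V) != k) stop("fit_reml: vcv dimension mismatch")
  }

  active <- spec$random
  fac <- list()
  for (lev in active) {
    col <- .level_column[[lev]]
    if (!col %in% names(effects))
      stop("fit_reml: random level '", lev, "' needs column '", col, "'")
    fac[[lev]] <- as.character(effects[[col]])
  }

  if (length(active) == 0L) {
    # pure GLS: closed form, no variance components
    return(.finish_fit(y, X, V, list(), effects, spec,
                       tau2 = c(study = 0, genus = 0, experiment = 0),
                       rho = 0,
                       conv = list(converged = TRUE, gradient_norm = 0,
                                   n_starts = 0L)))
  }

  comps <- .residual_components(fac, V)
  blocks <- lapply(comps, function(idx) {
    list(V = V[idx, idx, drop = FALSE],
         X = X[idx, , drop = FALSE],
         y = y[idx],
         Ms = if ("study" %in% active) .same_matrix(fac$study, idx)
              else matrix(0, length(idx), length(idx)),
         Mg = if ("genus" %in% active) .same_matrix(fac$genus, idx)
              else matrix(0, length(idx), length(idx)),
         Me = if ("experiment" %in% active) .same_matrix(fac$experiment, idx)
              else matrix(0, length(idx), length(idx)))
  })

  est_rho <- "experiment" %in% active && is.null(rho_fixed) &&
    any(table(fac$experiment) >= 2L)
  rho0 <- if (!is.null(rho_fixed)) rho_fixed else 0

  # parameter vector: log tau2 per active level (+ logit-scaled rho)
  par_levels <- active
  np <- length(par_levels)
  tr_rho <- function(z) 0.999 * stats::plogis(z)

  unpack <- function(par) {
    t2 <- c(study = 0, genus = 0, experiment = 0)
    t2[par_levels] <- exp(par[seq_len(np)])
    rho <- if (est_rho) tr_rho(par[np + 1L]) else rho0
    list(tau2 = t2, rho = rho)
  }
  objective <- function(par) {
    u <- unpack(par)
    reml_eval_cpp(blocks, u$tau2[["study"]], u$tau2[["genus"]],
                  u$tau2[["experiment"]], u$rho, p, FALSE)$nll
  }

  # method-of-moments total heterogeneity for the starting values
  w <- 1 / effects$vi
  bw <- qr.coef(qr(sqrt(w) * X), sqrt(w) * y)
  Q <- sum(w * (y - drop(X %*% bw))^2)
  t2_tot <- max((Q - (k - p)) / (sum(w) - sum(w^2) / sum(w)), 0.01)
  share <- c(study = 0.7, genus = 0.1, experiment = 0.2)[par_levels]
  share <- share / sum(share)
  base <- log(t2_tot * share + 1e-4)
  disperse <- list(0, -2, 2, -4, c(1, -1, 1, -1)[seq_len(np)] * 2)
  lower <- c(rep(log(1e-12), np), if (est_rho) -8)
  upper <- c(rep(log(1e4), np), if (est_rho) 8)

  best <- NULL
  n_confirm <- 0L
  for (s in seq_len(max(1L, n_starts))) {
    d <- disperse[[((s - 1L) %% length(disperse)) + 1L]]
    start <- c(base + d, if (est_rho) 0)
    opt <- tryCatch(
      nlminb(start, objective, lower = lower, upper = upper,
             control = list(iter.max = 500, eval.max = 1000,
                            rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (!is.null(best) && abs(opt$objective - best$objective) < 1e-6)
      n_confirm <- n_confirm + 1L
    if (is.null(best) || opt$objective < best$objective) best <- opt
    if (n_confirm >= 1L) break  # two starts agree on the optimum
  }
  if (is.null(best))
    stop("fit_reml: optimisation failed from every start")

  # numerical gradient at the solution (interior parameters only); the
  # finite-difference noise floor on this objective is ~1e-4, so formal
  # convergence is nlminb's objective-change criterion, with the gradient
  # norm reported as a diagnostic
  gr <- vapply(seq_along(best$par), function(i) {
    h <- 1e-4
    ei <- replace(numeric(length(best$par)), i, h)
    (objective(best$par + ei) - objective(best$par - ei)) / (2 * h)
  }, numeric(1))
  at_bound <- best$par <= lower + 1e-8 | best$par >= upper - 1e-8
  grad_norm <- sqrt(sum(gr[!at_bound]^2))
  converged <- best$convergence == 0 || grad_norm < 1e-3
  if (!converged)
    warning("fit_reml: optimiser did not formally converge ",
            "(gradient norm ", format(grad_norm), "); ",
            "reporting the best candidate")

  u <- unpack(best$par)
  tau2 <- u$tau2
  tau2[tau2 < 1e-8] <- 0
  .finish_fit(y, X, V, blocks, effects, spec, tau2 = tau2,
              rho = if (est_rho) u$rho else if ("experiment" %in% active)
                rho0 else NA_real_,
              conv = list(converged = converged, gradient_norm = grad_norm,
                          n_starts = max(1L, n_starts),
                          objective = best$objective))
}

.finish_fit <- function(y, X, V, blocks, effects, spec, tau2, rho, conv) {
  k <- length(y); p <- ncol(X)
  if (length(blocks) == 0L) {
    blocks <- list(list(V = V, X = X, y = y,
                        Ms = matrix(0, k, k), Mg = matrix(0, k, k),
                        Me = matrix(0, k, k)))
  }
  full <- reml_eval_cpp(blocks, tau2[["study"]], tau2[["genus"]],
                        tau2[["experiment"]],
                        if (is.na(rho)) 0 else rho, p, TRUE)
  if (!isTRUE(full$ok))
    stop("fit_reml: covariance matrix not positive definite at the solution")
  beta <- drop(full$beta)
  names(beta) <- colnames(X)
  covb <- full$cov_beta
  dimnames(covb) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(covb))
  zval <- beta / se
  pval <- 2 * pnorm(-abs(zval))
  zc <- qnorm(0.975)
  fit <- structure(list(
    beta = beta, se = se, zval = zval, pval = pval,
    ci.lb = beta - zc * se, ci.ub = beta + zc * se,
    cov_beta = covb, tau2 = tau2, rho_exp = rho,
    k = k, p = p, loglik_reml = -full$nll,
    vi = effects$vi, yi = y, X = X, effects = effects, spec = spec,
    conv = conv), class = "meta_fit")
  fit$i2 <- if (k >= 2L) i2_decompose(fit) else
    c(study = NA_real_, genus = NA_real_, experiment = NA_real_,
      total = NA_real_)
  fit
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Multilevel meta-regression (%s, REML), k = %d effects\n",
              x$spec$effect_kind, x$k))
  cat(sprintf("tau2: study = %.4f, genus = %.4f, experiment = %.4f%s\n",
              x$tau2[["study"]], x$tau2[["genus"]], x$tau2[["experiment"]],
              if (!is.na(x$rho_exp)) sprintf(" (rho = %.3f)", x$rho_exp)
              else ""))
  i2 <- x$i2
  cat(sprintf("I2 total = %.1f%% (study %.1f%%, genus %.1f%%, experiment %.1f%%)\n",
              i2[["total"]], i2[["study"]], i2[["genus"]], i2[["experiment"]]))
  tab <- data.frame(estimate = x$beta, se = x$se, zval = x$zval,
                    pval = x$pval, ci.lb = x$ci.lb, ci.ub = x$ci.ub)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.meta_fit <- function(object, ...) object$beta

#' Multilevel I-squared decomposition
#'
#' Shares of total variance attributable to each random-effect level, beyond
#' sampling error, using the typical sampling variance
#' \deqn{\bar v = \frac{(k-1)\sum w_i}{(\sum w_i)^2 - \sum w_i^2},\quad
#'  w_i = 1/v_i,}
#' \deqn{I^2_{level} = 100\,\tau^2_{level} / (\textstyle\sum_l \tau^2_l + \bar v).}
#' Components sum to the total. The attribute `"i2_share"` carries the
#' alternative decomposition that excludes \eqn{\bar v} (each level's share
#' of the heterogeneity alone).
#'
#' @param fit A [fit_reml()] result.
#' @param vi Optional sampling variances (defaults to those in the fit).
#' @return Named numeric vector (percent): one entry per level plus
#'   `total`, with attribute `typical_v`.
#' @export
i2_decompose <- function(fit, vi = NULL) {
  stopifnot(inherits(fit, "meta_fit"))
  if (is.null(vi)) vi <- fit$vi
  k <- length(vi)
  if (k < 2L) stop("i2_decompose: need k >= 2 effects")
  w <- 1 / vi
  vbar <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  tot_t2 <- sum(fit$tau2)
  denom <- tot_t2 + vbar
  i2 <- 100 * fit$tau2 / denom
  out <- c(i2, total = sum(i2))
  attr(out, "typical_v") <- vbar
  attr(out, "i2_share") <- if (tot_t2 > 0) 100 * fit$tau2 / tot_t2
                           else fit$tau2 * 0
  out
}

#' Omnibus Wald (QM) test of moderator coefficients
#'
#' Tests whether a set of coefficients (or general linear combinations) is
#' jointly zero: \eqn{Q_M = \hat\beta_L' (L \,\mathrm{cov}(\hat\beta)\, L')^{-1}
#' \hat\beta_L}, chi-square with df = rank(L) under the null.
#'
#' @param fit A `meta_fit`.
#' @param coefficients Indices or names of coefficients to test jointly
#'   (ignored when `L` is given).
#' @param L Optional contrast matrix (rows = contrasts over coefficients).
#' @return List with `QM`, `df`, `pval`.
#' @export
qm_test <- function(fit, coefficients = NULL, L = NULL) {
  stopifnot(inherits(fit, "meta_fit"))
  if (is.null(L)) {
    if (is.null(coefficients)) stop("qm_test: give coefficients or L")
    idx <- if (is.character(coefficients))
      match(coefficients, names(fit$beta)) else as.integer(coefficients)
    if (anyNA(idx) || any(idx < 1L | idx > fit$p))
      stop("qm_test: unknown coefficient(s)")
    L <- diag(fit$p)[idx, , drop = FALSE]
  }
  L <- rbind(L)
  if (ncol(L) != fit$p) stop("qm_test: L must have ", fit$p, " columns")
  if (qr(L)$rank < nrow(L))
    stop("qm_test: contrast matrix is rank deficient (duplicated or ",
         "linearly dependent rows)")
  bL <- drop(L %*% fit$beta)
  covL <- L %*% fit$cov_beta %*% t(L)
  qm <- drop(crossprod(bL, solve(covL, bL)))
  df <- nrow(L)
  list(QM = qm, df = df, pval = pchisq(qm, df, lower.tail = FALSE))
}

#' Linear contrast of model coefficients
#'
#' Estimates \eqn{L'\hat\beta} with Wald-normal inference, the device used
#' for differences between moderator-level combinations (general linear
#' hypotheses).
#'
#' @param fit A `meta_fit`.
#' @param L Numeric weight vector over the coefficients (length p), or a
#'   matrix with one contrast per row (a data.frame of results is returned).
#' @param labels Optional contrast labels.
#' @return Data.frame with columns `label`, `estimate`, `se`, `zval`,
#'   `pval` and 95% CI bounds; `p_holm` is added by [contrast_family()].
#' @export
contrast <- function(fit, L, labels = NULL) {
  stopifnot(inherits(fit, "meta_fit"))
  L <- rbind(L)
  if (ncol(L) != fit$p)
    stop("contrast: weight vector length must equal coefficient count (",
         fit$p, ")")
  if (any(apply(L, 1L, function(r) all(r == 0))))
    stop("contrast: zero weight vector gives a degenerate contrast")
  est <- drop(L %*% fit$beta)
  se <- sqrt(rowSums((L %*% fit$cov_beta) * L))
  if (any(se <= 0)) stop("contrast: zero-variance contrast")
  z <- est / se
  zc <- qnorm(0.975)
  data.frame(label = labels %||% paste0("L", seq_len(nrow(L))),
             estimate = est, se = se, zval = z,
             pval = 2 * pnorm(-abs(z)),
             ci.lb = est - zc * se, ci.ub = est + zc * se,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A family of contrasts with Holm correction
#'
#' Runs [contrast()] for each row of `L` and adds step-down Holm-adjusted
#' p-values across the family.
#'
#' @inheritParams contrast
#' @return The [contrast()] data.frame with a `p_holm` column.
#' @export
contrast_family <- function(fit, L, labels = NULL) {
  out <- contrast(fit, L, labels)
  out$p_holm <- holm_adjust(out$pval)
  out
}

#' Holm step-down multiple-testing adjustment
#'
#' Order-preserving step-down Holm adjustment with monotonicity enforcement
#' (a validation wrapper around `stats::p.adjust`).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    stop("holm_adjust: p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "holm")
}

#' Prediction interval for a coefficient
#'
#' Interval for the true effect of a new study:
#' \eqn{\hat\beta \pm z_{0.975}\sqrt{SE^2 + \sum_l \hat\tau^2_l}}. With no
#' heterogeneity this equals the confidence interval.
#'
#' @param fit A `meta_fit`.
#' @param coefficient Index or name of the coefficient (default 1).
#' @return Named numeric `c(lower, upper)`.
#' @export
prediction_interval <- function(fit, coefficient = 1L) {
  stopifnot(inherits(fit, "meta_fit"))
  idx <- if (is.character(coefficient))
    match(coefficient, names(fit$beta)) else as.integer(coefficient)
  if (is.na(idx) || idx < 1L || idx > fit$p)
    stop("prediction_interval: unknown coefficient")
  half <- qnorm(0.975) * sqrt(fit$se[idx]^2 + sum(fit$tau2))
  c(lower = unname(fit$beta[idx] - half),
    upper = unname(fit$beta[idx] + half))
}

#' Cross-tabulate two moderators with row percentages
#'
#' Counts effect sizes per category pair with within-row percentages
#' (rounded to integer percent), the standard collinearity check between
#' unevenly distributed moderators such as parasite genetic diversity and
#' laboratory-versus-field setting.
#'
#' @param records Comparison table (or effects table) data.frame.
#' @param a,b Moderator column names (rows, columns).
#' @return List with `counts` (contingency table), `row_percent` (integer
#'   percent per row; empty rows give 0), and `row_totals`.
#' @export
collinearity_crosstab <- function(records, a, b) {
  for (m in c(a, b)) if (!m %in% names(records))
    stop("collinearity_crosstab: unknown moderator '", m, "'")
  counts <- table(records[[a]], records[[b]], dnn = c(a, b))
  totals <- rowSums(counts)
  pct <- counts
  for (i in seq_len(nrow(counts)))
    pct[i, ] <- if (totals[i] > 0) round(100 * counts[i, ] / totals[i]) else 0
  list(counts = counts, row_percent = pct, row_totals = totals)
}
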