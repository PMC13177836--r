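#' Standardised mean difference (Hedges' g) between diversity groups
#'
#' Computes the small-sample-corrected standardised mean difference of
#' parasite success between high- and low-diversity host groups,
#' \deqn{d = (m_H - m_L)/s_{pool}, \quad
#'       s_{pool}^2 = \frac{(n_H-1)s_H^2 + (n_L-1)s_L^2}{n_H+n_L-2},}
#' \deqn{J = 1 - \frac{3}{4(n_H+n_L-2)-1}, \quad g = J\,d,}
#' with sampling variance
#' \deqn{v = \frac{n_H+n_L}{n_H n_L} + \frac{g^2}{2(n_H+n_L)}.}
#' Positive g means higher parasite success in the high-diversity group. If
#' either group is flagged `direction_reversed` (survival-time metrics) the
#' sign of g is negated, since d(-x) = -d(x).
#'
#' @param low,high `group_summary` objects for the low- and high-diversity
#'   groups (n >= 2 each, SDs not both zero).
#' @param hedges_correct Apply the Hedges J correction (default `TRUE`;
#'   `FALSE` gives Cohen's d).
#' @param variance_denom Denominator variant for the g^2 term of the
#'   variance: `"2N"` (default, 2(n_H+n_L)) or `"2N-3.94"`.
#' @return A one-row data.frame with columns `kind`, `yi`, `vi`.
#' @examples
#' l <- group_summary(10, 2, 10, diversity_level = "low")
#' h <- group_summary(8, 2, 10, diversity_level = "high")
#' effect_smd(l, h)  # g ~ -0.9577, vi ~ 0.2229
#' @export
effect_smd <- function(low, high, hedges_correct = TRUE,
                       variance_denom = c("2N", "2N-3.94")) {
  variance_denom <- match.arg(variance_denom)
  stopifnot(inherits(low, "group_summary"), inherits(high, "group_summary"))
  nL <- low$n; nH <- high$n
  if (nL < 2 || nH < 2) stop("effect_smd: need n >= 2 per group")
  sp2 <- ((nH - 1) * high$sd^2 + (nL - 1) * low$sd^2) / (nH + nL - 2)
  if (sp2 <= 0) stop("effect_smd: pooled SD is zero; SMD undefined")
  d <- (high$mean - low$mean) / sqrt(sp2)
  J <- if (hedges_correct) 1 - 3 / (4 * (nH + nL - 2) - 1) else 1
  g <- J * d
  if (isTRUE(low$direction_reversed) || isTRUE(high$direction_reversed))
    g <- -g
  denom <- if (variance_denom == "2N") 2 * (nH + nL) else 2 * (nH + nL) - 3.94
  vi <- (nH + nL) / (nH * nL) + g^2 / denom
  data.frame(kind = "SMD", yi = g, vi = vi)
}

#' Log coefficient of variation ratio (lnCVR) between diversity groups
#'
#' Compares relative variability (CV = sd/mean) of parasite success between
#' high- and low-diversity host groups, with a small-sample correction:
#' \deqn{\mathrm{lnCVR} = \ln\frac{s_H}{m_H} - \ln\frac{s_L}{m_L}
#'       + \frac{1}{2(n_H-1)} - \frac{1}{2(n_L-1)},}
#' \deqn{v = \frac{s_L^2}{n_L m_L^2} + \frac{1}{2(n_L-1)}
#'         + \frac{s_H^2}{n_H m_H^2} + \frac{1}{2(n_H-1)}.}
#' The variance is the independence form: group summaries, not paired
#' replicate series, are the input, so the mean-SD correlation term of the
#' full published variance is set to zero (switchable via `mean_sd_cor`).
#' Positive lnCVR means relatively more variable parasite success in the
#' high-diversity group.
#'
#' @param low,high `group_summary` objects; means and SDs must be positive
#'   (apply [apply_offset()] first where zeros can occur), n >= 2 per group.
#' @param mean_sd_cor Optional mean-SD correlation per group (length 1 or 2,
#'   low then high) for the full variance formula; default 0.
#' @return A one-row data.frame with columns `kind`, `yi`, `vi`.
#' @examples
#' l <- group_summary(10, 2, 10, diversity_level = "low")
#' h <- group_summary(10, 4, 10, diversity_level = "high")
#' effect_lncvr(l, h)  # ln 2 ~ 0.6931, vi ~ 0.1311
#' @export
effect_lncvr <- function(low, high, mean_sd_cor = 0) {
  stopifnot(inherits(low, "group_summary"), inherits(high, "group_summary"))
  nL <- low$n; nH <- high$n
  if (nL < 2 || nH < 2) stop("effect_lncvr: need n >= 2 per group")
  if (low$mean <= 0 || high$mean <= 0 || low$sd <= 0 || high$sd <= 0)
    stop("effect_lncvr: non-positive mean or SD after offset; ",
         "lnCVR undefined")
  if (isTRUE(low$direction_reversed) || isTRUE(high$direction_reversed))
    stop("effect_lncvr: undefined for direction-reversed (shifted-mean) ",
         "survival metrics")
  rho <- rep_len(mean_sd_cor, 2L)
  yi <- log(high$sd / high$mean) - log(low$sd / low$mean) +
    1 / (2 * (nH - 1)) - 1 / (2 * (nL - 1))
  v_grp <- function(m, s, n, r) {
    s^2 / (n * m^2) + 1 / (2 * (n - 1)) -
      2 * r * sqrt(s^2 / (n * m^2) * 1 / (2 * (n - 1)))
  }
  vi <- v_grp(low$mean, low$sd, nL, rho[1L]) +
    v_grp(high$mean, high$sd, nH, rho[2L])
  data.frame(kind = "lnCVR", yi = yi, vi = vi)
}

#' Compute effect sizes for a comparison table
#'
#' Applies the log-safety offset and computes SMD and/or lnCVR with sampling
#' variances for every row of a canonical comparison table (see
#' [comparison_columns()]).
#'
#' @param records Comparison table data.frame.
#' @param kind `"SMD"`, `"lnCVR"`, or both (default).
#' @param offset Log-safety offset added to means and SDs before effect
#'   computation (the conventional 0.001); set `0` to disable.
#' @param offset_zero_only Apply the offset only to comparisons where a mean
#'   or SD is exactly zero (sensitivity switch; default `FALSE`, i.e. the
#'   offset is applied to every record).
#' @param ... Passed to [effect_smd()].
#' @return A data.frame with one row per comparison per effect kind:
#'   identifiers, moderators, `kind`, `yi`, `vi`. Carries an `offset`
#'   attribute recording the offset actually used.
#' @export
compute_effects <- function(records, kind = c("SMD", "lnCVR"),
                            offset = 0.001, offset_zero_only = FALSE, ...) {
  kind <- match.arg(kind, several.ok = TRUE)
  stopifnot(is.data.frame(records))
  keep <- intersect(c("study_id", "experiment_id", "comparison_id",
                      "host_genus", names(moderator_levels()),
                      "shared_control_key", "n_low", "n_high"),
                    names(records))
  if (any(records$n_low < 2 | records$n_high < 2))
    stop("compute_effects: need n >= 2 per group")
  if (any(records$sd_low < 0 | records$sd_high < 0))
    stop("compute_effects: negative SDs")

  do_off <- rep(offset > 0, nrow(records))
  if (offset > 0 && offset_zero_only)
    do_off <- records$mean_low == 0 | records$sd_low == 0 |
      records$mean_high == 0 | records$sd_high == 0
  off <- ifelse(do_off, offset, 0)
  mL <- records$mean_low + off;  sL <- records$sd_low + off
  mH <- records$mean_high + off; sH <- records$sd_high + off
  nL <- records$n_low;           nH <- records$n_high

  parts <- lapply(kind, function(kd) {
    if (kd == "SMD") {
      sp2 <- ((nH - 1) * sH^2 + (nL - 1) * sL^2) / (nH + nL - 2)
      if (any(sp2 <= 0)) stop("compute_effects: pooled SD is zero")
      dots <- list(...)
      J <- if (isFALSE(dots$hedges_correct)) 1
           else 1 - 3 / (4 * (nH + nL - 2) - 1)
      g <- J * (mH - mL) / sqrt(sp2)
      denom <- if (identical(dots$variance_denom, "2N-3.94"))
        2 * (nH + nL) - 3.94 else 2 * (nH + nL)
      vi <- (nH + nL) / (nH * nL) + g^2 / denom
      data.frame(kind = "SMD", yi = g, vi = vi)
    } else {
      if (any(mL <= 0 | mH <= 0 | sL <= 0 | sH <= 0))
        stop("compute_effects: non-positive mean or SD after offset; ",
             "lnCVR undefined")
      yi <- log(sH / mH) - log(sL / mL) +
        1 / (2 * (nH - 1)) - 1 / (2 * (nL - 1))
      vi <- sL^2 / (nL * mL^2) + 1 / (2 * (nL - 1)) +
        sH^2 / (nH * mH^2) + 1 / (2 * (nH - 1))
      data.frame(kind = "lnCVR", yi = yi, vi = vi)
    }
  })
  out <- do.call(rbind, lapply(parts, function(p)
    cbind(records[, keep, drop = FALSE], p, row.names = NULL)))
  rownames(out) <- NULL
  attr(out, "offset") <- if (offset > 0) offset else 0
  attr(out, "offset_zero_only") <- offset_zero_only
  out
}

#' Sampling variance-covariance matrix with shared-control blocks
#'
#' Builds the k x k sampling VCV for a set of effect sizes of one kind.
#' Effects that share a low-diversity reference group (same
#' `shared_control_key`) are correlated; all other off-diagonals are zero.
#' Two constructions are available:
#' \describe{
#'   \item{`fixed_r`}{cov_ij = r * sqrt(v_i v_j) within a shared-control
#'     block (default r = 0.5, the conventional choice; results should be
#'     labelled with the r used).}
#'   \item{`exact_smd`}{SMD only: cov_ij = 1/n_C + g_i g_j / (2 N), with n_C
#'     the shared control group size and N the total size of the three
#'     groups involved.}
#' }
#' The result is validated positive semidefinite; violations are an error
#' naming the offending block (no silent repair).
#'
#' @param effects Effects data.frame from [compute_effects()], single kind.
#' @param mode `"fixed_r"` (default) or `"exact_smd"`.
#' @param r Shared-control correlation for `fixed_r` mode, in (0, 1).
#' @param n_control Optional named vector of control-group sizes per
#'   `shared_control_key` (for `exact_smd`); defaults to the `n_low` column.
#' @return A list of class `sampling_vcv`: `matrix` (k x k, dimnames =
#'   comparison ids), `ordering`, `mode`, `r`.
#' @export
build_vcv <- function(effects, mode = c("fixed_r", "exact_smd"), r = 0.5,
                      n_control = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(effects), "yi" %in% names(effects))
  if (length(unique(effects$kind)) > 1L)
    stop("build_vcv: effects must share a common kind")
  if (mode == "exact_smd" && effects$kind[1L] != "SMD")
    stop("build_vcv: exact_smd mode applies to SMD effects only")
  if (mode == "fixed_r" && (r <= 0 || r >= 1))
    stop("build_vcv: r must lie in (0, 1)")

  k <- nrow(effects)
  ids <- as.character(effects$comparison_id)
  V <- diag(effects$vi, k, k)
  dimnames(V) <- list(ids, ids)

  key <- if ("shared_control_key" %in% names(effects))
    as.character(effects$shared_control_key) else rep(NA_character_, k)
  key[is.na(key) | key == ""] <- NA_character_
  for (b in unique(key[!is.na(key)])) {
    idx <- which(key == b)
    if (length(idx) < 2L) next
    for (i in idx) for (j in idx) {
      if (i >= j) next
      cv <- if (mode == "fixed_r") {
        r * sqrt(effects$vi[i] * effects$vi[j])
      } else {
        nC <- if (!is.null(n_control)) n_control[[b]] else effects$n_low[i]
        N <- nC + effects$n_high[i] + effects$n_high[j]
        1 / nC + effects$yi[i] * effects$yi[j] / (2 * N)
      }
      V[i, j] <- V[j, i] <- cv
    }
  }
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    bad <- unique(key[!is.na(key)])
    stop("build_vcv: matrix not positive semidefinite (min eigenvalue ",
         format(min(ev)), "); check shared-control blocks: ",
         paste(bad, collapse = ", "))
  }
  structure(list(matrix = V, ordering = ids, mode = mode,
                 r = if (mode == "fixed_r") r else NA_real_),
            class = "sampling_vcv")
}

#' @export
print.sampling_vcv <- function(x, ...) {
  nz <- sum(x$matrix[upper.tri(x$matrix)] != 0)
  cat(sprintf("sampling_vcv: %d effects, mode = %s%s, %d shared-control covariances\n",
              nrow(x$matrix), x$mode,
              if (!is.na(x$r)) sprintf(" (r = %g)", x$r) else "", nz))
  invisible(x)
}
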