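#' Group-level summary of a parasite-success metric
#'
#' One group of host populations (high or low genetic diversity) is described
#' by the mean, standard deviation and sample size of a parasite-success
#' metric. Proportion metrics (e.g. prevalence, mortality rate) must have
#' means in \[0, 1\].
#'
#' @param mean Group mean of the metric.
#' @param sd Group standard deviation, >= 0.
#' @param n Number of replicate populations, >= 1.
#' @param metric Metric class: one of `"prevalence"`, `"load"`,
#'   `"virulence"`, `"other"`.
#' @param diversity_level `"high"` or `"low"` host genetic diversity.
#' @param proportion Is the metric a proportion on \[0, 1\]? Defaults to
#'   `TRUE` for prevalence, `FALSE` otherwise.
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(0.4, 0.1, 12, metric = "prevalence", diversity_level = "low")
#' @export
group_summary <- function(mean, sd, n,
                          metric = "other",
                          diversity_level = c("low", "high"),
                          proportion = identical(metric, "prevalence")) {
  diversity_level <- match.arg(diversity_level)
  metric <- match.arg(metric, moderator_levels()$metric_of_success)
  if (!is.finite(mean)) stop("group_summary: 'mean' must be finite")
  if (!is.finite(sd) || sd < 0) stop("group_summary: 'sd' must be >= 0")
  if (!is.finite(n) || n < 1) stop("group_summary: 'n' must be >= 1")
  if (proportion && (mean < 0 || mean > 1))
    stop("group_summary: proportion metric must have mean in [0, 1]")
  structure(
    list(mean = mean, sd = sd, n = n, metric = metric,
         diversity_level = diversity_level, proportion = proportion,
         direction_reversed = FALSE),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary [%s diversity, %s]: mean = %.4g, sd = %.4g, n = %g%s\n",
              x$diversity_level, x$metric, x$mean, x$sd, x$n,
              if (isTRUE(x$direction_reversed)) " (direction-reversed)" else ""))
  invisible(x)
}

#' Pool shared groups of host populations
#'
#' Combines several group summaries of the same metric into one, as when
#' several high-diversity groups are reported against a shared low-diversity
#' reference, or several populations are collapsed into a diversity category.
#' The pooled n is the total n, the pooled mean the n-weighted mean, and the
#' pooled variance follows the total-sum-of-squares rule
#' \deqn{s^2 = \frac{\sum_i (n_i-1)s_i^2 + \sum_i n_i(m_i-\bar m)^2}{\sum_i n_i - 1},}
#' i.e. the variance of the concatenated sample (within- plus between-group
#' spread).
#'
#' @param groups A list of [group_summary()] objects with identical `metric`.
#' @return A single `group_summary`.
#' @examples
#' g1 <- group_summary(10, 2, 10)
#' g2 <- group_summary(14, 2, 10)
#' pool_groups(list(g1, g2))  # mean 12, variance 152/19, n 20
#' @export
pool_groups <- function(groups) {
  if (length(groups) == 0L) stop("pool_groups: empty group list")
  stopifnot(all(vapply(groups, inherits, logical(1), "group_summary")))
  metrics <- vapply(groups, `[[`, character(1), "metric")
  if (length(unique(metrics)) != 1L)
    stop("pool_groups: groups measure different metrics: ",
         paste(unique(metrics), collapse = ", "))
  if (length(groups) == 1L) return(groups[[1L]])

  m <- vapply(groups, `[[`, numeric(1), "mean")
  s <- vapply(groups, `[[`, numeric(1), "sd")
  n <- vapply(groups, `[[`, numeric(1), "n")
  N <- sum(n)
  mbar <- sum(n * m) / N
  ss <- sum((n - 1) * s^2) + sum(n * (m - mbar)^2)
  out <- groups[[1L]]
  out$mean <- mbar
  out$sd <- sqrt(ss / (N - 1))
  out$n <- N
  out
}

#' Split populations along a continuous diversity gradient
#'
#' Converts a set of host populations with a continuous measure of genetic
#' diversity (heterozygosity, allelic richness, ...) into a two-level
#' high/low contrast. Populations are ordered by score; the lower half forms
#' the low-diversity group and the upper half the high-diversity group, with
#' the same number of populations in each. With an odd count the median
#' population is dropped. Each half is pooled with [pool_groups()].
#' Tied scores at the boundary are broken by stable input order.
#'
#' @param populations A data.frame with one row per population and columns
#'   `diversity_score`, `mean`, `sd`, `n`.
#' @param metric Metric label passed to the pooled summaries.
#' @param proportion Is the metric a proportion?
#' @return A list with elements `low` and `high` (pooled `group_summary`
#'   objects) and `dropped` (the row index of a dropped median population, or
#'   `NA`).
#' @examples
#' pops <- data.frame(diversity_score = c(1, 2, 3, 4, 5, 6),
#'                    mean = c(5, 6, 7, 8, 9, 10), sd = 1, n = 10)
#' dichotomise_continuous(pops)
#' @export
dichotomise_continuous <- function(populations, metric = "other",
                                   proportion = FALSE) {
  req <- c("diversity_score", "mean", "sd", "n")
  if (!all(req %in% names(populations)))
    stop("dichotomise_continuous: need columns ",
         paste(setdiff(req, names(populations)), collapse = ", "))
  k <- nrow(populations)
  if (k < 2L) stop("dichotomise_continuous: need >= 2 populations")
  score <- populations$diversity_score
  if (any(!is.finite(score)))
    stop("dichotomise_continuous: non-finite diversity scores")
  if (length(unique(score)) == 1L)
    stop("dichotomise_continuous: degenerate diversity gradient ",
         "(all scores identical, no split defined)")

  ord <- order(score)  # stable for ties
  dropped <- NA_integer_
  if (k %% 2L == 1L) {
    dropped <- ord[(k + 1L) %/% 2L]
    ord <- ord[-((k + 1L) %/% 2L)]
    k <- k - 1L
  }
  half <- k %/% 2L
  as_groups <- function(idx, level) {
    lapply(idx, function(i)
      group_summary(populations$mean[i], populations$sd[i], populations$n[i],
                    metric = metric, diversity_level = level,
                    proportion = proportion))
  }
  low <- pool_groups(as_groups(ord[seq_len(half)], "low"))
  high <- pool_groups(as_groups(ord[half + seq_len(half)], "high"))
  list(low = low, high = high, dropped = dropped)
}

#' Convert a survival-direction metric to parasite success
#'
#' Parasite success is defined so that killing hosts counts positively, so
#' host survival must be reversed. For proportion metrics the mean becomes
#' `1 - mean` with the SD unchanged (the complement of a proportion has the
#' same spread). For non-proportion survival metrics (e.g. survival time)
#' there is no defensible transformation of the mean/SD scale, so the
#' summary is flagged `direction_reversed` and the downstream SMD sign is
#' negated; lnCVR is undefined for a shifted mean and is not computed for
#' such records.
#'
#' @param summary A `group_summary` measuring host survival.
#' @return The converted / flagged `group_summary`.
#' @examples
#' s <- group_summary(0.8, 0.1, 10, metric = "virulence",
#'                    diversity_level = "low", proportion = TRUE)
#' survival_to_mortality(s)$mean  # 0.2
#' @export
survival_to_mortality <- function(summary) {
  stopifnot(inherits(summary, "group_summary"))
  if (isTRUE(summary$proportion)) {
    summary$mean <- 1 - summary$mean
  } else {
    summary$direction_reversed <- TRUE
  }
  summary
}

#' Add a small log-safety offset to a group summary
#'
#' Adds a small constant (default 0.001) to both the mean and the SD so that
#' logarithms in lnCVR are defined for groups with zero means or zero
#' variance. Applied uniformly to both groups of a comparison it never
#' changes the sign of the mean difference.
#'
#' @param summary A `group_summary`.
#' @param offset Positive constant, default `0.001`.
#' @return The shifted `group_summary`.
#' @examples
#' apply_offset(group_summary(0, 0, 5))  # mean 0.001, sd 0.001
#' @export
apply_offset <- function(summary, offset = 0.001) {
  stopifnot(inherits(summary, "group_summary"))
  if (!is.finite(offset) || offset <= 0)
    stop("apply_offset: offset must be a positive constant")
  summary$mean <- summary$mean + offset
  summary$sd <- summary$sd + offset
  summary$proportion <- FALSE  # mean may now exceed [0, 1] checks
  summary
}

#' Summarise replicate-level observations per population
#'
#' Collapses a replicate-level table (one row per replicate observation) to
#' population-level mean/SD/n summaries, the form consumed by
#' [dichotomise_continuous()].
#'
#' @param replicates A data.frame with columns `population_id`,
#'   `diversity_score` and `value`.
#' @return A data.frame with one row per population and columns
#'   `population_id`, `diversity_score`, `mean`, `sd`, `n`.
#' @export
summarise_replicates <- function(replicates) {
  req <- c("population_id", "diversity_score", "value")
  if (!all(req %in% names(replicates)))
    stop("summarise_replicates: need columns ",
         paste(setdiff(req, names(replicates)), collapse = ", "))
  sp <- split(replicates, replicates$population_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(population_id = d$population_id[1L],
               diversity_score = d$diversity_score[1L],
               mean = mean(d$value),
               sd = stats::sd(d$value),
               n = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$population_id), , drop = FALSE]
}
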