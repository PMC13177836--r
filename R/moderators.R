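#' Moderator vocabulary and canonical comparison-table schema
#'
#' The comparison table carries ten categorical moderators: the 2x2 design
#' factors (parasite genetic diversity, parasite host range) and eight
#' contextual factors (metric of parasite success, host type, parasite type,
#' source and scale of host genetic diversity, host reproduction mode,
#' whether the parasite typically kills the host, and laboratory versus field
#' setting). Each moderator takes values from a closed vocabulary.
#'
#' @return `moderator_levels()` returns a named list mapping each moderator
#'   column to its allowed levels. `comparison_columns()` returns the
#'   canonical column names of the comparison table, in order.
#' @examples
#' moderator_levels()$host_range
#' comparison_columns()
#' @export
moderator_levels <- function() {
  list(
    metric_of_success          = c("prevalence", "load", "virulence", "other"),
    host_type                  = c("invertebrate", "vertebrate"),
    parasite_type              = c("microparasite", "macroparasite"),
    source_of_diversity        = c("relatedness", "genotypes", "natural"),
    scale_of_diversity         = c("discrete", "continuous"),
    host_reproduction          = c("sexual", "asexual", "mixed"),
    host_mortality             = c("yes", "no"),
    laboratory                 = c("yes", "no"),
    parasite_genetic_diversity = c("high", "low"),
    host_range                 = c("specialist", "generalist")
  )
}

#' @rdname moderator_levels
#' @export
comparison_columns <- function() {
  c("study_id", "experiment_id", "comparison_id", "host_genus",
    "mean_low", "sd_low", "n_low", "mean_high", "sd_high", "n_high",
    names(moderator_levels()), "shared_control_key")
}

# columns that must parse as finite numerics
.numeric_columns <- c("mean_low", "sd_low", "n_low",
                      "mean_high", "sd_high", "n_high")
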