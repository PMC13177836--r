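# Independent reference implementations used as oracles. These use plain
# dense linear algebra in R and never touch the package's fitting code.

# Restricted log-likelihood, Harville convention (matches standard REML
# implementations up to nothing: constants included).
reml_ll_ref <- function(y, X, V, tau2, group) {
  k <- length(y); p <- ncol(X)
  Z <- outer(group, group, `==`) * 1
  Sigma <- V + tau2 * Z
  Si <- solve(Sigma)
  XtSiX <- t(X) %*% Si %*% X
  beta <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  as.numeric(
    -0.5 * (determinant(Sigma)$modulus + determinant(XtSiX)$modulus +
              t(r) %*% Si %*% r) -
      0.5 * (k - p) * log(2 * pi) +
      0.5 * determinant(crossprod(X))$modulus)
}

# Exhaustive zoomed grid search of the REML objective over tau2 (one
# exchangeable random level); returns the maximising tau2 and its GLS beta.
grid_fit_ref <- function(y, X, V, group, tau2_max = NULL, stages = 3,
                         pts = 81) {
  if (is.null(tau2_max)) tau2_max <- max(4 * stats::var(y), 2)
  lo <- 0; hi <- tau2_max
  for (s in seq_len(stages)) {
    grid <- seq(lo, hi, length.out = pts)
    ll <- vapply(grid, function(t2) reml_ll_ref(y, X, V, t2, group),
                 numeric(1))
    i <- which.max(ll)
    step <- grid[2] - grid[1]
    lo <- max(0, grid[i] - step)
    hi <- grid[i] + step
  }
  tau2 <- grid[i]
  Si <- solve(V + tau2 * outer(group, group, `==`))
  beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  list(tau2 = tau2, beta = drop(beta), ll = ll[i])
}

# small comparison table built by hand for io / effect tests
toy_records <- function(n = 3) {
  ml <- moderator_levels()
  data.frame(
    study_id = paste0("S", seq_len(n)),
    experiment_id = paste0("S", seq_len(n), ".E1"),
    comparison_id = paste0("S", seq_len(n), ".E1.C1"),
    host_genus = paste0("G", seq_len(n)),
    mean_low = 10 + seq_len(n), sd_low = 2, n_low = 10,
    mean_high = 8 + seq_len(n), sd_high = 2.5, n_high = 12,
    metric_of_success = ml$metric_of_success[(seq_len(n) %% 3) + 1],
    host_type = "invertebrate", parasite_type = "microparasite",
    source_of_diversity = "genotypes", scale_of_diversity = "discrete",
    host_reproduction = "sexual", host_mortality = "yes",
    laboratory = "yes",
    parasite_genetic_diversity = rep(c("high", "low"), length.out = n),
    host_range = rep(c("specialist", "generalist"), length.out = n),
    shared_control_key = NA_character_,
    stringsAsFactors = FALSE)
}
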