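# Shared fixtures: everything is generated in code at test time.

# Small geometry / short chains for plumbing tests (not for calibration
# claims, which use the acceptance-scale settings).
tiny_scenario <- function(...) {
  scenario_config(M = 2, grid_dim = 4, ...)
}

tiny_fit_config <- function(variant = "latent_adjustment", ...) {
  fit_config(variant = variant, n_burn = 300, n_keep = 300, thin = 3,
             seed = 99, ...)
}

# Monte Carlo standard error via batch means (for chain comparisons).
mcse_mean <- function(x, n_batch = 20) {
  n <- floor(length(x) / n_batch) * n_batch
  bm <- colMeans(matrix(x[seq_len(n)], ncol = n_batch))
  stats::sd(bm) / sqrt(n_batch)
}
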