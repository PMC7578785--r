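# shared fixtures and independent oracles, built in code at test time

# simulate one participant's trial table on a given gamble grid
sim_trials <- function(n, beta, intercept = 0, gain_levels = seq(0, 2, 0.25),
                       loss_levels = gain_levels, seed = 1) {
  set.seed(seed)
  g <- data.frame(gain = sample(gain_levels, n, TRUE),
                  loss = sample(loss_levels, n, TRUE))
  p <- plogis(beta[1] * g$gain + beta[2] * g$loss + intercept)
  g$accept <- rbinom(n, 1, p)
  g
}

# independent oracle: coarse grid search over the penalised log-likelihood
grid_search_logistic <- function(data, bg_grid, bl_grid, ic_grid,
                                 lambda = 1e-6) {
  X <- cbind(1, data$gain, data$loss)
  y <- data$accept
  best <- NULL; best_ll <- -Inf
  for (ic in ic_grid) for (bg in bg_grid) for (bl in bl_grid) {
    eta <- X %*% c(ic, bg, bl)
    mu <- plogis(eta)
    ll <- sum(y * log(pmax(mu, 1e-300)) +
              (1 - y) * log(pmax(1 - mu, 1e-300))) -
      lambda / 2 * (ic^2 + bg^2 + bl^2)
    if (ll > best_ll) { best_ll <- ll; best <- c(ic, bg, bl) }
  }
  names(best) <- c("(Intercept)", "gain", "loss")
  best
}

# independent oracle: direct numerical HRF convolution of one event at a
# fine grid, sampled at TR
oracle_convolve_event <- function(onset, duration, TR, n_volumes, dt = 0.01) {
  tfine <- seq(0, (n_volumes - 1) * TR + 32, by = dt)
  box <- as.numeric(tfine >= onset & tfine < onset + duration)
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  y <- stats::convolve(box, rev(h), type = "open")[seq_along(tfine)] * dt
  y[match(round((seq_len(n_volumes) - 1) * TR, 8), round(tfine, 8))]
}

# tiny noiseless single-run dataset used by several first-level tests
noiseless_run <- function(dim3 = c(8, 8, 8), seed = 3, n_trials = 32) {
  cfg <- default_config(seed = seed, n_subjects = 1, dim3 = dim3,
                        noise = noise_model(sigma = 0, ar1_rho = 0,
                                            drift_amplitude = 0),
                        task = task_config(n_trials_per_run = n_trials,
                                           n_runs = 1))
  maps <- svide:::dataset_maps(cfg)
  m <- true_choice_model(0.1, -0.2, 0)
  tr <- simulate_participant(cfg$task, m, seed = seed + 2)
  tr$sv <- tr$sv_true
  tr$ide <- inverse_decision_entropy(tr$p_accept_true)
  nv <- attr(tr, "n_volumes")
  bold <- generate_bold(tr, maps, cfg$noise, TR = 1, n_volumes = nv[[1]],
                        seed = seed + 5)
  list(trials = tr, maps = maps, bold = bold, n_volumes = nv[[1]], cfg = cfg)
}
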