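# Independent oracles used across the suite.

# Euler-Maruyama integration of the raw coupled equations: deliberately does
# not share any code path with simulate_paths (no diagonalization), so it can
# serve as an independent dynamics oracle at small step size.
euler_pair_oracle <- function(params, dt_obs, n_obs, h = 0.02, burn_time = 50,
                              seed = 1) {
  set.seed(seed)
  sub <- max(1L, round(dt_obs / h))
  h <- dt_obs / sub
  y1 <- 0; y2 <- 0
  nburn <- round(burn_time / h)
  for (i in seq_len(nburn)) {
    y1n <- y1 - params$alpha1 * (y1 - y2) * h + params$beta1 * rnorm(1, 0, sqrt(h))
    y2  <- y2 - params$alpha2 * (y2 - y1) * h + params$beta2 * rnorm(1, 0, sqrt(h))
    y1 <- y1n
  }
  x1 <- numeric(n_obs); x2 <- numeric(n_obs); k <- 0L
  for (i in seq_len(n_obs * sub)) {
    y1n <- y1 - params$alpha1 * (y1 - y2) * h + params$beta1 * rnorm(1, 0, sqrt(h))
    y2  <- y2 - params$alpha2 * (y2 - y1) * h + params$beta2 * rnorm(1, 0, sqrt(h))
    y1 <- y1n
    if (i %% sub == 0) { k <- k + 1L; x1[k] <- y1; x2[k] <- y2 }
  }
  list(x1 = x1, x2 = x2)
}

# monthly series of a pure linear trend plus optional noise, for detrend tests
linear_fixture <- function(n = 240, c0 = 5, c1 = 0.1, noise_sd = 0,
                           seed = NULL, precision = 0.001) {
  if (!is.null(seed)) set.seed(seed)
  t <- 0:(n - 1)
  monthly_series(2000 + t %/% 12, t %% 12 + 1,
                 c0 + c1 * t + rnorm(n, 0, noise_sd), precision = precision)
}
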