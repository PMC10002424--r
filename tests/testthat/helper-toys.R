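# Shared fixtures: built in code at test time, no stored data.

toy_layout <- function(m) {
  tibble::tibble(depth_cm = seq_len(m), das = 1L, role = "both")
}

# Observation set with exactly the given values (no realized noise) but a
# stated noise level for the error covariance.
exact_obs <- function(values, noise_sd) {
  ob <- perturb_observations(values, toy_layout(length(values)),
                             noise_sd = noise_sd, seed = 1L)
  ob$data$value <- values
  ob
}

# Linear-Gaussian inverse problem with a closed-form posterior.
# forward f(m) = H m, obs error variance r; with a Gaussian prior (mu0, S0)
# the posterior is N(mu_post, S_post); with an (improper) flat prior the
# limit S0 -> Inf applies.
linear_gaussian_toy <- function() {
  H <- matrix(c(1, 0.5,
                0, 1,
                1, 1), nrow = 3, byrow = TRUE)
  r <- 0.04
  dobs <- c(1.2, -0.4, 0.9)
  mu0 <- c(1, -1)
  S0 <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  S_post <- solve(solve(S0) + t(H) %*% H / r)
  mu_post <- drop(S_post %*% (solve(S0) %*% mu0 + t(H) %*% dobs / r))
  S_flat <- solve(t(H) %*% H / r)
  mu_flat <- drop(S_flat %*% (t(H) %*% dobs / r))
  list(H = H, r = r, dobs = dobs, mu0 = mu0, S0 = S0,
       mu_post = mu_post, S_post = S_post,
       mu_flat = mu_flat, S_flat = S_flat,
       forward = function(m) as.numeric(H %*% m),
       obs = exact_obs(dobs, sqrt(r)))
}

# Gaussian prior ensemble for the linear toy (multivariate normal via
# Cholesky, independent of any package under test).
rmvn <- function(n, mu, S) {
  L <- chol(S)
  sweep(matrix(rnorm(n * length(mu)), n) %*% L, 2, mu, `+`)
}

# Monte-Carlo standard error of a chain mean via batch means.
batch_se <- function(x, n_batches = 20) {
  n <- length(x)
  bs <- floor(n / n_batches)
  bm <- vapply(seq_len(n_batches),
               function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  sd(bm) / sqrt(n_batches)
}

# Bimodal toy: f(m) = m^2, observed 4, uniform prior on [-5, 5]; true
# posterior has equal modes at +/-2. Mode occupancy = fraction of samples
# within +/-0.5 of each mode.
bimodal_modes <- function(samples) {
  c(neg = mean(abs(samples + 2) < 0.5), pos = mean(abs(samples - 2) < 0.5))
}
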