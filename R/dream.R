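#' Gaussian log-likelihood of a parameter vector
#'
#' Independent Gaussian measurement-error likelihood of the residual
#' `d - f(theta)` under `N(0, R)` (diagonal `R`), plus a uniform-prior box
#' indicator: `-Inf` outside `[lower, upper]`.
#'
#' @param theta Parameter vector.
#' @param forward Forward-model function.
#' @param obs An `observation_set`.
#' @param lower,upper Optional prior box bounds.
#' @return Scalar log density.
#' @export
log_likelihood <- function(theta, forward, obs, lower = NULL, upper = NULL) {
  if (!is.null(lower) && (any(theta < lower) || any(theta > upper))) return(-Inf)
  gauss_loglik(obs_values(obs) - forward(theta), obs_cov_diag(obs))
}

gauss_loglik <- function(r, rdiag) {
  rdiag <- rep(rdiag, length.out = length(r))
  -0.5 * (length(r) * log(2 * pi) + sum(log(rdiag)) + sum(r^2 / rdiag))
}

#' DREAM parallel-direction proposal
#'
#' Differential-evolution jump from archived past states:
#' `theta_p = theta + (1 + e) * gamma(delta, d') * sum(z_a - z_b) + eps` on
#' a random coordinate subset selected with crossover probability `cr`,
#' with `gamma = 2.38 / sqrt(2 * delta * d')` and small seeded perturbations
#' `e ~ U(-b_e, b_e)`, `eps ~ N(0, b_star)`.
#'
#' @param theta Current state.
#' @param archive Matrix of archived states (rows).
#' @param delta Number of difference pairs.
#' @param cr Crossover probability (each coordinate enters the jump with
#'   probability `cr`; at least one always does).
#' @param gamma Optional jump-rate override (e.g. 1 for a mode-jumping
#'   generation).
#' @param b_e,b_star Magnitudes of the multiplicative / additive jitter.
#' @return Candidate parameter vector.
#' @export
parallel_direction_proposal <- function(theta, archive, delta = 1, cr = 1,
                                        gamma = NULL, b_e = 0.05,
                                        b_star = 1e-6) {
  archive <- as.matrix(archive)
  if (nrow(archive) < 2 * delta)
    stop("archive too small for ", delta, " difference pairs", call. = FALSE)
  d <- length(theta)
  mask <- runif(d) < cr
  if (!any(mask)) mask[sample.int(d, 1L)] <- TRUE
  dprime <- sum(mask)
  idx <- sample.int(nrow(archive), 2 * delta)
  za <- archive[idx[seq_len(delta)], , drop = FALSE]
  zb <- archive[idx[delta + seq_len(delta)], , drop = FALSE]
  diffs <- colSums(za) - colSums(zb)
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * delta * dprime)
  e <- runif(dprime, -b_e, b_e)
  eps <- if (b_star > 0) rnorm(dprime, 0, b_star) else numeric(dprime)
  out <- theta
  out[mask] <- theta[mask] + (1 + e) * gamma * diffs[mask] + eps
  out
}

#' DREAM snooker proposal
#'
#' Moves along the line through the current state `theta` and an archived
#' anchor `z`: two further archive points are projected onto that line and
#' the jump is `gamma_s` times their projected difference, with
#' `gamma_s ~ U(1.2, 2.2)`. Because the move is not symmetric, the
#' Metropolis ratio must be multiplied by the returned correction
#' `(||theta_p - z|| / ||theta - z||)^(d - 1)`.
#'
#' @param theta Current state.
#' @param archive Matrix of archived states (>= 3 rows).
#' @return List with `theta` (the candidate) and `correction`.
#' @export
snooker_proposal <- function(theta, archive) {
  archive <- as.matrix(archive)
  if (nrow(archive) < 3) stop("archive too small for a snooker move", call. = FALSE)
  d <- length(theta)
  for (try in 1:25) {
    idx <- sample.int(nrow(archive), 3)
    z <- archive[idx[1], ]
    e <- theta - z
    if (sum(e^2) > 0) break
  }
  if (sum(e^2) == 0) stop("archive degenerate: no direction for snooker move",
                          call. = FALSE)
  z1 <- archive[idx[2], ]; z2 <- archive[idx[3], ]
  gamma_s <- runif(1, 1.2, 2.2)
  # projections of z1, z2 onto the line share the base point, so only the
  # projected difference matters
  jump <- gamma_s * (sum((z1 - z2) * e) / sum(e^2)) * e
  thp <- theta + jump
  num <- sqrt(sum((thp - z)^2)); den <- sqrt(sum((theta - z)^2))
  corr <- if (d == 1) 1 else (num / den)^(d - 1)
  list(theta = thp, correction = corr)
}

#' Kalman-inspired proposal
#'
#' Proposes `theta_p = theta + K r + K eps`, where `r = d - f(theta)` is the
#' current data residual, `eps ~ N(0, R)`, and the gain
#' `K = C_theta_d (C_dd + R)^-1` is estimated from archived parameter /
#' prediction pairs. A powerful move toward the high-likelihood region, but
#' asymmetric — intended for burn-in only.
#'
#' @param theta Current state.
#' @param pred Current state's prediction `f(theta)`.
#' @param archive Matrix of archived parameter states.
#' @param archive_pred Matrix of the archived states' predictions.
#' @param d_obs Observation vector.
#' @param r_diag Diagonal of the measurement error covariance `R`.
#' @param K Optional precomputed gain (cache across calls).
#' @return Candidate parameter vector.
#' @export
kalman_proposal <- function(theta, pred, archive, archive_pred, d_obs, r_diag,
                            K = NULL) {
  if (is.null(K)) K <- kalman_gain(archive, archive_pred, r_diag)
  r <- d_obs - pred
  eps <- rnorm(length(d_obs), 0, sqrt(rep(r_diag, length.out = length(d_obs))))
  as.numeric(theta + K %*% (r + eps))
}

#' Multi-chain Gelman-Rubin statistic
#'
#' @param x Array `n_iter x n_chains x d` (or a matrix for `d = 1`).
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[1]; m <- dim(x)[2]
  apply(x, 3, function(s) {
    mu <- colMeans(s)
    w <- mean(apply(s, 2, var))
    b <- n * var(mu)
    if (w == 0) return(1)
    sqrt(((n - 1) / n * w + b / n) / w)
  })
}

#' DREAM(ZS) / DREAM(KZS) adaptive multi-chain MCMC
#'
#' Samples the posterior of a box-constrained parameter vector under a
#' Gaussian measurement-error likelihood, using an archive of thinned past
#' states to generate candidate moves: parallel-direction and snooker jumps
#' (`variant = "zs"`), optionally augmented with the Kalman-inspired
#' proposal during the first `t_kalman` generations
#' (`variant = "kzs"`). Moves are selected with probabilities
#' `p_parallel`, `p_snooker`, `p_kalman` (renormalised without the Kalman
#' share once `t > t_kalman` or for `"zs"`). Sampling happens in
#' bound-normalised coordinates; proposals leaving the box are reflected
#' back inside. Because the Kalman proposal is asymmetric and used without
#' a proposal-ratio correction, all generations `t <= t_kalman` are treated
#' as burn-in and excluded from posterior summaries for both variants.
#'
#' @param forward Forward-model function (parameter vector -> predictions).
#' @param lower,upper Prior box bounds.
#' @param obs An `observation_set`.
#' @param variant `"kzs"` or `"zs"`.
#' @param n_chains Number of chains (>= 2; default 3).
#' @param n_gen Generations per chain (default 1000).
#' @param p_parallel,p_snooker,p_kalman Proposal mixture (defaults 0.7,
#'   0.1, 0.2; must sum to 1).
#' @param t_kalman Kalman cutoff generation (default `0.2 * n_gen`).
#' @param archive_init Initial archive size (default `10 * d` prior draws).
#' @param stride Archive thinning stride (default 10).
#' @param delta_max Maximum number of difference pairs (default 3).
#' @param seed Integer seed; one seeded stream drives the whole run.
#' @return A list of class `dream_result`: `samples` (array
#'   `n_gen x n_chains x d`, original scale), `loglik`, `rmse`, `move`,
#'   `accepted` (matrices `n_gen x n_chains`), `map`, `map_prediction`,
#'   `burnin`, `rhat`, `acceptance` (by move type), `config`.
#' @export
dream <- function(forward, lower, upper, obs, variant = c("kzs", "zs"),
                  n_chains = 3, n_gen = 1000,
                  p_parallel = 0.7, p_snooker = 0.1, p_kalman = 0.2,
                  t_kalman = ceiling(0.2 * n_gen), archive_init = NULL,
                  stride = 10, delta_max = 3, seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(n_chains >= 2, abs(p_parallel + p_snooker + p_kalman - 1) < 1e-12)
  d <- length(lower)
  rng <- upper - lower
  if (is.null(archive_init)) archive_init <- max(10 * d, 5 * n_chains)
  d_obs <- obs_values(obs)
  r_diag <- obs_cov_diag(obs)
  m <- length(d_obs)
  f_u <- function(u) forward(lower + u * rng)

  run <- function() {
    Z <- matrix(runif(archive_init * d), ncol = d)
    Zp <- apply_forward(f_u, Z, m)
    U <- matrix(runif(n_chains * d), ncol = d)
    P <- apply_forward(f_u, U, m)
    ll <- vapply(seq_len(n_chains), function(c) gauss_loglik(d_obs - P[c, ], r_diag),
                 numeric(1))

    samples <- array(NA_real_, c(n_gen, n_chains, d))
    llmat <- matrix(NA_real_, n_gen, n_chains)
    rmsemat <- matrix(NA_real_, n_gen, n_chains)
    movemat <- matrix(NA_character_, n_gen, n_chains)
    accmat <- matrix(FALSE, n_gen, n_chains)
    Kcache <- NULL; Kcache_n <- -1L
    best_ll <- -Inf; best <- NULL; best_pred <- NULL

    for (t in seq_len(n_gen)) {
      kal_ok <- variant == "kzs" && t <= t_kalman
      probs <- if (kal_ok) c(p_parallel, p_snooker, p_kalman)
               else c(p_parallel, p_snooker, 0) / (p_parallel + p_snooker)
      for (c in seq_len(n_chains)) {
        move <- sample(c("parallel", "snooker", "kalman"), 1L, prob = probs)
        logcorr <- 0
        if (move == "parallel") {
          delta <- sample.int(delta_max, 1L)
          cr <- sample(c(1 / 3, 2 / 3, 1), 1L)
          gamma <- if (t %% 5 == 0) 1 else NULL
          up <- parallel_direction_proposal(U[c, ], Z, delta = delta, cr = cr,
                                            gamma = gamma)
        } else if (move == "snooker") {
          sp <- snooker_proposal(U[c, ], Z)
          up <- sp$theta
          logcorr <- log(sp$correction)
        } else {
          if (Kcache_n != nrow(Z)) {
            Kcache <- kalman_gain(Z, Zp, r_diag)
            Kcache_n <- nrow(Z)
          }
          up <- kalman_proposal(U[c, ], P[c, ], Z, Zp, d_obs, r_diag, K = Kcache)
        }
        up <- reflect_box(up, rep(0, d), rep(1, d))
        pp <- f_u(up)
        llp <- gauss_loglik(d_obs - pp, r_diag)
        if (is.finite(llp) && log(runif(1)) < llp - ll[c] + logcorr) {
          U[c, ] <- up; P[c, ] <- pp; ll[c] <- llp
          accmat[t, c] <- TRUE
        }
        movemat[t, c] <- move
        samples[t, c, ] <- lower + U[c, ] * rng
        llmat[t, c] <- ll[c]
        rmsemat[t, c] <- sqrt(mean((d_obs - P[c, ])^2))
        if (t > t_kalman && ll[c] > best_ll) {
          best_ll <- ll[c]; best <- lower + U[c, ] * rng; best_pred <- P[c, ]
        }
      }
      if (t %% stride == 0) {
        Z <- rbind(Z, U)
        Zp <- rbind(Zp, P)
      }
    }

    post <- samples[(t_kalman + 1):n_gen, , , drop = FALSE]
    acc_by_move <- vapply(c("parallel", "snooker", "kalman"), function(mv) {
      i <- movemat == mv
      if (!any(i)) NA_real_ else mean(accmat[i])
    }, numeric(1))
    structure(list(
      samples = samples, loglik = llmat, rmse = rmsemat, move = movemat,
      accepted = accmat, map = best, map_prediction = best_pred,
      map_loglik = best_ll, burnin = t_kalman,
      rhat = gelman_rubin(post),
      acceptance = acc_by_move,
      param_names = names(lower),
      obs = obs, lower = lower, upper = upper,
      config = list(variant = variant, n_chains = n_chains, n_gen = n_gen,
                    p_parallel = p_parallel, p_snooker = p_snooker,
                    p_kalman = p_kalman, t_kalman = t_kalman,
                    archive_init = archive_init, stride = stride,
                    delta_max = delta_max),
      seed = seed
    ), class = "dream_result")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.dream_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dream_result> DREAM%s: %d chains x %d generations (burn-in %d)\n",
              cfg$variant, cfg$n_chains, cfg$n_gen, x$burnin))
  cat(sprintf("  acceptance: parallel %.2f, snooker %.2f, kalman %s\n",
              x$acceptance[["parallel"]], x$acceptance[["snooker"]],
              ifelse(is.na(x$acceptance[["kalman"]]), "-",
                     sprintf("%.2f", x$acceptance[["kalman"]]))))
  cat(sprintf("  max R-hat %.3f, RMSE_MAP %.4g\n", max(x$rhat), rmse_map(x)))
  invisible(x)
}

#' Post-burn-in posterior samples of a DREAM run
#'
#' @param result A `dream_result`.
#' @return Matrix of retained samples (rows) by parameter (columns).
#' @export
posterior_samples <- function(result) {
  stopifnot(inherits(result, "dream_result"))
  post <- result$samples[(result$burnin + 1):result$config$n_gen, , ,
                         drop = FALSE]
  out <- matrix(post, ncol = dim(post)[3])
  colnames(out) <- result$param_names
  out
}

#' Serialize DREAM chains to CSV
#'
#' One row per chain-generation with move type, acceptance flag,
#' log-likelihood and all parameter coordinates.
#'
#' @param result A `dream_result`.
#' @param path File path.
#' @export
write_chains <- function(result, path) {
  cfg <- result$config
  d <- dim(result$samples)[3]
  nm <- result$param_names %||% paste0("p", seq_len(d))
  tbl <- tibble::tibble(
    chain = rep(seq_len(cfg$n_chains), each = cfg$n_gen),
    generation = rep(seq_len(cfg$n_gen), cfg$n_chains),
    loglik = as.vector(result$loglik),
    rmse = as.vector(result$rmse),
    move = as.vector(result$move),
    accepted = as.vector(result$accepted)
  )
  for (k in seq_len(d)) tbl[[nm[k]]] <- as.vector(result$samples[, , k])
  readr::write_csv(tbl, path)
  invisible(path)
}
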