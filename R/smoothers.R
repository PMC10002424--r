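#' Ensemble Kalman gain
#'
#' `K = C_MD (C_DD + CD)^-1`, with `C_MD` the sample cross-covariance of
#' parameters and predictions and `C_DD` the prediction auto-covariance,
#' both with `1/(Ne-1)` normalisation. The linear system is solved (never
#' inverted), after adding a trace-scaled ridge `1e-10 * mean(diag)` for
#' numerical safety; a system still singular after regularisation is an
#' error.
#'
#' @param M `Ne x d` matrix of parameter vectors (rows = members).
#' @param D `Ne x m` matrix of the members' predictions.
#' @param cd_diag Diagonal of the observation error covariance (length `m`
#'   or scalar).
#' @return The `d x m` gain matrix.
#' @export
kalman_gain <- function(M, D, cd_diag) {
  M <- as.matrix(M); D <- as.matrix(D)
  stopifnot(nrow(M) == nrow(D), nrow(M) >= 2)
  cd_diag <- rep(cd_diag, length.out = ncol(D))
  cmd <- cov(M, D)
  a <- cov(D)
  diag(a) <- diag(a) + cd_diag
  a <- a + diag(1e-10 * mean(diag(a)), ncol(a))
  kt <- tryCatch(solve(a, t(cmd)),
                 error = function(e) stop("prediction covariance is singular ",
                                          "after regularization", call. = FALSE))
  t(kt)
}

# Reflect rows of x back into the box [lower, upper] (NULL bounds = no-op).
reflect_box <- function(x, lower, upper) {
  if (is.null(lower) || is.null(upper)) return(x)
  vec <- is.null(dim(x))
  x <- rbind(x)
  rngm <- matrix(upper - lower, nrow(x), ncol(x), byrow = TRUE)
  y <- sweep(x, 2, lower) %% (2 * rngm)      # fold into [0, 2*range)
  y <- ifelse(y > rngm, 2 * rngm - y, y)     # mirror the upper half back
  out <- sweep(y, 2, lower, `+`)
  if (vec) as.numeric(out) else out
}

# Evaluate the forward model on every row of M.
apply_forward <- function(forward, M, m_out) {
  out <- vapply(seq_len(nrow(M)), function(j) forward(M[j, ]), numeric(m_out))
  if (m_out == 1L) matrix(out, ncol = 1L) else t(out)
}

# Data-misfit objective J1 = (d - f(m))' CD^-1 (d - f(m)) for each row of D.
misfit_j1 <- function(D, d, cd_diag) {
  r <- sweep(as.matrix(D), 2, d)
  as.numeric(r^2 %*% (1 / rep(cd_diag, length.out = length(d))))
}

new_calibration_result <- function(method, M, D, obs, history, config, seed) {
  d <- obs_values(obs)
  cd <- obs_cov_diag(obs)
  j1 <- misfit_j1(D, d, cd)
  i <- which.min(j1)
  rmse_hist <- vapply(history, function(h) {
    k <- which.min(misfit_j1(h$D, d, cd))
    sqrt(mean((h$D[k, ] - d)^2))
  }, numeric(1))
  structure(list(
    method = method, samples = M, predictions = D,
    param_names = colnames(M), obs = obs,
    map_index = i, map = M[i, ], map_prediction = D[i, ],
    history = history, rmse_history = rmse_hist,
    config = config, seed = seed
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s: %d samples x %d parameters, %d observations\n",
              x$method, nrow(x$samples), ncol(x$samples), nrow(x$obs$data)))
  cat(sprintf("  RMSE_MAP = %.4g (prior %.4g)\n", rmse_map(x),
              x$rmse_history[1]))
  invisible(x)
}

#' One ensemble-smoother analysis step
#'
#' Updates every ensemble member with the Kalman formula
#' `m_a = m_f + K (d_j - f(m_f))`, where each member assimilates its own
#' perturbed copy `d_j = d + N(0, CD)` of the observations, then re-runs the
#' forward model on the updated members. Updated vectors falling outside
#' the prior box are reflected back inside.
#'
#' @param forward Function mapping a parameter vector to a prediction vector.
#' @param M,D Current ensemble parameter / prediction matrices.
#' @param obs An `observation_set` (see [perturb_observations()]).
#' @param inflation Multiplier applied to the observation error covariance
#'   (both in the gain and in the observation perturbations); 1 = plain ES.
#' @param lower,upper Optional prior box bounds (length `d`).
#' @param seed Optional integer seed for the observation perturbations.
#' @return List with updated `M` and re-simulated `D`.
#' @export
es_update <- function(forward, M, D, obs, inflation = 1,
                      lower = NULL, upper = NULL, seed = NULL) {
  run <- function() {
    d <- obs_values(obs)
    cd <- obs_cov_diag(obs) * inflation
    K <- kalman_gain(M, D, cd)
    ne <- nrow(M)
    dpert <- matrix(rnorm(ne * length(d), mean = rep(d, each = ne),
                          sd = rep(sqrt(cd), each = ne)), nrow = ne)
    Ma <- M + (dpert - D) %*% t(K)
    Ma <- reflect_box(Ma, lower, upper)
    colnames(Ma) <- colnames(M)
    list(M = Ma, D = apply_forward(forward, Ma, length(d)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Ensemble smoother with multiple data assimilation (ES-MDA)
#'
#' Assimilates the same observations `n_assim` times, inflating the
#' observation error covariance by a factor `alpha_i` at each pass. The
#' default schedule uses constant `alpha_i = n_assim`, satisfying the
#' standard consistency condition `sum(1/alpha_i) = 1` (which makes the
#' scheme exact for linear-Gaussian problems). An alternative convention
#' requiring `sum(1/alpha_i^2) = 1` (constant `alpha_i = sqrt(n_assim)`)
#' is available via `inflation_variant = "sum_inv_sq"`.
#'
#' @inheritParams es_update
#' @param prior `Ne x d` matrix of prior parameter draws
#'   ([sample_prior()]).
#' @param n_assim Number of assimilation passes (default 3).
#' @param alphas Optional explicit inflation schedule (overrides
#'   `n_assim`); must satisfy the active consistency condition.
#' @param inflation_variant `"sum_inv"` (standard) or `"sum_inv_sq"`.
#' @param seed Integer seed controlling all observation perturbations.
#' @return A `calibration_result`.
#' @export
esmda <- function(forward, prior, obs, n_assim = 3, alphas = NULL,
                  inflation_variant = c("sum_inv", "sum_inv_sq"),
                  lower = NULL, upper = NULL, seed = NULL) {
  inflation_variant <- match.arg(inflation_variant)
  if (is.null(alphas)) {
    alphas <- if (inflation_variant == "sum_inv") rep(n_assim, n_assim)
              else rep(sqrt(n_assim), n_assim)
  }
  if (any(alphas < 1)) stop("inflation factors must be >= 1", call. = FALSE)
  s <- if (inflation_variant == "sum_inv") sum(1 / alphas) else sum(1 / alphas^2)
  if (abs(s - 1) > 1e-8)
    stop("inflation schedule violates the consistency condition", call. = FALSE)

  run <- function() {
    M <- as.matrix(prior)
    D <- apply_forward(forward, M, nrow(obs$data))
    history <- list(list(M = M, D = D))
    for (a in alphas) {
      st <- es_update(forward, M, D, obs, inflation = a,
                      lower = lower, upper = upper)
      M <- st$M; D <- st$D
      history[[length(history) + 1L]] <- list(M = M, D = D)
    }
    new_calibration_result("ESMDA", M, D, obs, history,
                           config = list(n_assim = length(alphas),
                                         alphas = alphas,
                                         inflation_variant = inflation_variant),
                           seed = seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' ILUES combined ranking objective
#'
#' `J(m) = a J1(m)/J1max + b J2(m)/J2max`, where `J1` is the data misfit
#' `(d - f(m))' CD^-1 (d - f(m))` and `J2` the parameter-space Mahalanobis
#' distance `(m - m_ref)' CMM^-1 (m - m_ref)` to the member whose local
#' ensemble is being formed; the normalising maxima are taken over the
#' candidate set being ranked.
#'
#' @param M Candidate parameter matrix (`n x d`).
#' @param D Candidate prediction matrix (`n x m`).
#' @param d Observation vector.
#' @param cd_diag Diagonal observation error covariance.
#' @param m_ref Reference parameter vector (length `d`).
#' @param CMM Parameter auto-covariance matrix of the global ensemble.
#' @param a,b Weights of the two terms (default 1, 1).
#' @return Numeric vector of `J` values, one per candidate.
#' @export
ilues_objective <- function(M, D, d, cd_diag, m_ref, CMM, a = 1, b = 1) {
  M <- as.matrix(M)
  CMM <- CMM + diag(1e-10 * mean(diag(CMM)), ncol(CMM))
  j1 <- misfit_j1(D, d, cd_diag)
  j2 <- stats::mahalanobis(M, center = as.numeric(m_ref), cov = CMM)
  t1 <- if (max(j1) > 0) j1 / max(j1) else j1
  t2 <- if (max(j2) > 0) j2 / max(j2) else j2
  a * t1 + b * t2
}

#' Iterative local updating ensemble smoother (ILUES)
#'
#' Instead of one global Kalman update, each member `j` is updated through
#' a local ensemble: the `NL = local_fraction * Ne` members with smallest
#' combined objective [ilues_objective()] (data misfit + parameter distance
#' to member `j`). The local ensemble is updated with the Kalman formula
#' using local covariances and per-member perturbed observations, and the
#' new member `j` is drawn uniformly at random from the updated local
#' ensemble — the mechanism that lets distinct posterior modes survive.
#' All members are then re-simulated and the process repeats.
#'
#' @inheritParams esmda
#' @param n_iter Number of outer iterations (default 3).
#' @param local_fraction Fraction of the ensemble forming each local set
#'   (default 0.1, i.e. `NL = 50` at `Ne = 500`); `NL` must be >= 2.
#' @param a,b Objective weights (default equal).
#' @param mda_inflation Also inflate the observation error per iteration
#'   with an ES-MDA style schedule (default `FALSE`: plain iteration).
#' @return A `calibration_result`.
#' @export
ilues <- function(forward, prior, obs, n_iter = 3, local_fraction = 0.1,
                  a = 1, b = 1, lower = NULL, upper = NULL,
                  mda_inflation = FALSE, seed = NULL) {
  ne <- nrow(prior)
  nl <- round(local_fraction * ne)
  if (nl < 2) stop("local ensemble size NL = round(local_fraction * Ne) must be >= 2",
                   call. = FALSE)
  alphas <- if (mda_inflation) rep(n_iter, n_iter) else rep(1, n_iter)

  run <- function() {
    d <- obs_values(obs)
    cd <- obs_cov_diag(obs)
    M <- as.matrix(prior)
    D <- apply_forward(forward, M, length(d))
    history <- list(list(M = M, D = D))

    for (it in seq_len(n_iter)) {
      infl <- alphas[it]
      CMM <- cov(M)
      CMM <- CMM + diag(1e-10 * mean(diag(CMM)), ncol(CMM))
      j1 <- misfit_j1(D, d, cd)
      t1 <- if (max(j1) > 0) j1 / max(j1) else j1
      # pairwise Mahalanobis distances via the Cholesky factor of CMM
      L <- chol(CMM)
      X <- t(backsolve(L, t(M), transpose = TRUE))
      d2 <- as.matrix(stats::dist(X))^2

      Mnew <- M
      for (j in seq_len(ne)) {
        j2 <- d2[, j]
        t2 <- if (max(j2) > 0) j2 / max(j2) else j2
        idx <- order(a * t1 + b * t2)[seq_len(nl)]
        ML <- M[idx, , drop = FALSE]
        DL <- D[idx, , drop = FALSE]
        K <- kalman_gain(ML, DL, cd * infl)
        dpert <- matrix(rnorm(nl * length(d), mean = rep(d, each = nl),
                              sd = rep(sqrt(cd * infl), each = nl)), nrow = nl)
        MLa <- ML + (dpert - DL) %*% t(K)
        MLa <- reflect_box(MLa, lower, upper)
        Mnew[j, ] <- MLa[sample.int(nl, 1L), ]
      }
      M <- Mnew
      D <- apply_forward(forward, M, length(d))
      history[[length(history) + 1L]] <- list(M = M, D = D)
    }
    new_calibration_result("ILUES", M, D, obs, history,
                           config = list(n_iter = n_iter, ne = ne,
                                         local_fraction = local_fraction,
                                         nl = nl, a = a, b = b,
                                         mda_inflation = mda_inflation),
                           seed = seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
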