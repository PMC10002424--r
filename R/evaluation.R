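#' Model fit statistics: ME, RMSE and index of agreement
#'
#' Mean bias error `ME = sum(S - O) / n`, root-mean-square error
#' `RMSE = sqrt(sum((S - O)^2) / n)`, and Willmott's index of agreement
#' `IA = 1 - sum((S - O)^2) / sum((|S - Obar| + |O - Obar|)^2)`, a bounded
#' [0, 1] agreement score (1 = perfect). `IA` is undefined (returned as
#' `NA`) when both series are identically equal to the observed mean.
#'
#' @param sim Simulated values.
#' @param obs Observed values (same length, n >= 1).
#' @return A one-row tibble with columns `me`, `rmse`, `ia`, `n`.
#' @export
fit_stats <- function(sim, obs) {
  if (length(sim) != length(obs)) stop("sim and obs lengths differ", call. = FALSE)
  stopifnot(length(obs) >= 1)
  e <- sim - obs
  obar <- mean(obs)
  den <- sum((abs(sim - obar) + abs(obs - obar))^2)
  ia <- if (den > 0) 1 - sum(e^2) / den else NA_real_
  tibble::tibble(me = mean(e), rmse = sqrt(mean(e^2)), ia = ia,
                 n = length(obs))
}

#' RMSE of the maximum a posteriori member
#'
#' For MCMC results the MAP is the retained sample with maximal
#' log-likelihood; for ensemble results, the member with minimal data
#' misfit `J1` (the samplers carry no posterior density). The statistic is
#' the RMSE between that member's simulated observations and the (noisy)
#' observation vector.
#'
#' @param result A `calibration_result` or `dream_result`.
#' @param obs Optional `observation_set` to evaluate against (defaults to
#'   the set the result was fitted on).
#' @return Scalar RMSE, same units as the observations.
#' @export
rmse_map <- function(result, obs = NULL) {
  d <- obs_values(obs %||% result$obs)
  pred <- result$map_prediction
  if (is.null(pred)) stop("result carries no MAP prediction", call. = FALSE)
  stopifnot(length(pred) == length(d))
  sqrt(mean((pred - d)^2))
}

#' Extract posterior parameter samples from any result
#' @param result A `calibration_result` or `dream_result`.
#' @return Matrix of samples by parameter.
#' @export
result_samples <- function(result) {
  if (inherits(result, "dream_result")) posterior_samples(result)
  else result$samples
}

#' Pointwise 95% simulation uncertainty bands
#'
#' Parameter-uncertainty band: central quantiles of the posterior members'
#' predictions at each observation point. Total-uncertainty band: the same
#' after adding a fresh measurement-noise draw to every member's
#' prediction, so it contains the parameter band in expectation.
#'
#' @param predictions Matrix of posterior predictions (members x points),
#'   e.g. `result$predictions`.
#' @param layout Observation layout aligned to the prediction columns.
#' @param noise_sd Measurement error sd used for the total band.
#' @param level Band coverage (default 0.95).
#' @param seed Optional seed for the noise draws.
#' @return Tibble: layout columns plus `median`, `param_lo`, `param_hi`,
#'   `total_lo`, `total_hi`.
#' @export
uncertainty_bands <- function(predictions, layout, noise_sd, level = 0.95,
                              seed = NULL) {
  predictions <- as.matrix(predictions)
  if (nrow(predictions) < 20)
    stop("need at least 20 posterior samples for quantile bands", call. = FALSE)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qp <- apply(predictions, 2, quantile, probs = pr, names = FALSE)
  noisy <- function() predictions +
    matrix(rnorm(length(predictions), 0, noise_sd), nrow = nrow(predictions))
  tot <- if (is.null(seed)) noisy() else withr::with_seed(seed, noisy())
  qt <- apply(tot, 2, quantile, probs = pr, names = FALSE)
  out <- layout
  out$median <- apply(predictions, 2, median)
  out$param_lo <- qp[1, ]; out$param_hi <- qp[2, ]
  out$total_lo <- qt[1, ]; out$total_hi <- qt[2, ]
  out
}

#' Posterior marginal histograms with deterministic binning
#'
#' Freedman-Diaconis bin width `2 * IQR * n^(-1/3)` per parameter (one
#' single bin when the IQR is zero), computed identically on every run.
#'
#' @param samples Matrix of posterior samples (rows) by parameter
#'   (columns), e.g. from [result_samples()].
#' @return Tibble with columns `parameter`, `mid`, `count`, `density`.
#' @export
summarize_marginals <- function(samples) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) >= 1)
  nm <- colnames(samples) %||% paste0("p", seq_len(ncol(samples)))
  purrr::map_dfr(seq_len(ncol(samples)), function(k) {
    x <- samples[, k]
    h <- 2 * IQR(x) * length(x)^(-1 / 3)
    if (h <= 0 || diff(range(x)) == 0) {
      return(tibble::tibble(parameter = nm[k], mid = mean(x),
                            count = length(x), density = NA_real_))
    }
    breaks <- seq(min(x), max(x) + h, by = h)
    cut_i <- findInterval(x, breaks, rightmost.closed = TRUE)
    cnt <- tabulate(cut_i, nbins = length(breaks) - 1)
    tibble::tibble(parameter = nm[k],
                   mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                   count = cnt,
                   density = cnt / (length(x) * h))
  })
}

#' Per-step RMSE evolution
#'
#' For MCMC results, the RMSE of each chain's current state at every
#' generation; for ensemble results, the per-iteration RMSE of the best
#' (minimum misfit) member.
#'
#' @param result A `calibration_result` or `dream_result`.
#' @return Tibble with columns `step`, `chain` (NA for ensembles), `rmse`.
#' @export
rmse_evolution <- function(result) {
  if (inherits(result, "dream_result")) {
    cfg <- result$config
    tibble::tibble(
      step = rep(seq_len(cfg$n_gen), cfg$n_chains),
      chain = rep(seq_len(cfg$n_chains), each = cfg$n_gen),
      rmse = as.vector(result$rmse)
    )
  } else {
    tibble::tibble(step = seq_along(result$rmse_history) - 1L,
                   chain = NA_integer_, rmse = result$rmse_history)
  }
}

#' First generation at which each chain's RMSE drops below a threshold
#'
#' Used to compare burn-in speed between samplers; chains that never reach
#' the threshold are censored at `n_gen + 1`.
#'
#' @param result A `dream_result`.
#' @param threshold RMSE threshold (e.g. `sqrt(2) * noise_sd`).
#' @return Integer vector, one first-passage generation per chain.
#' @export
first_passage <- function(result, threshold) {
  apply(result$rmse, 2, function(r) {
    i <- which(r < threshold)
    if (length(i)) i[1] else nrow(result$rmse) + 1L
  })
}
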