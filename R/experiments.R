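#' Synthetic-case calibration experiment (ILUES vs ES-MDA)
#'
#' End-to-end seeded pipeline: draw a reference parameter vector from the
#' 45-parameter uniform prior, simulate the 16-depth x 17-day soil water
#' content observation vector with the surrogate model, perturb it with
#' `N(0, noise_sd^2)` measurement error, then calibrate with both ILUES and
#' ES-MDA (default: ensemble size 500, 3 iterations, noise sd 0.005).
#'
#' @param seed Integer root seed.
#' @param ne Ensemble size (default 500).
#' @param n_iter Iterations / assimilation passes (default 3).
#' @param noise_sd Observation error sd, cm3/cm3 (default 0.005).
#' @param treatment,year Management scenario (default W1N1, 2008).
#' @param methods Which samplers to run (default both).
#' @return A list with the `observation_set` (`obs`, carrying the reference
#'   vector), one `calibration_result` per method, and a `comparison`
#'   tibble of [glance()] rows.
#' @export
run_synthetic_case <- function(seed = 1L, ne = 500, n_iter = 3,
                               noise_sd = 0.005, treatment = "W1N1",
                               year = 2008,
                               methods = c("ilues", "esmda")) {
  space <- param_space()
  case <- make_synthetic_case(space, treatment_schedule(treatment, year),
                              observation_layout("synthetic"),
                              noise_sd = noise_sd, seed = seed)
  prior <- sample_prior(space, ne, seed = seed + 3L)
  out <- list(obs = case$obs, reference = case$obs$reference)
  if ("ilues" %in% methods)
    out$ilues <- ilues(case$forward, prior, case$obs, n_iter = n_iter,
                       lower = space$lower, upper = space$upper,
                       seed = seed + 4L)
  if ("esmda" %in% methods)
    out$esmda <- esmda(case$forward, prior, case$obs, n_assim = n_iter,
                       lower = space$lower, upper = space$upper,
                       seed = seed + 5L)
  out$comparison <- purrr::map_dfr(out[intersect(methods, names(out))], glance)
  out
}

#' Practical-style calibration/validation experiment
#'
#' Mirrors the field design on synthetic truth: the practical observation
#' layout assigns 8 depths (20..160 by 20 cm; 136 points over 17 days) to
#' calibration and 7 interleaved depths (30..130 odd tens plus 170 cm; 119
#' points) to validation. The samplers see only the calibration subset; the
#' MAP member is then evaluated on the held-out validation depths.
#'
#' @inheritParams run_synthetic_case
#' @param treatment Management scenario (default `"W2N1"`, the
#'   water-saving irrigation x standard fertilization treatment).
#' @return A list with `obs` (full `observation_set`), per-method
#'   `calibration_result`s (fitted on the calibration subset), and `stats`,
#'   a tibble of ME/RMSE/IA for calibration and validation subsets.
#' @export
run_practical_case <- function(seed = 1L, ne = 500, n_iter = 3,
                               noise_sd = 0.005, treatment = "W2N1",
                               year = 2008,
                               methods = c("ilues", "esmda")) {
  space <- param_space()
  layout <- observation_layout("practical")
  schedule <- treatment_schedule(treatment, year)
  case <- make_synthetic_case(space, schedule, layout,
                              noise_sd = noise_sd, seed = seed)
  cal_idx <- which(layout$role == "calibration")
  val_idx <- which(layout$role == "validation")
  obs_cal <- obs_subset(case$obs, "calibration")
  fwd_cal <- function(p) case$forward(p)[cal_idx]

  prior <- sample_prior(space, ne, seed = seed + 3L)
  out <- list(obs = case$obs, reference = case$obs$reference,
              n_cal = length(cal_idx), n_val = length(val_idx))
  fits <- list()
  if ("ilues" %in% methods)
    fits$ilues <- ilues(fwd_cal, prior, obs_cal, n_iter = n_iter,
                        lower = space$lower, upper = space$upper,
                        seed = seed + 4L)
  if ("esmda" %in% methods)
    fits$esmda <- esmda(fwd_cal, prior, obs_cal, n_assim = n_iter,
                        lower = space$lower, upper = space$upper,
                        seed = seed + 5L)
  out <- c(out, fits)
  out$stats <- purrr::map_dfr(names(fits), function(m) {
    r <- fits[[m]]
    full_pred <- case$forward(r$map)
    dplyr::bind_rows(
      dplyr::mutate(fit_stats(r$map_prediction,
                              obs_values(case$obs)[cal_idx]),
                    method = r$method, subset = "calibration",
                    .before = 1),
      dplyr::mutate(fit_stats(full_pred[val_idx],
                              obs_values(case$obs)[val_idx]),
                    method = r$method, subset = "validation", .before = 1)
    )
  })
  out
}

#' DREAMkzs vs DREAMzs sampling-efficiency experiment
#'
#' Runs both MCMC variants on the same synthetic-truth observation set
#' (practical calibration layout: 136 points, treatment W1N1 by default)
#' with identical seeds and settings: 3 chains, `n_gen` generations,
#' proposal mixture (0.7, 0.1, 0.2), Kalman cutoff `0.2 * n_gen`. Reports
#' the per-generation RMSE series, the first-passage generation at which
#' each chain's RMSE falls below `sqrt(2) * noise_sd` (the noise floor of a
#' perfectly calibrated model plus measurement error), and ME/IA
#' distributions over re-simulated posterior samples.
#'
#' @inheritParams run_synthetic_case
#' @param n_gen Generations per chain (default 1000).
#' @param n_chains Number of chains (default 3).
#' @param n_stat_samples Posterior samples re-simulated for the ME/IA
#'   distributions (default 100).
#' @return A list with `kzs` and `zs` `dream_result`s, `threshold`,
#'   `first_passage` tibble, `rmse_series` tibble and `stats` tibble of
#'   per-sample ME/IA values by variant.
#' @export
run_mcmc_comparison <- function(seed = 1L, n_gen = 1000, n_chains = 3,
                                noise_sd = 0.005, treatment = "W1N1",
                                year = 2008, n_stat_samples = 100) {
  space <- param_space()
  layout <- observation_layout("practical")
  schedule <- treatment_schedule(treatment, year)
  case <- make_synthetic_case(space, schedule, layout,
                              noise_sd = noise_sd, seed = seed)
  cal_idx <- which(layout$role == "calibration")
  obs_cal <- obs_subset(case$obs, "calibration")
  fwd_cal <- function(p) case$forward(p)[cal_idx]
  lower <- setNames(space$lower, space$name)
  upper <- setNames(space$upper, space$name)

  res <- purrr::map(c(kzs = "kzs", zs = "zs"), function(v) {
    dream(fwd_cal, lower, upper, obs_cal, variant = v, n_chains = n_chains,
          n_gen = n_gen, seed = seed + 10L)
  })
  threshold <- sqrt(2) * noise_sd
  fp <- purrr::map_dfr(names(res), function(v) {
    tibble::tibble(variant = v,
                   chain = seq_len(n_chains),
                   first_passage = first_passage(res[[v]], threshold))
  })
  rmse_series <- purrr::map_dfr(names(res), function(v) {
    dplyr::mutate(rmse_evolution(res[[v]]), variant = v, .before = 1)
  })
  stats <- purrr::map_dfr(names(res), function(v) {
    s <- posterior_samples(res[[v]])
    take <- seq(1, nrow(s), length.out = min(n_stat_samples, nrow(s)))
    purrr::map_dfr(unique(round(take)), function(i) {
      dplyr::mutate(fit_stats(fwd_cal(s[i, ]), obs_values(obs_cal)),
                    variant = v, sample = i, .before = 1)
    })
  })
  list(kzs = res$kzs, zs = res$zs, obs = case$obs, threshold = threshold,
       first_passage = fp, rmse_series = rmse_series, stats = stats)
}
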