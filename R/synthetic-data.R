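#' Generate a reference truth for a synthetic calibration experiment
#'
#' Draws one reference parameter vector from the uniform prior and runs the
#' forward model to obtain the noiseless observation vector at the layout's
#' depth-day points — the first two steps of the synthetic-case protocol
#' (the third, noise perturbation, is [perturb_observations()]).
#'
#' @param space Parameter table ([param_space()]).
#' @param schedule Management schedule ([treatment_schedule()]).
#' @param weather Weather series ([generate_weather()]).
#' @param layout Observation layout ([observation_layout()]).
#' @param seed Optional integer seed.
#' @return A list with `reference` (named parameter vector) and `noiseless`
#'   (numeric observation vector aligned to `layout`).
#' @export
generate_reference_truth <- function(space, schedule, weather, layout,
                                     seed = NULL) {
  ref <- drop(sample_prior(space, 1, seed = seed))
  fwd <- make_forward(schedule, weather, layout, space)
  list(reference = ref, noiseless = fwd(ref))
}

#' Perturb noiseless observations with Gaussian measurement error
#'
#' Adds i.i.d. `N(0, noise_sd^2)` error to each observation; the default
#' `noise_sd = 0.005` cm3/cm3 is the assumed TDR measurement error of the
#' synthetic protocol. Perturbed values are deliberately not clipped to the
#' physical range so the diagonal error covariance remains the exact error
#' model the samplers assume.
#'
#' @param noiseless Numeric vector of noiseless observations.
#' @param layout Observation layout the values are aligned to.
#' @param noise_sd Measurement error standard deviation (>= 0), cm3/cm3.
#' @param seed Optional integer seed.
#' @param reference Optional named reference parameter vector to carry along.
#' @return An `observation_set`: list with `data` (layout tibble plus
#'   columns `noiseless`, `value`), `noise_sd`, `reference`, `seed`.
#' @export
perturb_observations <- function(noiseless, layout, noise_sd = 0.005,
                                 seed = NULL, reference = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  stopifnot(length(noiseless) == nrow(layout))
  eps <- if (noise_sd == 0) {
    numeric(length(noiseless))
  } else if (is.null(seed)) {
    rnorm(length(noiseless), 0, noise_sd)
  } else {
    withr::with_seed(seed, rnorm(length(noiseless), 0, noise_sd))
  }
  data <- layout
  data$noiseless <- noiseless
  data$value <- noiseless + eps
  structure(list(data = data, noise_sd = noise_sd, reference = reference,
                 seed = seed),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d points (%d depths x %d days), noise sd %g\n",
              nrow(x$data), dplyr::n_distinct(x$data$depth_cm),
              dplyr::n_distinct(x$data$das), x$noise_sd))
  if (!is.null(x$reference)) cat("  carries a synthetic reference parameter vector\n")
  invisible(x)
}

#' Subset an observation set by role
#' @param obs An `observation_set`.
#' @param role `"calibration"` or `"validation"`; points with role
#'   `"both"` are always included.
#' @return An `observation_set` restricted to the matching rows.
#' @export
obs_subset <- function(obs, role) {
  keep <- obs$data$role %in% c(role, "both")
  out <- obs
  out$data <- obs$data[keep, ]
  out
}

#' Observed values and diagonal noise covariance of an observation set
#' @param obs An `observation_set`.
#' @return For `obs_values()` the numeric vector of (noisy) observations;
#'   for `obs_cov_diag()` the diagonal of the error covariance.
#' @export
obs_values <- function(obs) obs$data$value

#' @rdname obs_values
#' @export
obs_cov_diag <- function(obs) rep(obs$noise_sd^2, nrow(obs$data))

#' Write / read an observation set (CSV values + JSON sidecar)
#'
#' The depth-day table goes to `<path>` as CSV; seed, noise level and any
#' synthetic reference parameters go to `<path>.json`.
#'
#' @param obs An `observation_set`.
#' @param path CSV file path.
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(obs$data, path)
  meta <- list(noise_sd = obs$noise_sd, seed = obs$seed,
               reference = as.list(obs$reference))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    depth_cm = readr::col_integer(), das = readr::col_integer(),
    role = readr::col_character(), noiseless = readr::col_double(),
    value = readr::col_double()
  ))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ref <- if (length(meta$reference)) unlist(meta$reference) else NULL
  structure(list(data = data, noise_sd = meta$noise_sd,
                 reference = ref, seed = meta$seed),
            class = "observation_set")
}

#' Generate a complete synthetic observation set in one call
#'
#' Convenience wrapper chaining [generate_weather()],
#' [generate_reference_truth()] and [perturb_observations()] under one root
#' seed, reproducing the full three-step synthetic protocol.
#'
#' @inheritParams generate_reference_truth
#' @param noise_sd Measurement error sd (cm3/cm3).
#' @param seed Integer root seed.
#' @return A list with `weather`, `obs` (the `observation_set`, carrying the
#'   reference vector) and `forward` (the fast forward closure on `layout`).
#' @export
make_synthetic_case <- function(space = param_space(),
                                schedule = treatment_schedule("W1N1", 2008),
                                layout = observation_layout("synthetic"),
                                noise_sd = 0.005, seed = 1L) {
  weather <- generate_weather(schedule$season_days, seed = seed)
  truth <- generate_reference_truth(space, schedule, weather, layout,
                                    seed = seed + 1L)
  obs <- perturb_observations(truth$noiseless, layout, noise_sd,
                              seed = seed + 2L, reference = truth$reference)
  list(weather = weather, obs = obs,
       forward = make_forward(schedule, weather, layout, space))
}
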