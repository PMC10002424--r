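#' Tidy posterior summaries of a calibration result
#'
#' One row per parameter: posterior mean, sd and central 95% interval of
#' the final ensemble (or of the retained MCMC samples), plus the MAP
#' coordinate.
#'
#' @param x A `calibration_result` or `dream_result`.
#' @param level Interval coverage (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`, `map`.
#' @export
tidy.calibration_result <- function(x, level = 0.95, ...) {
  tidy_samples(result_samples(x), x$map, level)
}

#' @rdname tidy.calibration_result
#' @export
tidy.dream_result <- function(x, level = 0.95, ...) {
  tidy_samples(result_samples(x), x$map, level)
}

tidy_samples <- function(s, map, level) {
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  nm <- colnames(s) %||% paste0("p", seq_len(ncol(s)))
  tibble::tibble(
    parameter = nm,
    mean = colMeans(s),
    sd = apply(s, 2, sd),
    lower = apply(s, 2, quantile, probs = pr[1], names = FALSE),
    upper = apply(s, 2, quantile, probs = pr[2], names = FALSE),
    map = as.numeric(map)[seq_len(ncol(s))]
  )
}

#' One-row fit summary of a calibration result
#'
#' @param x A `calibration_result` or `dream_result`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_samples`, `n_obs`, `me`, `rmse`,
#'   `ia` (MAP member fit statistics) and `rmse_map`.
#' @export
glance.calibration_result <- function(x, ...) {
  fs <- fit_stats(x$map_prediction, obs_values(x$obs))
  tibble::tibble(method = x$method, n_samples = nrow(result_samples(x)),
                 n_obs = fs$n, me = fs$me, rmse = fs$rmse, ia = fs$ia,
                 rmse_map = rmse_map(x))
}

#' @rdname glance.calibration_result
#' @export
glance.dream_result <- function(x, ...) {
  fs <- fit_stats(x$map_prediction, obs_values(x$obs))
  tibble::tibble(method = paste0("DREAM", x$config$variant),
                 n_samples = nrow(result_samples(x)),
                 n_obs = fs$n, me = fs$me, rmse = fs$rmse, ia = fs$ia,
                 rmse_map = rmse_map(x), max_rhat = max(x$rhat))
}

#' Plot MAP fit with 95% uncertainty bands
#'
#' Observed soil water content against the MAP simulation per depth-day
#' point, with pointwise parameter-uncertainty and total-uncertainty bands
#' shaded, panelled by measurement depth.
#'
#' @param object A `calibration_result`.
#' @param seed Seed for the total-band noise draws.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_result <- function(object, seed = 1L, ...) {
  bands <- uncertainty_bands(object$predictions, object$obs$data,
                             object$obs$noise_sd, seed = seed)
  bands$observed <- obs_values(object$obs)
  bands$map <- object$map_prediction
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$das)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$total_lo,
                                      ymax = .data$total_hi),
                         fill = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$param_lo,
                                      ymax = .data$param_hi),
                         fill = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$map), colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "red",
                        size = 0.8) +
    ggplot2::facet_wrap(~depth_cm, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "day after sowing",
                  y = expression(theta ~ (cm^3 / cm^3)),
                  title = sprintf("%s MAP fit with 95%% uncertainty bands",
                                  object$method))
}

#' Plot the RMSE evolution of one or more results
#'
#' @param ... Named `calibration_result` / `dream_result` objects.
#' @param threshold Optional horizontal reference line.
#' @return A ggplot object.
#' @export
plot_rmse_evolution <- function(..., threshold = NULL) {
  results <- list(...)
  nm <- names(results) %||% paste0("run", seq_along(results))
  df <- purrr::map2_dfr(results, nm, function(r, n) {
    out <- rmse_evolution(r)
    out$run <- n
    out
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$rmse,
                                        colour = .data$run,
                                        group = interaction(.data$run,
                                                            .data$chain))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation / iteration", y = "RMSE (cm3/cm3)")
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "red")
  p
}

#' Plot posterior marginal densities
#'
#' @param samples Posterior sample matrix ([result_samples()]).
#' @param parameters Optional subset of parameter names.
#' @return A ggplot object (histogram panels per parameter).
#' @export
plot_marginals <- function(samples, parameters = NULL) {
  tbl <- summarize_marginals(samples)
  if (!is.null(parameters)) tbl <- dplyr::filter(tbl, .data$parameter %in% parameters)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = NA, fill = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "posterior density")
}
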