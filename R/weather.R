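#' Generate a seeded arid-site daily weather series
#'
#' Emulates the weather regime of an extremely arid irrigated oasis:
#' roughly 116 mm of precipitation per year concentrated in sparse summer
#' events, with potential evaporation about twenty times the precipitation.
#' Over a 189-day growing season the generator places 16 wet days at random
#' and draws event depths from a Gamma(4, 1) (mean 4 mm), giving an expected
#' seasonal total near 64 mm — the warm-season share of the annual 116 mm.
#' Reference evapotranspiration follows a smooth seasonal cycle (mean about
#' 6 mm/d, peaking in midsummer) plus small day-to-day noise, so cumulative
#' ET0 is roughly 20 x cumulative precipitation. Daily mean temperature is a
#' continental sinusoid (about 10 degC at April sowing, 26 degC in late
#' July) with noise; it drives growing-degree-day accumulation in the crop
#' model (base temperature 8 degC).
#'
#' @param n_days Number of days to generate (day 1 = sowing day; >= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `day`, `precip_mm`, `et0_mm`, `tmean_c`.
#' @export
generate_weather <- function(n_days = 189, seed = NULL) {
  stopifnot(n_days >= 1)
  gen <- function() {
    day <- seq_len(n_days)
    doy <- 102 + day - 1                       # sowing = April 12 (doy 102)
    season <- sin(2 * pi * (doy - 110) / 365)  # peak near July 20
    tmean <- 12 + 14 * season + rnorm(n_days, 0, 1.5)

    precip <- numeric(n_days)
    n_wet <- max(1L, round(16 * n_days / 189))
    wet <- sample.int(n_days, min(n_wet, n_days))
    precip[wet] <- stats::rgamma(length(wet), shape = 4, rate = 1)

    et0 <- pmax(0.5, 5.5 + 2.5 * season + rnorm(n_days, 0, 0.4))

    tibble::tibble(day = day, precip_mm = precip, et0_mm = et0,
                   tmean_c = tmean)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Read / write a weather series as CSV
#' @param weather Weather tibble from [generate_weather()].
#' @param path File path.
#' @export
write_weather <- function(weather, path) {
  readr::write_csv(weather, path)
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    day = readr::col_integer(), precip_mm = readr::col_double(),
    et0_mm = readr::col_double(), tmean_c = readr::col_double()
  ))
}
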