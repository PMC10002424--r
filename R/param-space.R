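#' The default 45-parameter calibration space
#'
#' Builds the parameter table the whole package is indexed against: 32 soil
#' hydraulic parameters (saturated conductivity `Ks`, saturated water content
#' `SAT`, field capacity `FC` and wilting point `PWP` for each of 8 soil
#' layers over a 180 cm profile), 5 nitrogen transformation parameters
#' (`Vn`, `Kn`, `Kd`, `Ad`, `Kv`) and 8 crop parameters (`Kini`, `Kmid`,
#' `Kend`, `Tsum`, `SLAmax`, `SLAmin`, `AMAX`, `Rmax`), each with a uniform
#' prior over a published calibration interval.
#'
#' The row order is canonical and defines the index semantics of every
#' parameter vector, ensemble matrix and MCMC chain in the package:
#' hydraulic parameters grouped per layer as (Ks, SAT, FC, PWP) for layers
#' 1..8, then the nitrogen block, then the crop block.
#'
#' @return A tibble with 45 rows and columns `name`, `symbol`, `layer`
#'   (integer, `NA` for non-hydraulic parameters), `unit`, `lower`, `upper`.
#' @examples
#' sp <- param_space()
#' nrow(sp)
#' dplyr::filter(sp, symbol == "Ks", layer == 1)
#' @export
param_space <- function() {
  hyd <- list(
    # layer   Ks_lo  Ks_hi  SAT_lo SAT_hi FC_lo FC_hi PWP_lo PWP_hi
    c(1, 56.59, 69.17, 0.30, 0.36, 0.20, 0.25, 0.11, 0.13),
    c(2, 72.58, 88.70, 0.32, 0.40, 0.18, 0.22, 0.09, 0.12),
    c(3, 46.22, 56.50, 0.32, 0.40, 0.18, 0.22, 0.08, 0.10),
    c(4, 63.50, 77.62, 0.23, 0.29, 0.18, 0.22, 0.06, 0.08),
    c(5, 29.81, 36.43, 0.26, 0.31, 0.16, 0.19, 0.06, 0.08),
    c(6, 31.10, 38.02, 0.24, 0.30, 0.15, 0.18, 0.04, 0.06),
    c(7, 37.37, 45.67, 0.23, 0.28, 0.14, 0.18, 0.04, 0.06),
    c(8, 56.38, 68.90, 0.22, 0.26, 0.10, 0.13, 0.06, 0.08)
  )
  hyd_tbl <- purrr::map_dfr(hyd, function(r) {
    tibble::tibble(
      name   = paste0(c("Ks", "SAT", "FC", "PWP"), "_", r[1]),
      symbol = c("Ks", "SAT", "FC", "PWP"),
      layer  = as.integer(r[1]),
      unit   = c("cm/d", "cm3/cm3", "cm3/cm3", "cm3/cm3"),
      lower  = r[c(2, 4, 6, 8)],
      upper  = r[c(3, 5, 7, 9)]
    )
  })
  other <- tibble::tribble(
    ~name,     ~symbol,  ~unit,        ~lower, ~upper,
    "Vn",      "Vn",     "g/(m3.d)",    5,      15,
    "Kn",      "Kn",     "g/m3",        25,     75,
    "Kd",      "Kd",     "-",           0.50,   1.50,
    "Ad",      "Ad",     "-",           0.05,   0.15,
    "Kv",      "Kv",     "1/d",         0.015,  0.045,
    "Kini",    "Kini",   "-",           0.36,   0.54,
    "Kmid",    "Kmid",   "-",           1.0,    1.5,
    "Kend",    "Kend",   "-",           0.64,   0.96,
    "Tsum",    "Tsum",   "degC.d",      1480,   2220,
    "SLAmax",  "SLAmax", "m2/kg",       24,     36,
    "SLAmin",  "SLAmin", "m2/kg",       8,      12,
    "AMAX",    "AMAX",   "kg/(hm2.h)",  36,     54,
    "Rmax",    "Rmax",   "cm",          96,     144
  )
  other$layer <- NA_integer_
  out <- dplyr::bind_rows(hyd_tbl, other[, c("name", "symbol", "layer",
                                             "unit", "lower", "upper")])
  stopifnot(nrow(out) == 45L, !anyDuplicated(out$name), all(out$lower < out$upper))
  out
}

#' Sample parameter vectors from the uniform prior
#'
#' Draws `n` independent parameter vectors, each coordinate i.i.d. uniform
#' within its `[lower, upper]` interval.
#'
#' @param space Parameter table as returned by [param_space()].
#' @param n Number of draws (>= 0).
#' @param seed Optional integer seed; the draw is reproducible given the seed
#'   and leaves the global RNG state untouched.
#' @return An `n` x `nrow(space)` numeric matrix with columns named by
#'   `space$name`.
#' @export
sample_prior <- function(space, n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  n <- as.integer(n)
  d <- nrow(space)
  draw <- function() {
    u <- matrix(runif(n * d), nrow = n, ncol = d)
    m <- sweep(u, 2, space$upper - space$lower, `*`)
    m <- sweep(m, 2, space$lower, `+`)
    colnames(m) <- space$name
    m
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Export / import a parameter space as CSV
#'
#' @param space Parameter table.
#' @param path File path.
#' @return `read_param_space()` returns the parameter tibble;
#'   `write_param_space()` returns `path` invisibly.
#' @export
write_param_space <- function(space, path) {
  readr::write_csv(space, path)
  invisible(path)
}

#' @rdname write_param_space
#' @export
read_param_space <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(), symbol = readr::col_character(),
    layer = readr::col_integer(), unit = readr::col_character(),
    lower = readr::col_double(), upper = readr::col_double()
  ))
}

#' Management schedule for one treatment-year
#'
#' Returns the flood-irrigation and urea-N fertilization events of the four
#' spring maize treatments: two irrigation regimes (standard `W1` = Istd,
#' five events of 150 mm; water-saving `W2` = Icsv, events of 105, 105, 120,
#' 120, 120 mm) crossed with two fertilization rates (`N1` = Nstd, 138 kg
#' urea-N/ha; `N2` = Ncsv, 92 kg), applied at the first scheduled date.
#' Sowing is April 12 and harvest October 18 (a 189-day season); event dates
#' are also given as days after sowing (`das`, sowing = day 0).
#'
#' @param treatment One of `"W1N1"`, `"W1N2"`, `"W2N1"`, `"W2N2"`.
#' @param year 2008 or 2009 (the two field seasons; event dates differ).
#' @return A list of class `management_schedule` with elements `treatment`,
#'   `year`, `sowing`, `harvest`, `season_days` and `events` (a tibble with
#'   columns `date`, `das`, `kind`, `amount`, `unit`).
#' @export
treatment_schedule <- function(treatment = c("W1N1", "W1N2", "W2N1", "W2N2"),
                               year = 2008) {
  if (!is.character(treatment) || !treatment[1] %in% c("W1N1", "W1N2", "W2N1", "W2N2"))
    stop("unknown treatment code: ", treatment[1], call. = FALSE)
  treatment <- treatment[1]
  if (!year %in% c(2008, 2009)) stop("year must be 2008 or 2009", call. = FALSE)

  sowing  <- as.Date(sprintf("%d-04-12", year))
  harvest <- as.Date(sprintf("%d-10-18", year))
  dates <- if (year == 2008) {
    as.Date(c("2008-06-03", "2008-06-21", "2008-07-13", "2008-08-04", "2008-08-29"))
  } else {
    as.Date(c("2009-06-01", "2009-06-22", "2009-07-13", "2009-08-01", "2009-08-23"))
  }
  irr <- if (substr(treatment, 1, 2) == "W1") rep(150, 5) else c(105, 105, 120, 120, 120)
  nfert <- if (substr(treatment, 3, 4) == "N1") 138 else 92

  events <- dplyr::bind_rows(
    tibble::tibble(date = dates, kind = "irrigation", amount = irr, unit = "mm"),
    tibble::tibble(date = dates[1], kind = "fertilization", amount = nfert,
                   unit = "kg N/ha")
  )
  events$das <- as.integer(events$date - sowing)
  events <- events[, c("date", "das", "kind", "amount", "unit")]
  stopifnot(all(events$date >= sowing & events$date <= harvest))

  structure(list(treatment = treatment, year = year, sowing = sowing,
                 harvest = harvest,
                 season_days = as.integer(harvest - sowing),
                 events = events),
            class = "management_schedule")
}

#' @export
print.management_schedule <- function(x, ...) {
  cat(sprintf("<management_schedule> %s, %d (%s to %s, %d days)\n",
              x$treatment, x$year, format(x$sowing), format(x$harvest),
              x$season_days))
  tot <- dplyr::summarise(dplyr::group_by(x$events, .data$kind),
                          total = sum(.data$amount))
  print(x$events, ...)
  cat(sprintf("totals: irrigation %g mm, fertilization %g kg N/ha\n",
              tot$total[tot$kind == "irrigation"],
              tot$total[tot$kind == "fertilization"]))
  invisible(x)
}

#' Export a management schedule as CSV
#' @param schedule A `management_schedule`.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule$events[, c("date", "kind", "amount", "unit")], path)
  invisible(path)
}

#' Observation layout: depths, days and calibration/validation roles
#'
#' Soil water content is observed by TDR every 10 cm from 20 to 170 cm depth
#' on 17 fixed days after sowing. The synthetic design uses all 16 depths
#' with every point serving both roles (272 points). The practical design
#' calibrates on depths 20..160 by 20 cm (8 depths, 136 points) and
#' validates on 30, 50, 70, 90, 110, 130 and 170 cm (7 depths, 119 points);
#' 150 cm is unused.
#'
#' @param case `"synthetic"` or `"practical"`.
#' @return A tibble with one row per observation point: columns `depth_cm`,
#'   `das` (day after sowing) and `role` (`"both"`, `"calibration"` or
#'   `"validation"`).
#' @export
observation_layout <- function(case = c("synthetic", "practical")) {
  case <- match.arg(case)
  days <- obs_days()
  if (case == "synthetic") {
    depths <- seq(20L, 170L, by = 10L)
    role <- rep("both", length(depths))
  } else {
    cal <- seq(20L, 160L, by = 20L)
    val <- c(30L, 50L, 70L, 90L, 110L, 130L, 170L)
    depths <- c(cal, val)
    role <- c(rep("calibration", length(cal)), rep("validation", length(val)))
  }
  out <- tidyr::expand_grid(
    tibble::tibble(depth_cm = depths, role = role),
    das = days
  )
  dplyr::arrange(out[, c("depth_cm", "das", "role")], .data$depth_cm, .data$das)
}

#' The 17 TDR measurement days (days after sowing)
#' @return Integer vector of length 17.
#' @export
obs_days <- function() {
  c(41L, 52L, 54L, 63L, 70L, 74L, 82L, 91L, 95L, 104L, 109L, 115L,
    124L, 135L, 146L, 154L, 160L)
}

#' Map a measurement depth to its soil layer
#'
#' The 180 cm profile is divided into 8 equal layers of 22.5 cm; a depth
#' `d` cm belongs to the layer whose interval contains it (depths on a
#' boundary belong to the layer above).
#'
#' @param depth_cm Numeric vector of depths in (0, 180].
#' @return Integer layer indices in 1..8.
#' @export
depth_to_layer <- function(depth_cm) {
  stopifnot(all(depth_cm > 0), all(depth_cm <= 180))
  pmin(8L, as.integer(ceiling(depth_cm / 22.5)))
}
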