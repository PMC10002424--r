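#' FAO-56-style piecewise-linear crop coefficient curve
#'
#' Phenology is indexed by accumulated growing degree days relative to the
#' crop's thermal requirement `Tsum`: the coefficient holds at `Kini` over
#' the initial 20% of `Tsum`, rises linearly to `Kmid` by 45%, plateaus to
#' 75%, falls linearly to `Kend` at `Tsum` and stays at `Kend` beyond.
#'
#' @param gdd Accumulated growing degree days (>= 0), vectorised.
#' @param Tsum Thermal time from emergence to maturity, degC d (> 0).
#' @param Kini,Kmid,Kend Stage crop coefficients (dimensionless).
#' @return Crop coefficient, same length as `gdd`.
#' @export
crop_coefficient <- function(gdd, Tsum, Kini, Kmid, Kend) {
  if (!is.numeric(Tsum) || Tsum <= 0) stop("Tsum must be positive", call. = FALSE)
  stopifnot(all(gdd >= 0))
  u <- gdd / Tsum
  out <- numeric(length(u))
  out[u <= 0.2] <- Kini
  i <- u > 0.2 & u < 0.45
  out[i] <- Kini + (Kmid - Kini) * (u[i] - 0.2) / 0.25
  i <- u >= 0.45 & u <= 0.75
  out[i] <- Kmid
  i <- u > 0.75 & u < 1
  out[i] <- Kmid + (Kend - Kmid) * (u[i] - 0.75) / 0.25
  out[u >= 1] <- Kend
  out
}

#' One explicit daily step of the soil nitrogen pools
#'
#' Bulk ammonium/nitrate bookkeeping with three first-order style fluxes:
#' Michaelis-Menten nitrification `Vn * nh4 / (Kn + nh4)`, first-order
#' ammonia volatilization `Kv * nh4`, and denitrification
#' `Kd * Ad * no3 * s(theta)` where the moisture switch `s` is 0 below field
#' capacity and rises linearly to 1 at saturation. Fluxes are capped so
#' pools never go negative (nitrification + volatilization are scaled down
#' proportionally if they would overdraw ammonium). The nitrogen state has
#' no feedback on the water balance.
#'
#' @param nh4,no3 Pool concentrations, g/m3 (>= 0).
#' @param theta Volumetric water content of the layer, cm3/cm3.
#' @param params Named vector or list with `Vn`, `Kn`, `Kd`, `Ad`, `Kv`.
#' @param fc,sat Field capacity and saturation of the layer, cm3/cm3.
#' @return A list with updated `nh4`, `no3` and the realised daily fluxes
#'   `nitrification`, `volatilization`, `denitrification`.
#' @export
nitrogen_step <- function(nh4, no3, theta, params, fc, sat) {
  if (nh4 < 0 || no3 < 0) stop("nitrogen pools must be non-negative", call. = FALSE)
  p <- as.list(params)
  nitr <- p$Vn * nh4 / (p$Kn + nh4)
  vol <- p$Kv * nh4
  out_nh4 <- nitr + vol
  if (out_nh4 > nh4 && out_nh4 > 0) {           # cap at pool size
    scale <- nh4 / out_nh4
    nitr <- nitr * scale
    vol <- vol * scale
  }
  s <- if (theta <= fc) 0 else min(1, (theta - fc) / (sat - fc))
  denit <- min(p$Kd * p$Ad * no3 * s, no3 + nitr)
  list(nh4 = nh4 - nitr - vol,
       no3 = max(0, no3 + nitr - denit),
       nitrification = nitr, volatilization = vol, denitrification = denit)
}

#' Run the layered tipping-bucket water balance
#'
#' Low-level driver around the compiled daily loop; [simulate_swc()] is the
#' high-level interface for the 45-parameter space. Exposed separately so
#' small hand-checkable profiles (e.g. a single layer) can be driven
#' directly.
#'
#' @param profile List with numeric vectors `thick_cm`, `Ks`, `SAT`, `FC`,
#'   `PWP` (one entry per layer) and optionally `theta0` (defaults to `FC`).
#' @param water_in_cm Daily water input (precipitation + irrigation), cm.
#' @param evap_cm,transp_cm Daily potential evaporation / transpiration, cm.
#' @param root_depth_cm Daily rooting depth, cm (0 disables transpiration).
#' @return A list with matrix `theta` (day x layer) and daily vectors
#'   `runoff`, `drainage`, `et_act`, `storage` (all cm).
#' @export
water_balance <- function(profile, water_in_cm,
                          evap_cm = rep(0, length(water_in_cm)),
                          transp_cm = rep(0, length(water_in_cm)),
                          root_depth_cm = rep(0, length(water_in_cm))) {
  nl <- length(profile$thick_cm)
  stopifnot(length(profile$Ks) == nl, length(profile$SAT) == nl,
            length(profile$FC) == nl, length(profile$PWP) == nl)
  if (any(profile$PWP <= 0) || any(profile$PWP >= profile$FC) ||
      any(profile$FC >= profile$SAT) || any(profile$SAT >= 1))
    stop_invalid_params("soil profile must satisfy 0 < PWP < FC < SAT < 1")
  theta0 <- profile$theta0 %||% profile$FC
  .water_balance_cpp(as.numeric(profile$thick_cm), as.numeric(profile$Ks),
                     as.numeric(profile$SAT), as.numeric(profile$FC),
                     as.numeric(profile$PWP), as.numeric(theta0),
                     as.numeric(water_in_cm), as.numeric(evap_cm),
                     as.numeric(transp_cm), as.numeric(root_depth_cm))
}

stop_invalid_params <- function(msg) {
  stop(structure(class = c("soilcalib_invalid_params", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a named 45-vector into the blocks the simulator consumes.
bind_params <- function(params, space) {
  if (is.null(names(params)) || !all(space$name %in% names(params))) {
    stopifnot(length(params) == nrow(space))
    names(params) <- space$name
  }
  hyd <- function(sym) unname(params[paste0(sym, "_", 1:8)])
  list(Ks = hyd("Ks"), SAT = hyd("SAT"), FC = hyd("FC"), PWP = hyd("PWP"),
       nitro = params[c("Vn", "Kn", "Kd", "Ad", "Kv")],
       crop = params[c("Kini", "Kmid", "Kend", "Tsum", "SLAmax", "SLAmin",
                       "AMAX", "Rmax")])
}

#' Simulate daily soil water content for one season
#'
#' The forward operator `f(m)` of the calibration problem: a deterministic
#' daily soil-crop surrogate over an 8-layer, 180 cm profile. Water is
#' routed by a tipping-bucket cascade (drainage of storage above field
#' capacity, capped by `Ks`; super-saturated topsoil sheds runoff), crop
#' evapotranspiration follows `Kc(gdd) * ET0` partitioned 30% soil
#' evaporation / 70% transpiration over a root zone that deepens linearly
#' with thermal time to `Rmax`, and transpiration demand carries a bounded
#' leaf-area proxy multiplier `max(0.5, AMAX * SLAmax / (54 * 36))`.
#' Profile moisture starts at field capacity on the sowing day. Nitrogen
#' pools (initialised at 5 g/m3 ammonium, 20 g/m3 nitrate, fertilizer added
#' on its scheduled day) are stepped daily in topsoil but have no feedback
#' on water — soil water content observations are insensitive to the five
#' nitrogen parameters by construction.
#'
#' @param params Numeric vector of length 45 aligned to [param_space()]
#'   (names optional).
#' @param schedule A [treatment_schedule()].
#' @param weather Weather tibble covering the season ([generate_weather()]).
#' @param layout Observation layout tibble ([observation_layout()]).
#' @param space Parameter table; defaults to [param_space()].
#' @param nitrogen Track nitrogen pools (`TRUE`) or skip them for speed.
#' @return A list of class `simulation_result` with `theta` (long tibble
#'   `day`, `layer`, `theta`), `observed` (numeric vector aligned to
#'   `layout` rows), `ledger` (daily water balance tibble) and, if
#'   requested, `nitrogen` (daily pool tibble).
#' @export
simulate_swc <- function(params, schedule, weather, layout,
                         space = param_space(), nitrogen = TRUE) {
  fwd <- make_forward(schedule, weather, layout, space,
                      detail = TRUE, nitrogen = nitrogen)
  fwd(params)
}

#' Build a fast forward-model closure
#'
#' Pre-computes everything that does not depend on the parameter vector
#' (irrigation series, thermal time, observation index map) and returns a
#' function mapping a 45-parameter vector to the observation vector —
#' the form the samplers consume. With `detail = TRUE` the closure returns
#' the full `simulation_result` instead.
#'
#' @inheritParams simulate_swc
#' @param detail Return the full result instead of the observation vector.
#' @return A function of one parameter vector.
#' @export
make_forward <- function(schedule, weather, layout, space = param_space(),
                         detail = FALSE, nitrogen = FALSE) {
  n_days <- max(c(layout$das, schedule$events$das, 1L))
  n_days <- max(n_days, min(nrow(weather), schedule$season_days))
  if (nrow(weather) < n_days)
    stop("weather series shorter than the simulation horizon", call. = FALSE)

  precip_cm <- weather$precip_mm[seq_len(n_days)] / 10
  irrig_cm <- numeric(n_days)
  irr <- dplyr::filter(schedule$events, .data$kind == "irrigation")
  irrig_cm[irr$das] <- irrig_cm[irr$das] + irr$amount / 10
  water_in <- precip_cm + irrig_cm
  et0_cm <- weather$et0_mm[seq_len(n_days)] / 10
  gdd <- cumsum(pmax(0, weather$tmean_c[seq_len(n_days)] - 8))
  fert <- dplyr::filter(schedule$events, .data$kind == "fertilization")

  obs_idx <- cbind(layout$das, depth_to_layer(layout$depth_cm))
  thick <- rep(22.5, 8)

  function(params) {
    b <- bind_params(params, space)
    if (any(b$PWP <= 0) || any(b$PWP >= b$FC) || any(b$FC >= b$SAT) ||
        any(b$SAT >= 1))
      stop_invalid_params("parameter vector violates 0 < PWP < FC < SAT < 1")
    cp <- b$crop
    kc <- crop_coefficient(gdd, cp[["Tsum"]], cp[["Kini"]], cp[["Kmid"]],
                           cp[["Kend"]])
    lai_mult <- max(0.5, cp[["AMAX"]] * cp[["SLAmax"]] / (54 * 36))
    etc <- kc * et0_cm
    evap <- 0.3 * etc
    transp <- 0.7 * etc * lai_mult
    root <- pmin(1, gdd / cp[["Tsum"]]) * cp[["Rmax"]]

    wb <- .water_balance_cpp(thick, b$Ks, b$SAT, b$FC, b$PWP, b$FC,
                             water_in, evap, transp, root)
    obs <- wb$theta[obs_idx]
    if (!detail) return(obs)

    theta_tbl <- tibble::tibble(
      day = rep(seq_len(n_days), times = 8),
      layer = rep(1:8, each = n_days),
      theta = as.vector(wb$theta)
    )
    storage0 <- sum(b$FC * thick)
    ledger <- tibble::tibble(
      day = seq_len(n_days), precip_cm = precip_cm, irrigation_cm = irrig_cm,
      et_cm = wb$et_act, drainage_cm = wb$drainage, runoff_cm = wb$runoff,
      storage_cm = wb$storage,
      dstorage_cm = wb$storage - c(storage0, wb$storage[-n_days])
    )
    res <- list(theta = theta_tbl, observed = obs, ledger = ledger,
                params = setNames(as.numeric(params)[seq_len(nrow(space))],
                                  space$name))
    if (nitrogen) {
      nh4 <- 5; no3 <- 20
      th1 <- wb$theta[, 1]
      pools <- matrix(0, n_days, 2)
      for (t in seq_len(n_days)) {
        if (t %in% fert$das)  # urea-N enters the ammonium pool, 1 g/m3 per 10 kg/ha
          nh4 <- nh4 + sum(fert$amount[fert$das == t]) / 10
        st <- nitrogen_step(nh4, no3, th1[t], b$nitro, b$FC[1], b$SAT[1])
        nh4 <- st$nh4; no3 <- st$no3
        pools[t, ] <- c(nh4, no3)
      }
      res$nitrogen <- tibble::tibble(day = seq_len(n_days),
                                     nh4 = pools[, 1], no3 = pools[, 2])
    }
    class(res) <- "simulation_result"
    res
  }
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d days x 8 layers, %d observation points\n",
              max(x$theta$day), length(x$observed)))
  cat(sprintf("  seasonal: in %.1f cm, ET %.1f cm, drainage %.1f cm, runoff %.1f cm\n",
              sum(x$ledger$precip_cm + x$ledger$irrigation_cm),
              sum(x$ledger$et_cm), sum(x$ledger$drainage_cm),
              sum(x$ledger$runoff_cm)))
  invisible(x)
}

#' Export simulated soil water content in long CSV form
#' @param result A `simulation_result`.
#' @param layout The observation layout the result was extracted on.
#' @param path File path.
#' @export
write_simulation <- function(result, layout, path) {
  out <- layout
  out$theta <- result$observed
  readr::write_csv(out, path)
  invisible(path)
}
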