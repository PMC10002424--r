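test_that("crop coefficient curve hits its stage values", {
  expect_equal(crop_coefficient(0, 1800, 0.4, 1.2, 0.8), 0.4)
  expect_equal(crop_coefficient(0.2 * 1800, 1800, 0.4, 1.2, 0.8), 0.4)
  expect_equal(crop_coefficient(0.6 * 1800, 1800, 0.4, 1.2, 0.8), 1.2)
  expect_equal(crop_coefficient(1800, 1800, 0.4, 1.2, 0.8), 0.8)
  expect_equal(crop_coefficient(3000, 1800, 0.4, 1.2, 0.8), 0.8)
  # midpoint of the rise
  expect_equal(crop_coefficient(0.325 * 1800, 1800, 0.4, 1.2, 0.8), 0.8)
  expect_error(crop_coefficient(100, 0, 0.4, 1.2, 0.8), "Tsum")
})

test_that("nitrogen step follows Michaelis-Menten and the moisture switch", {
  p <- c(Vn = 10, Kn = 50, Kd = 1, Ad = 0.1, Kv = 0.02)
  # half-saturation: nh4 = Kn gives nitrification Vn/2
  st <- nitrogen_step(nh4 = 50, no3 = 20, theta = 0.15, p, fc = 0.2, sat = 0.35)
  expect_equal(st$nitrification, 5)
  expect_equal(st$volatilization, 0.02 * 50)
  expect_equal(st$denitrification, 0)      # theta below FC
  # zero ammonium pool: no ammonium fluxes
  st0 <- nitrogen_step(0, 20, 0.3, p, fc = 0.2, sat = 0.35)
  expect_equal(st0$nitrification, 0)
  expect_equal(st0$volatilization, 0)
  # saturation-excess switch: linear between FC and SAT
  st1 <- nitrogen_step(10, 20, 0.275, p, fc = 0.2, sat = 0.35)
  expect_equal(st1$denitrification, 1 * 0.1 * 20 * 0.5)
  # pools can never be driven negative
  p2 <- c(Vn = 100, Kn = 1, Kd = 5, Ad = 1, Kv = 2)
  st2 <- nitrogen_step(3, 1, 0.35, p2, fc = 0.2, sat = 0.35)
  expect_gte(st2$nh4, 0)
  expect_gte(st2$no3, 0)
  expect_error(nitrogen_step(-1, 0, 0.2, p, 0.2, 0.35), "non-negative")
})

test_that("single-layer water balance matches a hand-stepped recurrence", {
  prof <- list(thick_cm = 22.5, Ks = 50, SAT = 0.4, FC = 0.3, PWP = 0.1)
  rain <- c(1, 0, 0, 0, 0)                 # 10 mm on day 1, then dry
  wb <- water_balance(prof, rain)
  # independent plain-R oracle for the same rules
  th <- 0.3; exp_theta <- exp_drain <- numeric(5)
  for (t in 1:5) {
    th <- min(0.4, th + rain[t] / 22.5)
    ex <- (th - 0.3) * 22.5
    d <- if (ex > 0) min(ex * (50 / (50 + 22.5)) * min(1, (th - 0.3) / 0.1), 50) else 0
    th <- th - d / 22.5
    exp_theta[t] <- th; exp_drain[t] <- d
  }
  expect_equal(drop(wb$theta), exp_theta, tolerance = 1e-12)
  expect_equal(wb$drainage, exp_drain, tolerance = 1e-12)
  expect_equal(wb$runoff, rep(0, 5))
  # all input water is accounted for
  expect_equal(sum(rain), sum(wb$drainage) + (wb$storage[5] - 0.3 * 22.5),
               tolerance = 1e-12)
})

test_that("drying limit: without input, storage never increases and theta >= 0", {
  sp <- param_space()
  sch <- treatment_schedule("W1N1", 2008)
  w <- generate_weather(189, seed = 4)
  w$precip_mm[] <- 0
  sch$events <- sch$events[sch$events$kind != "irrigation", ]
  lay <- observation_layout("synthetic")
  p <- drop(sample_prior(sp, 1, seed = 11))
  sim <- simulate_swc(p, sch, w, lay)
  expect_true(all(diff(sim$ledger$storage_cm) <= 1e-12))
  expect_true(all(sim$theta$theta >= 0))
})

test_that("simulation is deterministic and conserves water to 1e-9 cm", {
  sp <- param_space()
  sch <- treatment_schedule("W2N1", 2008)
  w <- generate_weather(189, seed = 2)
  lay <- observation_layout("synthetic")
  fwd <- make_forward(sch, w, lay)
  for (s in 1:3) {
    p <- drop(sample_prior(sp, 1, seed = 20 + s))
    expect_identical(fwd(p), fwd(p))     # bit-identical reruns
    sim <- simulate_swc(p, sch, w, lay)
    bal <- with(sim$ledger,
                precip_cm + irrigation_cm - et_cm - drainage_cm - runoff_cm -
                  dstorage_cm)
    expect_lt(max(abs(bal)), 1e-9)
    sat <- rep(sim$params[paste0("SAT_", 1:8)], each = 189)
    expect_true(all(sim$theta$theta <= sat + 1e-12))
    expect_true(all(sim$theta$theta >= 0))
  }
})

test_that("adding an irrigation event never decreases later profile storage", {
  sp <- param_space()
  w <- generate_weather(189, seed = 3)
  lay <- observation_layout("synthetic")
  base <- treatment_schedule("W2N1", 2008)
  extra <- base
  extra$events <- dplyr::bind_rows(
    extra$events,
    tibble::tibble(date = as.Date("2008-07-25"), das = 104L,
                   kind = "irrigation", amount = 50, unit = "mm"))
  for (s in 1:3) {
    p <- drop(sample_prior(sp, 1, seed = 30 + s))
    s0 <- simulate_swc(p, base, w, lay)$ledger$storage_cm
    s1 <- simulate_swc(p, extra, w, lay)$ledger$storage_cm
    expect_true(all(s1 - s0 >= -1e-9))
  }
})

test_that("water observations are bit-insensitive to nitrogen parameters", {
  sp <- param_space()
  sch <- treatment_schedule("W1N1", 2008)
  w <- generate_weather(189, seed = 5)
  lay <- observation_layout("synthetic")
  fwd <- make_forward(sch, w, lay)
  p <- drop(sample_prior(sp, 1, seed = 41))
  base <- fwd(p)
  for (nm in c("Vn", "Kn", "Kd", "Ad", "Kv")) {
    p2 <- p
    j <- which(sp$name == nm)
    p2[j] <- sp$lower[j]
    expect_identical(fwd(p2), base)
  }
  # but nitrogen parameters do drive the nitrogen pools
  p3 <- p; p3[which(sp$name == "Vn")] <- sp$lower[sp$name == "Vn"]
  n1 <- simulate_swc(p, sch, w, lay)$nitrogen
  n2 <- simulate_swc(p3, sch, w, lay)$nitrogen
  expect_false(isTRUE(all.equal(n1$no3, n2$no3)))
})

test_that("non-physical parameter vectors are rejected with a typed error", {
  sp <- param_space()
  sch <- treatment_schedule("W1N1", 2008)
  w <- generate_weather(189, seed = 6)
  fwd <- make_forward(sch, w, observation_layout("synthetic"))
  p <- drop(sample_prior(sp, 1, seed = 50))
  p["FC_3"] <- p["SAT_3"] + 0.05           # FC above SAT
  expect_error(fwd(p), class = "soilcalib_invalid_params")
})

test_that("one season simulates in well under 10 ms", {
  sp <- param_space()
  sch <- treatment_schedule("W1N1", 2008)
  w <- generate_weather(189, seed = 7)
  fwd <- make_forward(sch, w, observation_layout("synthetic"))
  p <- drop(sample_prior(sp, 1, seed = 60))
  fwd(p)  # warm up
  dt <- system.time(for (i in 1:100) fwd(p))[["elapsed"]] / 100
  expect_lt(dt, 0.01)
})
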