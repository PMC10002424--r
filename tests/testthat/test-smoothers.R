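test_that("kalman gain: degenerate and scalar cases", {
  # identical members: zero covariance, zero gain
  M <- matrix(2, nrow = 5, ncol = 2)
  D <- matrix(1, nrow = 5, ncol = 3)
  expect_equal(kalman_gain(M, D, 0.1), matrix(0, 2, 3))
  # infinite-noise limit: gain vanishes
  M2 <- matrix(rnorm(40), ncol = 2)
  D2 <- M2 %*% t(matrix(rnorm(6), ncol = 2))
  expect_lt(max(abs(kalman_gain(M2, D2, 1e12))), 1e-8)
  # scalar identity model on a 3-member ensemble: K = v / (v + r)
  m <- matrix(c(1, 2, 3), ncol = 1)
  v <- var(c(1, 2, 3))
  r <- 0.5
  expect_equal(drop(kalman_gain(m, m, r)), v / (v + r), tolerance = 1e-6)
})

test_that("es_update matches the analytic linear-Gaussian posterior", {
  toy <- linear_gaussian_toy()
  ne <- 2000
  withr::with_seed(101, {
    M <- rmvn(ne, toy$mu0, toy$S0)
    D <- t(apply(M, 1, toy$forward))
    up <- es_update(toy$forward, M, D, toy$obs, seed = 102)
  })
  se_mean <- sqrt(diag(toy$S_post) / ne)
  expect_true(all(abs(colMeans(up$M) - toy$mu_post) < 3 * se_mean))
  # covariance agrees loosely (sampling error of second moments)
  expect_equal(cov(up$M), toy$S_post, tolerance = 0.15)
})

test_that("zero-innovation members are not moved by the update", {
  toy <- linear_gaussian_toy()
  # all members already reproduce the data, and perturbed obs = d (sd -> 0)
  th0 <- drop(solve(toy$H[c(1, 2), ], toy$dobs[c(1, 2)]))
  M <- matrix(rep(th0, 10), ncol = 2, byrow = TRUE) +
    matrix(rnorm(20, 0, 1e-12), ncol = 2)
  D <- t(apply(M, 1, toy$forward))
  ob <- exact_obs(toy$forward(th0), 1e-15)
  up <- es_update(toy$forward, M, D, ob, seed = 5)
  expect_equal(up$M, M, tolerance = 1e-6)
})

test_that("a one-step MDA schedule is bitwise a single ES update", {
  toy <- linear_gaussian_toy()
  withr::with_seed(201, {
    M <- rmvn(300, toy$mu0, toy$S0)
  })
  D <- t(apply(M, 1, toy$forward))
  one <- es_update(toy$forward, M, D, toy$obs, seed = 77)
  mda <- esmda(toy$forward, M, toy$obs, alphas = 1, seed = 77)
  expect_identical(mda$samples, one$M)
  expect_identical(mda$predictions, one$D)
})

test_that("ES-MDA with inflated multi-step schedules matches the analytic posterior", {
  toy <- linear_gaussian_toy()
  ne <- 2000
  withr::with_seed(301, M <- rmvn(ne, toy$mu0, toy$S0))
  r22 <- esmda(toy$forward, M, toy$obs, alphas = c(2, 2), seed = 302)
  se_mean <- sqrt(diag(toy$S_post) / ne)
  expect_true(all(abs(colMeans(r22$samples) - toy$mu_post) < 3 * se_mean))
  # invalid schedules are refused
  expect_error(esmda(toy$forward, M, toy$obs, alphas = c(2, 3)), "consistency")
  expect_error(esmda(toy$forward, M, toy$obs, alphas = c(0.5, 1)), ">= 1")
  # the alternative printed-constraint convention: sum(1/a^2) = 1
  r_alt <- esmda(toy$forward, M, toy$obs, n_assim = 2,
                 inflation_variant = "sum_inv_sq", seed = 303)
  expect_equal(r_alt$config$alphas, rep(sqrt(2), 2))
})

test_that("ilues objective reproduces a hand-computed 3-member ranking", {
  M <- matrix(c(0, 1, 2), ncol = 1)
  D <- M                                  # f(m) = m
  d <- 1; cd <- 1
  # J1 = (1, 0, 1); J2 to m_ref = 0 with unit CMM: (0, 1, 4)
  j <- ilues_objective(M, D, d, cd, m_ref = 0, CMM = matrix(1, 1, 1))
  expect_equal(j, c(1, 0.25, 2), tolerance = 1e-9)
  expect_equal(which.min(j), 2L)
  # distance to itself contributes nothing; exact fit contributes nothing
  expect_equal(j[1], 1)                   # J2(m_ref) = 0, pure misfit term
  expect_equal(ilues_objective(M, D, 1, cd, m_ref = 1,
                               CMM = matrix(1, 1, 1))[2], 0)
})

test_that("ilues reduces toward a global update when the local set is everything", {
  toy <- linear_gaussian_toy()
  ne <- 1500
  withr::with_seed(401, M <- rmvn(ne, toy$mu0, toy$S0))
  r <- ilues(toy$forward, M, toy$obs, n_iter = 1, local_fraction = 1, a = 0,
             seed = 402)
  se_mean <- sqrt(diag(toy$S_post) / ne)
  # random resampling from the updated local (= global) ensemble inflates
  # Monte-Carlo error; allow 5 batch standard errors
  expect_true(all(abs(colMeans(r$samples) - toy$mu_post) < 5 * se_mean))
  expect_equal(r$config$nl, ne)
})

test_that("ilues enforces a minimum local ensemble and records NL = alpha * Ne", {
  toy <- linear_gaussian_toy()
  withr::with_seed(403, M <- rmvn(500, toy$mu0, toy$S0))
  r <- ilues(toy$forward, M, toy$obs, n_iter = 1, local_fraction = 0.1,
             seed = 404)
  expect_equal(r$config$nl, 50L)
  expect_error(ilues(toy$forward, M[1:10, ], toy$obs, local_fraction = 0.1),
               "NL")
})

test_that("updates stay finite and inside the prior box under reflection", {
  sp <- param_space()
  case <- make_synthetic_case(seed = 15)
  prior <- sample_prior(sp, 60, seed = 16)
  r <- ilues(case$forward, prior, case$obs, n_iter = 2,
             lower = sp$lower, upper = sp$upper, seed = 17)
  expect_true(all(is.finite(r$samples)))
  expect_true(all(sweep(r$samples, 2, sp$lower, `>=`)))
  expect_true(all(sweep(r$samples, 2, sp$upper, `<=`)))
  e <- esmda(case$forward, prior, case$obs, n_assim = 2,
             lower = sp$lower, upper = sp$upper, seed = 18)
  expect_true(all(is.finite(e$samples)))
  expect_true(all(sweep(e$samples, 2, sp$lower, `>=`)))
  expect_true(all(sweep(e$samples, 2, sp$upper, `<=`)))
})

test_that("reflection into the box is an in-box identity and measure-preserving", {
  lo <- c(0, -1); hi <- c(1, 3)
  x <- matrix(c(0.5, 2, 0.2, -0.5), ncol = 2, byrow = TRUE)
  expect_equal(reflect_box(x[1, ], lo, hi), x[1, ])
  y <- reflect_box(c(1.3, -1.5), lo, hi)
  expect_equal(y, c(0.7, -0.5))
  # far excursions fold back inside
  z <- reflect_box(c(7.3, 12.9), lo, hi)
  expect_true(all(z >= lo & z <= hi))
  # piecewise isometry: |d reflect / dx| = 1 almost everywhere
  withr::with_seed(42, {
    for (i in 1:50) {
      x0 <- runif(1, -3, 4); h <- 1e-6
      d <- abs(reflect_box(x0 + h, 0, 1) - reflect_box(x0, 0, 1))
      expect_equal(d, h, tolerance = 1e-3)
    }
  })
})
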