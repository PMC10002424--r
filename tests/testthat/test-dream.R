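test_that("log likelihood matches the closed-form Gaussian density", {
  ob <- exact_obs(0.25, 0.005)
  fwd <- function(th) th
  # residual 0.01 at sd 0.005
  expect_equal(log_likelihood(0.24, fwd, ob),
               dnorm(0.01, 0, 0.005, log = TRUE))
  # zero residual attains the maximum -0.5 (m log 2pi + log|R|)
  expect_equal(log_likelihood(0.25, fwd, ob),
               -0.5 * (log(2 * pi) + log(0.005^2)))
  # outside the prior box
  expect_identical(log_likelihood(2, fwd, ob, lower = 0, upper = 1), -Inf)
})

test_that("parallel-direction proposal follows the jump algebra", {
  theta <- c(1, 2, 3, 4)
  # identical archive rows: zero difference vector, no jitter -> no move
  arch0 <- rbind(c(5, 5, 5, 5), c(5, 5, 5, 5))
  withr::with_seed(1, {
    p0 <- parallel_direction_proposal(theta, arch0, delta = 1, cr = 1,
                                      b_e = 0, b_star = 0)
  })
  expect_equal(p0, theta)
  # delta = 1, gamma forced to 1, no jitter: theta + (z_a - z_b)
  arch <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  withr::with_seed(2, {
    p1 <- parallel_direction_proposal(theta, arch, delta = 1, cr = 1,
                                      gamma = 1, b_e = 0, b_star = 0)
  })
  dd <- arch[1, ] - arch[2, ]
  expect_true(isTRUE(all.equal(p1, theta + dd)) ||
                isTRUE(all.equal(p1, theta - dd)))
  # default gamma = 2.38 / sqrt(2 * delta * d') with all 4 dims selected
  withr::with_seed(3, {
    p2 <- parallel_direction_proposal(theta, arch, delta = 1, cr = 1,
                                      b_e = 0, b_star = 0)
  })
  g <- 2.38 / sqrt(8)
  expect_true(isTRUE(all.equal(p2, theta + g * dd)) ||
                isTRUE(all.equal(p2, theta - g * dd)))
  expect_error(parallel_direction_proposal(theta, arch, delta = 3), "archive")
})

test_that("snooker proposal projects along the current-to-anchor line", {
  theta <- c(1, 1)
  arch <- rbind(c(0, 0), c(2, 0), c(0, 2), c(3, 1))
  withr::with_seed(7, sp <- snooker_proposal(theta, arch))
  # replay the draws to recompute the projection by hand
  withr::with_seed(7, {
    idx <- sample.int(4, 3)
    z <- arch[idx[1], ]; z1 <- arch[idx[2], ]; z2 <- arch[idx[3], ]
    gs <- runif(1, 1.2, 2.2)
  })
  e <- theta - z
  hand <- theta + gs * (sum((z1 - z2) * e) / sum(e^2)) * e
  expect_equal(sp$theta, hand, tolerance = 1e-12)
  # the move stays on the line through theta and z
  expect_equal((sp$theta - theta)[1] * e[2], (sp$theta - theta)[2] * e[1],
               tolerance = 1e-12)
  expect_equal(sp$correction,
               (sqrt(sum((sp$theta - z)^2)) / sqrt(sum((theta - z)^2)))^(2 - 1))
  # in one dimension the correction is identically 1
  withr::with_seed(8, sp1 <- snooker_proposal(0.5, matrix(c(0, 1, 2), ncol = 1)))
  expect_equal(sp1$correction, 1)
})

test_that("kalman proposal reduces to scalar gain algebra on a linear toy", {
  # archive of states with f(theta) = theta
  arch <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  v <- var(drop(arch))
  r <- 0.5
  d_obs <- 4; theta <- 1
  withr::with_seed(9, {
    prop <- kalman_proposal(theta, pred = theta, arch, arch, d_obs, r)
  })
  withr::with_seed(9, eps <- rnorm(1, 0, sqrt(r)))
  k <- v / (v + r)
  expect_equal(prop, theta + k * (d_obs - theta) + k * eps, tolerance = 1e-6)
  # identical archive predictions: zero gain, proposal = current state
  archc <- matrix(rep(2, 5), ncol = 1)
  expect_equal(kalman_proposal(theta, theta, arch, archc, d_obs, r), theta)
  # infinite noise: gain vanishes
  expect_equal(kalman_proposal(theta, theta, arch, arch, d_obs, 1e12), theta,
               tolerance = 1e-3)
})

test_that("variants respect the Kalman cutoff and mixture bookkeeping", {
  toy <- linear_gaussian_toy()
  ob <- toy$obs
  dz <- dream(toy$forward, c(-10, -10), c(10, 10), ob, variant = "zs",
              n_gen = 150, seed = 21)
  expect_equal(sum(dz$move == "kalman"), 0L)
  dk <- dream(toy$forward, c(-10, -10), c(10, 10), ob, variant = "kzs",
              n_gen = 150, t_kalman = 30, seed = 21)
  expect_gt(sum(dk$move[1:30, ] == "kalman"), 0L)
  expect_equal(sum(dk$move[31:150, ] == "kalman"), 0L)
  expect_equal(dk$burnin, 30)
  # acceptance rates strictly inside (0, 1) after burn-in
  post_acc <- mean(dz$accepted[31:150, ])
  expect_gt(post_acc, 0)
  expect_lt(post_acc, 1)
  # all samples inside the prior box
  expect_true(all(dz$samples >= -10 & dz$samples <= 10))
})

test_that("both DREAM variants recover the analytic Gaussian posterior", {
  toy <- linear_gaussian_toy()
  for (v in c("zs", "kzs")) {
    dr <- dream(toy$forward, c(-10, -10), c(10, 10), toy$obs, variant = v,
                n_gen = 3000, seed = 22)
    s <- posterior_samples(dr)
    for (k in 1:2) {
      se <- batch_se(s[, k])
      expect_lt(abs(mean(s[, k]) - toy$mu_flat[k]), 3 * se)
      expect_equal(sd(s[, k]), sqrt(toy$S_flat[k, k]), tolerance = 0.15)
    }
  }
})

test_that("both DREAM variants populate a grid-verified bimodal posterior", {
  f2 <- function(m) m^2
  ob <- exact_obs(4, 0.5)
  # dense-grid oracle: equal mass near the two modes
  grid <- seq(-5, 5, length.out = 20001)
  post <- exp(dnorm(4 - grid^2, 0, 0.5, log = TRUE))
  post <- post / sum(post)
  mass_neg <- sum(post[abs(grid + 2) < 0.5])
  mass_pos <- sum(post[abs(grid - 2) < 0.5])
  expect_equal(mass_neg, mass_pos, tolerance = 1e-6)
  expect_gt(mass_neg + mass_pos, 0.99)
  for (v in c("zs", "kzs")) {
    dr <- dream(f2, -5, 5, ob, variant = v, n_gen = 4000, seed = 23)
    s <- drop(posterior_samples(dr))
    occ <- bimodal_modes(s)
    expect_gt(occ["neg"], 0.25)          # each mode holds half its true mass
    expect_gt(occ["pos"], 0.25)
    expect_gt(occ["neg"] + occ["pos"], 0.95)
  }
})

test_that("gelman-rubin is 1 for identical chains and flags divergent ones", {
  x <- array(rnorm(600), c(100, 3, 2))
  x[, 2, ] <- x[, 1, ]; x[, 3, ] <- x[, 1, ]
  # identical chains: B = 0, so R-hat attains its floor sqrt((n-1)/n)
  expect_equal(unname(gelman_rubin(x)), rep(sqrt(99 / 100), 2),
               tolerance = 1e-12)
  y <- array(rnorm(600), c(100, 3, 2))
  y[, 2, ] <- y[, 2, ] + 50
  expect_true(all(gelman_rubin(y) > 5))
})

test_that("chains serialize to CSV with full per-generation bookkeeping", {
  toy <- linear_gaussian_toy()
  dr <- dream(toy$forward, c(-10, -10), c(10, 10), toy$obs, n_gen = 60,
              seed = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chains(dr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 60 * 3)
  expect_equal(back$loglik, as.vector(dr$loglik), tolerance = 1e-12)
  expect_equal(sort(unique(back$chain)), 1:3)
})
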