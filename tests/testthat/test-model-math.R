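test_that("initial occupancy probability is the inverse-logit linear predictor", {
  p0 <- param_set(0, c(f = 0))
  expect_equal(initial_occupancy_prob(p0, matrix(0, 1, 1)), 0.5)
  # little brown bat intercept at average conditions
  plb <- param_set(3.53, c(f = 0))
  expect_equal(initial_occupancy_prob(plb, matrix(0, 1, 1)), 0.9715,
               tolerance = 1e-3)
  pf <- param_set(0, c(forest = 1))
  expect_equal(initial_occupancy_prob(pf, matrix(-1, 1, 1)), 0.2689,
               tolerance = 1e-3)
  expect_error(initial_occupancy_prob(pf, matrix(0, 1, 2)),
               "length mismatch")
})

test_that("transition probability implements the autologistic predictor", {
  p <- param_set(0, c(f = 0), a = -0.68, b = 4.32)
  X <- matrix(0, 1, 1)
  expect_equal(transition_prob(p, X, z_prev = 1, t = 2), 0.9744, tolerance = 1e-3)
  expect_equal(transition_prob(p, X, z_prev = 0, t = 2), 0.3363, tolerance = 1e-3)
  p0 <- param_set(0, c(f = 0), a = 0.3, b = 0)
  expect_equal(transition_prob(p0, X, 0, 2), transition_prob(p0, X, 1, 2))
  expect_error(transition_prob(p, X, 1, t = 3), "out of range")
  expect_error(transition_prob(p, X, 1, t = 1), "out of range")
})

test_that("derived phi/gamma match the hand-computed values", {
  expect_equal(derived_dynamics(0, 0), list(phi = 0.5, gamma = 0.5))
  d_ho <- derived_dynamics(-0.68, 4.32)
  expect_equal(d_ho$phi, 0.9744, tolerance = 1e-3)
  expect_equal(d_ho$gamma, 0.3363, tolerance = 1e-3)
  d_lb <- derived_dynamics(0.14, 3.49)
  expect_equal(d_lb$phi, 0.9742, tolerance = 1e-3)
  expect_equal(d_lb$gamma, 0.5349, tolerance = 1e-3)
})

test_that("the occupancy recursion and its fixed points behave", {
  expect_equal(occupancy_recursion(0.5, 0.9, 0.1), 0.5)
  expect_equal(occupancy_recursion(0.87, 0.9744, 0.3363), 0.8914,
               tolerance = 1e-3)
  # algebraic equilibrium gamma/(gamma + 1 - phi) is a fixed point
  set.seed(4)
  for (i in 1:20) {
    phi <- runif(1); gamma <- runif(1)
    eq <- gamma / (gamma + 1 - phi)
    expect_equal(occupancy_recursion(eq, phi, gamma), eq, tolerance = 1e-12)
  }
  expect_error(occupancy_recursion(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("psi trajectories stay in [0, 1] for any valid dynamics", {
  set.seed(8)
  for (i in 1:50) {
    T <- sample(2:6, 1)
    traj <- psi_trajectory(runif(1), runif(T - 1), runif(T - 1))
    expect_true(all(traj >= 0 & traj <= 1))
  }
})

test_that("occurrence growth rate matches the trend arithmetic", {
  expect_equal(occurrence_growth_rate(c(0.8, 0.8, 0.8)),
               list(lambda_total = 1, lambda_annual = 1))
  # the emulated decline: 0.87 down to 0.65 over two transitions
  g <- occurrence_growth_rate(c(0.87, 0.76, 0.65))
  expect_equal(g$lambda_total, 0.7471, tolerance = 1e-3)
  expect_equal(g$lambda_annual, 0.8644, tolerance = 1e-3)
  expect_equal(round(g$lambda_annual, 2), 0.86)
  expect_equal(occurrence_growth_rate(c(0.5, 1.0)),
               list(lambda_total = 2, lambda_annual = 2))
  expect_error(occurrence_growth_rate(c(0, 0.5)), "positive")
  expect_error(occurrence_growth_rate(0.5), "length")
})

test_that("detection probability responds to the date covariate", {
  expect_equal(detection_prob(0, 0, 1.7), 0.5)
  expect_equal(detection_prob(-1, 0.5, 2), 0.5)
  expect_equal(detection_prob(0, 1, -700), 0, tolerance = 1e-100)
})

test_that("complete-data log likelihood handles the canonical cases", {
  # all-half case: every z and y term contributes log 0.5
  p <- param_set(0, numeric(0), a = 0, b = 0, alpha0 = 0, alpha1 = 0)
  y <- array(0, c(1, 2, 2)); date <- array(0, c(1, 2, 2))
  d <- survey_dataset(y, date, date_scaling = c(mean = 0, sd = 1))
  expect_equal(complete_data_loglik(p, matrix(1, 1, 2), d), 6 * log(0.5))

  # a detection at an unoccupied site-year is impossible
  y1 <- array(c(1, 0, 0, 0), c(1, 2, 2))
  d1 <- survey_dataset(y1, date, date_scaling = c(mean = 0, sd = 1))
  expect_identical(complete_data_loglik(p, matrix(c(0, 1), 1, 2), d1), -Inf)

  # direct product: psi * p for one site, one season, one visit
  p2 <- param_set(qlogis(0.7), numeric(0), alpha0 = qlogis(0.6))
  d2 <- survey_dataset(array(1, c(1, 1, 1)), array(0, c(1, 1, 1)),
                       date_scaling = c(mean = 0, sd = 1))
  expect_equal(complete_data_loglik(p2, matrix(1), d2), log(0.7 * 0.6))
})

test_that("site marginal likelihood equals the closed-form tiny cases", {
  p <- param_set(0, numeric(0), alpha0 = 0)
  date <- array(0, c(1, 1, 2))
  d00 <- survey_dataset(array(c(0, 0), c(1, 1, 2)), date,
                        date_scaling = c(mean = 0, sd = 1))
  expect_equal(site_marginal_loglik(p, d00, 1), log(0.625), tolerance = 1e-12)
  d10 <- survey_dataset(array(c(1, 0), c(1, 1, 2)), date,
                        date_scaling = c(mean = 0, sd = 1))
  expect_equal(site_marginal_loglik(p, d10, 1), log(0.125), tolerance = 1e-12)
})

test_that("forward recursion matches brute-force enumeration", {
  set.seed(11)
  for (case in 1:25) {
    T <- sample(1:4, 1); J <- sample(1:3, 1); n <- 3
    params <- param_set(rnorm(1), c(c1 = rnorm(1), c2 = rnorm(1)),
                        a = rnorm(max(T - 1, 0)), b = rnorm(max(T - 1, 0)),
                        alpha0 = rnorm(1), alpha1 = rnorm(1))
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
    date <- array(rnorm(n * T * J), c(n, T, J))
    y <- array(rbinom(n * T * J, 1, 0.4), c(n, T, J))
    miss <- array(runif(n * T * J) < 0.2, c(n, T, J))
    miss[, 1, 1] <- FALSE  # keep every site observed at least once
    y[miss] <- NA; date[miss] <- NA
    d <- survey_dataset(y, date, as.data.frame(X),
                        scaling = identity_scaling(c("c1", "c2")),
                        date_scaling = c(mean = 0, sd = 1))
    for (i in 1:n) {
      expect_equal(
        site_marginal_loglik(params, d, i),
        enum_site_loglik(params$beta0, params$beta, params$a, params$b,
                         params$alpha0, params$alpha1, X[i, ],
                         matrix(y[i, , ], T, J), matrix(date[i, , ], T, J)),
        tolerance = 1e-10)
    }
  }
})

test_that("the model is a proper probability distribution (tiny instance)", {
  # summing exp(complete-data loglik) over every (z, y) configuration is 1
  params <- param_set(0.4, c(c1 = 0.7), a = -0.3, b = 1.1,
                      alpha0 = -0.2, alpha1 = 0.5)
  T <- 2; J <- 2
  X <- matrix(0.6, 1, 1, dimnames = list(NULL, "c1"))
  date <- array(c(0.3, -1, 0.2, 1.4), c(1, T, J))
  zs <- as.matrix(expand.grid(0:1, 0:1))
  ys <- as.matrix(expand.grid(rep(list(0:1), T * J)))
  total <- 0
  for (zi in seq_len(nrow(zs))) {
    for (yi in seq_len(nrow(ys))) {
      y <- array(as.numeric(ys[yi, ]), c(1, T, J))
      d <- survey_dataset(y, date, data.frame(c1 = 0.6),
                          scaling = identity_scaling("c1"),
                          date_scaling = c(mean = 0, sd = 1))
      total <- total + exp(complete_data_loglik(params, zs[zi, , drop = FALSE], d))
    }
  }
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("b = 0 removes the autologistic effect entirely", {
  p <- param_set(0.2, c(f = 0.5), a = -0.4, b = 0)
  dyn <- derived_dynamics(p$a, p$b)
  expect_equal(dyn$phi, dyn$gamma)
  X <- matrix(rnorm(5), 5, 1, dimnames = list(NULL, "f"))
  expect_equal(transition_prob(p, X, 0, 2), transition_prob(p, X, 1, 2))
})

test_that("the optional interaction term enters the transition predictor", {
  X <- matrix(c(0.5, 1.2), 2, 1, dimnames = list(NULL, "precipitation"))
  p <- param_set(0, c(precipitation = -0.4), a = -0.6, b = 2,
                 beta_zint = 0.8)
  got <- transition_prob(p, X, z_prev = 1, t = 2)
  expect_equal(got, plogis(-0.6 + 2 + -0.4 * X[, 1] + 0.8 * X[, 1]),
               ignore_attr = TRUE)
  # with z_prev = 0 the interaction vanishes
  expect_equal(transition_prob(p, X, 0, 2), plogis(-0.6 + -0.4 * X[, 1]),
               ignore_attr = TRUE)
})
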