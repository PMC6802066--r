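test_that("fitting is exactly reproducible for a fixed seed", {
  sim <- sim_dataset(default_params(), n = 40, T = 3, J = 4, seed = 51)
  pri <- vague_priors(full_param_names())
  cfg <- mcmc_config(seed = 5, n_chains = 2, n_burnin = 100,
                     n_retained = 200, thin = 1)
  f1 <- fit_model(sim$data, pri, cfg)
  f2 <- fit_model(sim$data, pri, cfg)
  expect_identical(f1$values, f2$values)
  expect_identical(f1$z, f2$z)
  f3 <- fit_model(sim$data, pri, mcmc_config(seed = 6, n_chains = 2,
                                             n_burnin = 100, n_retained = 200,
                                             thin = 1))
  expect_false(identical(f1$values, f3$values))
})

test_that("fit_model validates inputs before sampling", {
  sim <- sim_dataset(default_params(), n = 10, T = 3, J = 2, seed = 52)
  cfg <- mcmc_config(seed = 1, n_chains = 1, n_burnin = 10, n_retained = 20,
                     thin = 1)
  expect_error(fit_model(sim$data, vague_priors(c("beta0", "alpha0")), cfg),
               "priors missing")
  expect_error(mcmc_config(), "seed is required")
  expect_error(mcmc_config(seed = 1, n_chains = 0), "invalid MCMC counts")
})

test_that("split-chain R-hat separates mixed from unmixed chains", {
  set.seed(61)
  iid <- array(rnorm(4 * 5000), c(4, 5000, 1), dimnames = list(NULL, NULL, "x"))
  expect_lt(abs(gelman_rubin(iid)[["x"]] - 1), 0.01)

  apart <- array(c(rnorm(1000), rnorm(1000, 100)), c(2, 1000, 1),
                 dimnames = list(NULL, NULL, "x"))
  apart[1, , 1] <- rnorm(1000); apart[2, , 1] <- rnorm(1000, 100)
  expect_gt(gelman_rubin(apart)[["x"]], 1.1)

  const <- array(1, c(2, 100, 1), dimnames = list(NULL, NULL, "x"))
  expect_true(is.nan(gelman_rubin(const)[["x"]]))
  chk <- convergence_check(stats::setNames(c(1.01, NaN), c("good", "bad")))
  expect_false(chk$converged)
  expect_identical(chk$offending, "bad")

  expect_error(gelman_rubin(array(1, c(1, 100, 1))), "2 chains")
})

test_that("split R-hat agrees with the classic diagnostic on stationary chains", {
  set.seed(62)
  arr <- array(rnorm(3 * 2000), c(3, 2000, 1), dimnames = list(NULL, NULL, "x"))
  classic <- coda::gelman.diag(coda::mcmc.list(lapply(1:3, function(ch)
    coda::mcmc(arr[ch, , 1]))), autoburnin = FALSE)$psrf[1, 1]
  expect_equal(gelman_rubin(arr)[["x"]], unname(classic), tolerance = 0.01)
})

test_that("posterior summaries derive quantities per draw, not from means", {
  # point-mass draws reproduce the closed-form dynamics
  m <- cbind(beta0 = rep(0.15, 200), a_1 = -0.68, b_1 = 4.32)
  fd <- fake_draws(m, T = 2)
  s <- summarize_posterior(fd)
  expect_equal(s$mean[s$parameter == "phi_1"], 0.9744, tolerance = 1e-3)
  expect_equal(s$mean[s$parameter == "gamma_1"], 0.3363, tolerance = 1e-3)

  # Jensen: E[psi_T/psi_1] differs from E[psi_T]/E[psi_1] on skewed draws
  set.seed(63)
  m2 <- cbind(beta0 = rnorm(5000, 0, 2.5), a_1 = rnorm(5000, -1, 1),
              b_1 = rnorm(5000, 2, 1))
  fd2 <- fake_draws(m2, T = 2)
  da <- derived_array(fd2)
  lam_perdraw <- mean(da[1, , "lambda_total"])
  lam_of_means <- mean(da[1, , "psi_2"]) / mean(da[1, , "psi_1"])
  expect_gt(abs(lam_perdraw - lam_of_means), 0.02)
  # and lambda_annual is the per-draw root of lambda_total
  expect_equal(da[1, , "lambda_annual"], da[1, , "lambda_total"]^(1),
               tolerance = 1e-12)  # T = 2: one transition
})

test_that("frame prediction is consistent, monotone and scales stored", {
  sf <- small_fit()
  fit <- sf$fit; ds <- sf$ds
  # a cell at raw covariates equal to the fitted means is the covariate-0 cell
  mid <- as.list(stats::setNames(ds$data$scaling$mean, ds$data$scaling$covariate))
  pf <- predict_psi_frame(fit, as.data.frame(mid), year = 3)
  s <- summarize_posterior(fit)
  expect_equal(pf$psi_mean, s$mean[s$parameter == "psi_3"], tolerance = 1e-9)
  expect_equal(nrow(pf), 1)

  # monotone: with all-positive forest slope draws, psi rises with forest
  m <- cbind(beta0 = rnorm(300, 0, 0.3), beta_forest = runif(300, 0.2, 1))
  fd <- fake_draws(m, T = 1, covariate_names = "forest")
  grid <- data.frame(forest = seq(-2, 2, length.out = 9))
  pg <- predict_psi_frame(fd, grid, year = 1, standardized = TRUE)
  expect_true(all(diff(pg$psi_mean) > 0))
})

test_that("a huge-sd informative prior washes out to the vague posterior", {
  sim <- sim_dataset(default_params(), n = 120, T = 3, J = 4, seed = 53)
  nm <- full_param_names()
  cfg <- mcmc_config(seed = 11, n_chains = 2, n_burnin = 400,
                     n_retained = 2000, thin = 2)
  fv <- fit_model(sim$data, vague_priors(nm), cfg, save_z = FALSE)
  wide <- new_prior <- vague_priors(nm)
  wide$entries$sd <- 60
  fw <- fit_model(sim$data, wide, cfg, save_z = FALSE)
  sv <- summarize_posterior(fv, derived = FALSE)
  sw <- summarize_posterior(fw, derived = FALSE)
  # posterior means agree within Monte-Carlo error for the well-identified
  # parameters (intercepts/slopes; transition terms are weakly identified)
  for (p in c("beta0", "beta_forest", "alpha0", "alpha1")) {
    dv <- sv[sv$parameter == p, ]
    dw <- sw[sw$parameter == p, ]
    expect_lt(abs(dv$mean - dw$mean), 4 * sqrt(dv$sd^2 + dw$sd^2) / sqrt(50))
  }
})

test_that("the sampler agrees with an independent MCMC engine", {
  skip_if_not_installed("rjags")
  sim <- sim_dataset(default_params(), n = 60, T = 3, J = 4, seed = 54)
  nm <- full_param_names()
  cfg <- mcmc_config(seed = 3, n_chains = 2, n_burnin = 1500,
                     n_retained = 8000, thin = 2)
  fit <- fit_model(sim$data, vague_priors(nm), cfg, save_z = FALSE)
  s <- summarize_posterior(fit, derived = FALSE)

  model_str <- "model {
    beta0 ~ dnorm(0, 0.1)
    for (k in 1:4) { beta[k] ~ dnorm(0, 0.1) }
    for (s in 1:2) { a[s] ~ dnorm(0, 0.1); b[s] ~ dnorm(0, 0.1) }
    alpha0 ~ dnorm(0, 0.1); alpha1 ~ dnorm(0, 0.1)
    for (i in 1:n) {
      eta[i] <- inprod(beta[], X[i,])
      logit(psi1[i]) <- beta0 + eta[i]
      z[i,1] ~ dbern(psi1[i])
      for (t in 2:3) {
        logit(pi[i,t]) <- a[t-1] + b[t-1]*z[i,t-1] + eta[i]
        z[i,t] ~ dbern(pi[i,t])
      }
      for (t in 1:3) { for (j in 1:4) {
        logit(p[i,t,j]) <- alpha0 + alpha1*date[i,t,j]
        y[i,t,j] ~ dbern(z[i,t]*p[i,t,j])
      } }
    }
  }"
  zinit <- apply(sim$data$y == 1, c(1, 2), function(v) as.integer(any(v)))
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = sim$data$y, date = sim$data$date, X = sim$data$covariates,
                n = 60),
    inits = list(z = zinit, .RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = 7),
    n.chains = 1, n.adapt = 500, quiet = TRUE)
  update(jm, 1500, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta0", "beta", "a", "b", "alpha0",
                                    "alpha1"),
                              n.iter = 16000, thin = 2,
                              progress.bar = "none")
  jm_mean <- colMeans(as.matrix(samp))
  map <- c(beta0 = "beta0", beta_forest = "beta[1]",
           beta_elevation = "beta[2]", beta_precipitation = "beta[3]",
           beta_roughness = "beta[4]", a_1 = "a[1]", a_2 = "a[2]",
           b_1 = "b[1]", b_2 = "b[2]", alpha0 = "alpha0", alpha1 = "alpha1")
  for (p in names(map)) {
    row <- s[s$parameter == p, ]
    # both chains carry MC error; allow a generous joint margin
    expect_lt(abs(row$mean - jm_mean[[map[[p]]]]), 0.15 * max(row$sd, 0.2))
  }
})
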