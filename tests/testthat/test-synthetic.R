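test_that("frame generation honors the requested structure", {
  fr <- generate_frame(1200, corr_forest_precip = 0.7, seed = 81)
  expect_equal(nrow(fr), 1200)
  # 10-km cell spacing
  expect_equal(sort(unique(diff(sort(unique(fr$x_km))))), 10)
  # forest-precipitation correlation near target
  expect_lt(abs(cor(fr$forest_pct, fr$precip_mm) - 0.7), 0.1)
  # west-to-east forest gradient: negative correlation with x
  expect_lt(cor(fr$x_km, fr$forest_pct), -0.3)
  # bounds respected
  expect_true(all(fr$forest_pct >= 0 & fr$forest_pct <= 100))
  expect_true(all(fr$precip_mm >= 50 & fr$elev_m >= 0 & fr$rough_sd_m >= 2))

  expect_identical(generate_frame(100, seed = 5), generate_frame(100, seed = 5))
  expect_equal(nrow(generate_frame(seed = 82)), 4500)  # default frame size
  expect_error(generate_frame(100, corr_forest_precip = 1, seed = 1),
               "invalid correlation")
  expect_error(generate_frame(2, seed = 1), "at least 4")
})

test_that("site selection is spatially balanced with a legacy admixture", {
  fr <- generate_frame(400, seed = 83)
  sel <- select_sites(fr, 60, legacy_fraction = 0.2, seed = 84)
  expect_equal(nrow(sel), 60)
  expect_equal(sum(sel$selection == "legacy"), 12)

  sel0 <- select_sites(fr, 60, legacy_fraction = 0, seed = 84)
  expect_true(all(sel0$selection == "balanced"))

  census <- select_sites(fr, 400, seed = 85)
  expect_equal(sort(census$cell_id), fr$cell_id)

  expect_error(select_sites(fr, 10, legacy_fraction = 1.2, seed = 1),
               "legacy_fraction")
  expect_error(select_sites(fr, 500, seed = 1), "exceeds frame")

  # balance: mean nearest-neighbor distance beats a uniform draw on average
  mean_nn <- function(coords) {
    D <- as.matrix(dist(coords)); diag(D) <- Inf
    mean(apply(D, 1, min))
  }
  set.seed(86)
  nn <- replicate(50, {
    bal <- select_sites(fr, 40, legacy_fraction = 0,
                        seed = sample.int(1e6, 1))
    uni <- fr[sample.int(400, 40), ]
    c(mean_nn(bal[, c("x_km", "y_km")]), mean_nn(uni[, c("x_km", "y_km")]))
  })
  expect_gte(mean(nn[1, ]), mean(nn[2, ]))
})

test_that("presets encode the intended dynamics", {
  st <- preset_params("stable")
  dyn <- derived_dynamics(st$a[1], st$b[1])
  expect_equal(dyn$phi, 0.9744, tolerance = 1e-3)
  expect_equal(dyn$gamma, 0.3363, tolerance = 1e-3)
  traj <- psi_trajectory(plogis(st$beta0), dyn$phi * c(1, 1),
                         dyn$gamma * c(1, 1))
  expect_equal(occurrence_growth_rate(traj)$lambda_annual, 1, tolerance = 1e-9)

  de <- preset_params("declining")
  dyn_d <- derived_dynamics(de$a, de$b)
  traj_d <- psi_trajectory(plogis(de$beta0), dyn_d$phi, dyn_d$gamma)
  expect_equal(occurrence_growth_rate(traj_d)$lambda_annual, 0.86,
               tolerance = 1e-9)
  expect_lt(dyn_d$gamma[1], 0.15)  # low-colonization background
  expect_error(preset_params("declining", T = 1), "T >= 2")
})

test_that("latent-state simulation follows the generative model", {
  # frozen dynamics: phi = 1, gamma = 0 keeps z constant over years
  frozen <- param_set(0.3, numeric(0), a = c(-40, -40), b = c(80, 80))
  tr <- simulate_truth(frozen, matrix(0, 50, 0), T = 3, seed = 87)
  expect_true(all(tr$z[, 1] == tr$z[, 2] & tr$z[, 2] == tr$z[, 3]))

  # large-n year-1 occupancy matches mean psi1 within 2 binomial SEs
  pars <- default_params()
  set.seed(88)
  X <- matrix(rnorm(4000 * 4), 4000, 4,
              dimnames = list(NULL, names(pars$beta)))
  tr2 <- simulate_truth(pars, X, T = 3, seed = 89)
  psi1 <- initial_occupancy_prob(pars, X)
  se <- sqrt(sum(psi1 * (1 - psi1))) / 4000
  expect_lt(abs(mean(tr2$z[, 1]) - mean(psi1)), 2 * se + 1e-12)

  # declining preset: empirical annualized decline near the target
  de <- preset_params("declining")
  de$beta <- numeric(0)
  tr3 <- simulate_truth(de, matrix(0, 2000, 0), T = 3, seed = 90)
  ratio <- sqrt(mean(tr3$z[, 3]) / mean(tr3$z[, 1]))
  expect_lt(abs(ratio - 0.86), 0.05)
})

test_that("survey simulation has no false positives and calibrated detection", {
  z0 <- matrix(0L, 30, 2)
  s0 <- simulate_surveys(z0, 0, 0, J = 3, seed = 91)
  expect_true(all(s0$y == 0))

  z1 <- matrix(1L, 400, 2)
  s1 <- simulate_surveys(z1, 0, 0, J = 4, seed = 92)
  expect_lt(abs(mean(s1$y) - 0.5), 2 * sqrt(0.25 / length(s1$y)))
  expect_true(all(s1$date >= 152 & s1$date <= 273))

  # alpha0 at logit(0.4): ~40% detection at occupied site-years
  s2 <- simulate_surveys(z1, qlogis(0.4), 0, J = 4, seed = 93)
  expect_lt(abs(mean(s2$y) - 0.4), 0.02)

  s3 <- simulate_surveys(z1, 0, 0, J = 4, seed = 94, missingness = 0.3)
  expect_gt(sum(is.na(s3$y)), 0)
  expect_error(simulate_surveys(z1, 0, 0, J = 0, seed = 1), "J >= 1")
})

test_that("the default scenario reproduces the emulated design", {
  ds <- generate_dataset(scenario_config(seed = 95))
  expect_equal(dim(ds$data$y), c(190, 3, 4))
  expect_equal(nrow(ds$frame), 4500)
  expect_equal(ds$data$years, 2016:2018)
  # truth lambda agrees with the growth rate of the truth trajectory
  expect_equal(ds$truth$lambda_annual,
               occurrence_growth_rate(ds$truth$psi_true)$lambda_annual)
  expect_equal(ds$truth$lambda_total,
               occurrence_growth_rate(ds$truth$psi_true)$lambda_total)
})

test_that("dataset writing is byte-identical under one seed", {
  sc <- scenario_config(seed = 96, n_cells = 120, n_sites = 30, T = 2, J = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(sc), d1)
  write_dataset(generate_dataset(sc), d2)
  for (f in c("detections.csv", "sites.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("single-visit designs trigger the identifiability warning", {
  expect_warning(generate_dataset(scenario_config(seed = 97, n_cells = 60,
                                                  n_sites = 12, T = 2, J = 1)),
                 "weakly identify")
})
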