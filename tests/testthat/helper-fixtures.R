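# Shared fixture builders. All data are generated in code at test time.

the_covs <- c("forest", "elevation", "precipitation", "roughness")
identity_scaling <- function(covs = the_covs) {
  data.frame(covariate = covs, mean = rep(0, length(covs)),
             sd = rep(1, length(covs)))
}

# dataset with standard-normal covariates/dates simulated from `params`
sim_dataset <- function(params, n, T, J, seed, coords = NULL) {
  set.seed(seed)
  K <- length(params$beta)
  X <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, names(params$beta)))
  date <- array(rnorm(n * T * J), c(n, T, J))
  z <- matrix(0L, n, T)
  z[, 1] <- rbinom(n, 1, initial_occupancy_prob(params, X))
  if (T > 1) for (t in 2:T) {
    z[, t] <- rbinom(n, 1, transition_prob(params, X, z[, t - 1], t))
  }
  p <- plogis(params$alpha0 + params$alpha1 * date)
  y <- array(rbinom(n * T * J, 1, as.vector(p) * rep(as.vector(z), J)),
             c(n, T, J))
  list(data = survey_dataset(y, date, as.data.frame(X),
                             scaling = if (K) identity_scaling(names(params$beta)),
                             date_scaling = c(mean = 0, sd = 1),
                             coords = coords),
       z = z, X = X)
}

default_params <- function() {
  param_set(0.15,
            c(forest = 0.64, elevation = -0.52, precipitation = -0.41,
              roughness = -0.08),
            a = c(-0.68, -0.68), b = c(4.32, 4.32),
            alpha0 = qlogis(0.4), alpha1 = 0.3)
}

full_param_names <- function(T = 3, covs = the_covs) {
  nm <- model_param_names(covs, T - 1)
  c(nm$occupancy, nm$detection)
}

# hand-built posterior_draws object from a named draw matrix (one chain
# unless a chain column count is given)
fake_draws <- function(m, T, n_chains = 1, covariate_names = NULL,
                       z = NULL, priors = NULL) {
  m <- as.matrix(m)
  iters <- nrow(m) / n_chains
  values <- array(NA_real_, c(n_chains, iters, ncol(m)),
                  dimnames = list(NULL, NULL, colnames(m)))
  for (ch in seq_len(n_chains)) {
    values[ch, , ] <- m[(ch - 1) * iters + seq_len(iters), ]
  }
  covariate_names <- covariate_names %||%
    sub("^beta_", "", grep("^beta_", colnames(m), value = TRUE))
  n <- if (!is.null(z)) dim(z)[3] else 1
  structure(list(
    values = values, z = z,
    param_names = list(
      occupancy = setdiff(colnames(m), c("alpha0", "alpha1")),
      detection = intersect(c("alpha0", "alpha1"), colnames(m))),
    config = NULL, priors = priors,
    scaling = identity_scaling(covariate_names),
    date_scaling = c(mean = 0, sd = 1),
    covariate_names = covariate_names,
    dims = c(n = n, T = T, J = 1),
    share_transitions = FALSE, interaction = FALSE, interaction_cov = NULL
  ), class = "posterior_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one small fitted model, cached across tests in this session
local_fit_cache <- new.env()
small_fit <- function() {
  if (!is.null(local_fit_cache$fit)) return(local_fit_cache$fit)
  ds <- generate_dataset(scenario_config(seed = 421, n_cells = 300,
                                         n_sites = 80, preset = "stable"))
  cfg <- mcmc_config(seed = 17, n_chains = 2, n_burnin = 400,
                     n_retained = 1200, thin = 2)
  pri <- vague_priors(full_param_names())
  fit <- fit_model(ds$data, pri, cfg)
  local_fit_cache$fit <- list(fit = fit, ds = ds)
  local_fit_cache$fit
}
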