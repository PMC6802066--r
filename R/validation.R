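#' Simulation-based calibration of the sampler
#'
#' For each replicate: draw a parameter vector from the prior, simulate a
#' dataset of the requested dimensions from it, fit the model with the same
#' prior, and record the rank of the generating value within the retained
#' posterior draws. If the sampler targets the correct posterior, each rank
#' is uniform on `{0, ..., L}` where `L` is the number of retained draws —
#' so `L = n_ranks - 1` gives `n_ranks` equiprobable rank values.
#'
#' Covariates and (standardized) dates are drawn standard-normal per
#' replicate; the fit uses a single chain with a deliberately small budget,
#' thinned to decorrelate the rank draws.
#'
#' @param prior a `prior_spec` covering the full model (used for both
#'   simulation and fitting).
#' @param n_sites,T,J dataset dimensions per replicate.
#' @param n_replicates number of replicates.
#' @param n_ranks number of possible rank values (retained draws + 1).
#' @param n_burnin,thin per-replicate MCMC budget.
#' @param seed integer seed.
#' @param params parameters to track (default: occupancy-level).
#' @return matrix `n_replicates x length(params)` of integer ranks, class
#'   `sbc_ranks`.
#' @export
sbc_ranks <- function(prior, n_sites = 60, T = 3, J = 4, n_replicates = 200,
                      n_ranks = 100, n_burnin = 800, thin = 15, seed,
                      params = NULL) {
  if (missing(seed)) stop("an explicit seed is required")
  nm <- model_param_names(c("forest", "elevation", "precipitation", "roughness"),
                          T - 1)
  all_params <- c(nm$occupancy, nm$detection)
  pe <- prior$entries
  if (length(setdiff(all_params, pe$parameter))) {
    stop("prior must cover every model parameter")
  }
  params <- params %||% nm$occupancy
  L <- n_ranks - 1
  seeds <- derive_seeds(seed, paste0("rep", seq_len(n_replicates)))
  ident <- data.frame(covariate = c("forest", "elevation", "precipitation",
                                    "roughness"), mean = 0, sd = 1)
  K <- 4

  ranks <- matrix(NA_integer_, n_replicates, length(params),
                  dimnames = list(NULL, params))
  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    th <- stats::setNames(rnorm(nrow(pe), pe$mean, pe$sd), pe$parameter)
    S <- T - 1
    pars <- param_set(
      beta0 = th[["beta0"]],
      beta = th[paste0("beta_", ident$covariate)],
      a = if (S > 0) th[paste0("a_", seq_len(S))] else numeric(0),
      b = if (S > 0) th[paste0("b_", seq_len(S))] else numeric(0),
      alpha0 = th[["alpha0"]], alpha1 = th[["alpha1"]]
    )
    names(pars$beta) <- ident$covariate
    X <- matrix(rnorm(n_sites * K), n_sites, K,
                dimnames = list(NULL, ident$covariate))
    date <- array(rnorm(n_sites * T * J), c(n_sites, T, J))
    z <- matrix(0L, n_sites, T)
    z[, 1] <- rbinom(n_sites, 1, initial_occupancy_prob(pars, X))
    if (T > 1) for (t in 2:T) {
      z[, t] <- rbinom(n_sites, 1, transition_prob(pars, X, z[, t - 1], t))
    }
    p <- invlogit(pars$alpha0 + pars$alpha1 * date)
    y <- array(rbinom(n_sites * T * J, 1, as.vector(p) * rep(as.vector(z), J)),
               c(n_sites, T, J))
    data <- survey_dataset(y, date, as.data.frame(X), scaling = ident,
                           date_scaling = c(mean = 0, sd = 1))
    cfg <- mcmc_config(seed = seeds[r], n_chains = 1, n_burnin = n_burnin,
                       n_retained = L, thin = thin)
    draws <- fit_model(data, prior, cfg, save_z = FALSE)
    m <- draws_matrix(draws, params)
    ranks[r, ] <- vapply(params, function(p) sum(m[, p] < th[[p]]), numeric(1))
  }
  structure(ranks, class = c("sbc_ranks", class(ranks)), n_ranks = n_ranks)
}

#' Chi-squared uniformity test of SBC ranks
#'
#' Bins the ranks of each tracked parameter and tests the counts against
#' uniformity.
#'
#' @param ranks an `sbc_ranks` matrix.
#' @param n_bins number of equal-width bins (default 10).
#' @return data frame `parameter`, `statistic`, `p_value`.
#' @export
sbc_uniformity <- function(ranks, n_bins = 10) {
  n_ranks <- attr(ranks, "n_ranks")
  breaks <- seq(-0.5, n_ranks - 0.5, length.out = n_bins + 1)
  out <- lapply(colnames(ranks), function(p) {
    counts <- table(cut(ranks[, p], breaks))
    ct <- suppressWarnings(stats::chisq.test(as.numeric(counts)))
    data.frame(parameter = p, statistic = unname(ct$statistic),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
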