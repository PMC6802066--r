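#' MCMC configuration
#'
#' Defaults mirror the standard budget for this model family: 3 chains,
#' 5,000 burn-in iterations, 10,000 retained samples pooled across chains,
#' thinning by 3. The seed must be given explicitly; every chain derives its
#' own sub-seed from it.
#'
#' @param seed integer seed (required).
#' @param n_chains number of chains.
#' @param n_burnin burn-in iterations per chain.
#' @param n_retained total retained draws, pooled across chains.
#' @param thin thinning factor.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(seed, n_chains = 3, n_burnin = 5000,
                        n_retained = 10000, thin = 3) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  counts <- c(n_chains, n_burnin, thin, n_retained)
  if (any(counts < c(1, 0, 1, 1))) stop("invalid MCMC counts")
  structure(list(seed = as.integer(seed), n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_retained = as.integer(n_retained), thin = as.integer(thin)),
            class = "mcmc_config")
}

#' Fit the autologistic multi-season occupancy model
#'
#' Posterior sampling targets the complete-data likelihood (see
#' [complete_data_loglik()]) times independent Normal priors, via a blocked
#' Gibbs sampler: latent states are updated site-year by site-year from
#' their full conditionals, and the two logistic regression blocks
#' (occupancy-level and detection-level coefficients) are updated jointly
#' after Polya-Gamma augmentation. Latent states are initialized at the
#' observed ever-detected indicator (guaranteeing a positive-likelihood
#' start); coefficients start at their prior means, jittered per chain.
#'
#' @param data a [survey_dataset()].
#' @param priors a `prior_spec` covering every model parameter (see
#'   [vague_priors()], [informative_priors()]).
#' @param config an [mcmc_config()].
#' @param share_transitions use a single `a`, `b` for all transitions.
#' @param interaction add the covariate-by-previous-state transition term
#'   (`beta_zint`), using the covariate named in `interaction_cov`.
#' @param interaction_cov covariate entering the interaction.
#' @param save_z retain posterior draws of the latent states (needed for
#'   [posterior_auc()] and [moran_profile()]).
#' @return object of class `posterior_draws`: `values` is a
#'   `chains x iterations x parameters` array, `z` (optionally) a
#'   `chains x iterations x sites x seasons` array.
#' @export
fit_model <- function(data, priors, config, share_transitions = FALSE,
                      interaction = FALSE, interaction_cov = "precipitation",
                      save_z = TRUE) {
  stopifnot(inherits(data, "survey_dataset"), inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  d <- dim(data$y); n <- d[1]; T <- d[2]; J <- d[3]
  X <- data$covariates
  K <- ncol(X)
  nm <- model_param_names(colnames(X), T - 1, share_transitions, interaction)
  all_params <- c(nm$occupancy, nm$detection)

  pe <- priors$entries
  missing <- setdiff(all_params, pe$parameter)
  if (length(missing)) {
    stop("priors missing for parameter(s): ", paste(missing, collapse = ", "))
  }
  pm <- pe$mean[match(all_params, pe$parameter)]
  psd <- pe$sd[match(all_params, pe$parameter)]
  P_occ <- length(nm$occupancy)

  if (interaction) {
    if (!interaction_cov %in% colnames(X)) {
      stop("interaction covariate not found: ", interaction_cov)
    }
    inter_cov <- X[, interaction_cov]
  } else {
    inter_cov <- numeric(n)
  }

  y_int <- data$y
  y_int[is.na(y_int)] <- -1
  storage.mode(y_int) <- "integer"
  z_init <- apply(data$y == 1, c(1, 2), function(v) as.integer(any(v, na.rm = TRUE)))
  if (T == 1) z_init <- matrix(z_init, n, 1)

  per_chain <- as.integer(ceiling(config$n_retained / config$n_chains))
  chain_seeds <- derive_seeds(config$seed, paste0("chain", seq_len(config$n_chains)))

  values <- array(NA_real_, c(config$n_chains, per_chain, length(all_params)),
                  dimnames = list(NULL, NULL, all_params))
  z_arr <- if (save_z) {
    array(NA_integer_, c(config$n_chains, per_chain, n, T))
  } else NULL

  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    th0_occ <- rnorm(P_occ, pm[seq_len(P_occ)], 0.1)
    th0_det <- rnorm(2, pm[P_occ + 1:2], 0.1)
    res <- .occu_gibbs_chain(
      as.vector(y_int), as.vector(data$date), X, n, T, J,
      pm[seq_len(P_occ)], 1 / psd[seq_len(P_occ)]^2,
      pm[P_occ + 1:2], 1 / psd[P_occ + 1:2]^2,
      th0_occ, th0_det, z_init,
      config$n_burnin, per_chain, config$thin,
      share_transitions, interaction, inter_cov, save_z
    )
    values[ch, , ] <- res$theta
    if (save_z) z_arr[ch, , , ] <- array(res$z, c(per_chain, n, T))
  }

  structure(list(
    values = values,
    z = z_arr,
    param_names = nm,
    config = config,
    priors = priors,
    scaling = data$scaling,
    date_scaling = data$date_scaling,
    covariate_names = colnames(X),
    dims = c(n = n, T = T, J = J),
    share_transitions = share_transitions,
    interaction = interaction,
    interaction_cov = if (interaction) interaction_cov else NULL
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$values)
  cat("posterior_draws:", d[1], "chains x", d[2], "iterations x", d[3],
      "parameters\n")
  cat("  priors:", x$priors$provenance, "| latent z retained:",
      !is.null(x$z), "\n")
  invisible(x)
}

#' Pooled draws matrix
#'
#' @param draws a `posterior_draws`.
#' @param params optional subset of parameter names.
#' @return matrix `(chains * iterations) x parameters`.
#' @export
draws_matrix <- function(draws, params = NULL) {
  v <- draws$values
  d <- dim(v)
  m <- matrix(aperm(v, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(v)[[3]]
  if (!is.null(params)) m <- m[, params, drop = FALSE]
  m
}

# a/b draw columns for transition s (handles shared transitions)
ab_cols <- function(draws, s) {
  if (draws$share_transitions) c(a = "a", b = "b")
  else c(a = paste0("a_", s), b = paste0("b_", s))
}

#' Per-draw derived dynamic quantities
#'
#' Computes, for every retained draw and at standardized covariates 0:
#' \eqn{\phi_t}, \eqn{\gamma_t} per transition, the occupancy trajectory
#' \eqn{\Psi_1 \ldots \Psi_T}, and the growth rates `lambda_total`,
#' `lambda_annual`. Derived quantities are always computed draw by draw,
#' never from summarized parameters.
#'
#' @param draws a `posterior_draws`.
#' @return array `chains x iterations x quantities`.
#' @export
derived_array <- function(draws) {
  d <- dim(draws$values)
  T <- draws$dims[["T"]]
  S <- T - 1
  qn <- c(if (S > 0) c(paste0("phi_", seq_len(S)), paste0("gamma_", seq_len(S))),
          paste0("psi_", seq_len(T)),
          if (S > 0) c("lambda_total", "lambda_annual"))
  out <- array(NA_real_, c(d[1], d[2], length(qn)),
               dimnames = list(NULL, NULL, qn))
  for (ch in seq_len(d[1])) {
    v <- draws$values[ch, , , drop = TRUE]
    if (is.null(dim(v))) v <- matrix(v, d[2], d[3], dimnames = list(NULL, dimnames(draws$values)[[3]]))
    psi <- invlogit(v[, "beta0"])
    out[ch, , paste0("psi_", 1)] <- psi
    if (S > 0) {
      for (s in seq_len(S)) {
        ab <- ab_cols(draws, s)
        dyn <- derived_dynamics(v[, ab[["a"]]], v[, ab[["b"]]])
        out[ch, , paste0("phi_", s)] <- dyn$phi
        out[ch, , paste0("gamma_", s)] <- dyn$gamma
        psi <- occupancy_recursion(psi, dyn$phi, dyn$gamma)
        out[ch, , paste0("psi_", s + 1)] <- psi
      }
      lt <- out[ch, , paste0("psi_", T)] / out[ch, , "psi_1"]
      out[ch, , "lambda_total"] <- lt
      out[ch, , "lambda_annual"] <- lt^(1 / S)
    }
  }
  out
}

summary_rows <- function(arr, kind, probs = c(0.025, 0.975)) {
  d <- dim(arr)
  pooled <- matrix(aperm(arr, c(2, 1, 3)), d[1] * d[2], d[3])
  rhat <- tryCatch(gelman_rubin(arr), error = function(e) rep(NA_real_, d[3]))
  data.frame(
    parameter = dimnames(arr)[[3]],
    kind = kind,
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    q2.5 = apply(pooled, 2, quantile, probs[1]),
    q97.5 = apply(pooled, 2, quantile, probs[2]),
    rhat = as.numeric(rhat),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Posterior summary table
#'
#' Mean, SD and equal-tailed 95% interval per parameter, plus (by default)
#' the derived dynamic quantities of [derived_array()], each computed per
#' draw and then summarized. A split-chain Gelman-Rubin statistic is
#' attached per row.
#'
#' @param draws a `posterior_draws`.
#' @param derived include derived quantities?
#' @param probs interval probabilities (equal-tailed).
#' @return data frame with columns `parameter`, `kind`, `mean`, `sd`,
#'   `q2.5`, `q97.5`, `rhat`.
#' @export
summarize_posterior <- function(draws, derived = TRUE,
                                probs = c(0.025, 0.975)) {
  stopifnot(inherits(draws, "posterior_draws"))
  out <- summary_rows(draws$values, "parameter", probs)
  if (derived) {
    out <- rbind(out, summary_rows(derived_array(draws), "derived", probs))
  }
  out
}

# site-by-draw matrix of Psi_{year, i}: the per-draw occupancy probability
# trajectory evaluated at each row of the standardized covariate matrix X
psi_site_draws <- function(draws, X, year, draw_idx = NULL) {
  m <- draws_matrix(draws)
  if (!is.null(draw_idx)) m <- m[draw_idx, , drop = FALSE]
  X <- as.matrix(X)
  eta <- if (ncol(X)) X %*% t(m[, paste0("beta_", draws$covariate_names),
                                drop = FALSE]) else
    matrix(0, nrow(X), nrow(m))
  psi <- invlogit(matrix(m[, "beta0"], nrow(X), nrow(m), byrow = TRUE) + eta)
  if (year > 1) {
    for (s in seq_len(year - 1)) {
      ab <- ab_cols(draws, s)
      ea <- matrix(m[, ab[["a"]]], nrow(X), nrow(m), byrow = TRUE) + eta
      eb <- matrix(m[, ab[["b"]]], nrow(X), nrow(m), byrow = TRUE)
      if (isTRUE(draws$interaction)) {
        eb <- eb + outer(X[, draws$interaction_cov], m[, "beta_zint"])
      }
      gam <- invlogit(ea)
      phi <- invlogit(ea + eb)
      psi <- psi * phi + (1 - psi) * gam
    }
  }
  psi
}

#' Frame-wide posterior occupancy prediction
#'
#' For every cell of a sampling-frame covariate table, runs the initial
#' occupancy model and the occupancy recursion with each retained draw's
#' parameters and summarizes the posterior of \eqn{\Psi_{year, i}}. Raw
#' frame covariates are transformed with the standardization constants
#' stored at fitting time, so predictions are on the fitted scale.
#'
#' @param draws a `posterior_draws`.
#' @param frame_covariates data frame of raw frame covariates (same columns
#'   as the fitted data); a `cell_id` column is carried through.
#' @param year season index to predict (default: last fitted season).
#' @param standardized set `TRUE` only if `frame_covariates` are already on
#'   the fitted standardized scale.
#' @param chunk_size draws processed per block (memory control).
#' @return data frame `cell_id`, `psi_mean`, `psi_sd`.
#' @export
predict_psi_frame <- function(draws, frame_covariates,
                              year = draws$dims[["T"]], standardized = FALSE,
                              chunk_size = 2000) {
  stopifnot(inherits(draws, "posterior_draws"))
  fr <- as.data.frame(frame_covariates)
  cell_id <- fr$cell_id %||% seq_len(nrow(fr))
  covs <- fr[, draws$covariate_names, drop = FALSE]
  if (!standardized) {
    if (!nrow(draws$scaling) && length(draws$covariate_names)) {
      stop("no stored standardization constants; pass standardized covariates")
    }
    covs <- standardize_covariates(covs, scaling = draws$scaling)$standardized
  }
  X <- as.matrix(covs)
  M <- prod(dim(draws$values)[1:2])
  s1 <- numeric(nrow(X)); s2 <- numeric(nrow(X))
  for (start in seq(1, M, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, M)
    psi <- psi_site_draws(draws, X, year, draw_idx = idx)
    s1 <- s1 + rowSums(psi)
    s2 <- s2 + rowSums(psi^2)
  }
  mu <- s1 / M
  data.frame(cell_id = cell_id, psi_mean = mu,
             psi_sd = sqrt(pmax(s2 / M - mu^2, 0) * M / (M - 1)))
}
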