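#' Model parameter set
#'
#' Collects all free parameters of the autologistic multi-season occupancy
#' model: the initial-occupancy intercept `beta0` and covariate slopes
#' `beta`, the per-transition intercepts `a[t]` and autologistic offsets
#' `b[t]` (length `T - 1`), and the detection intercept/date slope
#' `alpha0`, `alpha1`. An optional `beta_zint` adds a covariate-by-previous-
#' state interaction to the transition predictor.
#'
#' @param beta0 initial-occupancy intercept (logit scale).
#' @param beta named numeric vector of covariate slopes (may be length 0).
#' @param a,b numeric vectors of equal length `T - 1`.
#' @param alpha0,alpha1 detection intercept and (standardized) date slope.
#' @param beta_zint optional interaction coefficient (previous state times
#'   the covariate named in `interaction_cov`).
#' @param interaction_cov covariate entering the interaction (default
#'   `"precipitation"`).
#' @return object of class `param_set`.
#' @export
param_set <- function(beta0, beta = numeric(0), a = numeric(0), b = numeric(0),
                      alpha0 = 0, alpha1 = 0, beta_zint = NULL,
                      interaction_cov = "precipitation") {
  if (length(a) != length(b)) stop("a and b must have equal length (T - 1)")
  vals <- c(beta0, beta, a, b, alpha0, alpha1, beta_zint)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  structure(list(beta0 = beta0, beta = beta, a = a, b = b,
                 alpha0 = alpha0, alpha1 = alpha1, beta_zint = beta_zint,
                 interaction_cov = interaction_cov),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("param_set: beta0 =", format(x$beta0, digits = 3),
      "| K =", length(x$beta), "slopes | T-1 =", length(x$a), "transitions\n")
  invisible(x)
}

check_covs <- function(params, site_covs) {
  site_covs <- as.matrix(site_covs)
  if (ncol(site_covs) != length(params$beta)) {
    stop("covariate/coefficient length mismatch: ", ncol(site_covs),
         " columns vs ", length(params$beta), " slopes")
  }
  site_covs
}

#' Initial-season occupancy probability
#'
#' \eqn{\Psi_{1,i} = \mathrm{logit}^{-1}(\beta_0 + \sum_k \beta_k x_{k,i})},
#' evaluated at standardized covariates, so at all-zero covariates it equals
#' `plogis(beta0)` (average environmental conditions).
#'
#' @param params a [param_set()].
#' @param site_covs matrix of standardized covariates (one row per site).
#' @return numeric vector of probabilities.
#' @export
initial_occupancy_prob <- function(params, site_covs) {
  X <- check_covs(params, site_covs)
  as.numeric(invlogit(params$beta0 + X %*% params$beta))
}

#' Transition probability for the autologistic dynamics
#'
#' Probability that a site is occupied in season `t` given its state in
#' season `t - 1`: \eqn{\mathrm{logit}(\pi_{t,i}) = a_t + b_t z_{i,t-1} +
#' \sum_k \beta_k x_{k,i}} (plus the optional interaction term). With
#' `z_prev = 1` and covariates at 0 this is the persistence probability
#' \eqn{\phi_t}; with `z_prev = 0` it is the colonization probability
#' \eqn{\gamma_t}.
#'
#' @inheritParams initial_occupancy_prob
#' @param z_prev previous occupancy state(s), 0/1 (scalar or one per site).
#' @param t season index, `2 <= t <= T`.
#' @return numeric vector of probabilities.
#' @export
transition_prob <- function(params, site_covs, z_prev, t) {
  T <- length(params$a) + 1
  if (t < 2 || t > T) stop("t out of range: need 2 <= t <= ", T)
  X <- check_covs(params, site_covs)
  if (!all(z_prev %in% c(0, 1))) stop("z_prev must be 0 or 1")
  eta <- params$a[t - 1] + params$b[t - 1] * z_prev +
    as.numeric(X %*% params$beta)
  if (!is.null(params$beta_zint)) {
    ic <- params$interaction_cov
    if (!ic %in% colnames(X)) stop("interaction covariate not found: ", ic)
    eta <- eta + params$beta_zint * X[, ic] * z_prev
  }
  as.numeric(invlogit(eta))
}

#' Derived dynamic parameters
#'
#' Persistence \eqn{\phi_t = \mathrm{logit}^{-1}(a_t + b_t)} and colonization
#' \eqn{\gamma_t = \mathrm{logit}^{-1}(a_t)}, at average environmental
#' conditions (standardized covariates equal to 0).
#'
#' @param a,b transition intercepts and autologistic offsets (vectors).
#' @return list with components `phi` and `gamma`.
#' @export
derived_dynamics <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  list(phi = invlogit(a + b), gamma = invlogit(a))
}

#' One step of the occupancy recursion
#'
#' \eqn{\Psi_t = \Psi_{t-1}\phi_t + (1 - \Psi_{t-1})\gamma_t}.
#'
#' @param psi_prev,phi_t,gamma_t probabilities in `[0, 1]` (vectorized).
#' @return \eqn{\Psi_t}.
#' @export
occupancy_recursion <- function(psi_prev, phi_t, gamma_t) {
  vals <- c(psi_prev, phi_t, gamma_t)
  if (any(vals < 0 | vals > 1)) stop("inputs must lie in [0, 1]")
  psi_prev * phi_t + (1 - psi_prev) * gamma_t
}

#' Full occupancy trajectory
#'
#' Applies [occupancy_recursion()] sequentially from \eqn{\Psi_1}.
#'
#' @param psi1 initial occupancy probability (scalar or per site).
#' @param phi,gamma vectors of length `T - 1` (or matrices, sites x T-1).
#' @return vector (or matrix) of \eqn{\Psi_1, \ldots, \Psi_T}.
#' @export
psi_trajectory <- function(psi1, phi, gamma) {
  phi <- rbind(phi); gamma <- rbind(gamma)
  S <- ncol(phi)
  out <- matrix(NA_real_, length(psi1), S + 1)
  out[, 1] <- psi1
  for (s in seq_len(S)) {
    out[, s + 1] <- occupancy_recursion(out[, s], phi[, s], gamma[, s])
  }
  if (nrow(out) == 1) drop(out) else out
}

#' Occurrence growth rate (trend metric)
#'
#' The total growth rate \eqn{\lambda_{total} = \Psi_T / \Psi_1} over the
#' monitored period, and its annualization \eqn{\lambda_{annual} =
#' \lambda_{total}^{1/(T-1)}}. Values below 1 indicate net contraction of
#' the occupied range.
#'
#' @param psi_trajectory vector \eqn{(\Psi_1, \ldots, \Psi_T)}, `T >= 2`.
#' @return list with `lambda_total` and `lambda_annual`.
#' @export
occurrence_growth_rate <- function(psi_trajectory) {
  T <- length(psi_trajectory)
  if (T < 2) stop("trajectory must have length >= 2")
  if (psi_trajectory[1] <= 0) stop("initial occupancy must be positive")
  lt <- psi_trajectory[T] / psi_trajectory[1]
  list(lambda_total = lt, lambda_annual = lt^(1 / (T - 1)))
}

#' Per-visit detection probability
#'
#' \eqn{\mathrm{logit}(p) = \alpha_0 + \alpha_1 \cdot date} with a
#' standardized date covariate.
#'
#' @param alpha0,alpha1 detection intercept and date slope.
#' @param date standardized date value(s).
#' @return probabilities.
#' @export
detection_prob <- function(alpha0, alpha1, date) {
  invlogit(alpha0 + alpha1 * date)
}

# log Bernoulli(y | p) evaluated stably on the logit scale; -Inf when the
# event is impossible (p exactly 0 or 1 against it)
log_bern_logit <- function(y, eta) {
  ifelse(y == 1, log_invlogit(eta), log_invlogit(-eta))
}

#' Complete-data log likelihood
#'
#' Joint log probability of latent states and observations:
#' \eqn{\sum_i [\log P(z_{i,1}) + \sum_t \log P(z_{i,t} | z_{i,t-1})
#' + \sum_{t,j} \log P(y_{i,t,j} | z_{i,t})]}, skipping missing visits.
#' A detection at an unoccupied site-year (`y = 1`, `z = 0`) yields
#' `-Inf` — the model admits no false positives.
#'
#' @param params a [param_set()].
#' @param z binary matrix `n x T` of latent states.
#' @param data a [survey_dataset()].
#' @return scalar log likelihood (possibly `-Inf`).
#' @export
complete_data_loglik <- function(params, z, data) {
  stopifnot(inherits(data, "survey_dataset"))
  z <- rbind(z)
  d <- dim(data$y); n <- d[1]; T <- d[2]; J <- d[3]
  if (nrow(z) != n || ncol(z) != T) stop("z dimensions must match data")
  if (!all(z %in% c(0, 1))) stop("z must be binary")
  X <- data$covariates

  psi1 <- initial_occupancy_prob(params, X)
  ll <- sum(log(ifelse(z[, 1] == 1, psi1, 1 - psi1)))
  if (T > 1) {
    for (t in 2:T) {
      pit <- transition_prob(params, X, z[, t - 1], t)
      ll <- ll + sum(log(ifelse(z[, t] == 1, pit, 1 - pit)))
    }
  }
  for (t in seq_len(T)) {
    for (j in seq_len(J)) {
      y <- data$y[, t, j]
      obs <- !is.na(y)
      if (!any(obs)) next
      p <- detection_prob(params$alpha0, params$alpha1, data$date[obs, t, j])
      pz <- p * z[obs, t]  # P(y = 1 | z)
      ll <- ll + sum(log(ifelse(y[obs] == 1, pz, 1 - pz)))
    }
  }
  ll
}

#' Marginal log likelihood of one site's detection history
#'
#' Sums the complete-data likelihood over all `2^T` latent sequences by a
#' forward recursion over seasons (two-state HMM filter), in log space.
#' Useful as an exact oracle for the sampler and for likelihood-based model
#' scoring without latent draws.
#'
#' @param params a [param_set()].
#' @param data a [survey_dataset()].
#' @param site site index.
#' @return scalar log marginal likelihood.
#' @export
site_marginal_loglik <- function(params, data, site) {
  stopifnot(inherits(data, "survey_dataset"))
  d <- dim(data$y); T <- d[2]; J <- d[3]
  X <- data$covariates[site, , drop = FALSE]

  # log P(y_{site,t,.} | z) for z = 0, 1
  obs_ll <- function(t, zst) {
    y <- data$y[site, t, ]
    obs <- which(!is.na(y))
    if (!length(obs)) return(0)
    p <- detection_prob(params$alpha0, params$alpha1, data$date[site, t, obs])
    pz <- p * zst
    sum(log(ifelse(y[obs] == 1, pz, 1 - pz)))
  }

  psi1 <- initial_occupancy_prob(params, X)
  lf <- c(log(1 - psi1) + obs_ll(1, 0), log(psi1) + obs_ll(1, 1))
  if (T > 1) {
    for (t in 2:T) {
      p0 <- transition_prob(params, X, 0, t)  # P(z_t = 1 | z_{t-1} = 0)
      p1 <- transition_prob(params, X, 1, t)
      new0 <- logsumexp(c(lf[1] + log(1 - p0), lf[2] + log(1 - p1))) + obs_ll(t, 0)
      new1 <- logsumexp(c(lf[1] + log(p0), lf[2] + log(p1))) + obs_ll(t, 1)
      lf <- c(new0, new1)
    }
  }
  logsumexp(lf)
}

#' Marginal log likelihood of the whole dataset
#'
#' @inheritParams site_marginal_loglik
#' @return sum of [site_marginal_loglik()] over sites.
#' @export
marginal_loglik <- function(params, data) {
  sum(vapply(seq_len(dim(data$y)[1]),
             function(i) site_marginal_loglik(params, data, i), numeric(1)))
}
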