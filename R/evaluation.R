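#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted 1/2 — the normalized Mann-Whitney U
#' statistic.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), at least one of each class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("labels must contain both classes")
  r <- rank(scores)  # average ranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior AUC predictive summary
#'
#' Internal-validation AUC in the style used for occupancy models: for each
#' retained draw m, the per-site occupancy probabilities
#' \eqn{\Psi^{(m)}_{i,year}} are scored against that same draw's latent
#' states \eqn{z^{(m)}_{i,year}}, and the resulting AUC distribution is
#' summarized. Draws whose latent states are single-class are skipped and
#' counted. Scoring against raw detection indicators (which conflates
#' detection and occupancy) is available via `labels = "observed"`.
#'
#' @param draws a `posterior_draws` fitted with `save_z = TRUE`.
#' @param data the fitted [survey_dataset()].
#' @param year season index to evaluate (default: last).
#' @param labels `"latent"` (default) or `"observed"`.
#' @return object of class `auc_summary`: posterior mean, sd, 2.5% and
#'   97.5% quantiles of AUC, the year, and the number of skipped draws.
#' @export
posterior_auc <- function(draws, data, year = draws$dims[["T"]],
                          labels = c("latent", "observed")) {
  stopifnot(inherits(draws, "posterior_draws"))
  labels <- match.arg(labels)
  if (is.null(draws$z)) stop("posterior z draws required (refit with save_z = TRUE)")
  d <- dim(draws$z)
  M <- d[1] * d[2]; n <- d[3]
  zmat <- matrix(aperm(draws$z[, , , year, drop = FALSE], c(2, 1, 3, 4)), M, n)
  psi <- psi_site_draws(draws, data$covariates, year)  # n x M
  if (labels == "observed") {
    obs <- apply(data$y[, year, , drop = FALSE] == 1, 1, function(v) as.integer(any(v, na.rm = TRUE)))
  }
  aucs <- rep(NA_real_, M)
  for (m in seq_len(M)) {
    lab <- if (labels == "latent") zmat[m, ] else obs
    if (length(unique(lab)) < 2) next
    aucs[m] <- auc_rank(psi[, m], lab)
  }
  skipped <- sum(is.na(aucs))
  if (skipped == M) stop("no draws with both label classes in year ", year)
  aucs <- aucs[!is.na(aucs)]
  structure(list(mean = mean(aucs), sd = stats::sd(aucs),
                 q2.5 = unname(quantile(aucs, 0.025)),
                 q97.5 = unname(quantile(aucs, 0.975)),
                 year = year, n_skipped = skipped, n_draws = M),
            class = "auc_summary")
}

#' @export
print.auc_summary <- function(x, ...) {
  cat(sprintf("posterior AUC (year %d): %.3f (95%% CrI %.3f-%.3f), %d/%d draws skipped\n",
              x$year, x$mean, x$q2.5, x$q97.5, x$n_skipped, x$n_draws))
  invisible(x)
}

# binary neighbor weights within a distance threshold (closed interval)
neighbor_weights <- function(coords, threshold_km) {
  D <- as.matrix(stats::dist(coords))
  W <- (D > 0 & D <= threshold_km) * 1
  diag(W) <- 0
  W
}

#' Moran's I spatial autocorrelation statistic
#'
#' \eqn{I = (n / \sum_{ij} w_{ij}) \cdot \sum_{ij} w_{ij}(x_i - \bar x)
#' (x_j - \bar x) / \sum_i (x_i - \bar x)^2} with binary weights
#' \eqn{w_{ij} = 1} iff `0 < d(i, j) <= threshold_km` (Euclidean on km
#' coordinates). Under no autocorrelation its expectation is
#' `-1/(n - 1)`.
#'
#' @param x per-site values (e.g. occupancy residuals).
#' @param coords n x 2 matrix of site coordinates (km).
#' @param threshold_km neighborhood distance threshold.
#' @return scalar Moran's I.
#' @export
morans_i <- function(x, coords, threshold_km) {
  x <- as.numeric(x)
  n <- length(x)
  if (nrow(as.matrix(coords)) != n) stop("coords/x length mismatch")
  if (stats::var(x) == 0) stop("zero variance in x")
  W <- neighbor_weights(coords, threshold_km)
  S0 <- sum(W)
  if (S0 == 0) stop("no neighbor pairs at threshold ", threshold_km, " km")
  xc <- x - mean(x)
  (n / S0) * sum(W * outer(xc, xc)) / sum(xc^2)
}

#' Permutation test for Moran's I
#'
#' One-sided (clustering) permutation test: site labels of `x` are permuted
#' and the observed I compared against the permutation distribution, with
#' the add-one correction `p = (1 + #{I* >= I}) / (n_perm + 1)`.
#'
#' @inheritParams morans_i
#' @param n_perm number of permutations.
#' @param seed seed for the permutation draw.
#' @return list with `I`, `p`, `null_mean`.
#' @export
morans_i_perm <- function(x, coords, threshold_km, n_perm = 999, seed = 1) {
  n <- length(x)
  I_obs <- morans_i(x, coords, threshold_km)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  W <- neighbor_weights(coords, threshold_km)
  S0 <- sum(W)
  i_of <- function(v) {
    vc <- v - mean(v)
    (n / S0) * sum(vc * (W %*% vc)) / sum(vc^2)
  }
  I_null <- replicate(n_perm, i_of(x[sample.int(n)]))
  list(I = I_obs, p = (1 + sum(I_null >= I_obs)) / (n_perm + 1),
       null_mean = -1 / (n - 1))
}

#' Moran's I profile of posterior occupancy residuals
#'
#' Per retained draw m, the occupancy-level residual \eqn{r^{(m)}_i =
#' z^{(m)}_{i,T} - \Psi^{(m)}_{i,T}} is computed and Moran's I evaluated at
#' each distance threshold; the posterior-mean I per threshold is reported
#' with a one-sided (clustering) permutation p-value obtained by permuting
#' the posterior-mean residuals across sites.
#'
#' @param draws a `posterior_draws` fitted with `save_z = TRUE`.
#' @param data the fitted [survey_dataset()] (must carry coordinates).
#' @param thresholds_km distance thresholds (default 10, 20, ..., 50 km).
#' @param year season index (default: last).
#' @param n_perm permutations for the null (default 999).
#' @param seed seed for the permutation draw.
#' @return object of class `moran_profile`: data frame with columns
#'   `threshold_km`, `I`, `null_mean`, `p`.
#' @export
moran_profile <- function(draws, data, thresholds_km = seq(10, 50, by = 10),
                          year = draws$dims[["T"]], n_perm = 999, seed = 1) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(draws$z)) stop("posterior z draws required (refit with save_z = TRUE)")
  if (is.null(data$coords)) stop("data has no coordinates")
  d <- dim(draws$z)
  M <- d[1] * d[2]; n <- d[3]
  zmat <- t(matrix(aperm(draws$z[, , , year, drop = FALSE], c(2, 1, 3, 4)), M, n))  # n x M
  psi <- psi_site_draws(draws, data$covariates, year)
  R <- zmat - psi
  Rc <- sweep(R, 2, colMeans(R))
  den <- colSums(Rc^2)
  rbar <- rowMeans(R)

  rows <- lapply(thresholds_km, function(th) {
    W <- neighbor_weights(data$coords, th)
    S0 <- sum(W)
    if (S0 == 0) stop("no neighbor pairs at threshold ", th, " km")
    ok <- den > 0
    I_draws <- (n / S0) * colSums(Rc[, ok, drop = FALSE] *
                                    (W %*% Rc[, ok, drop = FALSE])) / den[ok]
    pt <- morans_i_perm(rbar, data$coords, th, n_perm = n_perm, seed = seed)
    data.frame(threshold_km = th, I = mean(I_draws),
               null_mean = -1 / (n - 1), p = pt$p)
  })
  structure(do.call(rbind, rows), class = c("moran_profile", "data.frame"))
}

ci_position <- function(q25, q975) {
  ifelse(q25 > 0, "excludes0+", ifelse(q975 < 0, "excludes0-", "contains0"))
}

#' Vague vs. informative prior-sensitivity comparison
#'
#' Compares posterior inference for the same model and data under the two
#' prior regimes: per-parameter posterior means and SDs, the SD ratio
#' (informative/vague; below 1 indicates the precision gain from carrying
#' information across periods), and whether the position of the 95%
#' credible interval relative to 0 agrees. Plot-ready prior and posterior
#' density curves are exported for both regimes.
#'
#' @param draws_vague,draws_informative `posterior_draws` for the same data
#'   and model under vague and informative priors.
#' @param params parameters to compare (default: all shared).
#' @return object of class `prior_sensitivity`: list with `table` and tidy
#'   `densities` (columns `parameter`, `regime`, `kind`, `grid_value`,
#'   `density`).
#' @export
prior_sensitivity <- function(draws_vague, draws_informative, params = NULL) {
  stopifnot(inherits(draws_vague, "posterior_draws"),
            inherits(draws_informative, "posterior_draws"))
  pv <- dimnames(draws_vague$values)[[3]]
  pi_ <- dimnames(draws_informative$values)[[3]]
  if (!setequal(pv, pi_)) stop("parameter sets differ between the two fits")
  params <- params %||% pv
  mv <- draws_matrix(draws_vague, params)
  mi <- draws_matrix(draws_informative, params)

  tab <- data.frame(
    parameter = params,
    mean_vague = colMeans(mv), sd_vague = apply(mv, 2, stats::sd),
    mean_informative = colMeans(mi), sd_informative = apply(mi, 2, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$sd_ratio <- tab$sd_informative / tab$sd_vague
  qv <- apply(mv, 2, quantile, c(0.025, 0.975))
  qi <- apply(mi, 2, quantile, c(0.025, 0.975))
  tab$ci_vague <- ci_position(qv[1, ], qv[2, ])
  tab$ci_informative <- ci_position(qi[1, ], qi[2, ])
  tab$sign_agreement <- tab$ci_vague == tab$ci_informative

  dens1 <- function(x, param, regime, kind) {
    d <- stats::density(x, n = 256)
    data.frame(parameter = param, regime = regime, kind = kind,
               grid_value = d$x, density = d$y, stringsAsFactors = FALSE)
  }
  prior_dens <- function(draws, param, regime) {
    e <- draws$priors$entries
    row <- e[e$parameter == param, ]
    g <- seq(row$mean - 4 * row$sd, row$mean + 4 * row$sd, length.out = 256)
    data.frame(parameter = param, regime = regime, kind = "prior",
               grid_value = g, density = dnorm(g, row$mean, row$sd),
               stringsAsFactors = FALSE)
  }
  dens <- do.call(rbind, c(
    lapply(params, function(p) dens1(mv[, p], p, "vague", "posterior")),
    lapply(params, function(p) dens1(mi[, p], p, "informative", "posterior")),
    lapply(params, function(p) prior_dens(draws_vague, p, "vague")),
    lapply(params, function(p) prior_dens(draws_informative, p, "informative"))
  ))
  structure(list(table = tab, densities = dens), class = "prior_sensitivity")
}

#' @export
print.prior_sensitivity <- function(x, ...) {
  cat("prior sensitivity comparison (", nrow(x$table), " parameters)\n", sep = "")
  print(x$table[, c("parameter", "mean_vague", "mean_informative",
                    "sd_ratio", "sign_agreement")], row.names = FALSE,
        digits = 3)
  invisible(x)
}
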