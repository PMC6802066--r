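#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (the split variant is more conservative than the original
#' diagnostic: it also flags non-stationarity within a chain). Values near 1
#' indicate convergence; the conventional acceptance rule for this model
#' family is `|rhat - 1| < 0.1`.
#'
#' @param x a `posterior_draws` or a `chains x iterations x parameters`
#'   array.
#' @return named vector of R-hat values (NaN for degenerate, constant
#'   chains).
#' @export
gelman_rubin <- function(x) {
  arr <- if (inherits(x, "posterior_draws")) x$values else x
  d <- dim(arr)
  if (length(d) != 3) stop("need a chains x iterations x parameters array")
  if (d[1] < 2) stop("at least 2 chains are required")
  half <- d[2] %/% 2
  if (half < 5) stop("at least 10 iterations per chain are required")
  vapply(seq_len(d[3]), function(p) {
    halves <- list()
    for (ch in seq_len(d[1])) {
      v <- arr[ch, , p]
      halves <- c(halves, list(v[seq_len(half)], v[(d[2] - half + 1):d[2]]))
    }
    m <- length(halves)
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W == 0) return(NaN)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(dimnames(arr)[[3]])
}

#' Convergence verdict under the |R-hat - 1| rule
#'
#' @param rhat named vector from [gelman_rubin()] (or a `posterior_draws`,
#'   which is summarized first).
#' @param tol tolerance on `|rhat - 1|` (default 0.1).
#' @return list with `converged` (logical), `max_dev` (max `|rhat - 1|`),
#'   and `offending` (parameter names failing the rule, including any with
#'   undefined R-hat).
#' @export
convergence_check <- function(rhat, tol = 0.1) {
  if (inherits(rhat, "posterior_draws")) rhat <- gelman_rubin(rhat)
  dev <- abs(rhat - 1)
  bad <- names(rhat)[is.na(dev) | dev >= tol]
  list(converged = length(bad) == 0,
       max_dev = if (all(is.na(dev))) NA_real_ else max(dev, na.rm = TRUE),
       offending = bad)
}
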