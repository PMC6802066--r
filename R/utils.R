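# small numeric helpers shared across the package

invlogit <- function(x) plogis(x)

logit <- function(p) qlogis(p)

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(plogis(x)) evaluated stably
log_invlogit <- function(x) plogis(x, log.p = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive named sub-seeds from one top-level seed, all < 2^31
derive_seeds <- function(seed, names) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}
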