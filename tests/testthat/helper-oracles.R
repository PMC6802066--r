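# Independent oracles: computed from first principles, never through the
# package's own likelihood or sampler code paths.

# Marginal likelihood of one site's history by brute-force enumeration of
# all 2^T latent sequences.
enum_site_loglik <- function(beta0, beta, a, b, alpha0, alpha1,
                             x, y, date) {
  # x: covariate vector; y, date: T x J matrices (NA = missing visit)
  T <- nrow(y)
  eta_x <- sum(beta * x)
  psi1 <- 1 / (1 + exp(-(beta0 + eta_x)))
  seqs <- as.matrix(expand.grid(rep(list(0:1), T)))
  total <- 0
  for (r in seq_len(nrow(seqs))) {
    zs <- as.numeric(seqs[r, ])
    pr <- if (zs[1] == 1) psi1 else 1 - psi1
    if (T > 1) {
      for (t in 2:T) {
        eta <- a[t - 1] + b[t - 1] * zs[t - 1] + eta_x
        pi_t <- 1 / (1 + exp(-eta))
        pr <- pr * if (zs[t] == 1) pi_t else 1 - pi_t
      }
    }
    for (t in seq_len(T)) {
      for (j in seq_len(ncol(y))) {
        if (is.na(y[t, j])) next
        p <- 1 / (1 + exp(-(alpha0 + alpha1 * date[t, j]))) * zs[t]
        pr <- pr * if (y[t, j] == 1) p else 1 - p
      }
    }
    total <- total + pr
  }
  log(total)
}

# Pairwise-counting AUC (ties count 1/2) - the Mann-Whitney definition
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (s1 in pos) for (s0 in neg) {
    tot <- tot + if (s1 > s0) 1 else if (s1 == s0) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
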