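# Brute-force lattice minimisation of the two scalar-variability
# likelihoods, used as an independent oracle for the optimizer-based fits.
# Lattice rows with a non-positive predicted mean or SD are excluded.

grid_search_linear <- function(numerosity, response, a_seq, b_seq, s_seq) {
  best <- NULL
  best_val <- Inf
  for (a in a_seq) {
    mu <- a + outer(b_seq, numerosity)          # length(b_seq) x n
    valid <- rowSums(mu <= 0) == 0
    if (!any(valid)) next
    for (s in s_seq) {
      ll <- rep(Inf, length(b_seq))
      m <- mu[valid, , drop = FALSE]
      dens <- dnorm(response[col(m)], m, s * m, log = TRUE)
      ll[valid] <- -rowSums(matrix(dens, nrow = nrow(m)))
      i <- which.min(ll)
      if (ll[i] < best_val) {
        best_val <- ll[i]
        best <- c(a, b_seq[i], s)
      }
    }
  }
  list(par = best, value = best_val)
}

grid_search_power <- function(numerosity, response, sc_seq, e_seq, s_seq) {
  best <- NULL
  best_val <- Inf
  for (sc in sc_seq) {
    mu <- sc * t(outer(numerosity, e_seq, `^`)) # length(e_seq) x n
    for (s in s_seq) {
      dens <- dnorm(response[col(mu)], mu, s * mu, log = TRUE)
      ll <- -rowSums(matrix(dens, nrow = nrow(mu)))
      i <- which.min(ll)
      if (ll[i] < best_val) {
        best_val <- ll[i]
        best <- c(sc, e_seq[i], s)
      }
    }
  }
  list(par = best, value = best_val)
}

# Deterministic mean observer: posterior-mean responses with no scatter.
mean_observer <- function(prior_mean = 15, prior_sd = 5, noise_k = 3,
                          noise_exponent = 0) {
  obs <- bayes_observer(prior_mean = prior_mean, prior_sd = prior_sd,
                        noise_k = noise_k, noise_exponent = noise_exponent,
                        response_jitter_sd = 0)
  lapply(stats::setNames(c("VSL", "IS", "ID"), c("VSL", "IS", "ID")),
         function(cc) obs)
}
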