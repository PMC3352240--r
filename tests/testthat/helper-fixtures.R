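# shared small fixtures, built in code

# a tiny 2-cluster spike matrix with known structure: two waveforms with
# per-spike amplitude variability (so both leading eigenvalues stand
# well above the white-noise floor and the first two PCs are
# identifiable) plus white noise, rows shuffled deterministically
tiny_spike_matrix <- function(n_per = 50, d = 16, noise_sd = 0.05,
                              amp_sd = 0.3, seed = 1) {
  set.seed(seed)
  t <- seq_len(d)
  w1 <- exp(-(t - 5)^2 / 2)
  w2 <- 0.55 * (exp(-(t - 5)^2 / 8) - 0.4 * exp(-(t - 11)^2 / 6))
  a1 <- 1 + amp_sd * rnorm(n_per)
  a2 <- 1 + amp_sd * rnorm(n_per)
  X <- rbind(outer(a1, w1), outer(a2, w2))
  X <- X + matrix(rnorm(2 * n_per * d, sd = noise_sd), ncol = d)
  lab <- rep(1:2, each = n_per)
  ord <- sample(2 * n_per)
  list(spikes = X[ord, ], labels = lab[ord])
}

# stationary Gaussian stream with a given diagonal covariance
gaussian_stream_matrix <- function(n, sds, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * length(sds)), ncol = length(sds)) %*% diag(sds)
}

# reference Hebbian update written element-by-element, independently of
# the package's linear-algebra implementation
hebbian_step_bruteforce <- function(W, x, eta) {
  l <- nrow(W); d <- ncol(W)
  y <- numeric(l)
  for (i in seq_len(l)) {
    s <- 0
    for (k in seq_len(d)) s <- s + W[i, k] * x[k]
    y[i] <- s
  }
  LT <- matrix(0, l, l)
  for (i in seq_len(l)) for (j in seq_len(l))
    if (j <= i) LT[i, j] <- y[i] * y[j]
  LTW <- matrix(0, l, d)
  for (i in seq_len(l)) for (k in seq_len(d)) {
    s <- 0
    for (j in seq_len(l)) s <- s + LT[i, j] * W[j, k]
    LTW[i, k] <- s
  }
  Wn <- matrix(0, l, d)
  for (i in seq_len(l)) for (k in seq_len(d))
    Wn[i, k] <- W[i, k] + eta * (y[i] * x[k] - LTW[i, k])
  Wn
}
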