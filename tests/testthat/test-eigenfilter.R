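test_that("the LT operator zeroes the strict upper triangle", {
  expect_equal(lt_lower_triangular(matrix(1:4, 2, byrow = TRUE)),
               matrix(c(1, 0, 3, 4), 2, byrow = TRUE))
  D <- diag(c(2, 5, 7))
  expect_equal(lt_lower_triangular(D), D)
  J <- matrix(1, 3, 3)
  expect_equal(lt_lower_triangular(J), lower.tri(J, diag = TRUE) * 1)
  expect_error(lt_lower_triangular(matrix(1:6, 2)), "square")
})

test_that("a single Hebbian step matches hand computation", {
  # l = d = 1: y = 0.5*2 = 1, LT = 1, dW = 0.1*(1*2 - 1*0.5) = 0.15
  expect_equal(hebbian_step(matrix(0.5, 1, 1), 2, eta = 0.1),
               matrix(0.65, 1, 1))
  # zero input leaves the weights untouched
  W <- matrix(runif(6), 2, 3)
  expect_equal(hebbian_step(W, c(0, 0, 0), 0.1), W)
  expect_error(hebbian_step(W, c(1, 2), 0.1), "invalid input")
})

test_that("hebbian_step equals an independent element-wise oracle", {
  set.seed(99)
  for (rep in 1:1000) {
    l <- sample(1:3, 1); d <- sample(2:6, 1)
    W <- matrix(rnorm(l * d), l, d)
    x <- rnorm(d)
    eta <- runif(1, 0.01, 0.3)
    expect_equal(hebbian_step(W, x, eta), hebbian_step_bruteforce(W, x, eta),
                 tolerance = 1e-12)
  }
})

test_that("the streaming state machine accumulates the mean then learns", {
  st <- eigenfilter_init(d = 2, l = 1, n = 2, N = 1)
  st <- eigenfilter_update(st, c(1, 3))
  expect_equal(st$phase, "mean_accumulation")
  st <- eigenfilter_update(st, c(3, 5))
  expect_equal(st$mu, c(2, 4))
  expect_equal(st$phase, "learning")
  # n = 1: the mean is that single spike
  s1 <- eigenfilter_update(eigenfilter_init(d = 3, l = 1, n = 1, N = 0),
                           c(7, 8, 9))
  expect_equal(s1$mu, c(7, 8, 9))
  # repeated identical spikes: the mean is exact
  st2 <- eigenfilter_init(d = 2, l = 1, n = 1024, N = 0, scale = FALSE)
  for (i in 1:1024) st2 <- eigenfilter_update(st2, c(0.25, -0.5))
  expect_identical(st2$mu, c(0.25, -0.5))
  expect_error(eigenfilter_update(st2, c(1, 1)), "finished")
})

test_that("eta = 0 returns the initial weights in both modes", {
  X <- gaussian_stream_matrix(64, c(2, 1, 1), seed = 1)
  for (mode in c("stream", "batch")) {
    f <- eigenfilter(X, l = 2, n = 16, N = 32, eta = 0, mode = mode)
    expect_equal(f$W, matrix(0.5, 2, 3))
  }
})

test_that("batch mode on a single repeated spike leaves weights at init", {
  X <- matrix(rep(c(1, 2, 4), 10), ncol = 3, byrow = TRUE)
  f <- eigenfilter(X, l = 1, N = 50, mode = "batch")
  expect_equal(f$W, matrix(0.5, 1, 3))
})

test_that("stream learning recovers the dominant axis of a diagonal covariance", {
  sds <- c(3, rep(1, 7))
  X <- gaussian_stream_matrix(2048, sds, seed = 11)
  f <- eigenfilter(X, l = 1, n = 1024, N = 1024)
  e1 <- c(1, rep(0, 7))
  expect_lte(error_pc(f$W[1, ], e1), 0.05)
})

test_that("stream and batch agree with the PCA oracle on stationary data", {
  # well-separated spectrum (eigenvalue ratios >= 3)
  sds <- c(6, 3, rep(1, 6))
  X <- gaussian_stream_matrix(4096, sds, seed = 5)
  fs <- eigenfilter(X, l = 2, n = 1024, N = 3072)
  fb <- eigenfilter(X, l = 2, N = 2048, mode = "batch")
  p <- spike_pca(X, l = 2)
  for (i in 1:2) {
    expect_lte(error_pc(fs$W[i, ], p$components[i, ]), 0.05)
    expect_lte(error_pc(fb$W[i, ], p$components[i, ]), 0.05)
    expect_lte(error_pc(fs$W[i, ], fb$W[i, ]), 0.05)
  }
  # norm convergence: GHA fixed points are unit eigenvectors (in the
  # scaled coordinates the filter learns in)
  expect_true(all(abs(sqrt(rowSums(fs$W^2)) - 1) < 0.1))
  # deflation ordering: component 1 captures at least component 2's variance
  sc <- predict(fs, X)
  expect_gte(var(sc[, 1]), var(sc[, 2]))
})

test_that("learned components match PCA on a two-neuron spike stream", {
  mix <- tiny_spike_matrix(n_per = 1200, d = 16, noise_sd = 0.25, seed = 13)
  f <- eigenfilter(mix$spikes, l = 2, n = 1024, N = 1024)
  p <- spike_pca(mix$spikes[1:2048, ], l = 2)
  expect_lte(error_pc(f$W[1, ], p$components[1, ]), 0.05)
  expect_lte(error_pc(f$W[2, ], p$components[2, ]), 0.05)
})

test_that("streaming is single-pass, O(1) in retained spikes, deterministic", {
  X <- gaussian_stream_matrix(2048, c(2, 1, 1, 1), seed = 3)
  f1 <- eigenfilter(X, l = 2, n = 1024, N = 1024)
  expect_lte(f1$max_spikes_live, 2)
  # a generator stream gives the identical fit (bit-for-bit)
  i <- 0
  gen <- function() { if (i >= nrow(X)) return(NULL); i <<- i + 1; X[i, ] }
  f2 <- eigenfilter(gen, l = 2, n = 1024, N = 1024)
  expect_identical(f1$W, f2$W)
  # exhausting the stream early is a diagnostic error
  j <- 0
  short <- function() { if (j >= 100) return(NULL); j <<- j + 1; X[j, ] }
  expect_error(eigenfilter(short, l = 2, n = 64, N = 128), "exhausted")
})

test_that("projection centres, scales, and matches oracle scores", {
  mix <- tiny_spike_matrix(n_per = 200, d = 16, seed = 2)
  f <- eigenfilter(mix$spikes, l = 2, n = 128, N = 272)
  # a spike equal to the mean projects to zero
  expect_equal(as.numeric(predict(f, f$mu)), c(0, 0))
  # identity rows pick out samples
  W <- diag(16)[1:2, ]
  sc <- project_spikes(mix$spikes, W, mu = rep(0, 16))
  expect_equal(sc, mix$spikes[, 1:2], ignore_attr = TRUE)
  # agreement with oracle projections up to per-component sign
  p <- spike_pca(mix$spikes, l = 2)
  Wal <- sign_align(f$W / sqrt(rowSums(f$W^2)), p)
  sc1 <- project_spikes(mix$spikes, Wal, f$mu)
  sc2 <- predict(p, mix$spikes)
  for (i in 1:2) expect_gt(abs(cor(sc1[, i], sc2[, i])), 0.99)
})

test_that("a numerically overflowing step raises a divergence error naming eta", {
  W <- matrix(1e200, 1, 2)
  expect_error(hebbian_step(W, c(1e200, 0), eta = 1), "eta")
})
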