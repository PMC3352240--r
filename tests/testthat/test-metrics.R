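test_that("k-means separates well-separated clouds and is deterministic", {
  set.seed(2)
  sc <- rbind(matrix(rnorm(200, 0, 0.1), ncol = 2),
              matrix(rnorm(200, 5, 0.1), ncol = 2))
  cl <- cluster_kmeans(sc, K = 2, seed = 9)
  expect_equal(length(unique(cl$assignments[1:100])), 1)
  expect_equal(length(unique(cl$assignments[101:200])), 1)
  expect_identical(cl$assignments, cluster_kmeans(sc, K = 2, seed = 9)$assignments)
  # degenerate cases
  expect_equal(unique(cluster_kmeans(sc, K = 1, seed = 1)$assignments), 1L)
  small <- sc[1:6, ]
  expect_lt(cluster_kmeans(small, K = 6, seed = 1)$inertia, 1e-20)
  expect_error(cluster_kmeans(small, K = 7, seed = 1), "fewer")
})

test_that("event matching pairs one-to-one within tolerance", {
  m <- match_events(c(10, 50, 90), c(10, 50, 90), tol = 5)
  expect_equal(nrow(m$pairs), 3)
  # offset beyond tolerance stays unpaired
  m2 <- match_events(c(10), c(16), tol = 5)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_det, 1L)
  expect_equal(m2$unmatched_truth, 1L)
  # random jitter at tol/2 always pairs completely
  set.seed(3)
  truth <- sort(sample(1000:100000, 200))
  det <- truth + sample(-6:6, 200, replace = TRUE)
  m3 <- match_events(det, truth, tol = 12)
  expect_equal(nrow(m3$pairs), 200)
  # a detection can consume at most one truth event
  m4 <- match_events(c(100, 101), c(100), tol = 12)
  expect_equal(nrow(m4$pairs), 1)
})

test_that("cluster-neuron matching maximizes correct spikes", {
  cl <- structure(list(assignments = c(1L, 1L, 2L, 2L, 2L), K = 2L,
                       centers = NULL, inertia = 0, mapping = NULL),
                  class = "sorting_result")
  lab <- c(5L, 5L, 9L, 9L, 5L)
  out <- match_clusters(cl, lab)
  expect_equal(out$mapping, c(5L, 9L))
  # permuting cluster ids leaves the mapped TPR invariant
  cl2 <- cl; cl2$assignments <- 3L - cl$assignments
  out2 <- match_clusters(cl2, lab)
  expect_equal(true_positive_rate(out, lab), true_positive_rate(out2, lab))
  # surplus clusters stay unmapped
  cl3 <- structure(list(assignments = c(1L, 2L, 3L, 1L, 2L, 3L), K = 3L,
                        centers = NULL, inertia = 0, mapping = NULL),
                   class = "sorting_result")
  out3 <- match_clusters(cl3, c(1L, 2L, 1L, 1L, 2L, 2L))
  expect_equal(sum(is.na(out3$mapping)), 1)
})

test_that("mean-vector error follows its definition", {
  expect_equal(error_mean(c(1, 1), c(2, 2)), 0.5)
  expect_equal(error_mean(c(2, 4), c(2, 4)), 0)
  # scale invariance
  mu1 <- runif(8); mu2 <- runif(8) + 0.1
  expect_equal(error_mean(3 * mu1, 3 * mu2), error_mean(mu1, mu2))
  expect_error(error_mean(c(1, 1), c(0, 0)), "zero")
})

test_that("PC deviation is zero for parallel or antiparallel directions", {
  v <- rnorm(16)
  expect_equal(error_pc(v, v), 0)
  expect_equal(error_pc(v, -v), 0)
  expect_equal(error_pc(2 * v, 5 * v), 0)
  expect_equal(error_pc(c(1, 0), c(0, 1)), 1)
  expect_error(error_pc(c(0, 0), c(1, 0)), "zero")
})

test_that("TPR and FPR follow the per-neuron averaged definitions", {
  # neuron 1: 8/10 correct; neuron 2: 15/20 correct -> TPR 0.775
  lab <- c(rep(1L, 10), rep(2L, 20))
  asg <- c(rep(1L, 8), rep(2L, 2), rep(2L, 15), rep(1L, 5))
  cl <- structure(list(assignments = asg, K = 2L, centers = NULL,
                       inertia = 0, mapping = c(1L, 2L)),
                  class = "sorting_result")
  expect_equal(true_positive_rate(cl, lab), (0.8 + 0.75) / 2)
  # FPR by direct evaluation: neuron 1 false pool = 20, receives 5;
  # neuron 2 false pool = 10, receives 2
  expect_equal(false_positive_rate(cl, lab), (5 / 20 + 2 / 10) / 2)
  # perfect sorting
  perf <- structure(list(assignments = lab, K = 2L, centers = NULL,
                         inertia = 0, mapping = c(1L, 2L)),
                    class = "sorting_result")
  expect_equal(true_positive_rate(perf, lab), 1)
  expect_equal(false_positive_rate(perf, lab), 0)
  # everything misassigned
  flip <- structure(list(assignments = 3L - lab, K = 2L, centers = NULL,
                         inertia = 0, mapping = c(1L, 2L)),
                    class = "sorting_result")
  expect_equal(true_positive_rate(flip, lab), 0)
  # K = 1 with every false spike assigned to the one neuron
  one <- structure(list(assignments = rep(1L, 4), K = 1L, centers = NULL,
                        inertia = 0, mapping = 1L),
                   class = "sorting_result")
  expect_equal(false_positive_rate(one, c(1L, 1L, 2L, 2L)), 1)
  # missed detections enlarge the TPR denominator
  expect_equal(true_positive_rate(perf, lab,
                                  n_truth = c("1" = 20, "2" = 40)),
               (10 / 20 + 20 / 40) / 2)
})

test_that("rates stay within [0, 1] across random sortings", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(20:60, 1); K <- sample(2:4, 1)
    lab <- sample(c(NA_integer_, 1:K), n, replace = TRUE)
    if (all(is.na(lab))) next
    asg <- sample.int(K, n, replace = TRUE)
    cl <- structure(list(assignments = asg, K = K, centers = NULL,
                         inertia = 0, mapping = NULL),
                    class = "sorting_result")
    cl <- match_clusters(cl, lab)
    suppressWarnings({
      tpr <- true_positive_rate(cl, lab)
      fpr <- false_positive_rate(cl, lab)
    })
    expect_gte(tpr, 0); expect_lte(tpr, 1)
    expect_gte(fpr, 0); expect_lte(fpr, 1)
  }
})

test_that("end-to-end evaluation on an easy recording is near-perfect", {
  tpl <- make_templates(2, seed = 5)
  rec <- generate_train(tpl, firing_rates = 10, duration = 20, snr = 10,
                        seed = 5)
  sm <- detect_spikes(rec)
  p <- spike_pca(sm$spikes, l = 2)
  cl <- cluster_kmeans(predict(p, sm$spikes), K = 2, seed = 5)
  ev <- evaluate_sorting(sm$event_times, cl, rec$truth, tol = 12)
  expect_gte(ev$tpr, 0.9)
  expect_lte(ev$fpr, 0.1)
})
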