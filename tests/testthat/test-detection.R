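test_that("NEO transform matches its closed form", {
  # constant trace: psi = c^2 - c*c = 0 everywhere
  expect_equal(neo_transform(rep(3, 10)), rep(0, 10))
  # direct evaluation on a small ramp
  expect_equal(neo_transform(c(0, 1, 2, 1, 0)), c(0, 1, 3, 1, 0))
  # pure sinusoid: interior psi is constant A^2 sin^2(omega)
  A <- 2; omega <- 0.3
  x <- A * sin(omega * (1:400))
  psi <- neo_transform(x)
  expect_equal(psi[2:399], rep(A^2 * sin(omega)^2, 398), tolerance = 1e-10)
  expect_error(neo_transform(c(1, 2)), "length")
  # smoothing preserves length and zeroes the boundary
  ps <- neo_transform(x, smooth = 7)
  expect_length(ps, 400)
})

test_that("threshold rule is multiplier times the mean energy", {
  expect_equal(train_threshold(rep(0, 5), 8), 0)
  expect_equal(train_threshold(c(1, 3), 8), 16)
  expect_error(train_threshold(numeric(0)), "empty")
  expect_error(train_threshold(1:3, -1), "positive")
})

test_that("event detection crosses, suppresses, and refines", {
  expect_identical(detect_events(rep(0.1, 50), 1), integer(0))
  e <- rep(0, 100); e[40:42] <- 5
  expect_identical(detect_events(e, 1), 40L)
  # two bumps closer than the dead time collapse to one event
  e2 <- rep(0, 100); e2[c(30, 40)] <- 5
  expect_length(detect_events(e2, 1, dead_time = 15), 1)
  expect_length(detect_events(e2, 1, dead_time = 5), 2)
  # refinement moves the event to the amplitude peak
  tr <- rep(0, 100); tr[45] <- -2
  expect_identical(detect_events(e, 1, dead_time = 10, trace = tr, refine = 10), 45L)
})

test_that("raising the threshold never increases the event count", {
  set.seed(42)
  e <- abs(rnorm(5000))
  thr <- seq(0.5, 3, by = 0.5)
  counts <- vapply(thr, function(th) length(detect_events(e, th, 10)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("alignment cuts windows with the peak at peak_index", {
  tr <- rep(0, 200); tr[100] <- 1
  sm <- align_spikes(tr, 100L, d = 4L, peak_index = 2L)
  expect_equal(sm$spikes[1, ], c(0, 1, 0, 0))
  expect_equal(sm$event_times, 100L)
  # boundary events are dropped and counted, not fatal
  sm2 <- align_spikes(tr, c(3L, 100L), d = 64L, peak_index = 21L)
  expect_equal(sm2$dropped_boundary, 1L)
  expect_equal(nrow(sm2$spikes), 1L)
  expect_error(align_spikes(tr, 100L, d = 4L, peak_index = 4L), "peak_index")
})

test_that("detection recovers nearly all ground-truth events on clean data", {
  tpl <- make_templates(2, seed = 1)
  rec <- generate_train(tpl, firing_rates = 10, duration = 20, snr = 50,
                        background_rate = 0, seed = 2)
  sm <- detect_spikes(rec)
  em <- match_events(sm$event_times, rec$truth$sample_index, tol = 2)
  expect_gte(nrow(em$pairs) / nrow(rec$truth), 0.97)
  # alignment invariant: every row peaks at peak_index
  expect_true(all(apply(abs(sm$spikes), 1, which.max) == 21))
})

test_that("default threshold detects most events at moderate noise", {
  # at snr 8 the mean-energy threshold still catches >= 90% of events;
  # the residual misses are threshold losses plus dead-time collisions
  tpl <- make_templates(2, seed = 4)
  rec <- generate_train(tpl, firing_rates = 10, duration = 20, snr = 8,
                        seed = 4)
  sm <- detect_spikes(rec)
  em <- match_events(sm$event_times, rec$truth$sample_index, tol = 12)
  expect_gte(nrow(em$pairs) / nrow(rec$truth), 0.9)
})

test_that("low-noise detection is near-complete with template-like rows", {
  tpl <- make_templates(2, seed = 4)
  rec <- generate_train(tpl, firing_rates = 10, duration = 20, snr = 15,
                        seed = 4)
  sm <- detect_spikes(rec)
  em <- match_events(sm$event_times, rec$truth$sample_index, tol = 12)
  expect_gte(nrow(em$pairs) / nrow(rec$truth), 0.95)
  lab <- rep(NA_integer_, length(sm$event_times))
  lab[em$pairs$det] <- rec$truth$neuron_id[em$pairs$truth]
  for (k in 1:2) {
    rows <- sm$spikes[!is.na(lab) & lab == k, , drop = FALSE]
    cors <- apply(rows, 1, cor, y = tpl[[k]]$waveform)
    expect_gt(median(cors), 0.9)
  }
})
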