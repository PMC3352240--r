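#' Default pipeline configuration
#'
#' Nested configuration for the full sorting pipeline, with defaults
#' reproducing the benchmark settings: 25 kHz sampling, 64-sample
#' spikes, mean over n = 1024 spikes, N = 1024 learning presentations,
#' eta = 0.1, initial weights 0.5, l = 2 components, 16-bit words.
#'
#' @param num_neurons neurons in the simulated recording (2--4 typical).
#' @param firing_rates per-neuron rates, Hz.
#' @param duration recording length, s.
#' @param fs sampling rate, Hz.
#' @param snr target signal-to-noise ratio.
#' @param background_rate interfering-spike rate, Hz.
#' @param d,peak_index spike window geometry.
#' @param threshold_mult NEO threshold multiplier.
#' @param l,n,N,eta,W_init eigenfilter parameters.
#' @param w word length, bits (complexity model).
#' @param K clusters for k-means (defaults to \code{num_neurons}).
#' @param tol_ms event-pairing tolerance, ms.
#' @param seed global seed for generator, training and clustering.
#' @return nested list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(num_neurons = 2L, firing_rates = 20,
                            duration = 100, fs = 25000, snr = 6,
                            background_rate = 10, d = 64L, peak_index = 21L,
                            threshold_mult = 8, l = 2L, n = 1024L,
                            N = 1024L, eta = 0.1, W_init = 0.5, w = 16L,
                            K = NULL, tol_ms = 0.5, seed = 1L) {
  structure(list(
    generator = list(num_neurons = num_neurons, firing_rates = firing_rates,
                     duration = duration, fs = fs, snr = snr,
                     background_rate = background_rate),
    detection = list(threshold_mult = threshold_mult, d = d,
                     peak_index = peak_index),
    eigenfilter = list(l = l, n = n, N = N, eta = eta, W_init = W_init),
    clustering = list(K = if (is.null(K)) num_neurons else K),
    complexity = list(w = w),
    tol_ms = tol_ms, seed = seed), class = "pipeline_config")
}

#' Run the full spike-sorting pipeline
#'
#' Simulate (or ingest) a recording, detect and align spikes, train the
#' stream-based eigenfilter and the batch PCA oracle, project, cluster
#' with k-means, and evaluate against ground truth. One seed governs
#' every random stage, so identical configurations give identical
#' results.
#'
#' @param config a \code{"pipeline_config"}.
#' @param rec optional pre-existing \code{"spike_recording"} (skips
#'   simulation).
#' @param out_dir optional directory; when given, the recording, spike
#'   matrix, filter bundles and \code{metrics.json} are written there.
#' @param verbose print a stage-by-stage log (default TRUE).
#' @return list of class \code{"pipeline_run"} with \code{rec},
#'   \code{spikes}, \code{fit_stream}, \code{fit_pca}, \code{metrics}
#'   (tpr/fpr per method, error_pc per component, error_mean of the
#'   detected-spike mean vs the training mean), and \code{log}.
#' @export
run_pipeline <- function(config = pipeline_config(), rec = NULL,
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    if (verbose) message(msg)
    log <<- c(log, msg)
  }
  g <- config$generator; dt <- config$detection; ef <- config$eigenfilter
  if (is.null(rec)) {
    tpl <- make_templates(g$num_neurons, d = dt$d,
                          peak_index = dt$peak_index, seed = config$seed)
    rec <- generate_train(tpl, g$firing_rates, g$duration, g$fs, g$snr,
                          g$background_rate, seed = config$seed)
    say("simulate: %d neurons, %.4g s, snr %.3g, %d ground-truth spikes",
        g$num_neurons, g$duration, g$snr, nrow(rec$truth))
  }
  sm <- detect_spikes(rec, threshold_mult = dt$threshold_mult, d = dt$d,
                      peak_index = dt$peak_index)
  say("detect: %d spikes aligned (%d boundary, %d misaligned dropped)",
      nrow(sm$spikes), sm$dropped_boundary, sm$dropped_misaligned)
  need <- ef$n + ef$N
  if (nrow(sm$spikes) < need)
    stop("pipeline stage 'train': only ", nrow(sm$spikes),
         " spikes detected but n + N = ", need, " are required; ",
         "lengthen the recording or reduce n/N")
  fit_stream <- eigenfilter(sm$spikes, l = ef$l, n = ef$n, N = ef$N,
                            eta = ef$eta, W_init = ef$W_init,
                            mode = "stream")
  train_set <- sm$spikes[seq_len(need), , drop = FALSE]
  fit_pca <- spike_pca(train_set, l = ef$l)
  say("train: stream eigenfilter (%d presentations) and batch PCA oracle on %d spikes",
      fit_stream$presentations, nrow(train_set))

  epc <- vapply(seq_len(ef$l), function(i)
    error_pc(fit_stream$W[i, ], fit_pca$components[i, ]), numeric(1))
  mu_learn <- colMeans(sm$spikes[ef$n + seq_len(ef$N), , drop = FALSE])
  emu <- error_mean(fit_stream$mu, mu_learn)

  K <- config$clustering$K
  tol <- as.integer(round(config$tol_ms * rec$fs / 1000))
  metrics <- list(error_pc = epc, error_mean = emu)
  for (m in c("stream", "pca")) {
    fit <- if (m == "stream") fit_stream else fit_pca
    sc <- predict(fit, sm$spikes)
    cl <- cluster_kmeans(sc, K, seed = config$seed)
    ev <- evaluate_sorting(sm$event_times, cl, rec$truth, tol = tol)
    metrics[[paste0("tpr_", m)]] <- ev$tpr
    metrics[[paste0("fpr_", m)]] <- ev$fpr
    say("sort[%s]: K=%d, TPR %.3f, FPR %.3f (missed %d, false det %d)",
        m, K, ev$tpr, ev$fpr, ev$n_missed, ev$n_false_detections)
  }
  out <- structure(list(rec = rec, spikes = sm, fit_stream = fit_stream,
                        fit_pca = fit_pca, metrics = metrics, log = log,
                        config = config), class = "pipeline_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_recording(rec, file.path(out_dir, "recording"))
    write_spike_matrix(sm, file.path(out_dir, "detected"))
    write_filter(fit_stream, file.path(out_dir, "filter_stream.json"))
    write_filter(fit_pca, file.path(out_dir, "filter_pca.json"))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Spike-sorting pipeline run\n")
  for (line in x$log) cat(" ", line, "\n")
  cat(sprintf("  PC deviation (stream vs PCA): %s\n",
              paste(sprintf("%.4f", x$metrics$error_pc), collapse = ", ")))
  cat(sprintf("  mean-vector error (frozen vs learning block): %.4f\n",
              x$metrics$error_mean))
  invisible(x)
}
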