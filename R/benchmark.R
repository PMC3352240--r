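#' Sweep sorting accuracy over an SNR grid
#'
#' Runs the full pipeline (simulate, detect, train, project, cluster,
#' evaluate) for every combination of SNR level, neuron count and seed,
#' sorting once with the stream-based eigenfilter features and once with
#' the batch PCA oracle features on the identical detected spikes. The
#' training split adapts to the number of detected spikes: the mean
#' phase and the learning phase each take half the available spikes, up
#' to the configured caps, so the sweep remains defined at noise levels
#' where detection recovers few events.
#'
#' When detection yields fewer spikes than clusters, the level is scored
#' TPR = 0 (every spike missed) and FPR = NA (no false-spike pool).
#'
#' @param snrs SNR levels (default \code{\link{snr_grid}()}).
#' @param num_neurons neuron counts to sweep (default 2:4).
#' @param seeds seeds to sweep (default 1:3).
#' @param firing_rates per-neuron rate, Hz.
#' @param duration recording length per run, s.
#' @param n_cap,N_cap upper bounds on the mean-phase and learning-phase
#'   spike counts. The mean phase caps at 1024 spikes; the learning
#'   phase defaults to unbounded -- the stream learns from every spike
#'   the recording supplies after the mean block, which the trailing
#'   component needs for full convergence.
#' @param l components used for the sorting feature space (default 3).
#' @param verbose print one line per run.
#' @return data.frame with columns snr, num_neurons, seed, n_detected,
#'   n_train, tpr_she, fpr_she, tpr_pca, fpr_pca, error_pc1, error_pc2.
#' @export
benchmark_grid <- function(snrs = snr_grid(), num_neurons = 2:4,
                           seeds = 1:3, firing_rates = 20, duration = 30,
                           n_cap = 1024L, N_cap = Inf, l = 3L,
                           verbose = FALSE) {
  rows <- list()
  for (nn in num_neurons) for (seed in seeds) {
    tpl <- make_templates(nn, seed = seed)
    for (snr in snrs) {
      rec <- generate_train(tpl, firing_rates, duration, snr = snr,
                            seed = seed)
      sm <- detect_spikes(rec)
      nspk <- nrow(sm$spikes)
      half <- nspk %/% 2L
      n_mean <- min(n_cap, half); n_learn <- min(N_cap, nspk - n_mean)
      row <- data.frame(snr = snr, num_neurons = nn, seed = seed,
                        n_detected = nspk, n_train = n_mean + n_learn,
                        tpr_she = 0, fpr_she = NA_real_,
                        tpr_pca = 0, fpr_pca = NA_real_,
                        error_pc1 = NA_real_, error_pc2 = NA_real_)
      if (nspk >= max(nn, 4L) && n_learn >= 1L) {
        fs_she <- eigenfilter(sm$spikes, l = l, n = n_mean, N = n_learn,
                              mode = "stream")
        fs_pca <- spike_pca(sm$spikes, l = l)
        row$error_pc1 <- error_pc(fs_she$W[1, ], fs_pca$components[1, ])
        if (l >= 2)
          row$error_pc2 <- error_pc(fs_she$W[2, ], fs_pca$components[2, ])
        for (m in c("she", "pca")) {
          fit <- if (m == "she") fs_she else fs_pca
          sc <- predict(fit, sm$spikes)
          cl <- cluster_kmeans(sc, nn, seed = seed)
          # when every detection is spurious there is nothing to map:
          # score TPR 0 (all truth spikes missed), FPR undefined
          ev <- tryCatch(
            evaluate_sorting(sm$event_times, cl, rec$truth, tol = 12L),
            error = function(e) NULL)
          if (!is.null(ev)) {
            row[[paste0("tpr_", m)]] <- ev$tpr
            row[[paste0("fpr_", m)]] <- ev$fpr
          }
        }
      }
      if (verbose)
        message(sprintf("snr %4.1f nn %d seed %d: det %4d  SHE %.3f/%.3f  PCA %.3f/%.3f",
                        snr, nn, seed, nspk, row$tpr_she, row$fpr_she,
                        row$tpr_pca, row$fpr_pca))
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
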