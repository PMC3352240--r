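#' Generate biphasic spike templates
#'
#' Builds a set of distinct, peak-aligned spike waveform templates modelled
#' as differences of Gaussians: a sharp depolarization lobe followed by a
#' slower after-hyperpolarization trough. Templates are normalized so the
#' maximum absolute amplitude is exactly 1 and sits at \code{peak_index}.
#'
#' @param num_neurons number of templates to generate (>= 1; the usual
#'   benchmark range is 2--4).
#' @param d template length in samples (default 64, about 2.56 ms at 25 kHz).
#' @param peak_index 1-based sample index of the peak (default 21,
#'   about 0.8 ms into the window).
#' @param seed integer RNG seed; identical seeds give identical templates.
#' @return a list of \code{num_neurons} templates, each a list with
#'   \code{waveform} (numeric, length \code{d}) and \code{neuron_id}.
#' @examples
#' tpl <- make_templates(2, seed = 1)
#' sapply(tpl, function(t) which.max(abs(t$waveform)))
#' @export
make_templates <- function(num_neurons, d = 64L, peak_index = 21L, seed = 1L) {
  if (num_neurons < 1L) stop("num_neurons must be >= 1")
  if (peak_index <= 1L || peak_index >= d)
    stop("peak_index must satisfy 1 < peak_index < d")
  if (d < 16L)
    stop("invalid configuration: d = ", d,
         " is too small to hold a biphasic waveform")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # parameter strata keep waveforms distinct across neurons; jitter keeps
  # different seeds from colliding. If a jitter draw collapses two
  # adjacent strata (pairwise correlation >= 0.989) the set is redrawn
  # from the same deterministic RNG stream.
  t <- seq_len(d)
  for (attempt in 1:25) {
    templates <- vector("list", num_neurons)
    for (k in seq_len(num_neurons)) {
      frac     <- if (num_neurons == 1L) 0.5 else (k - 1) / (num_neurons - 1)
      sigma_p  <- 1.0 + 0.6 * frac + stats::runif(1, -0.08, 0.08)
      delay    <- 7 + 3 * frac + stats::runif(1, -0.4, 0.4)
      sigma_n  <- 3.0 + 1.5 * (1 - frac) + stats::runif(1, -0.2, 0.2)
      depth    <- 0.30 + 0.10 * ((k %% 2 == 0)) + stats::runif(1, -0.03, 0.03)
      w <- exp(-(t - peak_index)^2 / (2 * sigma_p^2)) -
        depth * exp(-(t - (peak_index + delay))^2 / (2 * sigma_n^2))
      w <- w / max(abs(w))
      if (which.max(abs(w)) != peak_index)
        stop("internal error: template peak misplaced")  # nocov
      templates[[k]] <- list(waveform = w, neuron_id = k)
    }
    if (num_neurons == 1L) break
    wf <- sapply(templates, `[[`, "waveform")
    cc <- stats::cor(wf)
    if (max(cc[upper.tri(cc)]) < 0.989) break
    if (attempt == 25L)
      stop("invalid configuration: templates not distinct (correlation >= 0.99)")
  }
  structure(templates, d = d, peak_index = peak_index, class = "spike_templates")
}

#' @export
print.spike_templates <- function(x, ...) {
  cat(sprintf("%d spike template(s), d = %d samples, peak at sample %d\n",
              length(x), attr(x, "d"), attr(x, "peak_index")))
  invisible(x)
}

# save/restore global RNG state so generator calls do not disturb the caller
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Poisson train with an absolute refractory period. ISIs are
# refractory + Exp(rate_adj) with rate_adj chosen so the mean rate equals
# `rate` (dead-time correction).
.poisson_train <- function(rate, duration, fs, refractory_s) {
  if (rate <= 0) stop("firing rate must be positive")
  if (rate * refractory_s >= 1)
    stop("invalid configuration: firing rate ", rate,
         " Hz cannot satisfy the ", refractory_s * 1e3, " ms refractory period")
  rate_adj <- 1 / (1 / rate - refractory_s)
  times <- numeric(0)
  t <- 0
  # draw in blocks to avoid a sample-by-sample loop
  repeat {
    k <- max(16L, ceiling((duration - t) * rate * 1.5))
    isi <- refractory_s + stats::rexp(k, rate_adj)
    ts <- t + cumsum(isi)
    times <- c(times, ts[ts < duration])
    t <- ts[length(ts)]
    if (t >= duration) break
  }
  round(times * fs) + 1L  # 1-based sample indices
}

#' Simulate an extracellular recording with ground truth
#'
#' Superimposes spike templates at Poisson event times (with a 2 ms
#' refractory period per neuron; overlaps across neurons are allowed),
#' adds background interference from attenuated spikes of vicinity
#' neurons, and white Gaussian noise scaled so the realized
#' signal-to-noise ratio matches \code{snr}. SNR is defined as the mean
#' template peak amplitude divided by the standard deviation of the
#' spike-free noise (see \code{\link{measure_snr}}).
#'
#' @param templates templates from \code{\link{make_templates}} (one per
#'   neuron).
#' @param firing_rates per-neuron firing rate in Hz (recycled); the
#'   benchmark regime is 5--50 Hz.
#' @param duration recording length in seconds (default 100).
#' @param fs sampling rate in Hz (default 25000).
#' @param snr target signal-to-noise ratio (> 0; \code{Inf} = no white
#'   noise).
#' @param background_rate rate (Hz) of interfering background spikes,
#'   inserted as randomly chosen templates attenuated by 0.3.
#' @param refractory_ms per-neuron absolute refractory period (default 2).
#' @param amp_range range of per-neuron peak amplitudes (arbitrary units).
#' @param seed integer RNG seed.
#' @return list of class \code{"spike_recording"} with \code{trace}
#'   (numeric vector), \code{fs}, \code{truth} (data.frame with 1-based
#'   \code{sample_index} at the peak and \code{neuron_id}),
#'   \code{templates}, \code{amplitudes}, \code{noise_sd}, \code{snr},
#'   \code{seed}.
#' @examples
#' tpl <- make_templates(2, seed = 1)
#' rec <- generate_train(tpl, firing_rates = 10, duration = 2, snr = 6, seed = 1)
#' length(rec$trace)  # 2 s * 25 kHz
#' @export
generate_train <- function(templates, firing_rates, duration = 100, fs = 25000,
                           snr = 6, background_rate = 10, refractory_ms = 2,
                           amp_range = c(0.85, 1.15), seed = 1L) {
  stopifnot(inherits(templates, "spike_templates"))
  if (snr <= 0) stop("snr must be positive")
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  n_samp <- duration * fs
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("duration * fs must be an integer sample count")
  n_samp <- as.integer(round(n_samp))
  d <- attr(templates, "d"); peak_index <- attr(templates, "peak_index")
  num_neurons <- length(templates)
  firing_rates <- rep_len(firing_rates, num_neurons)

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  amps <- stats::runif(num_neurons, amp_range[1], amp_range[2])

  trace <- numeric(n_samp)
  ev_time <- integer(0); ev_id <- integer(0)
  lo_ok <- peak_index; hi_ok <- n_samp - (d - peak_index)
  for (k in seq_len(num_neurons)) {
    tk <- .poisson_train(firing_rates[k], duration, fs, refractory_ms / 1000)
    tk <- tk[tk >= lo_ok & tk <= hi_ok]
    wf <- amps[k] * templates[[k]]$waveform
    for (tt in tk) {
      idx <- (tt - peak_index + 1L):(tt - peak_index + d)
      trace[idx] <- trace[idx] + wf
    }
    ev_time <- c(ev_time, tk); ev_id <- c(ev_id, rep.int(k, length(tk)))
  }
  ord <- order(ev_time)
  truth <- data.frame(sample_index = ev_time[ord], neuron_id = ev_id[ord])

  # background interference: attenuated templates at Poisson times
  bg <- numeric(n_samp)
  if (background_rate > 0) {
    bt <- .poisson_train(background_rate, duration, fs, 0)
    bt <- bt[bt >= lo_ok & bt <= hi_ok]
    which_tpl <- sample.int(num_neurons, length(bt), replace = TRUE)
    for (i in seq_along(bt)) {
      idx <- (bt[i] - peak_index + 1L):(bt[i] - peak_index + d)
      bg[idx] <- bg[idx] + 0.3 * amps[which_tpl[i]] *
        templates[[which_tpl[i]]]$waveform
    }
  }

  # scale white noise so total spike-free noise SD hits mean(amps)/snr
  noise_sd <- 0
  if (is.finite(snr)) {
    target_sd <- mean(amps) / snr
    mask <- .spike_free_mask(n_samp, truth$sample_index, d, peak_index)
    bg_var <- if (any(mask)) stats::var(bg[mask]) else 0
    if (bg_var > target_sd^2)
      stop("invalid configuration: background interference alone exceeds ",
           "the noise budget for snr = ", snr,
           "; lower background_rate or snr")
    noise_sd <- sqrt(target_sd^2 - bg_var)
  }
  trace <- trace + bg + if (noise_sd > 0) stats::rnorm(n_samp, 0, noise_sd) else 0

  structure(list(trace = trace, fs = fs, truth = truth, templates = templates,
                 amplitudes = amps, noise_sd = noise_sd, snr = snr,
                 duration = duration, seed = seed),
            class = "spike_recording")
}

#' @export
print.spike_recording <- function(x, ...) {
  cat(sprintf(paste0("Synthetic extracellular recording: %.6g s at %g Hz ",
                     "(%d samples)\n  %d neurons, %d ground-truth spikes, ",
                     "target SNR %.3g\n"),
              x$duration, x$fs, length(x$trace), length(x$templates),
              nrow(x$truth), x$snr))
  invisible(x)
}

# logical mask of samples not covered by any foreground spike window
.spike_free_mask <- function(n_samp, peak_times, d, peak_index) {
  mask <- rep(TRUE, n_samp)
  for (tt in peak_times) {
    lo <- max(1L, tt - peak_index + 1L)
    hi <- min(n_samp, tt - peak_index + d)
    mask[lo:hi] <- FALSE
  }
  mask
}

#' Measure the realized signal-to-noise ratio of a recording
#'
#' SNR is defined as the mean spike peak amplitude (trace value at the
#' ground-truth peak samples, averaged over events) divided by the
#' standard deviation of the spike-free portion of the trace. Background
#' interference counts as noise; foreground spike windows are excluded.
#'
#' @param rec a \code{"spike_recording"}, or a numeric trace.
#' @param truth ground-truth data.frame (ignored when \code{rec} is a
#'   recording, which carries its own).
#' @param d,peak_index spike window geometry used to mask out spikes.
#' @return the realized SNR (possibly \code{Inf} for a noise-free trace).
#' @export
measure_snr <- function(rec, truth = NULL, d = 64L, peak_index = 21L) {
  if (inherits(rec, "spike_recording")) {
    trace <- rec$trace; truth <- rec$truth
    d <- attr(rec$templates, "d"); peak_index <- attr(rec$templates, "peak_index")
  } else trace <- as.numeric(rec)
  if (is.null(truth) || nrow(truth) == 0) stop("ground truth is empty")
  mask <- .spike_free_mask(length(trace), truth$sample_index, d, peak_index)
  if (!any(mask))
    stop("no spike-free segment available to estimate the noise level")
  peak_amp <- mean(abs(trace[truth$sample_index]))
  noise_sd <- stats::sd(trace[mask])
  if (noise_sd == 0) return(Inf)
  peak_amp / noise_sd
}

#' Default SNR grid for benchmark sweeps
#'
#' Eleven noise levels spanning the regime from near-undetectable spikes
#' to essentially clean recordings.
#' @return numeric vector of 11 SNR values.
#' @export
snr_grid <- function() c(1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 8, 10)
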