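#' Nonlinear energy operator (NEO) transform
#'
#' Computes psi(n) = x(n)^2 - x(n-1) x(n+1), which responds to signal
#' that is simultaneously large in amplitude and high in frequency --
#' the signature of an extracellular spike against low-frequency
#' background. Boundary samples are set to 0. An optional Bartlett
#' (triangular) window smooths the energy trace.
#'
#' @param trace numeric amplitude sequence, length >= 3.
#' @param smooth odd Bartlett window length in samples (0 = no smoothing).
#' @return energy sequence of the same length as \code{trace}.
#' @examples
#' neo_transform(c(0, 1, 2, 1, 0))  # interior psi = 1, 3, 1
#' @export
neo_transform <- function(trace, smooth = 0L) {
  n <- length(trace)
  if (n < 3L) stop("invalid input: trace must have length >= 3")
  psi <- numeric(n)
  i <- 2:(n - 1L)
  psi[i] <- trace[i]^2 - trace[i - 1L] * trace[i + 1L]
  if (smooth > 0L) {
    if (smooth %% 2L == 0L) smooth <- smooth + 1L
    w <- .bartlett(smooth)
    psi <- as.numeric(stats::filter(psi, w / sum(w), sides = 2))
    psi[is.na(psi)] <- 0
  }
  psi
}

.bartlett <- function(m) {
  k <- seq_len(m) - 1
  1 - abs(k - (m - 1) / 2) / ((m - 1) / 2)
}

#' Train a detection threshold from an energy trace
#'
#' The threshold is a multiple of the mean NEO energy; the scaled mean is
#' robust because spikes occupy a small fraction of the recording.
#'
#' @param energy NEO energy sequence.
#' @param multiplier positive scale factor (default 8).
#' @return scalar threshold.
#' @export
train_threshold <- function(energy, multiplier = 8) {
  if (length(energy) == 0L) stop("empty energy sequence")
  if (multiplier <= 0) stop("multiplier must be positive")
  multiplier * mean(energy)
}

#' Detect threshold crossings in an energy trace
#'
#' Finds upward crossings of \code{threshold}, suppresses re-triggers
#' within \code{dead_time} samples, and (when \code{trace} is supplied)
#' refines each event to the local absolute-amplitude peak within
#' \code{refine} samples.
#'
#' @param energy NEO energy sequence.
#' @param threshold positive detection threshold.
#' @param dead_time minimum spacing between events, in samples.
#' @param trace raw amplitude trace for peak refinement (optional).
#' @param refine half-width of the peak search window in samples
#'   (default 25, i.e. 1 ms at 25 kHz).
#' @return integer vector of event sample indices (1-based), at the
#'   refined peak when \code{trace} is given.
#' @export
detect_events <- function(energy, threshold, dead_time = 38L,
                          trace = NULL, refine = 25L) {
  if (threshold <= 0) stop("threshold must be positive")
  if (dead_time < 0) stop("dead_time must be >= 0")
  above <- energy >= threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  if (length(cross) == 0L) return(integer(0))
  keep <- cross[1]
  if (length(cross) > 1L) {
    last <- cross[1]
    for (cc in cross[-1]) {
      if (cc - last > dead_time) { keep <- c(keep, cc); last <- cc }
    }
  }
  if (is.null(trace)) return(as.integer(keep))
  n <- length(trace)
  peaks <- vapply(as.numeric(keep), function(cc) {
    lo <- max(1, cc - refine); hi <- min(n, cc + refine)
    as.numeric(lo + which.max(abs(trace[lo:hi])) - 1)
  }, numeric(1))
  unique(as.integer(peaks))
}

#' Extract peak-aligned fixed-length spike waveforms
#'
#' Cuts a window of \code{d} samples around each event so the peak falls
#' at \code{peak_index}. Events whose window would run off either end of
#' the trace are dropped, as are windows whose absolute maximum is not at
#' \code{peak_index} (a larger overlapping spike dominates the cut);
#' both counts are reported.
#'
#' @param trace amplitude trace.
#' @param events event peak indices from \code{\link{detect_events}}.
#' @param d spike length in samples (default 64).
#' @param peak_index 1-based within-window peak position (default 21).
#' @return list of class \code{"spike_matrix"}: \code{spikes} (n x d
#'   matrix), \code{event_times} (peak sample per row),
#'   \code{peak_index}, \code{dropped_boundary}, \code{dropped_misaligned}.
#' @export
align_spikes <- function(trace, events, d = 64L, peak_index = 21L) {
  if (peak_index <= 1L || peak_index >= d)
    stop("peak_index must satisfy 1 < peak_index < d")
  n <- length(trace)
  ok <- events - peak_index + 1L >= 1L & events - peak_index + d <= n
  dropped_boundary <- sum(!ok)
  events <- events[ok]
  if (length(events) == 0L)
    return(structure(list(spikes = matrix(numeric(0), 0, d),
                          event_times = integer(0), peak_index = peak_index,
                          dropped_boundary = dropped_boundary,
                          dropped_misaligned = 0L), class = "spike_matrix"))
  spikes <- t(vapply(events, function(tt)
    trace[(tt - peak_index + 1L):(tt - peak_index + d)], numeric(d)))
  aligned <- apply(abs(spikes), 1L, which.max) == peak_index
  structure(list(spikes = spikes[aligned, , drop = FALSE],
                 event_times = as.integer(events[aligned]),
                 peak_index = peak_index,
                 dropped_boundary = dropped_boundary,
                 dropped_misaligned = sum(!aligned)),
            class = "spike_matrix")
}

#' @export
print.spike_matrix <- function(x, ...) {
  cat(sprintf("Spike matrix: %d spikes x %d samples (peak at %d); dropped %d boundary, %d misaligned\n",
              nrow(x$spikes), ncol(x$spikes), x$peak_index,
              x$dropped_boundary, x$dropped_misaligned))
  invisible(x)
}

#' Detect and align spikes from a continuous recording
#'
#' Runs the full detection front end: NEO transform, Bartlett smoothing,
#' mean-based thresholding, dead-time suppression, peak refinement, and
#' peak alignment into a fixed-length spike matrix.
#'
#' @param rec a \code{"spike_recording"} or numeric trace.
#' @param fs sampling rate (taken from \code{rec} when available).
#' @param threshold_mult threshold multiplier on the mean NEO energy.
#' @param d,peak_index spike window geometry.
#' @param dead_time_ms dead time between detections, in ms (default 1.5).
#' @param smooth_ms Bartlett smoothing window, in ms (default 0.28).
#' @param refine_ms peak refinement half-window, in ms (default 1).
#' @return a \code{"spike_matrix"} (see \code{\link{align_spikes}}).
#' @examples
#' tpl <- make_templates(2, seed = 1)
#' rec <- generate_train(tpl, firing_rates = 10, duration = 2, snr = 8, seed = 1)
#' sm <- detect_spikes(rec)
#' nrow(sm$spikes)
#' @export
detect_spikes <- function(rec, fs = NULL, threshold_mult = 8, d = 64L,
                          peak_index = 21L, dead_time_ms = 1.5,
                          smooth_ms = 0.28, refine_ms = 1) {
  if (inherits(rec, "spike_recording")) {
    trace <- rec$trace
    if (is.null(fs)) fs <- rec$fs
  } else trace <- as.numeric(rec)
  if (is.null(fs)) stop("fs is required when rec is a plain trace")
  energy <- neo_transform(trace, smooth = as.integer(round(smooth_ms * fs / 1000)))
  thr <- train_threshold(energy, threshold_mult)
  if (thr <= 0) return(align_spikes(trace, integer(0), d, peak_index))
  ev <- detect_events(energy, thr,
                      dead_time = as.integer(round(dead_time_ms * fs / 1000)),
                      trace = trace,
                      refine = as.integer(round(refine_ms * fs / 1000)))
  align_spikes(trace, ev, d, peak_index)
}
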