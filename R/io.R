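# File formats: traces as flat little-endian int16 binary (with JSON
# sidecar) or single-column CSV; ground truth and spike matrices as CSV;
# filter bundles and metrics as JSON. Sample indices are 0-based on disk
# and converted to R's 1-based convention on read.

#' Write a recording to disk
#'
#' The trace is quantized to little-endian int16 (the quantization step,
#' in trace units per LSB, is stored in the sidecar) and written to
#' \code{<prefix>.i16}, with metadata in \code{<prefix>.json} and ground
#' truth (0-based \code{sample_index}) in \code{<prefix>_truth.csv}.
#'
#' @param rec a \code{"spike_recording"}.
#' @param prefix output path prefix.
#' @param format \code{"binary"} (int16) or \code{"csv"} (plain text,
#'   one amplitude per line).
#' @return \code{prefix}, invisibly.
#' @export
write_recording <- function(rec, prefix, format = c("binary", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "spike_recording"))
  lsb <- max(abs(rec$trace), .Machine$double.eps) / 32000
  meta <- list(fs = rec$fs, duration = rec$duration, seed = rec$seed,
               snr = rec$snr, units = "arbitrary", lsb = lsb,
               n_samples = length(rec$trace), format = format)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (format == "binary") {
    q <- as.integer(round(rec$trace / lsb))
    con <- file(paste0(prefix, ".i16"), "wb")
    writeBin(q, con, size = 2L, endian = "little")
    close(con)
  } else {
    utils::write.table(data.frame(amplitude = rec$trace),
                       paste0(prefix, ".csv"), sep = ",",
                       row.names = FALSE, col.names = TRUE)
  }
  truth <- rec$truth
  truth$sample_index <- truth$sample_index - 1L  # 0-based on disk
  utils::write.csv(truth, paste0(prefix, "_truth.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read a recording written by \code{\link{write_recording}}
#'
#' @param prefix path prefix used when writing.
#' @return a \code{"spike_recording"} (without templates; trace values
#'   are the quantized amplitudes for binary format).
#' @export
read_recording <- function(prefix) {
  side <- paste0(prefix, ".json")
  if (!file.exists(side)) stop("format error: missing sidecar file ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("fs", "n_samples", "format"))
    if (is.null(meta[[f]]))
      stop("format error: sidecar ", side, " lacks field '", f, "'")
  if (identical(meta$format, "binary")) {
    con <- file(paste0(prefix, ".i16"), "rb")
    q <- readBin(con, integer(), n = meta$n_samples, size = 2L,
                 endian = "little", signed = TRUE)
    close(con)
    if (length(q) != meta$n_samples)
      stop("format error: ", prefix, ".i16 truncated (", length(q),
           " of ", meta$n_samples, " samples)")
    trace <- q * meta$lsb
  } else {
    df <- utils::read.csv(paste0(prefix, ".csv"))
    if (!"amplitude" %in% names(df))
      stop("format error: ", prefix, ".csv line 1: missing 'amplitude' header")
    trace <- df$amplitude
    if (length(trace) != meta$n_samples)
      stop("format error: ", prefix, ".csv truncated (", length(trace),
           " of ", meta$n_samples, " samples)")
  }
  tf <- paste0(prefix, "_truth.csv")
  truth <- NULL
  if (file.exists(tf)) {
    truth <- utils::read.csv(tf)
    if (!all(c("sample_index", "neuron_id") %in% names(truth)))
      stop("format error: ", tf, " line 1: expected header sample_index,neuron_id")
    truth$sample_index <- truth$sample_index + 1L
  }
  structure(list(trace = trace, fs = meta$fs, truth = truth,
                 templates = NULL, amplitudes = NULL,
                 noise_sd = NA_real_, snr = meta$snr,
                 duration = meta$duration, seed = meta$seed),
            class = "spike_recording")
}

#' Write/read an aligned spike matrix as CSV
#'
#' \code{<prefix>_spikes.csv} holds one spike per row (columns
#' \code{s1..sd}); \code{<prefix>_events.csv} holds the 0-based
#' \code{sample_index} of each spike peak.
#'
#' @param sm a \code{"spike_matrix"}.
#' @param prefix path prefix.
#' @export
write_spike_matrix <- function(sm, prefix) {
  stopifnot(inherits(sm, "spike_matrix"))
  sp <- as.data.frame(sm$spikes)
  names(sp) <- paste0("s", seq_len(ncol(sp)))
  utils::write.csv(sp, paste0(prefix, "_spikes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_index = sm$event_times - 1L),
                   paste0(prefix, "_events.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_spike_matrix
#' @param peak_index within-window peak position of the stored spikes.
#' @export
read_spike_matrix <- function(prefix, peak_index = 21L) {
  sp <- utils::read.csv(paste0(prefix, "_spikes.csv"))
  ev <- utils::read.csv(paste0(prefix, "_events.csv"))
  if (!"sample_index" %in% names(ev))
    stop("format error: ", prefix, "_events.csv line 1: missing sample_index")
  structure(list(spikes = as.matrix(sp),
                 event_times = ev$sample_index + 1L,
                 peak_index = peak_index,
                 dropped_boundary = 0L, dropped_misaligned = 0L),
            class = "spike_matrix")
}

#' Write/read a trained filter bundle as JSON
#'
#' Stores the component matrix, mean vector, input scale and the fit
#' parameters at full double precision.
#'
#' @param object an \code{"eigenfilter"} or \code{"spike_pca"}.
#' @param path output file.
#' @export
write_filter <- function(object, path) {
  if (inherits(object, "eigenfilter")) {
    bundle <- list(method = object$mode, W = object$W, mu = object$mu,
                   scale = object$scale, l = object$l, d = object$d,
                   n = object$n, N = object$N, eta = object$eta)
  } else if (inherits(object, "spike_pca")) {
    bundle <- list(method = "pca", W = object$components, mu = object$mu,
                   scale = 1, l = object$l, d = object$d,
                   eigenvalues = object$eigenvalues)
  } else stop("unsupported filter object")
  jsonlite::write_json(bundle, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_filter
#' @export
read_filter <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(b$W) || is.null(b$mu))
    stop("format error: ", path, " is not a filter bundle")
  b$W <- matrix(unlist(b$W), nrow = b$l, byrow = FALSE)
  b
}
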