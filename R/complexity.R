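#' Memory footprint of spike feature-extraction methods
#'
#' Analytic memory model, in bits. The batch Hebbian eigenfilter (HE)
#' must buffer the n training spikes for the mean and zero-mean passes:
#' n * d * w bits. The stream-based variant (SHE) keeps only the mean
#' vector and the l x d weight matrix: (d + l*d) * w bits. Conventional
#' PCA must buffer the spikes and additionally hold the d x d covariance
#' plus solver workspace: the orthogonal-iteration (OI) and Jacobi
#' models add 2 d^2 w, the QR model 3 d^2 w.
#'
#' @param method one of \code{"HE"}, \code{"SHE"}, \code{"OI"},
#'   \code{"QR"}, \code{"Jacobi"}.
#' @param n training spikes (default 1024).
#' @param d samples per spike (default 64).
#' @param l components (default 2).
#' @param w word length in bits per sample (default 16).
#' @return memory in bits.
#' @examples
#' memory_bits("HE")   # 1048576, i.e. 1.05e6
#' memory_bits("SHE")  # 3072,    i.e. 0.0031e6
#' @export
memory_bits <- function(method, n = 1024L, d = 64L, l = 2L, w = 16L) {
  method <- match.arg(method, c("HE", "SHE", "OI", "QR", "Jacobi"))
  switch(method,
         HE     = n * d * w,
         SHE    = (d + l * d) * w,
         OI     = n * d * w + 2 * d^2 * w,
         Jacobi = n * d * w + 2 * d^2 * w,
         QR     = n * d * w + 3 * d^2 * w)
}

# published reference operation counts for the conventional PCA routes
# (covariance + iterative symmetric eigensolver, 8 iterations), at the
# benchmark configuration n=1024, d=64, l=2
.baseline_ops <- list(
  OI     = list(adds = 4.51e6, mults = 4.39e6, divs = 16,   sqrts = 16),
  QR     = list(adds = 4.77e6, mults = 4.75e6, divs = 1100, sqrts = 570),
  Jacobi = list(adds = 10.6e6, mults = 8.94e6, divs = 48400, sqrts = 322000))

#' Operation counts of spike feature-extraction methods
#'
#' For the Hebbian eigenfilters (HE/SHE) the counts are exact closed
#' forms of the learning kernel, summed over the N presentations:
#' per presentation, the score y = W x, the lower-triangular Gram
#' LT(y y'), the outer product y x', the product LT W, and the
#' learning-rate scaling cost 3 l d + l(l+1)/2 (d+1) multiplications,
#' and l(d-1) + d l(l-1)/2 + 2 l d additions. Mean-phase additions are
#' excluded and the division by a power-of-two n is a shift, so
#' divisions and square roots are zero. The conventional PCA baselines
#' (OI, QR, Jacobi) carry published reference constants valid only at
#' the benchmark configuration (n = 1024, d = 64, l = 2, 8 solver
#' iterations).
#'
#' @inheritParams memory_bits
#' @param N learning presentations (default 1024).
#' @param iters solver iterations assumed by the baseline constants
#'   (default 8).
#' @return list of class \code{"complexity_report"}: \code{method},
#'   \code{adds}, \code{mults}, \code{divs}, \code{sqrts},
#'   \code{memory_bits}.
#' @examples
#' op_counts("SHE")$adds   # 456704, i.e. 0.46e6
#' op_counts("SHE")$mults  # 592896, i.e. 0.59e6
#' @export
op_counts <- function(method, n = 1024L, d = 64L, l = 2L, N = 1024L,
                      w = 16L, iters = 8L) {
  method <- match.arg(method, c("HE", "SHE", "OI", "QR", "Jacobi"))
  if (method %in% c("HE", "SHE")) {
    mults_per <- 3 * l * d + (l * (l + 1) / 2) * (d + 1)
    adds_per  <- l * (d - 1) + d * l * (l - 1) / 2 + 2 * l * d
    rep <- list(method = method, adds = N * adds_per, mults = N * mults_per,
                divs = 0, sqrts = 0,
                memory_bits = memory_bits(method, n, d, l, w))
  } else {
    if (n != 1024L || d != 64L || l != 2L || iters != 8L)
      stop("unsupported parameters: the ", method, " reference constants ",
           "are only valid at n=1024, d=64, l=2, iters=8")
    b <- .baseline_ops[[method]]
    rep <- c(list(method = method), b,
             list(memory_bits = memory_bits(method, n, d, l, w)))
  }
  structure(rep, class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("%-8s adds %.3g x10^6  mults %.3g x10^6  divs %.3g x10^3  sqrts %.3g x10^3  mem %.3g x10^6 bits\n",
              x$method, x$adds / 1e6, x$mults / 1e6, x$divs / 1e3,
              x$sqrts / 1e3, x$memory_bits / 1e6))
  invisible(x)
}

#' Reduction rate between two operation or memory counts
#'
#' \code{100 * (1 - b / a)}: the percentage of cost \code{a} saved by
#' using cost \code{b} instead.
#'
#' @param a reference count (> 0).
#' @param b reduced count.
#' @return percentage.
#' @examples
#' reduction_rate(memory_bits("OI"), memory_bits("SHE"))  # 99.7
#' @export
reduction_rate <- function(a, b) {
  if (a <= 0) stop("undefined: reference count must be positive")
  100 * (1 - b / a)
}

#' Instrumented operation count of the Hebbian learning kernel
#'
#' Executes the learning kernel literally -- element-by-element scalar
#' loops for y = W x, LT(y y'), y x', LT W, the subtraction, the eta
#' scaling and the weight update -- incrementing a counter at every
#' scalar addition and multiplication. This is the brute-force oracle
#' the closed forms in \code{\link{op_counts}} are checked against.
#'
#' @param l,d weight matrix dimensions.
#' @param N presentations to run (default 1).
#' @param seed seed for the random inputs the kernel runs on.
#' @return list: \code{adds}, \code{mults} (totals over N
#'   presentations).
#' @export
count_hebbian_ops <- function(l, d, N = 1L, seed = 1L) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  W <- matrix(stats::rnorm(l * d, sd = 0.1), l, d)
  adds <- 0L; mults <- 0L
  eta <- 0.01
  for (pres in seq_len(N)) {
    x <- stats::rnorm(d)
    y <- numeric(l)
    for (i in seq_len(l)) {           # y = W x: d mults, d-1 adds per row
      acc <- W[i, 1] * x[1]; mults <- mults + 1L
      for (k in seq_len(d)[-1]) {
        acc <- acc + W[i, k] * x[k]; mults <- mults + 1L; adds <- adds + 1L
      }
      y[i] <- acc
    }
    LT <- matrix(0, l, l)             # lower triangle of y y'
    for (i in seq_len(l)) for (k in seq_len(i)) {
      LT[i, k] <- y[i] * y[k]; mults <- mults + 1L
    }
    LTW <- matrix(0, l, d)            # LT W, lower-triangular LT
    for (i in seq_len(l)) for (k in seq_len(d)) {
      acc <- LT[i, 1] * W[1, k]; mults <- mults + 1L
      if (i > 1) for (jj in 2:i) {
        acc <- acc + LT[i, jj] * W[jj, k]; mults <- mults + 1L; adds <- adds + 1L
      }
      LTW[i, k] <- acc
    }
    for (i in seq_len(l)) for (k in seq_len(d)) {
      diff <- y[i] * x[k] - LTW[i, k]           # y x' and subtraction
      mults <- mults + 1L; adds <- adds + 1L
      W[i, k] <- W[i, k] + eta * diff           # eta scaling + update
      mults <- mults + 1L; adds <- adds + 1L
    }
  }
  list(adds = adds, mults = mults)
}

#' Full complexity comparison table
#'
#' Computes the memory and operation counts of all five methods at a
#' common configuration and the reduction rates of each conventional
#' PCA route relative to the stream-based eigenfilter.
#'
#' @inheritParams op_counts
#' @return list: \code{reports} (named list of
#'   \code{"complexity_report"}), \code{reductions} (data.frame of
#'   percentage reductions vs SHE).
#' @export
complexity_table <- function(n = 1024L, d = 64L, l = 2L, N = 1024L,
                             w = 16L, iters = 8L) {
  methods <- c("HE", "SHE", "OI", "QR", "Jacobi")
  reports <- lapply(methods, op_counts, n = n, d = d, l = l, N = N,
                    w = w, iters = iters)
  names(reports) <- methods
  she <- reports$SHE
  red <- do.call(rbind, lapply(c("OI", "QR", "Jacobi"), function(m) {
    r <- reports[[m]]
    data.frame(comparison = paste(m, "vs SHE"),
               adds = reduction_rate(r$adds, she$adds),
               mults = reduction_rate(r$mults, she$mults),
               divs = if (r$divs > 0) reduction_rate(r$divs, she$divs) else NA,
               sqrts = if (r$sqrts > 0) reduction_rate(r$sqrts, she$sqrts) else NA,
               memory = reduction_rate(r$memory_bits, she$memory_bits))
  }))
  list(reports = reports, reductions = red)
}
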