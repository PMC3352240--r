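#' Lower-triangular operator
#'
#' Sets every element strictly above the diagonal of a square matrix to
#' zero, keeping the diagonal. In the Hebbian update this operator
#' enforces the deflation ordering among components: component i learns
#' only from variance not already captured by components 1..i.
#'
#' @param M square numeric matrix.
#' @return matrix of the same shape with the upper triangle zeroed.
#' @examples
#' lt_lower_triangular(matrix(1:4, 2, byrow = TRUE))
#' @export
lt_lower_triangular <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("invalid input: M must be square")
  M[upper.tri(M)] <- 0
  M
}

#' One Hebbian learning step (Sanger's rule)
#'
#' Given the current l x d synaptic weight matrix W and a zero-mean spike
#' x, computes the scores y = W x, the lower-triangular Gram matrix
#' LT(y y') and the update W <- W + eta (y x' - LT(y y') W). The fixed
#' points of this update on stationary input are the leading l
#' eigenvectors of the input covariance.
#'
#' @param W l x d weight matrix.
#' @param x zero-mean input vector of length d.
#' @param eta learning rate (> 0).
#' @param y_clip bound on each score component before the update
#'   (default Inf = the pure rule). The update contracts only while
#'   eta y_i^2 < 2; clipping |y_i| at sqrt(1.5 / eta) guarantees that
#'   for any input, tames the large-norm initial transient, and is
#'   inactive once the weights are near their unit-norm fixed points.
#' @return the updated weight matrix.
#' @examples
#' hebbian_step(matrix(0.5, 1, 1), 2, eta = 0.1)  # 0.65
#' @export
hebbian_step <- function(W, x, eta, y_clip = Inf) {
  W <- as.matrix(W)
  if (length(x) != ncol(W)) stop("invalid input: length(x) != ncol(W)")
  y <- W %*% x                      # l x 1
  if (is.finite(y_clip)) y <- pmin(pmax(y, -y_clip), y_clip)
  LT <- tcrossprod(y)               # y y'
  LT[upper.tri(LT)] <- 0
  Wnew <- W + eta * (y %*% t(x) - LT %*% W)
  if (!all(is.finite(Wnew)))
    stop("divergence: non-finite weights after update; ",
         "the learning rate eta = ", eta, " is likely too large")
  Wnew
}

#' Initialize a streaming eigenfilter state
#'
#' The state machine has two phases. In \code{mean_accumulation} the
#' first \code{n} spikes are summed into a running mean (and running
#' sum of squared norms, used to freeze the input scale) and then
#' discarded -- they are never stored. In \code{learning}, each
#' subsequent spike is centred with the frozen mean, rescaled, passed
#' once through \code{\link{hebbian_step}}, and discarded.
#'
#' @param d spike dimension.
#' @param l number of components to learn (1 <= l <= d).
#' @param n spikes consumed by the mean phase.
#' @param N learning presentations.
#' @param eta initial learning rate.
#' @param W_init scalar or l x d matrix of initial weights.
#' @param eta_decay if TRUE (default) the rate decays as
#'   eta / (1 + j / decay_halflife); if FALSE eta is constant.
#' @param decay_halflife presentations after which the decayed rate has
#'   halved (default 256).
#' @param eta_warmup presentations over which the rate ramps linearly
#'   from near zero to its schedule value (default 0 = no ramp).
#' @param norm_clip reject-artifact bound: a centred spike whose norm
#'   exceeds \code{norm_clip} times the target RMS is scaled down to
#'   that bound before the update (default 3). Outlier windows --
#'   overlaps, artifacts, noise bursts -- otherwise make single Hebbian
#'   steps arbitrarily large and can destabilize the weights. 0 or Inf
#'   disables clipping.
#' @param scale input rescaling: TRUE (default) rescales so centred
#'   spikes have unit RMS norm (estimated during the mean phase and
#'   frozen), FALSE disables rescaling, and a positive number sets the
#'   target RMS norm directly (default 2: a target above 1 raises the
#'   effective learning rate eta * RMS^2, which the trailing components
#'   need to converge within the presentation budget).
#' @return list of class \code{"eigenfilter_state"}.
#' @export
eigenfilter_init <- function(d, l = 2L, n = 1024L, N = 1024L, eta = 0.1,
                             W_init = 0.5, eta_decay = TRUE,
                             decay_halflife = 256, scale = 2,
                             eta_warmup = 0, norm_clip = 3) {
  if (l < 1L || l > d) stop("require 1 <= l <= d")
  if (eta < 0) stop("eta must be nonnegative")
  W <- if (is.matrix(W_init)) W_init else matrix(W_init, l, d)
  if (nrow(W) != l || ncol(W) != d) stop("W_init has wrong shape")
  structure(list(W = W, mu = numeric(d), ssq = 0, eta = eta, j = 0L,
                 n = as.integer(n), N = as.integer(N), l = l, d = d,
                 mean_count = 0L, phase = if (n > 0L) "mean_accumulation" else "learning",
                 scale = 1, do_scale = scale, eta_decay = eta_decay,
                 decay_halflife = decay_halflife, eta_warmup = eta_warmup,
                 norm_clip = norm_clip,
                 spikes_live = 0L, max_spikes_live = 0L),
            class = "eigenfilter_state")
}

#' Feed one spike to a streaming eigenfilter state
#'
#' Applies the phase-appropriate update (mean accumulation or a Hebbian
#' learning step) and returns the new state. The spike itself is not
#' retained: the state holds only the weight matrix, the mean vector and
#' a handful of scalars. The fields \code{spikes_live} /
#' \code{max_spikes_live} instrument the streaming memory contract (at
#' most one spike vector is held at any instant).
#'
#' @param state an \code{"eigenfilter_state"}.
#' @param x spike vector of length \code{state$d} (raw amplitudes; the
#'   state does its own centring and scaling during learning).
#' @return the updated state.
#' @export
eigenfilter_update <- function(state, x) {
  if (state$phase == "done") stop("eigenfilter already finished (j = N)")
  if (length(x) != state$d) stop("invalid input: length(x) != d")
  state$spikes_live <- state$spikes_live + 1L  # x is now held
  state$max_spikes_live <- max(state$max_spikes_live, state$spikes_live)
  if (state$phase == "mean_accumulation") {
    state$mu <- state$mu + x
    state$ssq <- state$ssq + sum(x^2)
    state$mean_count <- state$mean_count + 1L
    if (state$mean_count == state$n) {
      state$mu <- state$mu / state$n
      # E||x - mu||^2 = E||x||^2 - ||mu||^2, from one-pass sums
      v <- state$ssq / state$n - sum(state$mu^2)
      tgt <- if (is.numeric(state$do_scale)) state$do_scale else 1
      state$scale <- if (!isFALSE(state$do_scale) && v > 0) tgt / sqrt(v) else 1
      state$phase <- if (state$N > 0L) "learning" else "done"
    }
  } else {
    xc <- (x - state$mu) * state$scale
    if (!is.null(state$norm_clip) && state$norm_clip > 0 &&
        is.finite(state$norm_clip)) {
      tgt <- if (is.numeric(state$do_scale)) state$do_scale else 1
      nx <- sqrt(sum(xc^2))
      cap <- state$norm_clip * tgt
      if (nx > cap) xc <- xc * (cap / nx)
    }
    eta_j <- if (state$eta_decay)
      state$eta / (1 + state$j / state$decay_halflife) else state$eta
    if (state$eta_warmup > 0 && state$j < state$eta_warmup)
      eta_j <- eta_j * (state$j + 1) / state$eta_warmup
    state$W <- hebbian_step(state$W, xc, eta_j,
                            y_clip = if (eta_j > 0) sqrt(1.5 / eta_j) else Inf)
    state$j <- state$j + 1L
    if (state$j >= state$N) state$phase <- "done"
  }
  state$spikes_live <- state$spikes_live - 1L  # x discarded
  state
}

#' Fit a Hebbian eigenfilter to spike waveforms
#'
#' Learns the leading \code{l} principal components of aligned spike
#' waveforms by the generalized Hebbian algorithm (Sanger's rule),
#' without computing a covariance matrix or an eigendecomposition.
#'
#' Two modes are available. \code{mode = "stream"} is the single-pass
#' variant: the first \code{n} spikes are used only to accumulate the
#' mean (and are discarded), and the next \code{N} spikes are centred
#' with that frozen mean and each presented once to the Hebbian update.
#' No spike buffer is kept, so the memory footprint is the weight matrix
#' plus the mean vector. This relies on pseudo-stationarity: the spike
#' shape statistics of successive blocks of the recording are assumed
#' interchangeable. \code{mode = "batch"} is the conventional variant:
#' the mean is computed over all stored spikes, all spikes are centred,
#' and the update cycles over them until \code{N} presentations.
#'
#' @param x an n x d numeric matrix of aligned spikes (rows = spikes), a
#'   \code{"spike_matrix"} from \code{\link{detect_spikes}}, or (stream
#'   mode only) a function that returns the next spike vector, or
#'   \code{NULL} when exhausted.
#' @param l number of components (default 2; the feature space for
#'   sorting usually uses the first 2 or 3).
#' @param n spikes consumed by the mean phase (stream mode; default 1024).
#' @param N learning presentations (default 1024).
#' @param eta initial learning rate (default 0.1).
#' @param W_init initial weight value, scalar (default 0.5) or matrix.
#' @param mode \code{"stream"} or \code{"batch"}.
#' @param eta_decay,decay_halflife,scale,eta_warmup,norm_clip see
#'   \code{\link{eigenfilter_init}}.
#' @return object of class \code{"eigenfilter"}: a list with \code{W}
#'   (l x d learned components, one per row), \code{mu} (frozen mean),
#'   \code{scale}, \code{l}, \code{d}, \code{mode}, \code{n}, \code{N},
#'   \code{eta}, \code{presentations}, \code{max_spikes_live}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(4096 * 8), ncol = 8) %*% diag(c(4, 2, rep(1, 6)))
#' f <- eigenfilter(X, l = 2, n = 1024, N = 1024, mode = "stream")
#' f
#' @seealso \code{\link{spike_pca}} for the conventional batch PCA
#'   oracle, \code{\link{predict.eigenfilter}} for projections.
#' @export
eigenfilter <- function(x, l = 2L, n = 1024L, N = 1024L, eta = 0.1,
                        W_init = 0.5, mode = c("stream", "batch"),
                        eta_decay = TRUE, decay_halflife = 256,
                        scale = 2, eta_warmup = 0, norm_clip = 3) {
  mode <- match.arg(mode)
  if (inherits(x, "spike_matrix")) x <- x$spikes
  cl <- match.call()

  if (mode == "batch") {
    if (!is.matrix(x)) stop("batch mode needs a stored spike matrix")
    if (nrow(x) < 1L) stop("need at least one spike")
    d <- ncol(x)
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- mean(rowSums(xc^2))
    tgt <- if (is.numeric(scale)) scale else 1
    sc <- if (!isFALSE(scale) && v > 0) tgt / sqrt(v) else 1
    xc <- xc * sc
    if (norm_clip > 0 && is.finite(norm_clip)) {
      nx <- sqrt(rowSums(xc^2))
      cap <- norm_clip * tgt
      over <- nx > cap
      if (any(over)) xc[over, ] <- xc[over, , drop = FALSE] * (cap / nx[over])
    }
    st <- eigenfilter_init(d, l, n = 0L, N = N, eta = eta, W_init = W_init,
                           eta_decay = eta_decay,
                           decay_halflife = decay_halflife, scale = FALSE,
                           eta_warmup = eta_warmup, norm_clip = 0)
    nspk <- nrow(x)
    j <- 0L
    while (j < N) {
      st <- eigenfilter_update(st, xc[(j %% nspk) + 1L, ])
      j <- j + 1L
    }
    return(.eigenfilter_result(st$W, mu, sc, l, d, mode, n = nspk, N, eta,
                               st$j, st$max_spikes_live, cl))
  }

  # stream mode: one pass, one spike held at a time
  nextspike <-
    if (is.function(x)) x
    else {
      if (!is.matrix(x)) stop("x must be a matrix, spike_matrix, or function")
      i <- 0L
      nr <- nrow(x)
      function() { if (i >= nr) return(NULL); i <<- i + 1L; x[i, ] }
    }
  dim_probe <- nextspike()
  if (is.null(dim_probe)) stop("spike stream is empty")
  d <- length(dim_probe)
  st <- eigenfilter_init(d, l, n, N, eta, W_init, eta_decay,
                         decay_halflife, scale, eta_warmup, norm_clip)
  st <- eigenfilter_update(st, dim_probe)
  dim_probe <- NULL
  while (st$phase != "done") {
    xs <- nextspike()
    if (is.null(xs))
      stop("spike stream exhausted in phase '", st$phase, "' after ",
           st$mean_count, " mean spikes and ", st$j, " presentations; ",
           "need n + N = ", st$n + st$N)
    st <- eigenfilter_update(st, xs)
  }
  .eigenfilter_result(st$W, st$mu, st$scale, l, d, mode, st$n, st$N, eta,
                      st$j, st$max_spikes_live, cl)
}

.eigenfilter_result <- function(W, mu, scale, l, d, mode, n, N, eta, j,
                                max_live, call) {
  structure(list(W = W, mu = mu, scale = scale, l = l, d = d, mode = mode,
                 n = n, N = N, eta = eta, presentations = j,
                 max_spikes_live = max_live, call = call),
            class = "eigenfilter")
}

#' @export
print.eigenfilter <- function(x, ...) {
  cat(sprintf("%s Hebbian eigenfilter: %d component(s) of d = %d\n",
              if (x$mode == "stream") "Stream-based" else "Batch", x$l, x$d))
  cat(sprintf("  mean over n = %d spikes, N = %d presentations, eta0 = %g\n",
              x$n, x$N, x$eta))
  cat(sprintf("  component norms: %s\n",
              paste(sprintf("%.3f", sqrt(rowSums(x$W^2))), collapse = ", ")))
  invisible(x)
}

#' @export
summary.eigenfilter <- function(object, ...) {
  norms <- sqrt(rowSums(object$W^2))
  G <- object$W %*% t(object$W)
  ortho <- if (object$l > 1) max(abs(G[upper.tri(G)])) else 0
  out <- list(object = object, norms = norms, max_cross = ortho)
  class(out) <- "summary.eigenfilter"
  out
}

#' @export
print.summary.eigenfilter <- function(x, ...) {
  print(x$object)
  cat(sprintf("  max |cross-product| between components: %.4g\n", x$max_cross))
  cat(sprintf("  input scale factor: %.6g (unit-RMS centred spikes)\n",
              x$object$scale))
  invisible(x)
}

#' @export
coef.eigenfilter <- function(object, ...) object$W

#' Project spikes onto learned components
#'
#' Scores are \code{scale * (x - mu)} projected on each component row:
#' the coordinates of every spike in the learned feature space, used as
#' input to clustering.
#'
#' @param object a fitted \code{"eigenfilter"}.
#' @param newdata spike matrix (n x d), \code{"spike_matrix"}, or single
#'   spike vector.
#' @param ... unused.
#' @return n x l score matrix.
#' @export
predict.eigenfilter <- function(object, newdata, ...) {
  project_spikes(newdata, object$W, object$mu, object$scale)
}

#' @rdname predict.eigenfilter
#' @param spikes spike matrix as for \code{newdata}.
#' @param W l x d component matrix.
#' @param mu mean vector subtracted before projection.
#' @param scale scalar applied after centring (default 1).
#' @export
project_spikes <- function(spikes, W, mu, scale = 1) {
  if (inherits(spikes, "spike_matrix")) spikes <- spikes$spikes
  if (is.null(dim(spikes))) spikes <- matrix(spikes, nrow = 1L)
  if (ncol(spikes) != ncol(W)) stop("invalid input: spike length != ncol(W)")
  (sweep(spikes, 2L, mu) * scale) %*% t(W)
}

#' @export
plot.eigenfilter <- function(x, spikes = NULL, ...) {
  graphics::matplot(t(x$W), type = "l", lty = 1,
                    xlab = "sample", ylab = "weight",
                    main = "Learned components", ...)
  if (!is.null(spikes)) {
    sc <- predict(x, spikes)
    if (ncol(sc) >= 2) {
      graphics::plot(sc[, 1], sc[, 2], pch = 20, cex = 0.5,
                     xlab = "PC1 score", ylab = "PC2 score",
                     main = "Feature space")
    }
  }
  invisible(x)
}
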