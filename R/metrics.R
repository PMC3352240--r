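#' K-means clustering of spike feature scores
#'
#' Standard k-means with K fixed to the expected neuron count, multiple
#' restarts, best within-cluster sum of squares kept. Deterministic
#' under a fixed seed.
#'
#' @param scores n x l feature score matrix.
#' @param K number of clusters (1 <= K <= n).
#' @param seed RNG seed governing the restarts.
#' @param nstart number of random restarts (default 10).
#' @return list of class \code{"sorting_result"}: \code{assignments}
#'   (cluster id in 1..K per spike), \code{K}, \code{centers},
#'   \code{inertia}, and (after \code{\link{match_clusters}})
#'   \code{mapping}.
#' @export
cluster_kmeans <- function(scores, K, seed = 1L, nstart = 10L) {
  scores <- as.matrix(scores)
  if (K < 1L) stop("K must be >= 1")
  if (nrow(scores) < K) stop("invalid input: fewer spikes than clusters")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  if (K == nrow(scores)) {
    # degenerate: every spike its own cluster, zero inertia
    return(structure(list(assignments = seq_len(K), K = as.integer(K),
                          centers = scores, inertia = 0, mapping = NULL),
                     class = "sorting_result"))
  }
  km <- stats::kmeans(scores, centers = K, nstart = nstart, iter.max = 100L)
  structure(list(assignments = as.integer(km$cluster), K = as.integer(K),
                 centers = km$centers, inertia = km$tot.withinss,
                 mapping = NULL),
            class = "sorting_result")
}

#' @export
print.sorting_result <- function(x, ...) {
  cat(sprintf("Sorting result: %d spikes in %d cluster(s); inertia %.4g\n",
              length(x$assignments), x$K, x$inertia))
  if (!is.null(x$mapping)) {
    m <- ifelse(is.na(x$mapping), "-", x$mapping)
    cat("  cluster -> neuron mapping:", paste(m, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pair detected event times with ground-truth event times
#'
#' Greedy one-to-one nearest-time pairing within a tolerance: candidate
#' (detection, truth) pairs are considered in order of increasing time
#' difference and accepted when both members are still free. Unpaired
#' detections are false detections; unpaired truths are misses.
#'
#' @param detected sample indices of detected events.
#' @param truth_times sample indices of ground-truth events.
#' @param tol pairing tolerance in samples (default 12, i.e. ~0.5 ms at
#'   25 kHz).
#' @return list with \code{pairs} (data.frame \code{det}, \code{truth}:
#'   indices into the two input vectors), \code{unmatched_det},
#'   \code{unmatched_truth} (index vectors).
#' @export
match_events <- function(detected, truth_times, tol = 12L) {
  if (tol < 0) stop("tol must be >= 0")
  nd <- length(detected); nt <- length(truth_times)
  if (nd == 0L || nt == 0L)
    return(list(pairs = data.frame(det = integer(0), truth = integer(0)),
                unmatched_det = seq_len(nd), unmatched_truth = seq_len(nt)))
  ord_t <- order(truth_times); st <- truth_times[ord_t]
  # candidates: for each detection, the truth on either side
  pos <- findInterval(detected, st)
  cand <- rbind(
    cbind(det = seq_len(nd), tr = pos),
    cbind(det = seq_len(nd), tr = pos + 1L))
  cand <- cand[cand[, "tr"] >= 1L & cand[, "tr"] <= nt, , drop = FALSE]
  dt <- abs(detected[cand[, "det"]] - st[cand[, "tr"]])
  keep <- dt <= tol
  cand <- cand[keep, , drop = FALSE]; dt <- dt[keep]
  o <- order(dt)
  used_d <- logical(nd); used_t <- logical(nt)
  pd <- integer(0); pt <- integer(0)
  for (i in o) {
    dd <- cand[i, "det"]; tt <- cand[i, "tr"]
    if (!used_d[dd] && !used_t[tt]) {
      used_d[dd] <- TRUE; used_t[tt] <- TRUE
      pd <- c(pd, dd); pt <- c(pt, ord_t[tt])
    }
  }
  list(pairs = data.frame(det = pd, truth = pt),
       unmatched_det = which(!used_d),
       unmatched_truth = which(!used_t)[order(ord_t[!used_t])])
}

#' Map clusters to neurons by maximizing correctly classified spikes
#'
#' Finds the one-to-one cluster-to-neuron assignment that maximizes the
#' total number of correctly classified spikes, by exact enumeration
#' over injective assignments (the cluster counts here are small).
#' Surplus clusters remain unmapped and count only against the false
#' positive rate.
#'
#' @param result a \code{"sorting_result"}.
#' @param truth_labels neuron id per spike (NA for spikes with no paired
#'   ground-truth event).
#' @return the \code{"sorting_result"} with \code{mapping} filled in:
#'   element k is the neuron id assigned to cluster k, or NA.
#' @export
match_clusters <- function(result, truth_labels) {
  stopifnot(inherits(result, "sorting_result"))
  if (length(truth_labels) != length(result$assignments))
    stop("truth_labels length must match assignments")
  neurons <- sort(unique(truth_labels[!is.na(truth_labels)]))
  if (length(neurons) == 0L) stop("need at least one labelled spike")
  K <- result$K
  # contingency: clusters x neurons
  C <- matrix(0L, K, length(neurons))
  ok <- !is.na(truth_labels)
  for (i in which(ok)) {
    C[result$assignments[i], match(truth_labels[i], neurons)] <-
      C[result$assignments[i], match(truth_labels[i], neurons)] + 1L
  }
  maps <- .injective_maps(K, length(neurons))
  best <- NULL; best_score <- -1L
  for (m in maps) {
    sc <- sum(C[cbind(which(!is.na(m)), m[!is.na(m)])])
    if (sc > best_score) { best_score <- sc; best <- m }
  }
  result$mapping <- neurons[best]  # NA propagates for unmapped clusters
  result
}

# all injective maps from 1..K into 1..M (NA where unmapped when K > M)
.injective_maps <- function(K, M) {
  if (K <= M) {
    cols <- utils::combn(M, K, simplify = FALSE)
    out <- list()
    for (cc in cols)
      for (p in .perms(K)) out[[length(out) + 1L]] <- cc[p]
    out
  } else {
    out <- list()
    for (rows in utils::combn(K, M, simplify = FALSE))
      for (p in .perms(M)) {
        m <- rep(NA_integer_, K); m[rows] <- p
        out[[length(out) + 1L]] <- m
      }
    out
  }
}

.perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in .perms(k - 1L))
    for (pos in 0:(k - 1L))
      out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

#' Relative error between two mean vectors
#'
#' \code{sum(|mu1 - mu2|) / sum(|mu2|)}: the block-to-block discrepancy
#' of spike means, used to justify the streaming mean approximation
#' under pseudo-stationarity. Zero when the second block's mean is
#' estimated exactly by the first.
#'
#' @param mu1,mu2 numeric vectors of equal length; \code{mu2} is the
#'   reference.
#' @return nonnegative scalar (0 = identical means).
#' @examples
#' error_mean(c(1, 1), c(2, 2))  # 0.5
#' @export
error_mean <- function(mu1, mu2) {
  if (length(mu1) != length(mu2)) stop("mean vectors differ in length")
  den <- sum(abs(mu2))
  if (den == 0) stop("undefined: reference mean vector is all zero")
  sum(abs(mu1 - mu2)) / den
}

#' Angular deviation between a learned component and a reference PC
#'
#' Both vectors are normalized to unit length; the deviation is
#' \code{1 - |w . pc|}. It is zero when the directions coincide or are
#' opposite (eigenvector sign is arbitrary) and 1 for orthogonal
#' directions.
#'
#' @param w learned component (nonzero vector).
#' @param pc reference principal component (nonzero vector).
#' @return scalar in [0, 1].
#' @export
error_pc <- function(w, pc) {
  nw <- sqrt(sum(w^2)); np <- sqrt(sum(pc^2))
  if (nw == 0 || np == 0) stop("invalid input: zero vector")
  1 - abs(sum(w * pc)) / (nw * np)
}

#' Per-neuron true positive rate of a sorting result
#'
#' The unweighted mean over mapped cluster-neuron pairs of
#' (correctly classified spikes of neuron i) / (total ground-truth
#' spikes of neuron i). Missed detections count in the denominator.
#'
#' @param result a \code{"sorting_result"} with a cluster-neuron
#'   \code{mapping} (see \code{\link{match_clusters}}).
#' @param truth_labels neuron id per detected spike (NA = false
#'   detection).
#' @param n_truth named vector: total ground-truth spike count per
#'   neuron (including missed detections). If omitted, the labelled
#'   spike counts are used.
#' @return TPR in [0, 1].
#' @export
true_positive_rate <- function(result, truth_labels, n_truth = NULL) {
  m <- .mapped_pairs(result)
  if (is.null(n_truth)) {
    tab <- table(truth_labels)
    n_truth <- as.numeric(tab); names(n_truth) <- names(tab)
  }
  rates <- numeric(0)
  for (k in seq_len(nrow(m))) {
    neuron <- m$neuron[k]
    tot <- n_truth[as.character(neuron)]
    if (is.na(tot) || tot == 0) {
      warning("neuron ", neuron, " has no ground-truth spikes; excluded")
      next
    }
    correct <- sum(result$assignments == m$cluster[k] &
                     !is.na(truth_labels) & truth_labels == neuron)
    rates <- c(rates, correct / tot)
  }
  mean(rates)
}

#' Per-neuron false positive rate of a sorting result
#'
#' The unweighted mean over mapped cluster-neuron pairs of (false
#' spikes assigned to neuron i) / (total false spikes for neuron i),
#' where the false spikes for neuron i are all detected spikes not
#' belonging to i -- spikes of other neurons plus false detections.
#'
#' @inheritParams true_positive_rate
#' @return FPR in [0, 1].
#' @export
false_positive_rate <- function(result, truth_labels) {
  m <- .mapped_pairs(result)
  rates <- numeric(0)
  for (k in seq_len(nrow(m))) {
    neuron <- m$neuron[k]
    pool <- is.na(truth_labels) | truth_labels != neuron
    if (!any(pool)) {
      warning("no false spikes for neuron ", neuron, "; excluded")
      next
    }
    fp <- sum(pool & result$assignments == m$cluster[k])
    rates <- c(rates, fp / sum(pool))
  }
  mean(rates)
}

.mapped_pairs <- function(result) {
  stopifnot(inherits(result, "sorting_result"))
  if (is.null(result$mapping))
    stop("run match_clusters() before computing rates")
  k <- which(!is.na(result$mapping))
  data.frame(cluster = k, neuron = result$mapping[k])
}

#' Evaluate a sorting result against ground truth
#'
#' Convenience wrapper: pairs detected events with ground-truth events,
#' maps clusters to neurons, and computes TPR and FPR.
#'
#' @param event_times detected event peak samples (one per spike row).
#' @param result a \code{"sorting_result"} for those spikes.
#' @param truth ground-truth data.frame (\code{sample_index},
#'   \code{neuron_id}).
#' @param tol event-pairing tolerance in samples (default 12).
#' @return list: \code{tpr}, \code{fpr}, \code{n_detected},
#'   \code{n_truth}, \code{n_missed}, \code{n_false_detections},
#'   \code{result} (with mapping), \code{truth_labels}.
#' @export
evaluate_sorting <- function(event_times, result, truth, tol = 12L) {
  em <- match_events(event_times, truth$sample_index, tol)
  labels <- rep(NA_integer_, length(event_times))
  labels[em$pairs$det] <- truth$neuron_id[em$pairs$truth]
  result <- match_clusters(result, labels)
  n_truth <- table(truth$neuron_id)
  nt <- as.numeric(n_truth); names(nt) <- names(n_truth)
  list(tpr = true_positive_rate(result, labels, nt),
       fpr = false_positive_rate(result, labels),
       n_detected = length(event_times),
       n_truth = nrow(truth),
       n_missed = length(em$unmatched_truth),
       n_false_detections = length(em$unmatched_det),
       result = result, truth_labels = labels)
}
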