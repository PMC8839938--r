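# Consensus R-peak labeling: pool candidate positions from all
# (detector, lead) streams and reconcile them with a deterministic 1-D
# k-means, where k is the rounded median of per-stream candidate counts.

# plain Lloyd iteration in one dimension with fixed initial centers; written
# here (rather than stats::kmeans) because duplicate initial centers and
# singleton pools are routine for integer candidate positions and must not
# error, and because determinism is part of the consensus contract
kmeans_1d <- function(x, centers, max_iter = 100L) {
  k <- length(centers)
  assign <- rep(1L, length(x))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    new_assign <- max.col(-d, ties.method = "first")
    if (it > 1L && all(new_assign == assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      m <- assign == j
      if (any(m)) centers[j] <- mean(x[m])
    }
  }
  list(centers = centers, cluster = assign)
}

#' Reconcile detector candidates into consensus R-peaks
#'
#' Pools candidate positions from all non-empty (detector, lead) streams and
#' clusters them with one-dimensional k-means. The number of clusters k is
#' the rounded median of the candidate counts over non-empty streams; centers
#' are initialized at the k evenly spaced quantiles of the sorted pool, so
#' the whole procedure is deterministic and invariant to stream order.
#' Clusters supported by fewer than `support_frac` of the non-empty streams
#' are discarded; surviving centers are rounded to the nearest sample, and
#' centers closer than the refractory period are merged keeping the one with
#' higher support.
#'
#' @param candidates a `candidate_set` from [detect_candidates()].
#' @param fs sampling rate in Hz; defaults to the set's `fs` attribute.
#' @param refractory minimum credible inter-beat interval, seconds
#'   (default 0.2).
#' @param support_frac minimum fraction of non-empty streams that must
#'   contribute a member to a cluster (default 0.5).
#' @return an object of class `consensus_rpeaks`: list with `peaks` (sorted
#'   0-based sample indices) and `support` (per-peak count of contributing
#'   streams).
#' @export
consensus_rpeaks <- function(candidates, fs = attr(candidates, "fs"),
                             refractory = 0.2, support_frac = 0.5) {
  streams <- Filter(length, unclass(candidates))
  if (!length(streams)) stop("all candidate streams are empty")
  counts <- lengths(streams)
  k <- max(1L, as.integer(round(stats::median(counts))))
  pool <- unlist(streams, use.names = FALSE)
  stream_id <- rep(seq_along(streams), counts)
  ord <- order(pool)
  pool <- pool[ord]
  stream_id <- stream_id[ord]
  k <- min(k, length(pool))
  init <- stats::quantile(pool, probs = (seq_len(k) - 0.5) / k,
                          names = FALSE, type = 7)
  km <- kmeans_1d(pool, init)
  # robust centers: members farther than half the refractory period from
  # the cluster median are stray candidates (eg an isolated T-wave hit
  # absorbed into a true beat's cluster); they contribute neither to the
  # center nor to its support
  half_refr <- round(refractory * fs / 2)
  centers <- numeric(k)
  support <- integer(k)
  members <- integer(k)
  for (j in seq_len(k)) {
    m <- which(km$cluster == j)
    if (!length(m)) next
    core <- m[abs(pool[m] - stats::median(pool[m])) <= half_refr]
    centers[j] <- mean(pool[core])
    support[j] <- length(unique(stream_id[core]))
    members[j] <- length(core)
  }
  keep <- members > 0L & support >= support_frac * length(streams)
  peaks <- as.integer(round(centers[keep]))
  support <- support[keep]
  ord <- order(peaks)
  peaks <- peaks[ord]; support <- support[ord]
  # merge centers within the refractory distance, keeping higher support
  min_d <- round(refractory * fs)
  i <- 1L
  while (i < length(peaks)) {
    if (peaks[i + 1L] - peaks[i] < min_d) {
      drop <- if (support[i + 1L] > support[i]) i else i + 1L
      peaks <- peaks[-drop]; support <- support[-drop]
      i <- max(1L, i - 1L)
    } else i <- i + 1L
  }
  structure(list(peaks = peaks, support = support),
            fs = fs, class = "consensus_rpeaks")
}

#' @export
print.consensus_rpeaks <- function(x, ...) {
  cat(sprintf("<consensus_rpeaks: %d peaks, support %s>\n", length(x$peaks),
              paste(range(x$support), collapse = "-")))
  invisible(x)
}

#' Write consensus peaks as CSV
#'
#' One row per peak: `sample_index` (0-based) and `support`.
#'
#' @param peaks a `consensus_rpeaks`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_rpeaks <- function(peaks, path) {
  utils::write.csv(data.frame(sample_index = peaks$peaks,
                              support = peaks$support),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read consensus peaks from CSV
#'
#' @param path CSV written by [write_rpeaks()].
#' @param fs sampling rate to attach.
#' @return a `consensus_rpeaks`.
#' @export
read_rpeaks <- function(path, fs) {
  d <- utils::read.csv(path)
  structure(list(peaks = as.integer(d$sample_index),
                 support = as.integer(d$support)),
            fs = fs, class = "consensus_rpeaks")
}
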