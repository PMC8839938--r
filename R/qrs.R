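# Beat segmentation: cut the record at midpoints between consecutive
# consensus R-peaks, drop the first and last segments, resample each retained
# segment to 100 samples per lead, and attach per-beat BPM and
# resampling-ratio metadata.

#' Midpoint segment boundaries
#'
#' Cut points lie at `floor((r_i + r_(i+1)) / 2)` for consecutive peaks; the
#' resulting half-open intervals partition `[0, record_length)`. The first
#' and last intervals (the edge segments, which contain at most a partial
#' beat) are flagged for removal.
#'
#' @param rpeaks sorted 0-based R-peak sample indices (>= 3).
#' @param record_length record length in samples.
#' @return data.frame with columns `start`, `end` (half-open, 0-based) and
#'   `keep` (FALSE for the two edge segments).
#' @export
segment_boundaries <- function(rpeaks, record_length) {
  rpeaks <- as.integer(rpeaks)
  if (length(rpeaks) < 3L)
    stop("need at least 3 R-peaks to retain an interior segment")
  if (any(diff(rpeaks) <= 0L)) stop("`rpeaks` must be strictly increasing")
  cuts <- (rpeaks[-length(rpeaks)] + rpeaks[-1]) %/% 2L
  starts <- c(0L, cuts)
  ends <- c(cuts, as.integer(record_length))
  keep <- rep(TRUE, length(starts))
  keep[c(1L, length(keep))] <- FALSE
  data.frame(start = starts, end = ends, keep = keep)
}

resample_linear <- function(y, n_out) {
  n_in <- length(y)
  if (n_in == n_out) return(y)
  stats::approx(x = seq(0, 1, length.out = n_in), y = y,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Extract fixed-length QRS complexes from a record
#'
#' Applies [segment_boundaries()] to the consensus peaks, drops the edge
#' segments, and linearly resamples each retained segment to exactly 100
#' samples per lead. Each beat carries `bpm = 60 * fs / L` and
#' `resample_ratio = L / 100`, with `L` its pre-resampling segment length in
#' samples (the midpoint-to-midpoint span, about one RR interval).
#'
#' @param record an [ecg_record()].
#' @param rpeaks a `consensus_rpeaks` from [consensus_rpeaks()], or an
#'   integer vector of 0-based peak indices.
#' @param n_samples output samples per lead per beat (default 100).
#' @return an object of class `qrs_set`: list with `qrs` (list of 12 x 100
#'   matrices), `bpm`, `resample_ratio`, `beat_index`, `record_id`,
#'   `superclass`, `subclass`.
#' @export
extract_qrs <- function(record, rpeaks, n_samples = 100L) {
  stopifnot(inherits(record, "ecg_record"))
  pk <- if (inherits(rpeaks, "consensus_rpeaks")) rpeaks$peaks else rpeaks
  seg <- segment_boundaries(pk, ncol(record$signal))
  seg <- seg[seg$keep, , drop = FALSE]
  qrs <- vector("list", nrow(seg))
  bpm <- numeric(nrow(seg))
  ratio <- numeric(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    idx <- (seg$start[i] + 1L):seg$end[i]      # 0-based half-open -> 1-based
    len <- length(idx)
    block <- record$signal[, idx, drop = FALSE]
    qrs[[i]] <- t(apply(block, 1L, resample_linear, n_out = n_samples))
    bpm[i] <- 60 * record$fs / len
    ratio[i] <- len / n_samples
  }
  structure(list(qrs = qrs, bpm = bpm, resample_ratio = ratio,
                 beat_index = seq_len(nrow(seg)),
                 record_id = record$record_id,
                 superclass = record$superclass, subclass = record$subclass),
            class = "qrs_set")
}

#' @export
print.qrs_set <- function(x, ...) {
  cat(sprintf("<qrs_set '%s': %d beats of 12 x %d, bpm %s>\n",
              x$record_id, length(x$qrs), ncol(x$qrs[[1]]),
              paste(round(range(x$bpm), 1), collapse = "-")))
  invisible(x)
}

#' Number of beats in a QRS set
#' @param x a `qrs_set`.
#' @return integer beat count.
#' @export
n_beats <- function(x) length(x$qrs)

#' Write a QRS archive
#'
#' One CSV holds the stacked beat matrices (rows `beat_index`, `lead`,
#' then the 100 sample columns); a JSON sidecar holds per-beat metadata
#' (bpm, resample_ratio) and record labels.
#'
#' @param qs a `qrs_set`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_qrs_set <- function(qs, path) {
  mats <- do.call(rbind, qs$qrs)
  d <- data.frame(beat_index = rep(qs$beat_index, each = 12L),
                  lead = rep(1:12, length(qs$qrs)))
  utils::write.csv(cbind(d, as.data.frame(mats)), path, row.names = FALSE)
  meta <- list(record_id = qs$record_id, bpm = qs$bpm,
               resample_ratio = qs$resample_ratio)
  meta$superclass <- qs$superclass
  meta$subclass <- qs$subclass
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a QRS archive written by [write_qrs_set()]
#' @param path CSV path.
#' @return a `qrs_set`.
#' @export
read_qrs_set <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  beats <- sort(unique(d$beat_index))
  qrs <- lapply(beats, function(b) {
    m <- as.matrix(d[d$beat_index == b, -(1:2)])
    dimnames(m) <- NULL
    m[order(d$lead[d$beat_index == b]), , drop = FALSE]
  })
  structure(list(qrs = qrs, bpm = as.numeric(meta$bpm),
                 resample_ratio = as.numeric(meta$resample_ratio),
                 beat_index = beats, record_id = meta$record_id,
                 superclass = meta$superclass, subclass = meta$subclass),
            class = "qrs_set")
}
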