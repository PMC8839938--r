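# Six classical single-lead R-peak detectors. Each takes one lead (numeric
# vector, mV) and the sampling rate and returns sorted 0-based sample indices.
# They are deterministic pure functions; all-zero input yields no candidates.
# Each follows the published algorithm's characteristic transform and an
# adaptive or two-moving-average threshold, with the final fiducial snapped to
# the dominant deflection of the raw lead within a 100 ms window.

ma_centered <- function(x, w) {
  w <- max(1L, as.integer(w))
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

bandpass <- function(x, fs, lo, hi, order = 2) {
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# local maxima of y at least `min_dist` samples apart (greedy, by amplitude)
local_maxima <- function(y, min_dist) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[y[cand] > 0]
  if (length(cand) < 2L) return(cand)
  ord <- cand[order(y[cand], decreasing = TRUE)]
  keep <- logical(n)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(taken - i) > min_dist)) {
      keep[i] <- TRUE
      taken <- c(taken, i)
    }
  }
  sort(which(keep))
}

# snap rough fiducials to the strongest raw deflection nearby; dedupe within
# the refractory distance keeping the larger deflection
refine_peaks <- function(x, idx, fs, win = 0.10, refractory = 0.2) {
  if (!length(idx)) return(integer(0))
  w <- round(win * fs)
  n <- length(x)
  snapped <- vapply(as.integer(idx), function(i) {
    lo <- max(1L, i - as.integer(w)); hi <- min(n, i + as.integer(w))
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  snapped <- sort(unique(snapped))
  amps <- abs(x[snapped])
  min_d <- round(refractory * fs)
  keep <- rep(TRUE, length(snapped))
  i <- 1L
  while (i < length(snapped)) {
    j <- i + 1L
    if (keep[i] && snapped[j] - snapped[i] < min_d) {
      if (amps[j] >= amps[i]) keep[i] <- FALSE else keep[j] <- FALSE
      snapped2 <- snapped[keep]; amps2 <- amps[keep]
      snapped <- snapped2; amps <- amps2
      keep <- rep(TRUE, length(snapped))
      i <- max(1L, i - 1L)
    } else i <- i + 1L
  }
  snapped
}

# two-moving-average block detection (shared by the Elgendi-style stages);
# the offset term keeps low-amplitude stretches (T waves, noise floor) from
# opening blocks of interest
blocks_of_interest <- function(feature, fs, w_event, w_beat, min_block,
                               beta = 0.08) {
  ma_ev <- ma_centered(feature, w_event * fs)
  ma_bt <- ma_centered(feature, w_beat * fs)
  on <- ma_ev > ma_bt + beta * mean(feature) & ma_bt > 0
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= round(min_block * fs)
  mapply(function(s, e) s + which.max(feature[s:e]) - 1L,
         starts[ok], ends[ok])
}

det_pan_tompkins <- function(x, fs) {
  if (all(x == 0)) return(integer(0))
  bp <- bandpass(x, fs, 5, 15)
  d <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2)
  d[is.na(d)] <- 0
  mwi <- ma_centered(as.numeric(d)^2, 0.150 * fs)
  pk <- local_maxima(mwi, round(0.2 * fs))
  if (!length(pk)) return(integer(0))
  # running signal/noise level threshold (classic SPKI/NPKI updates)
  spki <- max(mwi[seq_len(min(length(mwi), 2 * fs))]) / 2
  npki <- mean(mwi[seq_len(min(length(mwi), 2 * fs))]) / 2
  qrs <- integer(0)
  for (i in pk) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] > thr) {
      qrs <- c(qrs, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  refine_peaks(x, qrs, fs) - 1L
}

det_hamilton <- function(x, fs) {
  if (all(x == 0)) return(integer(0))
  bp <- bandpass(x, fs, 8, 16)
  feat <- ma_centered(abs(bp), 0.08 * fs)
  pk <- local_maxima(feat, round(0.2 * fs))
  if (!length(pk)) return(integer(0))
  savg <- max(feat[seq_len(min(length(feat), 2 * fs))])
  navg <- 0
  qrs <- integer(0)
  for (i in pk) {
    thr <- navg + 0.3125 * (savg - navg)
    if (feat[i] > thr) {
      qrs <- c(qrs, i)
      savg <- 0.125 * feat[i] + 0.875 * savg
    } else {
      navg <- 0.125 * feat[i] + 0.875 * navg
    }
  }
  refine_peaks(x, qrs, fs) - 1L
}

det_two_average <- function(x, fs) {
  if (all(x == 0)) return(integer(0))
  bp <- bandpass(x, fs, 8, 20)
  pk <- blocks_of_interest(abs(bp), fs, w_event = 0.12, w_beat = 0.6,
                           min_block = 0.08)
  if (!length(pk)) return(integer(0))
  refine_peaks(x, pk, fs) - 1L
}

# db3 decomposition filters (stationary/undecimated transform, à trous)
.db3_lo <- c(0.035226291882100656, -0.08544127388224149, -0.13501102001039084,
             0.4598775021193313, 0.8068915093133388, 0.3326705529509569)
.db3_hi <- c(-0.3326705529509569, 0.8068915093133388, -0.4598775021193313,
             -0.13501102001039084, 0.08544127388224149, 0.035226291882100656)

# detail level whose passband straddles the QRS energy (~10-30 Hz)
swt_level_for <- function(fs) max(2L, round(log2(fs / 31.25)))

swt_detail <- function(x, level) {
  a <- x
  d <- NULL
  for (j in seq_len(level)) {
    up <- 2^(j - 1)
    lo <- rep(0, (length(.db3_lo) - 1) * up + 1)
    lo[seq(1, length(lo), by = up)] <- .db3_lo
    hi <- rep(0, (length(.db3_hi) - 1) * up + 1)
    hi[seq(1, length(hi), by = up)] <- .db3_hi
    pad <- length(lo)
    ax <- c(rev(a[seq_len(pad)]), a, rev(a[(length(a) - pad + 1):length(a)]))
    d <- stats::filter(ax, hi, sides = 2)[(pad + 1):(pad + length(a))]
    a <- stats::filter(ax, lo, sides = 2)[(pad + 1):(pad + length(a))]
  }
  as.numeric(d)
}

det_swt <- function(x, fs) {
  if (all(x == 0)) return(integer(0))
  sq <- ma_centered(swt_detail(x, swt_level_for(fs))^2, 0.05 * fs)
  pk <- blocks_of_interest(sq, fs, w_event = 0.11, w_beat = 0.66,
                           min_block = 0.04)
  if (!length(pk)) return(integer(0))
  refine_peaks(x, pk, fs) - 1L
}

# running steep-slope / amplitude threshold shared by the Christov and
# Engzee stages: candidates are local maxima of `feat`, accepted when they
# clear `theta` times the running mean of the last `memory` accepted peaks
# (seeded from the first two seconds), with a mild decay on rejection
adaptive_accept <- function(feat, fs, theta, memory = 5L) {
  pk <- local_maxima(feat, round(0.2 * fs))
  if (!length(pk)) return(integer(0))
  recent <- max(feat[seq_len(min(length(feat), 2 * fs))])
  qrs <- integer(0)
  for (i in pk) {
    if (feat[i] > theta * mean(recent)) {
      qrs <- c(qrs, i)
      recent <- c(recent, feat[i])
      if (length(recent) > memory) recent <- recent[-1]
    } else {
      recent <- recent * 0.99
    }
  }
  qrs
}

det_christov <- function(x, fs) {
  if (all(x == 0)) return(integer(0))
  # powerline / drift suppression then complex-lead style slope magnitude
  y <- ma_centered(x, fs / 50)
  y <- ma_centered(y, 0.014 * fs)
  cl <- ma_centered(abs(c(0, diff(y))), 0.016 * fs)
  qrs <- adaptive_accept(cl, fs, theta = 0.55)
  if (!length(qrs)) return(integer(0))
  refine_peaks(x, qrs, fs) - 1L
}

det_engzee <- function(x, fs) {
  if (all(x == 0)) return(integer(0))
  # four-sample differentiator and smoothing comb, per the original design
  d <- x - c(rep(0, 4), x[seq_len(length(x) - 4)])
  y <- stats::filter(d, c(1, 4, 6, 4, 1), sides = 2)
  y[is.na(y)] <- 0
  feat <- ma_centered(abs(as.numeric(y)), 0.024 * fs)
  qrs <- adaptive_accept(feat, fs, theta = 0.48)
  if (!length(qrs)) return(integer(0))
  refine_peaks(x, qrs, fs) - 1L
}

#' Registry of the available single-lead R-peak detectors
#'
#' @return named list of detector functions `function(x, fs)` returning
#'   sorted 0-based candidate sample indices.
#' @export
ecg_detectors <- function() {
  list("hamilton" = det_hamilton,
       "two-average" = det_two_average,
       "swt" = det_swt,
       "christov" = det_christov,
       "pan-tompkins" = det_pan_tompkins,
       "engzee" = det_engzee)
}

#' Run R-peak detectors on every lead of a record
#'
#' Applies each named detector independently to each of the 12 leads,
#' yielding one (possibly empty) candidate stream per (detector, lead) pair.
#'
#' @param record an [ecg_record()] of duration >= 2 s.
#' @param detectors character vector of detector names (see
#'   [ecg_detectors()]); default all six.
#' @return an object of class `candidate_set`: a named list
#'   `"<detector>.<lead>"` of sorted 0-based index vectors, with the
#'   sampling rate in attribute `fs`.
#' @export
detect_candidates <- function(record, detectors = names(ecg_detectors())) {
  stopifnot(inherits(record, "ecg_record"))
  if (ncol(record$signal) < 2 * record$fs)
    stop("record shorter than 2 s")
  if (!length(detectors)) stop("`detectors` must not be empty")
  reg <- ecg_detectors()
  unknown <- setdiff(detectors, names(reg))
  if (length(unknown))
    stop("unknown detector name(s): ", paste(unknown, collapse = ", "))
  out <- list()
  for (d in detectors)
    for (lead in 1:12)
      out[[paste0(d, ".", lead)]] <-
        as.integer(reg[[d]](record$signal[lead, ], record$fs))
  structure(out, fs = record$fs, class = "candidate_set")
}
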