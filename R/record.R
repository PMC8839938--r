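#' Multi-lead ECG record
#'
#' Container for one 12-lead ECG record. The signal is stored as a numeric
#' matrix with one row per lead (12 rows) and one column per sample, in
#' millivolts. All sample indices exposed by the package (ground-truth and
#' detected R-peaks, segment boundaries) are 0-based, and segments are
#' half-open intervals `[start, end)` on the sample grid.
#'
#' @param signal numeric matrix, 12 rows (leads) by T columns (samples), mV.
#' @param fs sampling rate in Hz (> 0).
#' @param record_id character identifier.
#' @param superclass optional class label (one of the 5 superclasses).
#' @param subclass optional subclass label (one of the 20 subclasses).
#' @param truth_rpeaks optional integer vector of 0-based R-peak sample
#'   positions, strictly increasing; only populated for synthetic records
#'   where the ground truth is known by construction.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, record_id = "record",
                       superclass = NULL, subclass = NULL,
                       truth_rpeaks = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (leads x samples)")
  if (nrow(signal) != 12L)
    stop("expected exactly 12 leads, got ", nrow(signal))
  if (ncol(signal) < 1L)
    stop("`signal` has no samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (!is.null(truth_rpeaks)) {
    truth_rpeaks <- as.integer(truth_rpeaks)
    if (any(diff(truth_rpeaks) <= 0L))
      stop("`truth_rpeaks` must be strictly increasing")
    if (any(truth_rpeaks < 0L) || any(truth_rpeaks >= ncol(signal)))
      stop("`truth_rpeaks` out of range [0, n_samples)")
  }
  structure(
    list(record_id = as.character(record_id), signal = signal, fs = fs,
         superclass = superclass, subclass = subclass,
         truth_rpeaks = truth_rpeaks),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': 12 leads x %d samples @ %g Hz (%.1f s)>\n",
              x$record_id, ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  if (!is.null(x$superclass))
    cat("  class:", x$superclass,
        if (!is.null(x$subclass)) paste0("/ ", x$subclass) else "", "\n")
  if (!is.null(x$truth_rpeaks))
    cat("  ground-truth R-peaks:", length(x$truth_rpeaks), "\n")
  invisible(x)
}

#' Label catalog
#'
#' Ordered sets of superclass and subclass names plus the subclass-to-
#' superclass mapping. The catalog order is also the deterministic tie-break
#' order used by the nearest-center classifier.
#'
#' @param superclasses character vector of superclass names.
#' @param subclasses character vector of subclass names.
#' @param subclass_to_superclass named character vector mapping each subclass
#'   to its superclass.
#' @return an object of class `label_catalog`.
#' @export
label_catalog <- function(superclasses, subclasses, subclass_to_superclass) {
  superclasses <- as.character(superclasses)
  subclasses <- as.character(subclasses)
  if (!all(subclasses %in% names(subclass_to_superclass)))
    stop("every subclass needs an entry in `subclass_to_superclass`")
  map <- subclass_to_superclass[subclasses]
  if (!all(map %in% superclasses))
    stop("subclass maps to unknown superclass")
  structure(list(superclasses = superclasses, subclasses = subclasses,
                 subclass_to_superclass = map),
            class = "label_catalog")
}

#' Default five-superclass diagnostic catalog
#'
#' The five diagnostic superclasses used throughout (normal, myocardial
#' infarction, ST/T change, conduction disturbance, hypertrophy) with four
#' generic subclasses each, as used by the synthetic fixtures.
#'
#' @return a `label_catalog` with 5 superclasses and 20 subclasses.
#' @export
default_catalog <- function() {
  supers <- c("NORM", "MI", "STTC", "CD", "HYP")
  subs <- as.vector(vapply(supers, function(s) paste0(s, "_", 1:4),
                           character(4)))
  map <- stats::setNames(rep(supers, each = 4), subs)
  label_catalog(supers, subs, map)
}
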