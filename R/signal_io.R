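# Record I/O: CSV (one row per sample, 12 mV columns, fs in a JSON sidecar)
# and a minimal WFDB format-16 header/signal pair for interoperability.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a 12-lead ECG record
#'
#' CSV records hold one row per sample and 12 comma-separated millivolt
#' columns; sampling rate, labels and (for synthetic records) ground-truth
#' R-peaks travel in a JSON sidecar next to the file. WFDB records are the
#' usual `.hea` + `.dat` pair, signal format 16.
#'
#' @param path path to the `.csv` file or to the WFDB record (with or without
#'   the `.hea` extension).
#' @param format `"csv"` or `"wfdb"`; default guesses from the extension.
#' @return an [ecg_record()].
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path)) "csv" else "wfdb"
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
}

#' Write a 12-lead ECG record
#'
#' @param record an [ecg_record()].
#' @param path destination path (see [read_record()] for layout).
#' @param format `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "csv") write_record_csv(record, path)
  else write_record_wfdb(record, path)
  invisible(path)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- as.matrix(utils::read.csv(path, header = FALSE))
  if (ncol(x) != 12L)
    stop("expected 12 channels, file has ", ncol(x))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar with sampling rate: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar lacks `fs`: ", sp)
  ecg_record(t(unname(x)), fs = as.numeric(meta$fs),
             record_id = meta$record_id %||% basename(path),
             superclass = meta$superclass, subclass = meta$subclass,
             truth_rpeaks = meta$truth_rpeaks)
}

write_record_csv <- function(record, path) {
  utils::write.table(t(record$signal), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(record_id = record$record_id, fs = record$fs)
  meta$superclass <- record$superclass
  meta$subclass <- record$subclass
  meta$truth_rpeaks <- record$truth_rpeaks
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

# Minimal WFDB subset: format 16, little-endian int16, one .dat for all
# channels, gain in adu/mV, zero baseline. Enough for round-tripping the
# records this package produces and for reading files laid out the same way.
read_record_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("no such file: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  if (is.na(nsig)) stop("unreadable header: ", hea)
  if (nsig != 12L) stop("expected 12 channels, header declares ", nsig)
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  sig <- lines[2:(1 + nsig)]
  fields <- strsplit(trimws(sig), "\\s+")
  datfile <- fields[[1]][1]
  fmt <- sub("x.*$", "", fields[[1]][2])
  if (fmt != "16") stop("only WFDB signal format 16 is supported, got ", fmt)
  gains <- vapply(fields, function(f) {
    g <- suppressWarnings(as.numeric(sub("\\(.*$", "", f[3])))
    if (is.na(g) || g == 0) 200 else g  # WFDB default gain
  }, numeric(1))
  dat <- file.path(dirname(hea), datfile)
  raw <- readBin(dat, "integer", n = nsig * nsamp, size = 2,
                 endian = "little", signed = TRUE)
  adu <- matrix(raw, nrow = nsig)          # interleaved: sample-major
  mv <- adu / gains
  ecg_record(mv, fs = fs,
             record_id = sub("\\.hea$", "", basename(hea)))
}

write_record_wfdb <- function(record, path, gain = 1000) {
  base <- sub("\\.hea$", "", path)
  name <- basename(base)
  nsamp <- ncol(record$signal)
  hea <- c(sprintf("%s 12 %g %d", name, record$fs, nsamp),
           sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s",
                   name, gain, paste0("lead", 1:12)))
  writeLines(hea, paste0(base, ".hea"))
  adu <- round(record$signal * gain)
  adu <- pmin(pmax(adu, -32768), 32767)
  writeBin(as.integer(adu), paste0(base, ".dat"), size = 2,
           endian = "little")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter a diagnostic-statement table down to confidently labeled records
#'
#' Applies, in order: (a) drop records with no diagnostic code; (b) keep only
#' codes carried at 100% likelihood; (c) keep only records whose confident
#' codes resolve to exactly one superclass and exactly one subclass; (d) drop
#' subclasses with fewer than `min_subclass_size` surviving records. The
#' size filter runs once, after (a)-(c), not iteratively.
#'
#' @param metadata data.frame in long form with columns `record_id`, `code`,
#'   `likelihood` (0-100): one row per diagnostic statement attached to a
#'   record.
#' @param statements data.frame with columns `code`, `superclass`, `subclass`
#'   mapping each diagnostic code to its classes; codes absent from this
#'   table are treated as non-diagnostic and ignored.
#' @param min_subclass_size minimum number of retained records a subclass
#'   needs to survive (default 20).
#' @return data.frame with columns `record_id`, `superclass`, `subclass`,
#'   one row per surviving record.
#' @export
filter_ptbxl <- function(metadata, statements, min_subclass_size = 20L) {
  need <- c("record_id", "code", "likelihood")
  if (!all(need %in% names(metadata)))
    stop("`metadata` must have columns: ", paste(need, collapse = ", "))
  if (!all(c("code", "superclass", "subclass") %in% names(statements)))
    stop("`statements` must have columns: code, superclass, subclass")

  m <- merge(metadata, statements, by = "code")        # diagnostic codes only
  m <- m[m$likelihood == 100, , drop = FALSE]          # fully confident
  if (nrow(m) == 0L)
    return(data.frame(record_id = character(), superclass = character(),
                      subclass = character(), stringsAsFactors = FALSE))
  nsuper <- tapply(m$superclass, m$record_id, function(x) length(unique(x)))
  nsub <- tapply(m$subclass, m$record_id, function(x) length(unique(x)))
  ok <- names(nsuper)[nsuper == 1L & nsub == 1L]       # unambiguous records
  m <- m[m$record_id %in% ok, , drop = FALSE]
  m <- unique(m[, c("record_id", "superclass", "subclass")])
  keep_sub <- names(which(table(m$subclass) >= min_subclass_size))
  m <- m[m$subclass %in% keep_sub, , drop = FALSE]
  m <- m[order(m$record_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}
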