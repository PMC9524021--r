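#' Construct a subject time-series object
#'
#' @param data numeric matrix, ROIs in rows and time points in columns (N x T).
#' @param subject_id subject identifier.
#' @param tr sampling interval (repetition time) in seconds.
#' @param demeaned logical; have rows already been mean-centred?
#' @return An object of class `subject_ts`.
#' @export
subject_ts <- function(data, subject_id = "subject", tr = 2, demeaned = FALSE) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stopf("time-series data must be numeric")
  if (anyNA(data) || any(!is.finite(data))) {
    stopf("subject %s: time series contains missing or non-finite values", subject_id)
  }
  if (ncol(data) < 2L) stopf("subject %s: need at least 2 time points", subject_id)
  if (tr <= 0) stopf("tr must be positive (seconds)")
  structure(list(subject_id = as.character(subject_id), data = data,
                 tr = tr, demeaned = isTRUE(demeaned)),
            class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("Subject '%s': %d ROIs x %d time points (tr = %gs, %s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr,
              if (x$demeaned) "demeaned" else "raw"))
  invisible(x)
}

#' @export
dim.subject_ts <- function(x) dim(x$data)

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read an ROI time-series table
#'
#' Reads a delimited text file (TSV or CSV, auto-detected) whose header row
#' holds ROI abbreviations and whose rows are successive fMRI volumes. Columns
#' are matched to the parcellation by abbreviation, so column order in the
#' file is irrelevant; a missing or surplus ROI column is an error.
#'
#' @param path file path.
#' @param parcellation a [parcellation] defining the expected ROIs and order.
#' @param tr sampling interval in seconds (default 2).
#' @param subject_id identifier; defaults to the file name without extension.
#' @return A [subject_ts] with data oriented N x T in parcellation order.
#' @export
read_timeseries <- function(path, parcellation, tr = 2, subject_id = NULL) {
  if (!file.exists(path)) stopf("time-series file not found: %s", path)
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  abbrevs <- parcellation$abbrev
  absent <- setdiff(abbrevs, names(tab))
  if (length(absent)) {
    stopf("%s: missing ROI column(s): %s", path, paste(absent, collapse = ", "))
  }
  extra <- setdiff(names(tab), abbrevs)
  if (length(extra)) {
    stopf("%s: unexpected column(s): %s", path, paste(extra, collapse = ", "))
  }
  tab <- tab[, abbrevs, drop = FALSE]
  if (!all(vapply(tab, is.numeric, logical(1)))) {
    bad <- names(tab)[!vapply(tab, is.numeric, logical(1))]
    stopf("%s: non-numeric values in column(s): %s", path, paste(bad, collapse = ", "))
  }
  if (nrow(tab) < 2L) stopf("%s: need at least 2 time points, found %d", path, nrow(tab))
  m <- t(as.matrix(tab))
  rownames(m) <- abbrevs
  id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  subject_ts(m, subject_id = id, tr = tr)
}

#' Write an ROI time-series table
#'
#' Inverse of [read_timeseries()]: one row per volume, one named column per
#' ROI, tab-separated.
#'
#' @param ts a [subject_ts].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "subject_ts"))
  tab <- as.data.frame(t(ts$data))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Zero-phase band-pass filter and mean-centre ROI signals
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass filter to
#' each ROI row, then removes the row mean. The default band 0.01--0.1 Hz is
#' the conventional resting-state fMRI band.
#'
#' @param ts a [subject_ts].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < Nyquist`,
#'   where Nyquist is `1 / (2 * tr)`.
#' @param order Butterworth filter order (default 4).
#' @return A [subject_ts] with `demeaned = TRUE`.
#' @export
bandpass_demean <- function(ts, low = 0.01, high = 0.1, order = 4) {
  stopifnot(inherits(ts, "subject_ts"))
  nyq <- 1 / (2 * ts$tr)
  if (!(low > 0 && low < high && high < nyq)) {
    stopf("infeasible band [%g, %g] Hz for tr = %gs (Nyquist %g Hz)",
          low, high, ts$tr, nyq)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filt <- t(apply(ts$data, 1L, function(row) {
    y <- signal::filtfilt(bf, row)
    y - mean(y)
  }))
  rownames(filt) <- rownames(ts$data)
  subject_ts(filt, subject_id = ts$subject_id, tr = ts$tr, demeaned = TRUE)
}

#' Remove the mean of a series
#'
#' @param x numeric vector of length >= 2.
#' @return `x - mean(x)`.
#' @export
demean <- function(x) {
  if (length(x) < 2L) stopf("demean needs at least 2 observations")
  x - mean(x)
}
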