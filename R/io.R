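#' Read a single-channel signal from a plain-text CSV file
#'
#' The expected layout is one numeric sample per line; lines starting with
#' `#` are treated as comments and skipped. Because plain text carries no
#' sampling-rate information, `fs` must be supplied.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz.
#' @param modality Signal modality tag, see [signal_record()].
#' @param label Optional identifier; defaults to the file name.
#' @return A [signal_record].
#' @export
read_signal_csv <- function(path, fs, modality = "ecg", label = basename(path)) {
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1]]
    stop(sprintf("non-numeric sample on line %d of %s: '%s'",
                 bad, path, lines[bad]))
  }
  if (length(vals) < 2L)
    stop("signal file must contain at least 2 samples: ", path)
  signal_record(vals, fs = fs, modality = modality, label = label)
}

#' Write a signal record to a plain-text CSV file
#'
#' One sample per line, full double precision, with a short `#` comment
#' header recording fs and modality. [read_signal_csv()] reads the result
#' back losslessly.
#'
#' @param path Output path.
#' @param rec A [signal_record].
#' @return Invisibly, `path`.
#' @export
write_signal_csv <- function(path, rec) {
  stopifnot(inherits(rec, "signal_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s modality=%s label=%s",
                     format(rec$fs), rec$modality, rec$label), con)
  writeLines(format(rec$samples, digits = 17, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' Write beat annotations to a tab-separated text file
#'
#' One beat per line: 0-based sample index and time in seconds
#' (`index / fs`), tab-separated, preceded by `#` comment lines recording
#' the sampling rate. The index column is authoritative; the seconds column
#' is a human convenience.
#'
#' @param path Output path, or an open writable connection.
#' @param ann A [beat_annotations] object.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(path, ann) {
  stopifnot(inherits(ann, "beat_annotations"))
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, "w")
    on.exit(close(con))
  }
  writeLines(sprintf("# beat annotations, fs=%s Hz", format(ann$fs)), con)
  writeLines("# index\tseconds", con)
  if (length(ann$indices))
    writeLines(sprintf("%d\t%.6f", ann$indices, ann$indices / ann$fs), con)
  invisible(path)
}

#' Read beat annotations written by [write_annotations()]
#'
#' @param path Path to the TSV file.
#' @param fs Sampling rate in Hz. If `NULL`, the `fs=` value in the header
#'   comment is used when present.
#' @return A [beat_annotations] object.
#' @export
read_annotations <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (is.null(fs)) {
    hdr <- grep("^#.*fs=", lines, value = TRUE)
    if (length(hdr)) {
      fs <- suppressWarnings(as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", hdr[1])))
    }
    if (is.null(fs) || is.na(fs))
      stop("no fs= header in ", path, "; pass `fs` explicitly")
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data <- lines[keep]
  if (!length(data)) return(beat_annotations(integer(0), fs))
  idx <- suppressWarnings(as.numeric(vapply(strsplit(data, "\t"), `[[`, "", 1L)))
  if (anyNA(idx)) {
    bad <- which(keep)[which(is.na(idx))[1]]
    stop(sprintf("unparseable annotation on line %d of %s", bad, path))
  }
  beat_annotations(idx, fs)
}
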