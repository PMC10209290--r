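# Minimal native WFDB support: header (.hea) parsing, signal formats 16 and
# 212, and MIT-format beat annotations (.atr/.qrs). Enough to read PhysioNet
# records of those formats and to round-trip the fixtures the test suite
# writes; CSV remains the guaranteed input path.

# standard WFDB beat annotation codes (NORMAL..UNKNOWN, BBB, AESC, SVESC,
# PFUS, RONT); everything else (rhythm changes, noise marks, comments) is
# not a beat
.wfdb_beat_codes <- c(1:13, 25, 34, 35, 38, 41)

.wfdb_symbol_code <- c(
  "N" = 1, "L" = 2, "R" = 3, "a" = 4, "V" = 5, "F" = 6, "J" = 7, "A" = 8,
  "S" = 9, "E" = 10, "j" = 11, "/" = 12, "Q" = 13, "~" = 14, "|" = 16,
  "s" = 18, "T" = 19, "*" = 20, "D" = 21, '"' = 22, "=" = 23, "p" = 24,
  "B" = 25, "^" = 26, "t" = 27, "+" = 28, "u" = 29, "?" = 30, "!" = 31,
  "[" = 32, "]" = 33, "e" = 34, "n" = 35, "@" = 36, "x" = 37, "f" = 38,
  "(" = 39, ")" = 40, "r" = 41
)

.parse_hea <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 2) stop("malformed WFDB header: ", hea_path)
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (length(lines) < 1 + nsig) stop("header lists ", nsig,
                                     " signals but has too few lines")
  sig <- lapply(lines[seq_len(nsig) + 1L], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_spec <- if (length(tok) >= 3) tok[3] else "200"
    units <- sub("^[^/]*/?", "", gain_spec)
    gb <- sub("/.*", "", gain_spec)
    baseline <- NA_real_
    if (grepl("\\(", gb)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gb))
      gb <- sub("\\(.*", "", gb)
    }
    gain <- as.numeric(gb)
    if (!is.finite(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(tok) >= 5) as.numeric(tok[5]) else 0
    if (!is.finite(baseline)) baseline <- adc_zero
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else ""
    list(file = tok[1], fmt = sub("[x+:].*$", "", tok[2]), gain = gain,
         baseline = baseline, units = if (nzchar(units)) units else "mV",
         desc = desc)
  })
  list(record = top[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

.read_dat <- function(path, fmt, nsig) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (fmt == "16") {
    n <- length(raw) %/% 2L
    vals <- readBin(raw, "integer", n = n, size = 2L, signed = TRUE,
                    endian = "little")
  } else if (fmt == "212") {
    n3 <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(n3)])
    b0 <- b[seq(1, n3, by = 3)]
    b1 <- b[seq(2, n3, by = 3)]
    b2 <- b[seq(3, n3, by = 3)]
    s1 <- bitwAnd(b1, 0x0F) * 256L + b0
    s2 <- bitwAnd(b1, 0xF0) %/% 16L * 256L + b2
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    vals <- as.vector(rbind(s1, s2))
  } else {
    stop("unsupported WFDB signal format: ", fmt,
         " (formats 16 and 212 are supported)")
  }
  nframe <- length(vals) %/% nsig
  matrix(vals[seq_len(nframe * nsig)], ncol = nsig, byrow = TRUE)
}

.read_atr <- function(path) {
  raw <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  i <- 1L; t_abs <- 0; codes <- integer(0); times <- numeric(0)
  pending <- 0
  while (i + 1L <= length(raw)) {
    w <- raw[i] + 256L * raw[i + 1L]; i <- i + 2L
    code <- w %/% 1024L; delta <- w %% 1024L
    if (code == 0L && delta == 0L) break                       # EOF
    if (code == 59L) {                                         # SKIP
      if (delta == 0L && i + 3L <= length(raw)) {
        hi <- raw[i] + 256L * raw[i + 1L]
        lo <- raw[i + 2L] + 256L * raw[i + 3L]
        i <- i + 4L
        pending <- pending + hi * 65536 + lo
      }
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN modifiers: no time advance, ignore value
    } else if (code == 63L) {                                  # AUX string
      i <- i + delta + (delta %% 2L)
    } else {
      t_abs <- t_abs + pending + delta
      pending <- 0
      codes <- c(codes, code)
      times <- c(times, t_abs)
    }
  }
  list(codes = codes, times = times)
}

#' Read a WFDB record (and beat annotations, if present)
#'
#' Reads the header, one signal channel converted to physical units, and --
#' when an annotation file (`.atr` or `.qrs`) accompanies the record -- its
#' beat annotations. Only the standard beat-type annotation codes are kept
#' (normal and ectopic beats, escapes, paced and fusion beats); rhythm
#' changes, noise marks and comments are dropped. Signal formats 16 and 212
#' are supported. All returned indices are 0-based.
#'
#' @param record Record base name (path without extension).
#' @param channel Channel selector: 0-based integer index, or the channel
#'   description string from the header.
#' @param modality Modality tag for the returned [signal_record].
#' @return A list with elements `record` (a [signal_record]) and
#'   `annotations` (a [beat_annotations], or `NULL` when no annotation file
#'   exists).
#' @export
read_wfdb_record <- function(record, channel = 0L, modality = "ecg") {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  h <- .parse_hea(hea)
  if (is.character(channel)) {
    ch <- match(channel, vapply(h$signals, `[[`, "", "desc"))
    if (is.na(ch)) stop("no channel named '", channel, "' in ", hea)
  } else {
    ch <- as.integer(channel) + 1L
    if (ch < 1L || ch > h$nsig)
      stop("channel index ", channel, " out of range (record has ",
           h$nsig, " channels)")
  }
  sig <- h$signals[[ch]]
  dat_path <- file.path(dirname(hea), sig$file)
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  adc <- .read_dat(dat_path, sig$fmt, h$nsig)[, ch]
  if (!is.na(h$nsamp) && h$nsamp > 0 && h$nsamp <= length(adc))
    adc <- adc[seq_len(h$nsamp)]
  rec <- signal_record((adc - sig$baseline) / sig$gain, fs = h$fs,
                       modality = modality, label = h$record)
  ann <- NULL
  for (ext in c(".atr", ".qrs")) {
    ap <- paste0(record, ext)
    if (file.exists(ap)) {
      a <- .read_atr(ap)
      beat <- a$codes %in% .wfdb_beat_codes
      idx <- a$times[beat]
      idx <- idx[idx < length(rec$samples)]
      ann <- beat_annotations(sort(unique(idx)), fs = h$fs)
      break
    }
  }
  list(record = rec, annotations = ann)
}

#' Write a minimal WFDB record (format 16)
#'
#' Intended for creating small test fixtures and for exporting synthetic
#' records; writes a `.hea` header and a 16-bit `.dat` file, plus an MIT
#' format `.atr` annotation file when `annotations` is given.
#'
#' @param record Record base name (path without extension).
#' @param channels A list of [signal_record]s sharing one sampling rate.
#' @param gain ADC gain (units per physical unit); samples are quantised to
#'   `round(x * gain)` 16-bit integers.
#' @param annotations Optional [beat_annotations]; written with symbol codes
#'   from `symbols` (default all normal beats).
#' @param symbols Optional character vector of annotation symbols (recycled),
#'   e.g. `c("N", "V", "+")`; non-beat symbols are written too, which lets
#'   tests verify that only beat symbols are read back.
#' @return Invisibly, `record`.
#' @export
write_wfdb_record <- function(record, channels, gain = 1000,
                              annotations = NULL, symbols = "N") {
  if (inherits(channels, "signal_record")) channels <- list(channels)
  fs <- channels[[1]]$fs
  nsamp <- length(channels[[1]]$samples)
  for (ch in channels)
    if (ch$fs != fs || length(ch$samples) != nsamp)
      stop("all channels must share fs and length")
  base <- basename(record)
  adc <- vapply(channels, function(ch) {
    q <- as.integer(round(ch$samples * gain))
    if (any(abs(q) > 32767L)) stop("samples overflow 16-bit range at gain ", gain)
    q
  }, integer(nsamp))
  hea <- c(sprintf("%s %d %s %d", base, length(channels), format(fs), nsamp),
           vapply(seq_along(channels), function(i)
             sprintf("%s.dat 16 %s(0)/mV 16 0 %d 0 0 %s",
                     base, format(gain), adc[1, i],
                     if (nzchar(channels[[i]]$label)) channels[[i]]$label
                     else paste0("ch", i - 1L)),
             ""))
  writeLines(hea, paste0(record, ".hea"))
  inter <- as.integer(t(adc))
  writeBin(inter, paste0(record, ".dat"), size = 2L, endian = "little")
  if (!is.null(annotations)) {
    codes <- .wfdb_symbol_code[rep_len(symbols, length(annotations$indices))]
    if (anyNA(codes)) stop("unknown annotation symbol(s)")
    con <- file(paste0(record, ".atr"), "wb")
    on.exit(close(con))
    # writeBin needs values in signed 16-bit range
    w16 <- function(v) writeBin(as.integer(ifelse(v > 32767, v - 65536, v)),
                                con, size = 2L, endian = "little")
    prev <- 0
    for (k in seq_along(codes)) {
      delta <- annotations$indices[k] - prev
      prev <- annotations$indices[k]
      if (delta > 1023) {
        w16(59L * 1024L)
        w16(c(delta %/% 65536, delta %% 65536))
        delta <- 0
      }
      w16(codes[k] * 1024L + delta)
    }
    w16(0L)
  }
  invisible(record)
}
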