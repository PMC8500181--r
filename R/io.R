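# Recording I/O: long/wide CSV, a minimal EDF (16-bit) codec, and JSON
# sidecars carrying sampling rate, markers and labels.

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

.writeSidecar <- function(rec, path, labels = NULL) {
  meta <- list(participant_id = rec@participantId, scene = rec@sceneId,
               segment_id = rec@segmentId, fs = rec@fs,
               channels = rec@channels, n_samples = nrow(rec@samples),
               watch_start = rec@watchStart, watch_end = rec@watchEnd,
               usable = rec@usable)
  if (!is.null(labels)) meta$labels <- as.list(labels)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE, digits = NA)
}

#' Write a recording to disk
#'
#' `dialect = "csv"` writes long format (`time_s`, `channel`, `value_uV`);
#' `dialect = "edf"` writes a minimal EDF file (16-bit samples, one
#' 1-second data record per block). Either way a JSON sidecar
#' (`<basename>.json`) stores the sampling rate, the 0-based viewing
#' markers, the usability flag and optional labels.
#'
#' @param rec An [EegRecording-class].
#' @param path Output path; the dialect defaults to the file extension.
#' @param dialect `"csv"` or `"edf"`.
#' @param labels Optional single-row `data.frame` or list of labels stored
#'   in the sidecar.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path,
                           dialect = c("auto", "csv", "edf"), labels = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (dialect == "csv") {
    n <- nrow(rec@samples)
    long <- data.frame(
      time_s = rep((seq_len(n) - 1) / rec@fs, times = ncol(rec@samples)),
      channel = rep(rec@channels, each = n),
      value_uV = as.vector(rec@samples))
    utils::write.csv(long, path, row.names = FALSE)
  } else {
    .writeEdf(rec, path)
  }
  .writeSidecar(rec, path, labels)
  invisible(path)
}

# ---- minimal EDF codec ------------------------------------------------------

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.writeEdf <- function(rec, path) {
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  x <- rec@samples
  n <- nrow(x)
  spr <- as.integer(round(fs))          # samples per 1-s data record
  ndr <- ceiling(n / spr)
  if (ndr * spr > n)                    # pad the tail record with zeros
    x <- rbind(x, matrix(0, ndr * spr - n, ncol(x)))
  ns <- ncol(x)
  physMax <- vapply(seq_len(ns), function(j) {
    m <- max(abs(x[, j])); if (m == 0) 1 else signif(m * 1.001, 5)
  }, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(.edfPad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(rec@participantId, 80)
  wr(paste("Startdate X", rec@segmentId), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(ndr, 8); wr("1", 8); wr(ns, 4)
  for (j in seq_len(ns)) wr(rec@channels[j], 16)
  for (j in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (j in seq_len(ns)) wr("uV", 8)
  for (j in seq_len(ns)) wr(format(-physMax[j], digits = 5), 8)
  for (j in seq_len(ns)) wr(format(physMax[j], digits = 5), 8)
  for (j in seq_len(ns)) wr("-32768", 8)
  for (j in seq_len(ns)) wr("32767", 8)
  for (j in seq_len(ns)) wr("", 80)
  for (j in seq_len(ns)) wr(spr, 8)
  for (j in seq_len(ns)) wr("", 32)
  scale <- 65535 / (2 * physMax)
  for (r in seq_len(ndr)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns)) {
      dig <- as.integer(round((x[rows, j] + physMax[j]) * scale[j] - 32768))
      writeBin(pmin(32767L, pmax(-32768L, dig)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

.readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  ndr <- as.integer(rd(8)); recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(j) rd(16), "")
  for (j in seq_len(ns)) rd(80)
  for (j in seq_len(ns)) rd(8)
  physMin <- as.numeric(vapply(seq_len(ns), function(j) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(j) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(j) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(j) rd(8), ""))
  for (j in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(j) rd(8), ""))
  for (j in seq_len(ns)) rd(32)
  out <- matrix(0, ndr * spr[1], ns)
  for (r in seq_len(ndr)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[j], size = 2, signed = TRUE,
                     endian = "little")
      rows <- ((r - 1) * spr[j] + 1):(r * spr[j])
      out[rows, j] <- physMin[j] + (dig - digMin[j]) *
        (physMax[j] - physMin[j]) / (digMax[j] - digMin[j])
    }
  }
  colnames(out) <- labels
  list(samples = out, fs = spr[1] / recDur, channels = labels)
}

# ---- reading ----------------------------------------------------------------

.resolveChannels <- function(have) {
  idx <- match(.CANONICAL_CHANNELS, toupper(trimws(have)))
  if (anyNA(idx))
    stop("schema error: missing channel(s): ",
         paste(.CANONICAL_CHANNELS[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Read a recording from disk
#'
#' Accepts the package's long CSV dialect (`time_s`, `channel`,
#' `value_uV`), a wide CSV (`time_s` plus one column per channel), or a
#' minimal EDF file. Channels are matched case-insensitively and reordered
#' to FP1, FPZ, FP2. Markers, sampling rate and labels come from the JSON
#' sidecar; a missing sidecar (or missing markers) is a marker error.
#'
#' @param path File path (`.csv` or `.edf`).
#' @param dialect `"auto"` (by extension), `"csv"` or `"edf"`.
#' @return An [EegRecording-class]; sidecar labels, when present, are in
#'   `attr(, "labels")`.
#' @export
readRecording <- function(path, dialect = c("auto", "csv", "edf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("marker error: sidecar not found: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$watch_start) || is.null(meta$watch_end))
    stop("marker error: watch_start/watch_end missing from sidecar", call. = FALSE)
  if (dialect == "edf") {
    raw <- .readEdf(path)
    fs <- meta$fs %||% raw$fs
    m <- raw$samples[, .resolveChannels(raw$channels), drop = FALSE]
  } else {
    df <- utils::read.csv(path, comment.char = "#")
    if (all(c("time_s", "channel", "value_uV") %in% names(df))) {
      chans <- unique(df$channel)
      m <- vapply(chans, function(ch) df$value_uV[df$channel == ch],
                  numeric(sum(df$channel == chans[1])))
      m <- m[, .resolveChannels(chans), drop = FALSE]
    } else {
      chCols <- setdiff(names(df), "time_s")
      m <- as.matrix(df[, chCols[.resolveChannels(chCols)], drop = FALSE])
    }
    fs <- meta$fs
    if (is.null(fs)) stop("sidecar must record fs for CSV recordings",
                          call. = FALSE)
  }
  if (!is.null(meta$n_samples) && nrow(m) > meta$n_samples)
    m <- m[seq_len(meta$n_samples), , drop = FALSE]
  colnames(m) <- .CANONICAL_CHANNELS
  rec <- new("EegRecording",
             participantId = meta$participant_id %||% "unknown",
             sceneId = meta$scene %||% "unknown",
             segmentId = meta$segment_id %||%
               tools::file_path_sans_ext(basename(path)),
             fs = fs, channels = .CANONICAL_CHANNELS, samples = m,
             watchStart = meta$watch_start, watchEnd = meta$watch_end,
             usable = meta$usable %||% TRUE)
  if (!is.null(meta$labels)) attr(rec, "labels") <- meta$labels
  rec
}
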