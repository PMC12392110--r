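#' Read and write LFP recordings
#'
#' Three on-disk formats are supported:
#' \describe{
#'   \item{`csv`}{greppable text: two header lines
#'     (`# sampling_rate_hz=<rate>` and `# key=value ...` metadata), then
#'     one sample per line.}
#'   \item{`edf`}{single-channel European Data Format (16-bit); samples
#'     are quantized to the signal's physical range, so round-trips are
#'     exact only to ~range/65,535. The recording id is stored in the
#'     patient field.}
#'   \item{`bin`}{compact binary container: little-endian doubles plus a
#'     JSON sidecar (`<path>.json`) holding rate and metadata.}
#' }
#'
#' @param path file path.
#' @param format one of `"csv"`, `"edf"`, `"bin"`; default guesses from
#'   the file extension.
#' @param recording an [LFPRecording-class].
#' @return `readRecording` returns an [LFPRecording-class];
#'   `writeRecording` returns `path` invisibly.
#' @export
readRecording <- function(path, format = c("auto", "csv", "edf", "bin")) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  switch(format,
         csv = readRecordingCsv(path),
         edf = readRecordingEdf(path),
         bin = readRecordingBin(path))
}

#' @rdname readRecording
#' @export
writeRecording <- function(recording, path,
                           format = c("auto", "csv", "edf", "bin")) {
  stopifnot(is(recording, "LFPRecording"))
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  switch(format,
         csv = writeRecordingCsv(recording, path),
         edf = writeRecordingEdf(recording, path),
         bin = writeRecordingBin(recording, path))
  invisible(path)
}

guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "edf", "bin")) return(ext)
  stop("cannot guess format from extension '", ext,
       "'; pass format explicitly", call. = FALSE)
}

metaToString <- function(meta) {
  paste(sprintf("%s=%s", names(meta), unlist(meta)), collapse = " ")
}

metaFromString <- function(s) {
  parts <- strsplit(trimws(s), "\\s+")[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) paste(x[-1], collapse = "="))
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

writeRecordingCsv <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%.10g", recording@samplingRate),
             con)
  writeLines(sprintf("# recording_id=%s %s", recording@recordingId,
                     metaToString(recording@meta)), con)
  writeLines(formatC(recording@samples, format = "g", digits = 17), con)
}

readRecordingCsv <- function(path) {
  header <- readLines(path, n = 2)
  if (length(header) < 2 || !grepl("^# sampling_rate_hz=", header[1])) {
    stop("malformed CSV recording: missing '# sampling_rate_hz=' header",
         call. = FALSE)
  }
  rate <- as.numeric(sub("^# sampling_rate_hz=", "", header[1]))
  if (!is.finite(rate) || rate <= 0) {
    stop("malformed CSV recording: sampling rate must be > 0",
         call. = FALSE)
  }
  if (!grepl("^# ", header[2])) {
    stop("malformed CSV recording: missing metadata header", call. = FALSE)
  }
  kv <- metaFromString(sub("^# ", "", header[2]))
  rid <- kv[["recording_id"]]
  kv[["recording_id"]] <- NULL
  x <- scan(path, what = numeric(), skip = 2, quiet = TRUE,
            comment.char = "#")
  LFPRecording(x, rate, if (is.null(rid)) "rec" else rid, kv)
}

writeRecordingBin <- function(recording, path) {
  con <- file(path, "wb")
  writeBin(recording@samples, con, size = 8, endian = "little")
  close(con)
  side <- list(sampling_rate_hz = recording@samplingRate,
               recording_id = recording@recordingId,
               meta = recording@meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

readRecordingBin <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar for binary recording: ", sidecar,
         call. = FALSE)
  }
  side <- jsonlite::fromJSON(sidecar)
  nbytes <- file.info(path)$size
  con <- file(path, "rb")
  x <- readBin(con, numeric(), n = nbytes / 8, size = 8,
               endian = "little")
  close(con)
  LFPRecording(x, side$sampling_rate_hz, side$recording_id, side$meta)
}

# --- minimal single-channel EDF ------------------------------------------

padField <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

writeRecordingEdf <- function(recording, path) {
  fs <- recording@samplingRate
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  x <- recording@samples
  nRecords <- length(x) %/% fs
  if (nRecords < 1) {
    stop("recording shorter than one 1-s EDF data record", call. = FALSE)
  }
  x <- x[seq_len(nRecords * fs)]
  physMax <- max(abs(x), 1e-12)
  physMin <- -physMax
  dig <- as.integer(round((x - physMin) / (physMax - physMin) * 65535 -
                            32768))
  dig <- pmin(pmax(dig, -32768L), 32767L)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField(recording@recordingId, 80),
    padField(metaToString(recording@meta), 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(as.character(256 + 256), 8),
    padField("", 44),
    padField(as.character(nRecords), 8),
    padField("1", 8),
    padField("1", 4),
    padField("LFP", 16),
    padField("", 80),
    padField("uV", 8),
    padField(formatC(physMin, format = "g", digits = 7), 8),
    padField(formatC(physMax, format = "g", digits = 7), 8),
    padField("-32768", 8), padField("32767", 8),
    padField("LP:30Hz", 80),
    padField(as.character(fs), 8),
    padField("", 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  writeBin(dig, con, size = 2, endian = "little")
}

readEdfField <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

readRecordingEdf <- function(path) {
  nbytes <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = nbytes)
  if (length(raw) < 512) stop("not an EDF file: too short", call. = FALSE)
  rid <- readEdfField(raw, 8, 80)
  metaStr <- readEdfField(raw, 88, 80)
  nRecords <- as.integer(readEdfField(raw, 236, 8))
  recDur <- as.numeric(readEdfField(raw, 244, 8))
  ns <- as.integer(readEdfField(raw, 252, 4))
  if (is.na(ns) || ns != 1L) {
    stop("only single-channel EDF is supported", call. = FALSE)
  }
  base <- 256
  physMin <- as.numeric(readEdfField(raw, base + 16 + 80 + 8, 8))
  physMax <- as.numeric(readEdfField(raw, base + 16 + 80 + 16, 8))
  digMin <- as.numeric(readEdfField(raw, base + 16 + 80 + 24, 8))
  digMax <- as.numeric(readEdfField(raw, base + 16 + 80 + 32, 8))
  spr <- as.integer(readEdfField(raw, base + 16 + 80 + 40 + 80, 8))
  dataRaw <- raw[(512 + 1):length(raw)]
  dig <- readBin(dataRaw, "integer", n = nRecords * spr, size = 2,
                 signed = TRUE, endian = "little")
  x <- physMin + (dig - digMin) / (digMax - digMin) * (physMax - physMin)
  fs <- spr / recDur
  LFPRecording(x, fs, rid, metaFromString(metaStr))
}

#' Duration in seconds recorded in an EDF file's header
#'
#' @param path path to an EDF file written by [writeRecording()].
#' @return number of data records times the record duration, in seconds.
#' @export
edfDurationS <- function(path) {
  nbytes <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = min(nbytes, 256))
  as.integer(readEdfField(raw, 236, 8)) *
    as.numeric(readEdfField(raw, 244, 8))
}

#' Read and write event interval files
#'
#' Plain-text interval files with one `onset_s<TAB>offset_s` pair per
#' line (half-open, in seconds). This is also the round-trip format for
#' manual review and correction of detected events.
#'
#' @param events an [EventList-class].
#' @param path file path.
#' @param samplingRate sampling rate (Hz) for the returned EventList.
#' @param totalWindowS analyzed window (s) for the returned EventList.
#' @return `readEvents` returns an [EventList-class]; `writeEvents`
#'   returns `path` invisibly.
#' @export
writeEvents <- function(events, path) {
  stopifnot(is(events, "EventList"))
  on <- eventOnsets(events) / events@samplingRate
  off <- eventOffsets(events) / events@samplingRate
  writeLines(sprintf("%.6f\t%.6f", on, off), path)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path, samplingRate, totalWindowS) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(eventList(integer(0), integer(0), samplingRate, totalWindowS))
  }
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  on <- as.numeric(parts[, 1]); off <- as.numeric(parts[, 2])
  eventList(round(on * samplingRate), round(off * samplingRate),
            samplingRate, totalWindowS)
}
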