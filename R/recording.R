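# Recording containers and file IO: the neutral fixture format
# (JSON header + float32 matrix), EDF, and BrainVision.

#' Construct an EEGRecording
#'
#' @param data numeric matrix, rows are channels (EEG plus auxiliaries),
#'   columns are samples, units microvolt.
#' @param labels character vector, one per row.
#' @param samplingRate Hz.
#' @param auxMap named integer vector mapping auxiliary roles (e.g.
#'   `veog`, `heog`, `emg1`) to row indices, or a character vector of
#'   labels to be resolved against `labels`.
#' @param band optional length-2 numeric filter provenance in Hz.
#' @return an [EEGRecording-class]
#' @export
eegRecording <- function(data, labels, samplingRate, auxMap = integer(0), band = numeric(0)) {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (is.character(auxMap)) {
    idx <- match(auxMap, labels)
    if (anyNA(idx)) stop("auxMap labels not present in recording labels")
    auxMap <- stats::setNames(as.integer(idx),
                              if (is.null(names(auxMap))) tolower(auxMap) else names(auxMap))
  }
  new("EEGRecording", data = data, labels = as.character(labels),
      samplingRate = samplingRate, auxMap = .namedInt(auxMap), band = as.numeric(band))
}

.namedInt <- function(x) {
  y <- as.integer(x)
  names(y) <- names(x)
  y
}

# ---------------------------------------------------------------------------
# neutral fixture format: `<path>` is a JSON header, `<path>.bin` a
# little-endian float32 matrix, column-major (one column per sample)

#' Write a recording in the neutral fixture format
#'
#' The fixture format is a JSON header (labels, sampling rate, auxiliary
#' map, band, shape) next to `<path>.bin` holding the data matrix as
#' little-endian float32, column-major (channels vary fastest).
#'
#' @param rec an [EEGRecording-class].
#' @param path header file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
writeRecordingFixture <- function(rec, path) {
  hdr <- list(format = "eegstream-recording", version = 1L,
              n_channels = nrow(rec@data), n_samples = ncol(rec@data),
              sampling_rate = rec@samplingRate, labels = rec@labels,
              aux_map = as.list(rec@auxMap), band = rec@band,
              binary = paste0(basename(path), ".bin"),
              dtype = "float32", order = "column-major")
  jsonlite::write_json(hdr, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec@data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a recording written in the neutral fixture format
#'
#' @param path header file path.
#' @return an [EEGRecording-class]
#' @export
readRecordingFixture <- function(path) {
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(hdr$format, "eegstream-recording"))
    stop("not a recording fixture: ", path)
  nC <- as.integer(hdr$n_channels); nS <- as.integer(hdr$n_samples)
  binPath <- file.path(dirname(path), hdr$binary)
  need <- 4 * nC * nS
  sz <- file.info(binPath)$size
  if (is.na(sz)) stop("missing binary payload: ", binPath)
  if (sz < need)
    stop(sprintf("truncated recording: %s ends at byte %d, expected %d", binPath, sz, need))
  con <- file(binPath, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = nC * nS, size = 4, endian = "little")
  aux <- unlist(hdr$aux_map)
  eegRecording(matrix(x, nC, nS), hdr$labels, hdr$sampling_rate,
               auxMap = if (length(aux)) stats::setNames(as.integer(aux), names(aux)) else integer(0),
               band = as.numeric(hdr$band))
}

# ---------------------------------------------------------------------------
# EDF

.padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Plain EDF with one-second data records and 16-bit samples. The
#' physical range per channel is set from the data (quantization step
#' `range / 65535`); a trailing partial record is zero-padded and its
#' true length recovered on read via the fixture of full records only.
#'
#' @param rec an [EEGRecording-class] with an integer sampling rate.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  fs <- rec@samplingRate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  X <- rec@data
  nC <- nrow(X); nS <- ncol(X)
  nRec <- as.integer(ceiling(nS / fs))
  if (nRec * fs > nS) X <- cbind(X, matrix(0, nC, nRec * fs - nS))
  pmin <- apply(X, 1, min); pmax <- apply(X, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    .padField("0", 8), .padField("X X X X", 80), .padField("Startdate X X X X", 80),
    .padField("01.01.00", 8), .padField("00.00.00", 8),
    .padField(as.character(256L * (1L + nC)), 8), .padField("", 44),
    .padField(as.character(nRec), 8), .padField("1", 8),
    .padField(as.character(nC), 4)), con, eos = NULL)
  fld <- function(vals, width) writeChar(paste(vapply(vals, .padField, "", width), collapse = ""),
                                         con, eos = NULL)
  fld(rec@labels, 16)
  fld(rep("", nC), 80)
  fld(rep("uV", nC), 8)
  fld(formatC(pmin, format = "g", digits = 6), 8)
  fld(formatC(pmax, format = "g", digits = 6), 8)
  fld(rep(as.character(dmin), nC), 8)
  fld(rep(as.character(dmax), nC), 8)
  fld(rep("", nC), 80)
  fld(rep(as.character(fs), nC), 8)
  fld(rep("", nC), 32)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nC)) {
      dig <- as.integer(round((X[ch, cols] - pmin[ch]) * scale[ch]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Supports plain EDF (and EDF+ continuous files without annotation use):
#' 16-bit records are rescaled to physical units per channel. All
#' channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param auxMap optional named character or integer vector marking
#'   auxiliary channels (see [eegRecording()]).
#' @return an [EEGRecording-class]
#' @export
readEDF <- function(path, auxMap = integer(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                     # version
  rd(80); rd(80); rd(8); rd(8)
  hdrBytes <- as.integer(rd(8))
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nC <- as.integer(rd(4))
  if (is.na(nC) || nC <= 0) stop("malformed EDF header: ", path)
  rdv <- function(w) vapply(seq_len(nC), function(i) trimws(readChar(con, w, useBytes = TRUE)), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1)
    stop("EDF with per-channel sampling rates is not supported")
  seek(con, hdrBytes)
  fs <- spr[1] / recDur
  X <- matrix(0, nC, nRec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nRec)) {
    for (ch in seq_len(nC)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2, endian = "little", signed = TRUE)
      if (length(dig) < spr[1])
        stop(sprintf("truncated EDF: record %d ends early at byte %d", r, seek(con)))
      X[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- pmin[ch] + (dig - dmin[ch]) * scale[ch]
    }
  }
  eegRecording(X, labels, fs, auxMap = auxMap)
}

# ---------------------------------------------------------------------------
# BrainVision (.vhdr / .vmrk / .eeg), binary multiplexed

.parseVhdrSection <- function(lines, section) {
  hdr <- grep(sprintf("^\\[%s\\]", section), lines, ignore.case = TRUE)
  if (!length(hdr)) return(character(0))
  rest <- lines[(hdr[1] + 1L):length(lines)]
  nxt <- grep("^\\[", rest)
  if (length(nxt)) rest <- rest[seq_len(nxt[1] - 1L)]
  rest[grepl("=", rest, fixed = TRUE) & !startsWith(trimws(rest), ";")]
}

#' Read a BrainVision recording (.vhdr + binary .eeg)
#'
#' Supports binary multiplexed data in IEEE_FLOAT_32 or INT_16 (with
#' per-channel resolution scaling), which covers the standard export of
#' BrainVision amplifiers.
#'
#' @param path path to the `.vhdr` header file.
#' @param auxMap optional auxiliary-channel map (see [eegRecording()]).
#' @return an [EEGRecording-class]
#' @export
readBrainVision <- function(path, auxMap = integer(0)) {
  lines <- readLines(path, warn = FALSE)
  kv <- function(section) {
    entries <- .parseVhdrSection(lines, section)
    if (!length(entries)) return(list())
    parts <- regmatches(entries, regexpr("=", entries), invert = TRUE)
    stats::setNames(lapply(parts, function(p) trimws(p[2])),
                    tolower(trimws(vapply(parts, `[`, "", 1))))
  }
  common <- kv("Common Infos")
  binary <- kv("Binary Infos")
  chans <- kv("Channel Infos")
  if (!identical(toupper(common$dataformat %||% "BINARY"), "BINARY"))
    stop("only BINARY BrainVision data are supported")
  if (!identical(toupper(common$dataorientation %||% "MULTIPLEXED"), "MULTIPLEXED"))
    stop("only MULTIPLEXED BrainVision data are supported")
  nC <- as.integer(common$numberofchannels)
  fs <- 1e6 / as.numeric(common$samplinginterval)
  fmt <- toupper(binary$binaryformat %||% "IEEE_FLOAT_32")
  chOrder <- order(as.integer(sub("^ch", "", names(chans))))
  chDefs <- strsplit(unlist(chans[chOrder]), ",", fixed = TRUE)
  labels <- vapply(chDefs, `[`, "", 1)
  res <- vapply(chDefs, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r) || r <= 0) 1 else r
  }, numeric(1))
  dataFile <- file.path(dirname(path), common$datafile)
  sz <- file.info(dataFile)$size
  if (is.na(sz)) stop("missing BrainVision data file: ", dataFile)
  bytes <- if (fmt == "IEEE_FLOAT_32") 4L else if (fmt == "INT_16") 2L else
    stop("unsupported BinaryFormat: ", fmt)
  nS <- as.integer(sz %/% (bytes * nC))
  con <- file(dataFile, "rb")
  on.exit(close(con))
  raw <- if (bytes == 4L)
    readBin(con, numeric(), n = nC * nS, size = 4, endian = "little")
  else
    readBin(con, integer(), n = nC * nS, size = 2, endian = "little", signed = TRUE)
  X <- matrix(raw, nC, nS) * res
  eegRecording(X, labels, fs, auxMap = auxMap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording, dispatching on file extension
#'
#' `.edf` files go to [readEDF()], `.vhdr` to [readBrainVision()], and
#' `.json` to [readRecordingFixture()].
#'
#' @param path recording path.
#' @param auxMap optional auxiliary-channel map.
#' @return an [EEGRecording-class]
#' @export
readRecording <- function(path, auxMap = integer(0)) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         edf = readEDF(path, auxMap),
         vhdr = readBrainVision(path, auxMap),
         json = readRecordingFixture(path),
         stop("unrecognized recording format: .", ext))
}
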