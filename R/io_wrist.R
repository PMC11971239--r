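#' Input dialect description
#'
#' A dialect captures everything about an external file layout that the
#' readers must not guess: source-column naming, timestamp format, and — for
#' the resampled WAV export of wrist recordings — the per-unit amplitude
#' scale and channel ordering. The WAV container itself carries no
#' engineering units, so `wav_scale` declares how many g one full-scale unit
#' of amplitude represents.
#'
#' @param format `"csv"` or `"wav"` (wrist stream only; behaviour tables are
#'   always CSV).
#' @param column_map Named character vector mapping canonical field names to
#'   source column names. For wrist CSV the canonical fields are `time`,
#'   `x`, `y`, `z`; for behaviour tables they are `epoch_start`, the eight
#'   activity classes (see [behaviour_classes()]) and `steps`.
#' @param time_format Timestamp format string (see [base::strptime()]);
#'   `NULL` uses the package default parser.
#' @param wav_scale Positive scalar: g per unit full-scale WAV amplitude.
#' @param wav_channel_order Integer permutation of 1:3 giving which WAV
#'   channel holds x, y and z respectively.
#' @return An object of class `limbwear_dialect`.
#' @export
dialect <- function(format = "csv",
                    column_map = NULL,
                    time_format = NULL,
                    wav_scale = 16,
                    wav_channel_order = 1:3) {
  format <- match.arg(format, c("csv", "wav"))
  if (!is.numeric(wav_scale) || length(wav_scale) != 1L || wav_scale <= 0) {
    stop("wav_scale must be a positive scalar", call. = FALSE)
  }
  if (!identical(sort(as.integer(wav_channel_order)), 1:3)) {
    stop("wav_channel_order must be a permutation of 1:3", call. = FALSE)
  }
  structure(
    list(format = format, column_map = column_map, time_format = time_format,
         wav_scale = wav_scale,
         wav_channel_order = as.integer(wav_channel_order)),
    class = "limbwear_dialect"
  )
}

default_wrist_map <- c(time = "time", x = "x", y = "y", z = "z")

resolve_map <- function(dl, required, default) {
  map <- dl$column_map
  if (is.null(map)) map <- default
  missing_fields <- setdiff(required, names(map))
  if (length(missing_fields)) {
    stop("dialect column_map does not cover mandatory field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  map
}

#' Construct a raw tri-axial recording
#'
#' The in-memory form of a wrist (or other body-site) accelerometer
#' recording: a fixed-rate, strictly ordered sample matrix in units of g.
#'
#' @param start_time Timestamp of the first sample (anything [clock_time()]
#'   accepts).
#' @param rate Sampling rate in Hz (> 0).
#' @param samples Numeric matrix with three columns (x, y, z) in g.
#' @param device_range Full-scale range in g; samples must satisfy
#'   `|value| <= device_range`.
#' @param participant_id Opaque participant label.
#' @param body_site One of `"prosthetic_wrist"`, `"socket_distal"`,
#'   `"thigh"`.
#' @return An object of class `raw_triaxial`.
#' @export
raw_triaxial <- function(start_time, rate, samples, device_range = 16,
                         participant_id = NA_character_,
                         body_site = "prosthetic_wrist") {
  body_site <- match.arg(body_site,
                         c("prosthetic_wrist", "socket_distal", "thigh"))
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("samples must have 3 columns", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar (Hz)", call. = FALSE)
  }
  if (any(abs(samples) > device_range + 1e-9, na.rm = TRUE)) {
    stop("sample component exceeds device_range of ", device_range, " g",
         call. = FALSE)
  }
  colnames(samples) <- c("x", "y", "z")
  structure(
    list(start_time = clock_time(start_time), rate = rate, samples = samples,
         device_range = device_range, participant_id = participant_id,
         body_site = body_site),
    class = "raw_triaxial"
  )
}

#' @export
print.raw_triaxial <- function(x, ...) {
  dur <- nrow(x$samples) / x$rate
  cat(sprintf(
    "<raw_triaxial> %s @ %s\n  %d samples @ %g Hz (%.1f s), range +/-%g g, participant %s\n",
    x$body_site, iso_stamp(x$start_time), nrow(x$samples), x$rate, dur,
    x$device_range, x$participant_id))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [raw_triaxial()] recording.
#' @return Duration in seconds (sample count / rate).
#' @export
recording_duration <- function(rec) {
  nrow(rec$samples) / rec$rate
}

#' Read a raw wrist recording
#'
#' Reads a raw tri-axial wrist recording from either a timestamped CSV
#' (columns mapped through the dialect) or the resampled 3-channel WAV
#' export dialect, returning a [raw_triaxial()] recording in g.
#'
#' CSV timestamps must be strictly increasing and equally spaced; the
#' sampling rate is taken from the median timestamp spacing. WAV carries no
#' wall-clock start, so `start_time` must be supplied for WAV input.
#'
#' @param path Path to the file.
#' @param dialect A [dialect()]; its `format` selects the parser.
#' @param start_time Start timestamp, required for WAV input (ignored for
#'   CSV, which carries timestamps).
#' @param device_range Full-scale range in g recorded by the device.
#' @param participant_id,body_site Metadata stored on the recording.
#' @return A [raw_triaxial()] recording.
#' @export
read_raw_wrist <- function(path, dialect = limbwear::dialect(),
                           start_time = NULL, device_range = 16,
                           participant_id = NA_character_,
                           body_site = "prosthetic_wrist") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect$format == "wav") {
    wav <- read_wav3(path)
    samples <- wav$data[, dialect$wav_channel_order, drop = FALSE] *
      dialect$wav_scale
    if (is.null(start_time)) {
      stop("start_time is required for WAV input (the container has no clock)",
           call. = FALSE)
    }
    return(raw_triaxial(start_time, wav$rate, samples,
                        device_range = device_range,
                        participant_id = participant_id,
                        body_site = body_site))
  }
  map <- resolve_map(dialect, c("time", "x", "y", "z"), default_wrist_map)
  df <- read.csv(path, check.names = FALSE)
  for (f in c("time", "x", "y", "z")) {
    if (!map[[f]] %in% names(df)) {
      stop("missing mandatory column '", map[[f]], "' (field ", f, ") in ",
           path, call. = FALSE)
    }
  }
  tt <- clock_time(df[[map[["time"]]]], format = dialect$time_format)
  if (nrow(df) < 2L) stop("recording has fewer than 2 samples", call. = FALSE)
  dt <- diff(as.numeric(tt))
  if (any(dt <= 0)) {
    stop("integrity error: timestamps not strictly increasing at row ",
         which(dt <= 0)[1L] + 1L, call. = FALSE)
  }
  rate <- 1 / stats::median(dt)
  # timestamps are printed at finite precision; snap a near-integer rate
  if (abs(rate - round(rate)) < 1e-3) rate <- round(rate)
  samples <- cbind(x = as.numeric(df[[map[["x"]]]]),
                   y = as.numeric(df[[map[["y"]]]]),
                   z = as.numeric(df[[map[["z"]]]]))
  raw_triaxial(tt[1L], rate, samples, device_range = device_range,
               participant_id = participant_id, body_site = body_site)
}

#' Write a raw wrist recording
#'
#' Inverse of [read_raw_wrist()]: emits either a timestamped CSV or a
#' 3-channel float WAV (amplitude = g / `wav_scale`).
#'
#' @inheritParams read_raw_wrist
#' @param rec A [raw_triaxial()] recording.
#' @return `path`, invisibly.
#' @export
write_raw_wrist <- function(rec, path, dialect = limbwear::dialect()) {
  if (dialect$format == "wav") {
    data <- rec$samples / dialect$wav_scale
    inv <- order(dialect$wav_channel_order)
    write_wav3(path, data[, inv, drop = FALSE], rec$rate)
    return(invisible(path))
  }
  map <- resolve_map(dialect, c("time", "x", "y", "z"), default_wrist_map)
  tt <- as.numeric(rec$start_time) + (seq_len(nrow(rec$samples)) - 1L) / rec$rate
  df <- data.frame(a = format(clock_time(tt), "%Y-%m-%d %H:%M:%OS3", tz = "UTC"),
                   b = rec$samples[, 1L], c = rec$samples[, 2L],
                   d = rec$samples[, 3L])
  names(df) <- unname(map[c("time", "x", "y", "z")])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- minimal RIFF/WAVE support (3 channels, PCM16 or IEEE float32) ---------
# None of the installed packages read WAV, and the exporter dialect is
# fixed: uncompressed RIFF with a single fmt and data chunk.

read_wav3 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("format error: not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("format error: not a WAVE file", call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1L, 2L, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1L, 2L, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("format error: missing fmt or data chunk", call. = FALSE)
  }
  if (fmt$n_channels != 3L) {
    stop("format error: expected 3 channels, found ", fmt$n_channels,
         call. = FALSE)
  }
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    v <- readBin(data_raw, "integer", length(data_raw) / 2L, size = 2L,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    v <- readBin(data_raw, "double", length(data_raw) / 4L, size = 4L,
                 endian = "little")
  } else {
    stop("format error: unsupported WAV encoding (format ", fmt$audio_format,
         ", ", fmt$bits, " bit)", call. = FALSE)
  }
  list(data = matrix(v, ncol = 3L, byrow = TRUE), rate = fmt$sample_rate)
}

write_wav3 <- function(path, data, rate) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == 3L)
  n <- nrow(data)
  payload <- as.numeric(t(data))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- n * 3L * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(3L, con, size = 2L, endian = "little")          # IEEE float
  writeBin(3L, con, size = 2L, endian = "little")          # channels
  writeBin(as.integer(round(rate)), con, size = 4L, endian = "little")
  writeBin(as.integer(round(rate) * 12L), con, size = 4L, endian = "little")
  writeBin(12L, con, size = 2L, endian = "little")         # block align
  writeBin(32L, con, size = 2L, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4L, endian = "little")
  writeBin(payload, con, size = 4L, endian = "little")
  invisible(path)
}
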