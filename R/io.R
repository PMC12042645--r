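#' Annotated call train
#'
#' Container for one bird's call annotations: onset/offset times (seconds
#' from recording start) and the call type of each call. Only the two contact
#' call categories used in the analysis are accepted (see [call_types()]).
#'
#' @param onset,offset Numeric vectors (s); onsets must be strictly
#'   increasing and each offset must exceed its onset.
#' @param call_type Character vector, `"stack"` or `"tet"`.
#' @param bird_id Single string identifying the bird.
#' @return A data frame of class `call_train` with columns `onset`, `offset`,
#'   `call_type` and attribute `bird_id`.
#' @export
call_train <- function(onset, offset, call_type, bird_id = "bird") {
  onset <- as.numeric(onset)
  offset <- as.numeric(offset)
  call_type <- as.character(call_type)
  n <- length(onset)
  if (length(offset) != n || length(call_type) != n) {
    stopf("onset, offset and call_type must have equal length")
  }
  if (n > 1 && any(diff(onset) <= 0)) stopf("call onsets must be strictly increasing")
  if (any(offset <= onset)) stopf("every call offset must exceed its onset")
  assert_call_types(call_type)
  structure(
    data.frame(onset = onset, offset = offset, call_type = call_type,
               stringsAsFactors = FALSE),
    bird_id = as.character(bird_id)[1],
    class = c("call_train", "data.frame")
  )
}

#' @export
print.call_train <- function(x, ...) {
  cat(sprintf("Call train for bird %s: %d calls (%s)\n",
              sQuote(attr(x, "bird_id")), nrow(x),
              paste(sprintf("%d %s", table(factor(x$call_type, call_types())),
                            call_types()), collapse = ", ")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Continuous waveform recording
#'
#' A mono extracellular trace as recorded to disk: integer samples in the
#' signed 16-bit range and a sampling rate (22,050 Hz in the original
#' recordings).
#'
#' @param samples Numeric/integer vector within `[-32768, 32767]`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_id Channel label.
#' @return An object of class `waveform_recording`.
#' @export
waveform_recording <- function(samples, sampling_rate = 22050, channel_id = "ch1") {
  samples <- as.numeric(samples)
  if (sampling_rate <= 0) stopf("sampling_rate must be positive")
  if (length(samples) && (max(samples) > 32767 || min(samples) < -32768)) {
    stopf("samples exceed the signed 16-bit range [-32768, 32767]")
  }
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         channel_id = as.character(channel_id)[1]),
    class = "waveform_recording"
  )
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf("Waveform recording %s: %d samples at %g Hz (%.2f s)\n",
              sQuote(x$channel_id), length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Detected spike records
#'
#' The on-disk unit of neural data: each detected event is a record holding a
#' timestamp (seconds, floating point) and a 64-sample waveform snippet of
#' integers. A set of records is stored as a timestamp vector plus an
#' `n x 64` integer waveform matrix.
#'
#' @param timestamps Numeric vector of event times (s), nonnegative.
#' @param waveforms Integer matrix with one 64-sample row per record.
#' @return An object of class `spike_records`.
#' @export
spike_records <- function(timestamps, waveforms) {
  timestamps <- as.numeric(timestamps)
  waveforms <- as.matrix(waveforms)
  storage.mode(waveforms) <- "integer"
  if (length(timestamps) != nrow(waveforms)) {
    stopf("need one 64-sample waveform row per timestamp")
  }
  if (length(timestamps) > 0 && ncol(waveforms) != 64L) {
    stopf("spike records carry exactly 64 samples per event (got %d)",
          ncol(waveforms))
  }
  if (any(timestamps < 0)) stopf("timestamps must be nonnegative")
  structure(list(timestamps = timestamps, waveforms = waveforms),
            class = "spike_records")
}

#' @export
print.spike_records <- function(x, ...) {
  cat(sprintf("Spike records: %d events", length(x$timestamps)))
  if (length(x$timestamps) > 0) {
    cat(sprintf(" spanning %.3f-%.3f s", min(x$timestamps), max(x$timestamps)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.spike_records <- function(x) length(x$timestamps)

# ---------------------------------------------------------------------------
# WAV (RIFF, 16-bit PCM mono)

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF reader for the recording format used throughout the pipeline
#' (16-bit PCM, mono). Other encodings or channel counts are rejected.
#'
#' @param path Path to a WAV file.
#' @return A [waveform_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stopf("not a WAV file (too short): %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  readBin(con, "integer", 1, size = 4, endian = "little") # chunk size
  wave <- rawToChar(readBin(con, "raw", 4))
  if (riff != "RIFF" || wave != "WAVE") stopf("not a RIFF/WAVE file: %s", path)
  sampling_rate <- NULL
  bits <- NULL
  channels <- NULL
  samples <- NULL
  repeat {
    tag <- readBin(con, "raw", 4)
    if (length(tag) < 4) break
    id <- rawToChar(tag)
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      audio_format <- fmt[1]
      channels <- fmt[2]
      sampling_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little") # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (audio_format != 1L) stopf("only PCM WAV is supported")
      if (len > 16) readBin(con, "raw", len - 16)
    } else if (id == "data") {
      if (is.null(bits)) stopf("malformed WAV: data chunk before fmt chunk")
      samples <- readBin(con, "integer", n = len / 2, size = 2, signed = TRUE,
                         endian = "little")
    } else {
      readBin(con, "raw", len + (len %% 2L))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stopf("malformed WAV: no data chunk in %s", path)
  if (bits != 16L) stopf("only 16-bit PCM is supported (file has %d bits)", bits)
  if (channels != 1L) stopf("only mono recordings are supported (file has %d channels)", channels)
  waveform_recording(samples, sampling_rate,
                     channel_id = sub("\\.wav$", "", basename(path)))
}

#' Write a 16-bit PCM mono WAV file
#'
#' @param rec A [waveform_recording()]; samples are rounded to integers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_recording"))
  samples <- as.integer(round(rec$samples))
  if (length(samples) && (max(samples) > 32767L || min(samples) < -32768L)) {
    stopf("samples exceed the signed 16-bit range; rescale before writing")
  }
  fs <- as.integer(round(rec$sampling_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(samples)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_len, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")     # PCM, mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")       # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Binary spike-record stream

SPIKE_RECORD_MAGIC <- "SPKREC01"
SPIKE_RECORD_BYTES <- 8L + 64L * 2L # float64 timestamp + 64 int16 samples

#' Write spike records to a binary stream
#'
#' One fixed-size record per detected event: a little-endian 64-bit float
#' timestamp followed by 64 little-endian signed 16-bit integers
#' (136 bytes/record), preceded by the 8-byte file tag `"SPKREC01"`.
#'
#' @param records A [spike_records()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_records <- function(records, path) {
  stopifnot(inherits(records, "spike_records"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(SPIKE_RECORD_MAGIC, con, eos = NULL)
  n <- length(records$timestamps)
  if (n > 0) {
    for (i in seq_len(n)) {
      writeBin(records$timestamps[i], con, size = 8, endian = "little")
      writeBin(as.integer(records$waveforms[i, ]), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read spike records from a binary stream
#'
#' @param path Path written by [write_spike_records()].
#' @return A [spike_records()] object, in file order.
#' @export
read_spike_records <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sz <- file.info(path)$size
  if (sz < 8) stopf("not a spike-record file (no %s tag): %s", SPIKE_RECORD_MAGIC, path)
  body <- sz - 8
  if (body %% SPIKE_RECORD_BYTES != 0) {
    stopf("truncated spike-record file: %d bytes after the header is not a multiple of %d (last whole record ends at byte offset %d)",
          body, SPIKE_RECORD_BYTES,
          8 + SPIKE_RECORD_BYTES * (body %/% SPIKE_RECORD_BYTES))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  tag <- rawToChar(readBin(con, "raw", 8))
  if (tag != SPIKE_RECORD_MAGIC) {
    stopf("not a spike-record file (tag %s != %s)", sQuote(tag),
          sQuote(SPIKE_RECORD_MAGIC))
  }
  n <- body %/% SPIKE_RECORD_BYTES
  ts <- numeric(n)
  wf <- matrix(0L, nrow = n, ncol = 64L)
  for (i in seq_len(n)) {
    ts[i] <- readBin(con, "double", 1, size = 8, endian = "little")
    wf[i, ] <- readBin(con, "integer", 64, size = 2, signed = TRUE,
                       endian = "little")
  }
  spike_records(ts, wf)
}

# ---------------------------------------------------------------------------
# Call annotation tables

#' Read a call annotation table
#'
#' Tab-separated UTF-8 with a header row and columns `bird_id`, `onset_s`,
#' `offset_s`, `call_type`. Rows are sorted by onset (with a warning if the
#' input was unsorted); unknown call types are rejected; overlapping calls of
#' one bird trigger a warning.
#'
#' @param path Path to a TSV file.
#' @return A [call_train()] (rows of the first bird if several are present;
#'   use [read_call_tables()] for multi-bird files).
#' @export
read_call_table <- function(path) {
  trains <- read_call_tables(path)
  if (length(trains) > 1) {
    warnf("call table %s contains %d birds; returning the first (%s)",
          path, length(trains), sQuote(names(trains)[1]))
  }
  if (length(trains) == 0) return(call_train(numeric(0), numeric(0), character(0)))
  trains[[1]]
}

#' Read a call annotation table with one train per bird
#'
#' @param path Path to a TSV file (format as [read_call_table()]).
#' @return Named list of [call_train()] objects, one per `bird_id`.
#' @export
read_call_tables <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = NA)
  need <- c("bird_id", "onset_s", "offset_s", "call_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stopf("call table %s lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  assert_call_types(df$call_type)
  out <- list()
  for (bird in unique(df$bird_id)) {
    sub <- df[df$bird_id == bird, , drop = FALSE]
    if (is.unsorted(sub$onset_s, strictly = FALSE)) {
      warnf("call table rows for bird %s were not sorted by onset; sorting",
            sQuote(bird))
      sub <- sub[order(sub$onset_s), , drop = FALSE]
    }
    if (nrow(sub) > 1 && any(sub$onset_s[-1] < sub$offset_s[-nrow(sub)])) {
      warnf("bird %s has overlapping calls in %s", sQuote(bird), path)
    }
    out[[as.character(bird)]] <-
      call_train(sub$onset_s, sub$offset_s, sub$call_type, bird_id = bird)
  }
  out
}

#' Write one or more call trains to a call annotation table
#'
#' @param train A [call_train()] or a list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(train, path) {
  if (inherits(train, "call_train")) train <- list(train)
  rows <- lapply(train, function(tr) {
    stopifnot(inherits(tr, "call_train"))
    data.frame(bird_id = attr(tr, "bird_id"), onset_s = tr$onset,
               offset_s = tr$offset, call_type = tr$call_type,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(bird_id = character(0), onset_s = numeric(0),
               offset_s = numeric(0), call_type = character(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
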