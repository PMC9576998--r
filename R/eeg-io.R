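# Raw multichannel recordings and their readers (EDF, delimited text).

#' Construct a raw multichannel recording
#'
#' @param signal C x T numeric matrix (channels in rows, microvolts).
#' @param channel_names Character vector of C unique channel names.
#' @param rate Sampling rate in samples/second.
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(signal, channel_names, rate) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 1L || ncol(signal) < 1L) {
    abort("Recording needs at least one channel and one sample.")
  }
  if (length(channel_names) != nrow(signal) || anyDuplicated(channel_names)) {
    abort("`channel_names` must be unique and match the number of rows.")
  }
  stopifnot_scalar_number(rate, "rate", lo = 1e-9)
  structure(list(signal = signal, channel_names = as.character(channel_names),
                 rate = as.numeric(rate)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$rate, ncol(x$signal) / x$rate))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a multichannel recording from delimited text
#'
#' One column per channel, one row per sample; the sampling rate is supplied
#' by the caller since delimited text carries no header metadata.
#'
#' @param path Path to a comma- or tab-delimited file with a header row of
#'   channel names.
#' @param rate Sampling rate in Hz.
#' @return A [raw_recording()].
#' @export
read_raw_delim <- function(path, rate) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  raw_recording(t(as.matrix(tab)), names(tab), rate)
}

#' Write a recording as delimited text
#'
#' @param raw A [raw_recording()].
#' @param path Output path (`.tsv` for tab, otherwise comma).
#' @return `path`, invisibly.
#' @export
write_raw_delim <- function(raw, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- tibble::as_tibble(t(raw$signal), .name_repair = "minimal")
  names(tab) <- raw$channel_names
  readr::write_delim(tab, path, delim = delim)
  invisible(path)
}

# EDF stores 16-bit integers per signal per data record, with per-signal
# physical/digital calibration in the 256-byte-per-signal header.
edf_pad <- function(x, width) {
  sprintf(paste0("%-", width, "s"), substr(as.character(x), 1L, width))
}

#' Write a recording to an EDF file
#'
#' Standard (continuous) EDF with all channels at the recording's rate and
#' 1-second data records. Values are linearly quantized to 16 bits over the
#' observed per-channel amplitude range. The duration is truncated to a whole
#' number of 1-second records.
#'
#' @param raw A [raw_recording()] whose `rate` is a whole number.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path) {
  rate <- raw$rate
  if (abs(rate - round(rate)) > 1e-9) abort("EDF writer needs an integer rate.")
  rate <- as.integer(round(rate))
  C <- nrow(raw$signal)
  n_rec <- ncol(raw$signal) %/% rate
  if (n_rec < 1L) abort("Recording shorter than one 1-second EDF record.")
  x <- raw$signal[, seq_len(n_rec * rate), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + C), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(C, 4)
  ), con, eos = NULL)
  fields <- list(
    edf_pad(raw$channel_names, 16), edf_pad("", 80), edf_pad("uV", 8),
    edf_pad(formatC(pmin_, digits = 6, format = "g"), 8),
    edf_pad(formatC(pmax_, digits = 6, format = "g"), 8),
    edf_pad(dmin, 8), edf_pad(dmax, 8), edf_pad("", 80),
    edf_pad(rate, 8), edf_pad("", 32)
  )
  for (f in fields) writeChar(paste(rep_len(f, C), collapse = ""), con, eos = NULL)
  scale_ <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * rate + 1L):(r * rate)
    for (ch in seq_len(C)) {
      dig <- round((x[ch, cols] - pmin_[ch]) * scale_[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a raw recording
#'
#' Supports standard continuous EDF with a common sampling rate across
#' signals; samples are mapped back to physical units with the header's
#' per-signal calibration.
#'
#' @param path Path to an EDF file.
#' @return A [raw_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  n_rec <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  C <- as.integer(fld(hdr, 253, 4))
  if (is.na(C) || C < 1L) abort("Malformed EDF header (signal count).")
  sig_hdr <- readChar(con, 256L * C, useBytes = TRUE)
  grab <- function(offset, width) {
    vapply(seq_len(C), function(i) {
      trimws(substr(sig_hdr, offset * C + (i - 1L) * width + 1L,
                    offset * C + i * width))
    }, character(1))
  }
  labels <- grab(0L, 16L)
  pmin_ <- as.numeric(grab(16L + 80L + 8L, 8L))
  pmax_ <- as.numeric(grab(16L + 80L + 8L + 8L, 8L))
  dmin <- as.numeric(grab(16L + 80L + 8L + 16L, 8L))
  dmax <- as.numeric(grab(16L + 80L + 8L + 24L, 8L))
  nsamp <- as.integer(grab(16L + 80L + 8L + 32L + 80L, 8L))
  if (length(unique(nsamp)) != 1L) {
    abort("EDF reader supports a single common sampling rate across signals.")
  }
  ns <- nsamp[1]
  rate <- ns / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- matrix(0, nrow = C, ncol = n_rec * ns)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = C * ns, size = 2, signed = TRUE,
                     endian = "little")
    cols <- ((r - 1L) * ns + 1L):(r * ns)
    for (ch in seq_len(C)) {
      dig <- block[((ch - 1L) * ns + 1L):(ch * ns)]
      sig[ch, cols] <- (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  raw_recording(sig, labels, rate)
}
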