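# Raw-EEG-to-feature pipeline: resample + band-pass, epoch, band-power (PSD)
# features per channel.

#' Standard EEG frequency bands
#'
#' Default band definitions: delta 0.1-4 Hz, theta 4-8 Hz, alpha 8-12 Hz,
#' beta 2-30 Hz. Note the beta band is deliberately kept as the wide 2-30 Hz
#' range used with this pipeline even though it overlaps theta and alpha;
#' supply your own table (e.g. beta 12-30) to change it.
#'
#' @return A tibble with columns `band`, `lo_hz`, `hi_hz`.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    lo_hz = c(0.1, 4, 8, 2),
    hi_hz = c(4, 8, 12, 30)
  )
}

check_bands <- function(bands, nyquist) {
  if (!all(c("band", "lo_hz", "hi_hz") %in% names(bands)) || nrow(bands) == 0L) {
    abort("`bands` must be a non-empty table with columns band, lo_hz, hi_hz.")
  }
  bad <- bands$lo_hz < 0 | bands$lo_hz >= bands$hi_hz | bands$hi_hz > nyquist
  if (any(bad)) {
    abort(sprintf("Band '%s' [%g, %g) is invalid for Nyquist %g Hz.",
                  bands$band[bad][1], bands$lo_hz[bad][1], bands$hi_hz[bad][1],
                  nyquist))
  }
  invisible(bands)
}

#' Resample and band-pass filter a recording
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' at the original rate, then an anti-alias zero-phase low-pass tied to the
#' target rate, and decimates by an integer factor. Zero-phase filtering
#' avoids the phase distortion that would smear band-power estimates across
#' epochs.
#'
#' @param raw A [raw_recording()].
#' @param target_rate Output sampling rate in Hz (default 250); must divide
#'   the input rate.
#' @param band Length-2 numeric band-pass edges in Hz (default `c(0.5, 45)`);
#'   both edges must lie below the target Nyquist.
#' @return A [raw_recording()] at `target_rate`.
#' @export
preprocess <- function(raw, target_rate = 250, band = c(0.5, 45)) {
  stopifnot(inherits(raw, "raw_recording"))
  stopifnot_scalar_number(target_rate, "target_rate", lo = 1e-9, hi = raw$rate)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    abort("`band` must be increasing positive edges c(lo, hi).")
  }
  nyq_out <- target_rate / 2
  if (band[2] >= nyq_out) {
    abort(sprintf("Band edge %g Hz is at or above the target Nyquist %g Hz.",
                  band[2], nyq_out))
  }
  factor_ <- raw$rate / target_rate
  if (abs(factor_ - round(factor_)) > 1e-9) {
    abort(sprintf("Target rate %g Hz must divide the input rate %g Hz.",
                  target_rate, raw$rate))
  }
  factor_ <- as.integer(round(factor_))
  nyq_in <- raw$rate / 2
  bp <- signal::butter(4, band / nyq_in, type = "pass")
  x <- t(apply(raw$signal, 1, function(ch) signal::filtfilt(bp, ch)))
  if (factor_ > 1L) {
    aa <- signal::butter(6, 0.8 * nyq_out / nyq_in, type = "low")
    x <- t(apply(x, 1, function(ch) signal::filtfilt(aa, ch)))
    x <- x[, seq(1L, ncol(x), by = factor_), drop = FALSE]
  }
  raw_recording(x, raw$channel_names, target_rate)
}

#' Cut a recording into fixed-length overlapping epochs
#'
#' Sliding windows of `epoch_length_s` seconds advancing by
#' `epoch_length_s - overlap_s`; the trailing partial window is discarded.
#' The number of epochs is
#' `floor((T/rate - epoch_length_s) / hop_s) + 1`.
#'
#' @param raw A [raw_recording()].
#' @param epoch_length_s Window length in seconds (default 4).
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (default 3).
#' @return An `epoched_recording`: list with `epochs` (E x C x L array),
#'   `channel_names`, `epoch_length_s`, `hop_s`, `rate`.
#' @export
epoch_recording <- function(raw, epoch_length_s = 4, overlap_s = 3) {
  stopifnot(inherits(raw, "raw_recording"))
  stopifnot_scalar_number(epoch_length_s, "epoch_length_s", lo = 1e-9)
  stopifnot_scalar_number(overlap_s, "overlap_s", lo = 0)
  if (overlap_s >= epoch_length_s) {
    abort("`overlap_s` must be smaller than `epoch_length_s`.")
  }
  hop_s <- epoch_length_s - overlap_s
  L <- epoch_length_s * raw$rate
  hop <- hop_s * raw$rate
  if (abs(L - round(L)) > 1e-9 || abs(hop - round(hop)) > 1e-9) {
    abort("Epoch length and hop must be whole numbers of samples.")
  }
  L <- as.integer(round(L)); hop <- as.integer(round(hop))
  T_ <- ncol(raw$signal)
  if (T_ < L) {
    abort(sprintf("Recording (%.3f s) is shorter than one epoch (%g s).",
                  T_ / raw$rate, epoch_length_s))
  }
  E <- floor((T_ / raw$rate - epoch_length_s) / hop_s) + 1
  E <- as.integer(round(E))
  C <- nrow(raw$signal)
  epochs <- array(0, dim = c(E, C, L))
  for (e in seq_len(E)) {
    from <- (e - 1L) * hop + 1L
    epochs[e, , ] <- raw$signal[, from:(from + L - 1L), drop = FALSE]
  }
  structure(list(epochs = epochs, channel_names = raw$channel_names,
                 epoch_length_s = epoch_length_s, hop_s = hop_s,
                 rate = raw$rate),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoched_recording> %d epoch(s) x %d channel(s) x %d samples (%g s, hop %g s) @ %g Hz\n",
              d[1], d[2], d[3], x$epoch_length_s, x$hop_s, x$rate))
  invisible(x)
}

# One-sided Hann-windowed periodogram of a single epoch. Normalized so that
# the trapezoidal integral over [0, Nyquist] approximates the signal's mean
# square value (Parseval).
periodogram_psd <- function(x, rate) {
  L <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  X <- fft(x * w)
  n_keep <- floor(L / 2) + 1L
  p <- (Mod(X[seq_len(n_keep)])^2) / (rate * sum(w^2))
  scale2 <- rep(2, n_keep)
  scale2[1] <- 1
  if (L %% 2 == 0) scale2[n_keep] <- 1
  list(freq = (seq_len(n_keep) - 1) * rate / L, psd = p * scale2)
}

#' Band-power features from an epoched recording
#'
#' For each epoch and channel, integrates the Hann-windowed periodogram over
#' each frequency band (trapezoidal rule over the periodogram's frequency
#' grid). Feature columns are ordered channel-major
#' (`<channel>_<band>` for each channel, then each band) so the layout is
#' deterministic.
#'
#' @param epoched An [epoch_recording()] result.
#' @param bands A band table as returned by [eeg_bands()].
#' @param log10_power If `TRUE`, return `log10` powers (a floor of 1e-15 is
#'   applied first). Default `FALSE` (linear power).
#' @return A tibble with one row per epoch and `C * nrow(bands)` feature
#'   columns, in microvolts squared (density integrated over Hz).
#' @export
band_power <- function(epoched, bands = eeg_bands(), log10_power = FALSE) {
  stopifnot(inherits(epoched, "epoched_recording"))
  check_bands(bands, epoched$rate / 2)
  d <- dim(epoched$epochs)
  E <- d[1]; C <- d[2]; L <- d[3]
  out <- matrix(0, nrow = E, ncol = C * nrow(bands))
  cn <- as.vector(t(outer(epoched$channel_names, bands$band, paste, sep = "_")))
  for (e in seq_len(E)) {
    for (ch in seq_len(C)) {
      pg <- periodogram_psd(epoched$epochs[e, ch, ], epoched$rate)
      for (b in seq_len(nrow(bands))) {
        sel <- pg$freq >= bands$lo_hz[b] & pg$freq <= bands$hi_hz[b]
        pow <- if (sum(sel) >= 2L) {
          pracma::trapz(pg$freq[sel], pg$psd[sel])
        } else if (sum(sel) == 1L) {
          pg$psd[sel] * (bands$hi_hz[b] - bands$lo_hz[b])
        } else 0
        out[e, (ch - 1L) * nrow(bands) + b] <- pow
      }
    }
  }
  if (log10_power) out <- log10(pmax(out, 1e-15))
  colnames(out) <- cn
  tibble::as_tibble(out)
}

#' Full recording-to-features pipeline
#'
#' [preprocess()] then [epoch_recording()] then [band_power()], returning a
#' feature-table fragment tagged with the given metadata.
#'
#' @param raw A [raw_recording()].
#' @param subject,session,phase Metadata for the emitted rows.
#' @param target_rate,band Passed to [preprocess()].
#' @param epoch_length_s,overlap_s Passed to [epoch_recording()].
#' @param bands Passed to [band_power()].
#' @param label Optional label for the rows (`NA` for baselines).
#' @return A feature table fragment (tibble) with metadata + feature columns.
#' @export
extract_features <- function(raw, subject, session, phase = "task",
                             label = NA_character_,
                             target_rate = 250, band = c(0.5, 45),
                             epoch_length_s = 4, overlap_s = 3,
                             bands = eeg_bands()) {
  feats <- band_power(
    epoch_recording(preprocess(raw, target_rate, band),
                    epoch_length_s, overlap_s),
    bands
  )
  dplyr::bind_cols(
    tibble::tibble(subject = as.character(subject),
                   session = as.character(session),
                   phase = phase, label = as.character(label),
                   .rows = nrow(feats)),
    feats
  )
}
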