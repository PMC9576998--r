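test_that("preprocess halves the rate and attenuates out-of-band tones", {
  set.seed(11)
  raw <- raw_recording(matrix(rnorm(500 * 20), nrow = 1), "C1", 500)
  out <- preprocess(raw, 250, c(0.5, 45))
  expect_equal(out$rate, 250)
  expect_lte(abs(ncol(out$signal) - ncol(raw$signal) / 2), 1)

  # a 60 Hz tone sits one octave-ish above the 45 Hz edge: RMS must drop
  # below 10% of the input RMS after the zero-phase band-pass
  t_ <- seq_len(500 * 20) / 500
  tone <- raw_recording(matrix(sin(2 * pi * 60 * t_), nrow = 1), "C1", 500)
  filtered <- preprocess(tone, 250, c(0.5, 45))
  expect_lt(sqrt(mean(filtered$signal^2)) / sqrt(0.5), 0.1)

  z <- preprocess(raw_recording(matrix(0, 1, 5000), "C1", 500))
  expect_equal(max(abs(z$signal)), 0)

  expect_error(preprocess(raw, 250, c(0.5, 130)), "Nyquist")
  expect_error(preprocess(raw, 600), "target_rate")
})

test_that("epoch counts follow the sliding-window formula exactly", {
  rec <- function(dur_s, rate) {
    raw_recording(matrix(0, 1, round(dur_s * rate)), "C1", rate)
  }
  expect_equal(dim(epoch_recording(rec(600, 250), 4, 3)$epochs)[1], 597)
  expect_equal(dim(epoch_recording(rec(4, 250), 4, 3)$epochs)[1], 1)
  expect_error(epoch_recording(rec(3.9, 250), 4, 3), "shorter")
  expect_error(epoch_recording(rec(10, 250), 4, 4), "overlap")

  # property: formula count == naive sliding-window count over a grid
  set.seed(21)
  for (i in 1:50) {
    rate <- sample(c(100, 128, 200, 250, 256, 500), 1)
    len <- sample(c(1, 2, 4), 1)
    hop <- sample(c(0.5, 1, 2), 1)
    if (hop >= len) next
    dur <- len + runif(1, 0, 20)
    n <- round(dur * rate)
    if ((hop * rate) %% 1 != 0) next
    ep <- epoch_recording(raw_recording(matrix(0, 1, n), "C1", rate),
                          len, len - hop)
    count <- 0; start <- 1
    while (start + len * rate - 1 <= n) {
      count <- count + 1
      start <- start + hop * rate
    }
    expect_equal(dim(ep$epochs)[1], count)
  }
})

test_that("band_power concentrates a pure tone in its own band", {
  t_ <- seq_len(250 * 8) / 250
  tone <- raw_recording(matrix(sin(2 * pi * 10 * t_), nrow = 1), "C1", 250)
  f <- band_power(epoch_recording(tone),
                  bands = tibble::tibble(band = c("delta", "theta", "alpha"),
                                         lo_hz = c(0.1, 4, 8),
                                         hi_hz = c(4, 8, 12)))
  expect_gt(f$C1_alpha[1], 10 * f$C1_theta[1])
  expect_gt(f$C1_alpha[1], 10 * f$C1_delta[1])

  z <- band_power(epoch_recording(
    raw_recording(matrix(0, 1, 2000), "C1", 250)))
  expect_true(all(as.matrix(z) == 0))
  expect_error(band_power(epoch_recording(tone), bands = eeg_bands()[0, ]),
               "non-empty")
})

test_that("white-noise band power is proportional to band width", {
  set.seed(31)
  raw <- raw_recording(matrix(rnorm(250 * 104), nrow = 1), "C1", 250)
  bands <- tibble::tibble(band = c("narrow", "wide"),
                          lo_hz = c(20, 40), hi_hz = c(30, 80))
  f <- band_power(epoch_recording(raw), bands)  # ~100 epochs averaged
  ratio <- mean(f$C1_wide) / mean(f$C1_narrow)
  expect_equal(ratio, 4, tolerance = 0.3)
})

test_that("band powers over a partition of [0, Nyquist] sum to the total", {
  set.seed(41)
  raw <- raw_recording(matrix(rnorm(250 * 12), nrow = 1), "C1", 250)
  ep <- epoch_recording(raw)
  cuts <- c(0, 10, 30, 60, 125)
  parts <- tibble::tibble(band = paste0("b", 1:4),
                          lo_hz = cuts[-5], hi_hz = cuts[-1])
  total <- tibble::tibble(band = "all", lo_hz = 0, hi_hz = 125)
  f_parts <- rowSums(as.matrix(band_power(ep, parts)))
  f_total <- band_power(ep, total)$C1_all
  expect_equal(f_parts, f_total, tolerance = 0.01)
})

test_that("band_power commutes with epoch permutation", {
  set.seed(51)
  raw <- raw_recording(matrix(rnorm(250 * 10 * 2), nrow = 2),
                       c("C1", "C2"), 250)
  ep <- epoch_recording(raw)
  f <- band_power(ep)
  perm <- rev(seq_len(dim(ep$epochs)[1]))
  ep$epochs <- ep$epochs[perm, , , drop = FALSE]
  expect_equal(as.matrix(band_power(ep)), as.matrix(f)[perm, ])
})

test_that("EDF and delimited-text recordings round-trip", {
  set.seed(61)
  rec <- raw_recording(matrix(rnorm(2 * 250 * 4), nrow = 2) * 40,
                       c("AF7", "FP1"), 250)
  edf <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, edf)
  back <- read_edf(edf)
  expect_equal(back$rate, 250)
  expect_equal(back$channel_names, c("AF7", "FP1"))
  expect_lt(max(abs(back$signal - rec$signal)), 0.01)  # 16-bit quantization

  txt <- withr::local_tempfile(fileext = ".csv")
  write_raw_delim(rec, txt)
  back2 <- read_raw_delim(txt, 250)
  expect_equal(back2$signal, rec$signal, ignore_attr = TRUE,
               tolerance = 1e-10)
})
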