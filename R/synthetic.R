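# Synthetic multi-domain data with independently controllable marginal and
# conditional shifts, plus synthetic multichannel EEG, so every estimator and
# the full pipeline can be exercised without any external recording.
#
# Geometry of the feature generator: domain m draws latent points
# z ~ N(0, scale_m^2 I_F); its labeling rule is the halfspace through the
# origin whose normal u(theta_m) lies in the first two coordinates, rotated
# by theta_m degrees. The geometric class is assigned before the domain's
# mean offset is added, so mean offsets (marginal shift) never touch labels,
# and at class_separation = 0 a balanced two-sided draw has exactly the
# N(0, scale^2 I) marginal for every rotation angle — rotations (conditional
# shift) never touch the marginal. The two shift controls are therefore
# exactly orthogonal at class_separation = 0.

#' Specification for a synthetic multi-domain feature dataset
#'
#' Defaults mirror a two-session wearable-EEG workload study: 9 subjects,
#' two sessions (one per workload level) of 600 epochs each, and 16 features
#' (4 channels x 4 bands).
#'
#' @param M Number of domains (subjects). Default 9.
#' @param n_per_cell Task rows per subject-session cell. Default 600.
#' @param F_dim Feature dimension (>= 2). Default 16.
#' @param class_prior Fraction of each domain's task rows in the
#'   high-workload session. Default 0.5.
#' @param marginal_offsets Per-domain mean-shift: either a single magnitude
#'   (per-domain directions drawn from the seed, recycled to M), a length-M
#'   vector of magnitudes, or an M x F matrix of explicit offset vectors.
#'   Default 1.
#' @param covariance_scale Per-domain standard-deviation scale (recycled to
#'   M). Default 1.
#' @param boundary_angles Per-domain rotation of the labeling rule, degrees
#'   (recycled to M). Default `seq(0, 40, length.out = M)`.
#' @param label_flip_rate Per-domain i.i.d. label-flip probability in
#'   `[0, 0.5]` (recycled to M). Default 0.05.
#' @param class_separation Margin added along the rule normal after
#'   labeling (each point moves `class_separation / 2` away from the
#'   boundary). Default 1.
#' @param n_baseline Rows per baseline phase per subject. Default 120.
#' @param seed RNG seed. Default 10.
#' @return A `multidomain_spec` object.
#' @export
multidomain_spec <- function(M = 9L, n_per_cell = 600L, F_dim = 16L,
                             class_prior = 0.5, marginal_offsets = 1,
                             covariance_scale = 1, boundary_angles = NULL,
                             label_flip_rate = 0.05, class_separation = 1,
                             n_baseline = 120L, seed = 10L) {
  stopifnot_scalar_number(M, "M", lo = 2)
  stopifnot_scalar_number(n_per_cell, "n_per_cell", lo = 1)
  stopifnot_scalar_number(F_dim, "F_dim", lo = 2)
  stopifnot_scalar_number(class_prior, "class_prior", lo = 1e-6, hi = 1 - 1e-6)
  stopifnot_scalar_number(class_separation, "class_separation", lo = 0)
  stopifnot_scalar_number(n_baseline, "n_baseline", lo = 2)
  M <- as.integer(M)
  if (is.null(boundary_angles)) boundary_angles <- seq(0, 40, length.out = M)
  boundary_angles <- rep_len(boundary_angles, M)
  label_flip_rate <- rep_len(label_flip_rate, M)
  if (any(label_flip_rate < 0 | label_flip_rate > 0.5)) {
    abort("`label_flip_rate` values must lie in [0, 0.5].")
  }
  covariance_scale <- rep_len(covariance_scale, M)
  if (any(covariance_scale <= 0)) abort("`covariance_scale` must be positive.")
  if (is.matrix(marginal_offsets)) {
    if (nrow(marginal_offsets) != M || ncol(marginal_offsets) != F_dim) {
      abort(sprintf("`marginal_offsets` matrix must be %d x %d.", M, F_dim))
    }
    offsets <- marginal_offsets
  } else {
    mags <- rep_len(marginal_offsets, M)
    if (any(mags < 0)) abort("Offset magnitudes must be >= 0.")
    offsets <- with_seed(derive_seed(seed, 41L), {
      t(vapply(seq_len(M), function(m) {
        if (mags[m] == 0) return(numeric(F_dim))
        v <- rnorm(F_dim)
        mags[m] * v / sqrt(sum(v^2))
      }, numeric(F_dim)))
    })
  }
  structure(list(M = M, n_per_cell = as.integer(n_per_cell),
                 F_dim = as.integer(F_dim), class_prior = class_prior,
                 offsets = offsets, covariance_scale = covariance_scale,
                 boundary_angles = boundary_angles,
                 label_flip_rate = label_flip_rate,
                 class_separation = class_separation,
                 n_baseline = as.integer(n_baseline),
                 seed = as.integer(seed)),
            class = "multidomain_spec")
}

rule_normal <- function(angle_deg, F_dim) {
  c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180),
    numeric(F_dim - 2L))
}

# Draw `n` latent points of domain m whose geometric class is `side`
# (rejection from the isotropic Gaussian; acceptance probability 1/2).
draw_side <- function(n, side, u, scale_) {
  F_dim <- length(u)
  out <- matrix(numeric(0), ncol = F_dim)
  while (nrow(out) < n) {
    cand <- matrix(rnorm(max(64L, 3L * (n - nrow(out))) * F_dim,
                         sd = scale_), ncol = F_dim)
    keep <- (as.vector(cand %*% u) > 0) == (side == 1L)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic multi-domain feature table
#'
#' Each domain's task rows are drawn per session (session = geometric class,
#' i.e. the workload condition), labeled by the domain's rotated halfspace
#' rule and then flipped i.i.d. at the domain's flip rate; the class margin,
#' mean offset and covariance scale are applied afterwards. Baseline-1 rows
#' come from a rest distribution shared by all subjects (standard normal);
#' baseline-2 rows come from the domain's own offset/scaled distribution
#' without class structure. Byte-identical output for identical specs.
#'
#' @param spec A [multidomain_spec()].
#' @return A feature table with subjects `S0 ... S<M-1>`, sessions
#'   `session1`/`session2`, phases `task`/`baseline1`/`baseline2` and
#'   feature columns `f01 ... f<F>`.
#' @export
generate_multidomain <- function(spec) {
  stopifnot(inherits(spec, "multidomain_spec"))
  feats <- sprintf("f%02d", seq_len(spec$F_dim))
  n_high <- round(2 * spec$n_per_cell * spec$class_prior)
  n_low <- 2L * spec$n_per_cell - n_high
  rows <- with_seed(spec$seed, {
    purrr::map_dfr(seq_len(spec$M), function(m) {
      u <- rule_normal(spec$boundary_angles[m], spec$F_dim)
      p <- spec$label_flip_rate[m]
      per_side <- purrr::map_dfr(c(0L, 1L), function(side) {
        n <- if (side == 1L) n_high else n_low
        z <- draw_side(n, side, u, spec$covariance_scale[m])
        x <- z + (side - 0.5) * spec$class_separation * rep(u, each = n)
        x <- sweep(x, 2, spec$offsets[m, ], "+")
        flip <- runif(n) < p
        lab <- ifelse(flip, 1L - side, side)
        colnames(x) <- feats
        dplyr::bind_cols(
          tibble::tibble(subject = sprintf("S%d", m - 1L),
                         session = sprintf("session%d", side + 1L),
                         phase = "task", label = int_to_label(lab)),
          tibble::as_tibble(x))
      })
      nb <- spec$n_baseline
      bl <- function(phase, x) {
        colnames(x) <- feats
        dplyr::bind_cols(
          tibble::tibble(subject = sprintf("S%d", m - 1L),
                         session = rep(c("session1", "session2"),
                                       length.out = nb),
                         phase = phase, label = NA_character_),
          tibble::as_tibble(x))
      }
      b1 <- bl("baseline1", matrix(rnorm(nb * spec$F_dim), ncol = spec$F_dim))
      b2 <- bl("baseline2",
               sweep(matrix(rnorm(nb * spec$F_dim,
                                  sd = spec$covariance_scale[m]),
                            ncol = spec$F_dim),
                     2, spec$offsets[m, ], "+"))
      dplyr::bind_rows(per_side, b1, b2)
    })
  })
  validate_feature_table(rows)
}

#' Specification for synthetic multichannel EEG recordings
#'
#' Each channel is a sum of band-limited oscillations (delta 2 Hz, theta
#' 6 Hz, alpha 10 Hz, beta 20 Hz carriers with seeded random phases) plus
#' white noise. The workload effect multiplies the alpha and theta carrier
#' amplitudes in the high-workload session.
#'
#' @param subjects Number of subjects. Default 2.
#' @param duration_s Task recording length per session, seconds. Default 60.
#' @param rate Sampling rate, Hz. Default 250.
#' @param channels Channel names. Default frontal 4-channel montage
#'   `AF7, FP1, FP2, AF8`.
#' @param amplitude_scale Per-subject overall amplitude scale (recycled).
#'   Default 1.
#' @param workload_multiplier Alpha/theta amplitude multiplier in the high
#'   session. Default 1.5.
#' @param noise_sd White-noise standard deviation (microvolts). Default 1.
#' @param baseline1_s,baseline2_s Baseline recording lengths, seconds.
#'   Default 30 each.
#' @param seed RNG seed. Default 10.
#' @return A `synthetic_eeg_spec` object.
#' @export
synthetic_eeg_spec <- function(subjects = 2L, duration_s = 60, rate = 250,
                               channels = c("AF7", "FP1", "FP2", "AF8"),
                               amplitude_scale = 1, workload_multiplier = 1.5,
                               noise_sd = 1, baseline1_s = 30,
                               baseline2_s = 30, seed = 10L) {
  stopifnot_scalar_number(subjects, "subjects", lo = 1)
  stopifnot_scalar_number(duration_s, "duration_s", lo = 4)
  stopifnot_scalar_number(rate, "rate", lo = 50)
  stopifnot_scalar_number(workload_multiplier, "workload_multiplier", lo = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lo = 0)
  structure(list(subjects = as.integer(subjects), duration_s = duration_s,
                 rate = rate, channels = channels,
                 amplitude_scale = rep_len(amplitude_scale,
                                           as.integer(subjects)),
                 workload_multiplier = workload_multiplier,
                 noise_sd = noise_sd, baseline1_s = baseline1_s,
                 baseline2_s = baseline2_s, seed = as.integer(seed)),
            class = "synthetic_eeg_spec")
}

synth_carriers <- tibble::tibble(
  band = c("delta", "theta", "alpha", "beta"),
  freq_hz = c(2, 6, 10, 20),
  amplitude = c(4, 3, 2, 1)
)

synth_record <- function(spec, subj_idx, duration_s, workload = FALSE,
                         rest = FALSE) {
  n <- round(duration_s * spec$rate)
  t_ <- seq_len(n) / spec$rate
  sig <- t(vapply(seq_along(spec$channels), function(ch) {
    x <- rnorm(n, sd = spec$noise_sd)
    for (b in seq_len(nrow(synth_carriers))) {
      a <- synth_carriers$amplitude[b] *
        (if (rest) 1 else spec$amplitude_scale[subj_idx])
      if (workload && synth_carriers$band[b] %in% c("alpha", "theta")) {
        a <- a * spec$workload_multiplier
      }
      x <- x + a * sin(2 * pi * synth_carriers$freq_hz[b] * t_ + runif(1, 0, 2 * pi))
    }
    x
  }, numeric(n)))
  raw_recording(sig, spec$channels, spec$rate)
}

#' Generate annotated synthetic EEG recordings
#'
#' One task recording per subject x session (session 2 carries the workload
#' effect), plus one baseline-1 (rest, shared amplitude profile) and one
#' baseline-2 (subject-specific amplitudes, no workload effect) recording
#' per subject. Byte-identical output for identical specs.
#'
#' @param spec A [synthetic_eeg_spec()].
#' @return A tibble with columns `subject`, `session`, `phase`, `label` and
#'   a list-column `recording` of [raw_recording()] objects.
#' @export
generate_synthetic_eeg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_eeg_spec"))
  with_seed(spec$seed, {
    purrr::map_dfr(seq_len(spec$subjects), function(s) {
      subj <- sprintf("S%d", s - 1L)
      tibble::tibble(
        subject = subj,
        session = c("session1", "session2", "session1", "session2"),
        phase = c("task", "task", "baseline1", "baseline2"),
        label = c("low", "high", NA, NA),
        recording = list(
          synth_record(spec, s, spec$duration_s, workload = FALSE),
          synth_record(spec, s, spec$duration_s, workload = TRUE),
          synth_record(spec, s, spec$baseline1_s, rest = TRUE),
          synth_record(spec, s, spec$baseline2_s, workload = FALSE)
        )
      )
    })
  })
}

#' Feature table from synthetic EEG recordings
#'
#' Runs the full band-power pipeline ([extract_features()]) over every
#' recording emitted by [generate_synthetic_eeg()].
#'
#' @param recordings Output of [generate_synthetic_eeg()].
#' @param ... Passed to [extract_features()] (rates, band edges, epoching,
#'   band table).
#' @return A feature table.
#' @export
features_from_recordings <- function(recordings, ...) {
  validate_feature_table(purrr::pmap_dfr(
    recordings[c("subject", "session", "phase", "label", "recording")],
    function(subject, session, phase, label, recording) {
      extract_features(recording, subject, session, phase, label, ...)
    }))
}
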