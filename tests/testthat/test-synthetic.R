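test_that("identical specs generate byte-identical tables", {
  s <- multidomain_spec(M = 3, n_per_cell = 50, F_dim = 4, n_baseline = 10,
                        seed = 42)
  expect_identical(generate_multidomain(s), generate_multidomain(s))
  s2 <- multidomain_spec(M = 3, n_per_cell = 50, F_dim = 4, n_baseline = 10,
                         seed = 43)
  expect_false(identical(generate_multidomain(s), generate_multidomain(s2)))
})

test_that("generated tables honour the cell and baseline layout", {
  s <- multidomain_spec(M = 4, n_per_cell = 30, F_dim = 3, n_baseline = 12,
                        seed = 1)
  tab <- generate_multidomain(s)
  counts <- dplyr::count(tab[tab$phase == "task", ], subject, session)
  expect_equal(nrow(counts), 8)
  expect_true(all(counts$n == 30))
  base_counts <- dplyr::count(tab[tab$phase != "task", ], subject, phase)
  expect_true(all(base_counts$n == 12))
  expect_equal(length(feature_cols(tab)), 3)
  expect_equal(sort(unique(tab$subject)), paste0("S", 0:3))
})

test_that("invalid specs are rejected", {
  expect_error(multidomain_spec(M = 1), "M")
  expect_error(multidomain_spec(label_flip_rate = 0.7), "0, 0.5")
  expect_error(multidomain_spec(covariance_scale = -1), "positive")
  expect_error(multidomain_spec(M = 3, F_dim = 4,
                                marginal_offsets = matrix(0, 2, 2)),
               "3 x 4")
})

test_that("a far-offset domain is flagged by the marginal estimator", {
  s <- multidomain_spec(M = 3, n_per_cell = 100, F_dim = 4,
                        marginal_offsets = c(0, 0, 100),
                        boundary_angles = 0, label_flip_rate = 0,
                        class_separation = 0, n_baseline = 10, seed = 2)
  doms <- partition_by_subject(generate_multidomain(s), "task")
  expect_gte(pairwise_divergence(doms$S0, doms$S2, seed = 1), 0.99)
  acc_null <- pairwise_divergence(doms$S0, doms$S1, seed = 1)
  expect_lt(abs(acc_null - 0.5), 0.1)
})

test_that("per-domain flip rates surface as conditional disagreement", {
  s <- multidomain_spec(M = 2, n_per_cell = 1000, F_dim = 2,
                        marginal_offsets = 0, boundary_angles = 0,
                        label_flip_rate = c(0, 0.3), class_separation = 1,
                        n_baseline = 10, seed = 3)
  doms <- partition_by_subject(generate_multidomain(s), "task")
  f_clean <- fit_labeling_function(doms$S0, k = 5)
  expect_equal(pairwise_disparity(doms$S1, f_clean), 0.3, tolerance = 0.05)
})

test_that("i.i.d. configurations pass a two-sample KS null check", {
  # all shift controls off: domains are i.i.d. standard normal; the KS
  # rejection rate at alpha = 0.01 should stay near its nominal level
  rejections <- 0L; tests <- 0L
  for (seed in 1:25) {
    s <- multidomain_spec(M = 2, n_per_cell = 100, F_dim = 2,
                          marginal_offsets = 0, boundary_angles = 0,
                          label_flip_rate = 0, class_separation = 0,
                          n_baseline = 5, seed = 500 + seed)
    doms <- partition_by_subject(generate_multidomain(s), "task")
    for (f in 1:2) {
      p <- suppressWarnings(
        stats::ks.test(doms$S0$X[, f], doms$S1$X[, f]))$p.value
      tests <- tests + 1L
      if (p < 0.01) rejections <- rejections + 1L
    }
  }
  expect_lte(rejections / tests, 0.05)
})

test_that("synthetic EEG carries the workload effect in alpha and theta", {
  spec <- synthetic_eeg_spec(subjects = 3, duration_s = 30, baseline1_s = 10,
                             baseline2_s = 10, workload_multiplier = 2,
                             seed = 4)
  recs <- generate_synthetic_eeg(spec)
  expect_identical(recs, generate_synthetic_eeg(spec))  # seeded
  tab <- features_from_recordings(recs)
  task <- tab[tab$phase == "task", ]
  for (s in unique(task$subject)) {
    alpha_cols <- grep("_alpha$", names(task), value = TRUE)
    hi <- colMeans(task[task$subject == s & task$label == "high", alpha_cols])
    lo <- colMeans(task[task$subject == s & task$label == "low", alpha_cols])
    expect_true(all(hi > lo))
  }
})

test_that("a clean 10 Hz carrier survives the full pipeline as alpha power", {
  spec <- synthetic_eeg_spec(subjects = 1, duration_s = 20, baseline1_s = 10,
                             baseline2_s = 10, noise_sd = 0, seed = 5)
  recs <- generate_synthetic_eeg(spec)
  tab <- features_from_recordings(
    recs, bands = tibble::tibble(band = c("alpha", "gamma"),
                                 lo_hz = c(8, 30), hi_hz = c(12, 45)))
  task <- tab[tab$phase == "task", ]
  alpha <- as.matrix(task[, grep("_alpha$", names(task))])
  gamma <- as.matrix(task[, grep("_gamma$", names(task))])
  expect_true(all(alpha > 100 * gamma))
})
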