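test_that("k-NN labeling functions follow the deterministic tie rules", {
  ref <- domain_sample("S0", matrix(c(0, 1), ncol = 1), c(0L, 1L))
  f <- fit_labeling_function(ref, k = 1)
  expect_equal(predict_labels(f, matrix(0.1)), 0L)
  expect_equal(predict_labels(f, matrix(0.9)), 1L)
  # equidistant query: lower reference index wins
  expect_equal(predict_labels(f, matrix(0.5)), 0L)
  # k = N with balanced classes: vote tie broken to label 0
  f_all <- fit_labeling_function(ref, k = 2)
  expect_equal(predict_labels(f_all, matrix(0.5)), 0L)

  expect_error(fit_labeling_function(ref, k = 3), "exceeds")
  one_class <- domain_sample("S1", matrix(1:3, ncol = 1), c(1L, 1L, 1L))
  expect_error(fit_labeling_function(one_class, k = 1), "single class")
})

test_that("pairwise_disparity is the empirical disagreement rate", {
  dom_i <- domain_sample("A", matrix(c(0.1, 0.2, 0.9, 0.8), ncol = 1),
                         c(0L, 0L, 1L, 0L))
  f_j <- fit_labeling_function(
    domain_sample("B", matrix(c(0, 1), ncol = 1), c(0L, 1L)), k = 1)
  # 1-NN predicts [0, 0, 1, 1]; labels are [0, 0, 1, 0] -> 1/4 disagree
  expect_equal(pairwise_disparity(dom_i, f_j), 0.25)

  agree <- domain_sample("A", matrix(c(0.1, 0.9), ncol = 1), c(0L, 1L))
  expect_equal(pairwise_disparity(agree, f_j), 0)
  flipped <- domain_sample("A", matrix(c(0.1, 0.9), ncol = 1), c(1L, 0L))
  expect_equal(pairwise_disparity(flipped, f_j), 1)

  wide <- domain_sample("C", matrix(1:4, ncol = 2), c(0L, 1L))
  expect_error(pairwise_disparity(wide, f_j), "dimension")
})

test_that("disparity_matrix is exactly symmetric with min-rule entries", {
  doms <- purrr::map(1:3, function(i) {
    make_rule_domain(paste0("S", i), 60, angle = 10 * i, seed = 100 + i)
  })
  dm <- disparity_matrix(doms, k = 3, seed = 5)
  expect_equal(max(abs(dm$D - t(dm$D))), 0)
  expect_true(all(dm$D >= 0 & dm$D <= 1))
  for (i in 1:3) for (j in 1:3) {
    if (i != j) expect_equal(dm$D[i, j], min(dm$mu[i, j], dm$mu[j, i]))
  }
})

test_that("near-identical separable domains give a near-zero matrix", {
  doms <- purrr::map(1:2, function(i) {
    make_rule_domain(paste0("S", i), 200, sep = 2, seed = 200 + i)
  })
  dm <- disparity_matrix(doms, k = 1, seed = 3)
  expect_true(all(dm$D < 0.05))
})

test_that("aggregate_disparity rescales the Frobenius norm by M", {
  z <- matrix(0, 4, 4)
  expect_equal(aggregate_disparity(z), 0)
  expect_equal(aggregate_disparity(matrix(1, 5, 5)), 1)
  expect_equal(aggregate_disparity(matrix(c(0, 0.5, 0.5, 0), 2, 2)),
               sqrt(0.5) / 2)
})

test_that("label-flip rates are recovered by the disagreement estimator", {
  clean <- make_rule_domain("A", 1500, sep = 1, seed = 11)
  f <- fit_labeling_function(clean, k = 5)
  noisy <- make_rule_domain("B", 1500, sep = 1, flip = 0.2, seed = 12)
  expect_lt(abs(pairwise_disparity(noisy, f) - 0.2), 0.05)
})

test_that("repeated conditional estimates are deterministic per protocol", {
  tab <- make_small_table(n_cell = 40, seed = 7)
  pro <- sampling_protocol(n_per_cell = 30, n_repetitions = 2, base_seed = 10)
  e1 <- estimate_conditional_shift(tab, pro, "none", k = 3)
  e2 <- estimate_conditional_shift(tab, pro, "none", k = 3)
  expect_identical(e1$aggregates, e2$aggregates)
  expect_identical(e1$mean_matrix, e2$mean_matrix)
  expect_equal(nrow(e1$aggregates), 2)

  single <- estimate_conditional_shift(
    tab, sampling_protocol(30, 1, 10), "none", k = 3)
  expect_equal(nrow(single$aggregates), 1)
  expect_length(single$subject_means, 2)
})

test_that("replicated separable domains keep the mean aggregate low", {
  spec <- multidomain_spec(M = 3, n_per_cell = 100, F_dim = 2,
                           marginal_offsets = 0, boundary_angles = 0,
                           label_flip_rate = 0, class_separation = 2,
                           n_baseline = 20, seed = 8)
  tab <- generate_multidomain(spec)
  est <- estimate_conditional_shift(
    tab, sampling_protocol(80, 2, 10), "none", k = 5)
  expect_lt(mean(est$aggregates$value), 0.1)
})
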