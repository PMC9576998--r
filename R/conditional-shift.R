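# Conditional (labeling-rule) shift across subjects. Each subject's unknown
# labeling function is approximated by a k-NN classifier trained on that
# subject's sample; the disagreement of subject j's approximation on subject
# i's labeled points estimates how far the two labeling rules are apart.

#' Approximate a subject's labeling function with k-NN
#'
#' The returned object predicts the majority label among the k
#' Euclidean-nearest reference points of the source domain. All ties are
#' broken deterministically: equal distances favour the lower reference-point
#' index (stable ordering), tied votes favour label 0 ("low").
#'
#' @param domain A `domain_sample` with both classes present.
#' @param k Number of neighbours; must not exceed the domain size. Odd values
#'   avoid vote ties. Default 5.
#' @return A `labeling_function` object; call [predict_labels()] on it.
#' @export
fit_labeling_function <- function(domain, k = 5L) {
  stopifnot(inherits(domain, "domain_sample"))
  if (anyNA(domain$y)) abort("Labeling functions need fully labeled domains.")
  if (length(unique(domain$y)) < 2L) {
    abort(sprintf("Domain '%s' has a single class; cannot approximate its labeling function.",
                  domain$subject_id))
  }
  stopifnot_scalar_number(k, "k", lo = 1)
  if (k > nrow(domain$X)) {
    abort(sprintf("k = %d exceeds the domain size N = %d.", k, nrow(domain$X)))
  }
  structure(list(source_subject = domain$subject_id, k = as.integer(k),
                 X = domain$X, y = domain$y),
            class = "labeling_function")
}

#' @export
print.labeling_function <- function(x, ...) {
  cat(sprintf("<labeling_function> %d-NN on subject %s (N = %d, F = %d)\n",
              x$k, x$source_subject, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Predict labels with an approximated labeling function
#'
#' @param f A [fit_labeling_function()] result.
#' @param X Query feature matrix (columns must match the reference set).
#' @return Integer vector of predicted labels (0 = low, 1 = high).
#' @export
predict_labels <- function(f, X) {
  stopifnot(inherits(f, "labeling_function"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(f$X)) {
    abort(sprintf("Feature dimension mismatch: query has %d, reference has %d.",
                  ncol(X), ncol(f$X)))
  }
  # Squared Euclidean distances, vectorized: |q|^2 + |r|^2 - 2 q r'.
  d2 <- outer(rowSums(X^2), rowSums(f$X^2), "+") - 2 * tcrossprod(X, f$X)
  k <- f$k
  apply(d2, 1, function(drow) {
    nn <- order(drow)[seq_len(k)]  # order() breaks ties by lower index
    votes <- sum(f$y[nn])
    if (votes * 2L > k) 1L else 0L # vote tie -> label 0
  })
}

#' Pairwise conditional-shift estimate between one labeled sample and a
#' labeling-function approximation
#'
#' The empirical disagreement
#' `mu_ij = (1/N) * sum_n 1[y_n^i != f_j(x_n^i)]`
#' between subject i's labels and subject j's approximated labeling function,
#' evaluated on all N points of subject i's sample.
#'
#' @param domain_i A labeled `domain_sample` (subject i).
#' @param f_j A [fit_labeling_function()] result for subject j.
#' @return Disagreement rate in `[0, 1]`.
#' @export
pairwise_disparity <- function(domain_i, f_j) {
  stopifnot(inherits(domain_i, "domain_sample"))
  if (anyNA(domain_i$y)) abort("pairwise_disparity() needs labeled domains.")
  pred <- predict_labels(f_j, domain_i$X)
  mean(pred != domain_i$y)
}

#' Cross-subject disparity matrix
#'
#' Builds the symmetric M x M conditional-shift matrix: off-diagonal
#' `D[i, j] = min(mu_ij, mu_ji)` (the smaller of the two directed
#' disagreements), and diagonal `D[i, i]` equal to the held-out disagreement
#' of subject i's own labeling approximation on a disjoint stratified split —
#' a direct read-out of how well the k-NN approximation captures each
#' subject's rule (0 for a perfect approximation).
#'
#' @param domains List of labeled `domain_sample`s (subject order is taken as
#'   given; [partition_by_subject()] yields lexicographic order).
#' @param k Neighbours for the labeling-function approximations (default 5).
#' @param train_fraction Stratified train fraction for the diagonal split
#'   (default 0.5).
#' @param seed RNG seed for the diagonal splits.
#' @return A `disparity_matrix` object with fields `subjects`, `D`, `mu`
#'   (raw directed disagreements) and `metadata`.
#' @export
disparity_matrix <- function(domains, k = 5L, train_fraction = 0.5, seed = 1L) {
  M <- length(domains)
  if (M < 2L) abort("Need at least 2 domains.")
  subjects <- vapply(domains, function(d) d$subject_id, character(1))
  fns <- purrr::map(domains, fit_labeling_function, k = k)
  mu <- matrix(NA_real_, M, M, dimnames = list(subjects, subjects))
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i != j) mu[i, j] <- pairwise_disparity(domains[[i]], fns[[j]])
    }
  }
  D <- matrix(0, M, M, dimnames = list(subjects, subjects))
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i < j) D[i, j] <- D[j, i] <- min(mu[i, j], mu[j, i])
    }
    parts <- split_disjoint(domains[[i]], train_fraction,
                            seed = derive_seed(seed, 7L, i))
    D[i, i] <- pairwise_disparity(parts$test,
                                  fit_labeling_function(parts$train, k = k))
  }
  structure(list(subjects = subjects, D = D, mu = mu,
                 metadata = list(k = as.integer(k), seed = as.integer(seed),
                                 train_fraction = train_fraction)),
            class = "disparity_matrix")
}

#' @export
print.disparity_matrix <- function(x, ...) {
  cat(sprintf("<disparity_matrix> %d subjects, k = %d, aggregate = %.4f\n",
              length(x$subjects), x$metadata$k, aggregate_disparity(x)))
  print(round(x$D, 3))
  invisible(x)
}

#' Aggregate a shift matrix to a single value in [0, 1]
#'
#' The Frobenius norm of the matrix divided by M, the largest Frobenius norm
#' attainable by an M x M matrix with entries in `[0, 1]`. Zero iff the
#' matrix is zero.
#'
#' @param matrix A `disparity_matrix` or `divergence_matrix` (or a plain
#'   numeric matrix with entries in `[0, 1]`).
#' @return Aggregate shift value in `[0, 1]`.
#' @export
aggregate_disparity <- function(matrix) {
  m <- if (inherits(matrix, "disparity_matrix")) matrix$D
       else if (inherits(matrix, "divergence_matrix")) matrix$H
       else as.matrix(matrix)
  frobenius(m) / nrow(m)
}

#' Repeated conditional-shift estimation
#'
#' Runs the full conditional-shift pipeline once per protocol repetition:
#' normalize the table with `strategy`, subsample task rows per
#' subject-session cell, partition into per-subject domains, build the
#' disparity matrix and aggregate it. Also accumulates the element-wise mean
#' disparity matrix and per-subject column means (average cross-subject
#' disparity).
#'
#' @param table A feature table (all phases; baselines are used for
#'   baseline normalization strategies).
#' @param protocol A [sampling_protocol()].
#' @param strategy Normalization strategy (see [normalize_features()]).
#' @param k Neighbours for the labeling functions (default 5).
#' @param train_fraction Diagonal split fraction (default 0.5).
#' @return A `shift_estimate` object: tibble of per-repetition aggregates,
#'   the mean disparity matrix, per-subject means, and metadata. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
estimate_conditional_shift <- function(table, protocol = sampling_protocol(),
                                       strategy = "none", k = 5L,
                                       train_fraction = 0.5) {
  strategy <- rlang::arg_match(strategy, STRATEGIES)
  normalized <- normalize_features(table, strategy)
  reps <- seq_len(protocol$n_repetitions)
  mats <- purrr::map(reps, function(r) {
    sub <- subsample(normalized, protocol, r)
    disparity_matrix(partition_by_subject(sub, "task"), k = k,
                     train_fraction = train_fraction,
                     seed = protocol$base_seed + r)
  })
  mean_D <- Reduce(`+`, purrr::map(mats, "D")) / length(mats)
  structure(list(
    aggregates = tibble::tibble(
      repetition = reps,
      value = vapply(mats, aggregate_disparity, numeric(1))
    ),
    mean_matrix = mean_D,
    subject_means = colMeans(mean_D),
    subjects = mats[[1]]$subjects,
    metadata = list(kind = "conditional", strategy = strategy,
                    k = as.integer(k), train_fraction = train_fraction,
                    protocol = unclass(protocol))
  ), class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> %s shift, strategy '%s': %.4f +/- %.4f over %d repetition(s)\n",
              x$metadata$kind, x$metadata$strategy, mean(x$aggregates$value),
              if (nrow(x$aggregates) > 1) sd(x$aggregates$value) else 0,
              nrow(x$aggregates)))
  invisible(x)
}
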