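# Marginal shift across subjects via the H-divergence classifier proxy: the
# better a classifier can tell two subjects' feature samples apart, the
# further apart their marginal distributions are. Workload labels are never
# read here; the classification target is domain identity.

#' Pairwise marginal shift between two domains
#'
#' Pools the two feature samples with labels equal to domain identity,
#' equalizes the class sizes by seeded truncation of the larger sample (so
#' chance level is exactly 0.5), and returns the mean k-fold cross-validated
#' accuracy of a random-forest domain discriminator. Values near 0.5 mean
#' indistinguishable marginals; values near 1 mean strongly shifted
#' marginals.
#'
#' @param domain_i,domain_j `domain_sample`s (labels, if any, are ignored).
#' @param n_folds Cross-validation folds (default 5), stratified by domain.
#' @param n_trees Random-forest size (default 20).
#' @param seed RNG seed controlling truncation, fold assignment and the
#'   forests.
#' @param min_bucket Minimum terminal-node size of the forest (default 10).
#'   A leaf-size floor keeps the cross-validated accuracy tracking the
#'   optimal (Bayes) discriminability of the two samples instead of the
#'   inflated disagreement of fully grown, nearest-neighbour-like trees.
#' @return Mean cross-validated accuracy in `[0, 1]`.
#' @export
pairwise_divergence <- function(domain_i, domain_j, n_folds = 5L,
                                n_trees = 20L, seed = 1L, min_bucket = 10L) {
  stopifnot(inherits(domain_i, "domain_sample"),
            inherits(domain_j, "domain_sample"))
  if (ncol(domain_i$X) != ncol(domain_j$X)) {
    abort("Feature dimension mismatch between the two domains.")
  }
  n <- min(nrow(domain_i$X), nrow(domain_j$X))
  if (n < n_folds) {
    abort(sprintf("Smaller domain has %d rows; need at least n_folds = %d.",
                  n, n_folds))
  }
  Xi <- domain_i$X; Xj <- domain_j$X
  with_seed(derive_seed(seed, 11L), {
    if (nrow(Xi) > n) Xi <- Xi[sort(sample(nrow(Xi), n)), , drop = FALSE]
    if (nrow(Xj) > n) Xj <- Xj[sort(sample(nrow(Xj), n)), , drop = FALSE]
  })
  X <- rbind(Xi, Xj)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  dom <- factor(rep(c(0L, 1L), each = n))
  # Stratified folds: shuffle within each domain, deal out round-robin.
  folds <- with_seed(derive_seed(seed, 13L), {
    f <- integer(2L * n)
    for (cl in c(0L, 1L)) {
      idx <- sample(which(dom == cl))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  df <- data.frame(domain = dom, X)
  # ranger consumes the R session RNG for split-candidate draws even when
  # `seed` is given, so every fit runs under a derived local seed
  acc <- vapply(seq_len(n_folds), function(fold) {
    tr <- df[folds != fold, , drop = FALSE]
    te <- df[folds == fold, , drop = FALSE]
    with_seed(derive_seed(seed, 17L, fold), {
      fit <- ranger::ranger(domain ~ ., data = tr, num.trees = n_trees,
                            min.bucket = min_bucket,
                            seed = derive_seed(seed, 17L, fold),
                            num.threads = 1L)
      mean(predict(fit, data = te, num.threads = 1L)$predictions == te$domain)
    })
  }, numeric(1))
  mean(acc)
}

#' Cross-subject divergence (marginal-shift) matrix
#'
#' Symmetric M x M matrix of pairwise marginal-shift estimates (each pair
#' computed once). The diagonal `H[i, i]` is the same discriminator applied
#' to a random half-vs-half split of subject i's own sample — expected at
#' chance (0.5) and serving as the finite-sample null reference.
#'
#' @param domains List of `domain_sample`s.
#' @param n_folds,n_trees,seed,min_bucket As in [pairwise_divergence()].
#' @return A `divergence_matrix` object with fields `subjects`, `H` and
#'   `metadata` (including `entry_semantics = "accuracy"`).
#' @export
divergence_matrix <- function(domains, n_folds = 5L, n_trees = 20L,
                              seed = 1L, min_bucket = 10L) {
  M <- length(domains)
  if (M < 2L) abort("Need at least 2 domains.")
  subjects <- vapply(domains, function(d) d$subject_id, character(1))
  H <- matrix(0, M, M, dimnames = list(subjects, subjects))
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i < j) {
        H[i, j] <- H[j, i] <- pairwise_divergence(
          domains[[i]], domains[[j]], n_folds, n_trees,
          seed = derive_seed(seed, 19L, i * 1000L + j),
          min_bucket = min_bucket)
      }
    }
    Ni <- nrow(domains[[i]]$X)
    half <- with_seed(derive_seed(seed, 23L, i), sort(sample(Ni, Ni %/% 2L)))
    H[i, i] <- pairwise_divergence(
      domain_sample(subjects[i], domains[[i]]$X[half, , drop = FALSE]),
      domain_sample(subjects[i], domains[[i]]$X[-half, , drop = FALSE]),
      n_folds, n_trees, seed = derive_seed(seed, 29L, i),
      min_bucket = min_bucket)
  }
  structure(list(subjects = subjects, H = H,
                 metadata = list(n_trees = as.integer(n_trees),
                                 n_folds = as.integer(n_folds),
                                 seed = as.integer(seed),
                                 min_bucket = as.integer(min_bucket),
                                 entry_semantics = "accuracy")),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("<divergence_matrix> %d subjects (%s entries), aggregate = %.4f\n",
              length(x$subjects), x$metadata$entry_semantics,
              aggregate_divergence(x)))
  print(round(x$H, 3))
  invisible(x)
}

#' Aggregate a divergence matrix
#'
#' `||H||_F / M`, mapping any matrix with entries in `[0, 1]` into `[0, 1]`.
#'
#' @param matrix A `divergence_matrix` (or plain matrix).
#' @return Aggregate marginal shift in `[0, 1]`.
#' @export
aggregate_divergence <- function(matrix) {
  aggregate_disparity(matrix)
}

#' Repeated marginal-shift estimation
#'
#' As [estimate_conditional_shift()], but building [divergence_matrix()]s:
#' one per protocol repetition, each on an independent per-cell subsample of
#' the normalized table.
#'
#' @inheritParams estimate_conditional_shift
#' @param n_folds,n_trees Discriminator settings (defaults 5 folds,
#'   20 trees).
#' @return A `shift_estimate` object (see [estimate_conditional_shift()]).
#' @export
estimate_marginal_shift <- function(table, protocol = sampling_protocol(),
                                    strategy = "none", n_folds = 5L,
                                    n_trees = 20L) {
  strategy <- rlang::arg_match(strategy, STRATEGIES)
  normalized <- normalize_features(table, strategy)
  reps <- seq_len(protocol$n_repetitions)
  mats <- purrr::map(reps, function(r) {
    sub <- subsample(normalized, protocol, r)
    divergence_matrix(partition_by_subject(sub, "task"), n_folds = n_folds,
                      n_trees = n_trees, seed = protocol$base_seed + r)
  })
  mean_H <- Reduce(`+`, purrr::map(mats, "H")) / length(mats)
  structure(list(
    aggregates = tibble::tibble(
      repetition = reps,
      value = vapply(mats, aggregate_divergence, numeric(1))
    ),
    mean_matrix = mean_H,
    subject_means = colMeans(mean_H),
    subjects = mats[[1]]$subjects,
    metadata = list(kind = "marginal", strategy = strategy,
                    n_folds = as.integer(n_folds),
                    n_trees = as.integer(n_trees),
                    entry_semantics = "accuracy",
                    protocol = unclass(protocol))
  ), class = "shift_estimate")
}
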