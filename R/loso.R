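# Leave-one-subject-out (LOSO) workload classification: train on all
# subjects but one, test on the excluded subject, and read the
# generalization gap off the difference between source-domain and
# target-subject accuracy.

#' Split a feature table into LOSO train and test parts
#'
#' Test = all task rows of the held-out subject; train = pooled task rows of
#' every other subject (the source domain is the mixture of the training
#' subjects).
#'
#' @param table A feature table.
#' @param held_out Subject id to hold out.
#' @return List with feature tables `train` and `test`.
#' @export
loso_split <- function(table, held_out) {
  task <- table[table$phase == "task", , drop = FALSE]
  subjects <- unique(task$subject)
  if (length(subjects) < 2L) abort("LOSO needs at least 2 subjects.")
  if (!held_out %in% subjects) {
    abort(sprintf("Unknown subject '%s'.", held_out))
  }
  list(train = task[task$subject != held_out, , drop = FALSE],
       test = task[task$subject == held_out, , drop = FALSE])
}

#' Generalization gap
#'
#' The absolute difference between training (source-domain) and test
#' (held-out subject) accuracy.
#'
#' @param train_accuracy,test_accuracy Accuracies in `[0, 1]`.
#' @return `|train_accuracy - test_accuracy|`.
#' @export
gap <- function(train_accuracy, test_accuracy) {
  stopifnot_scalar_number(train_accuracy, "train_accuracy", lo = 0, hi = 1)
  stopifnot_scalar_number(test_accuracy, "test_accuracy", lo = 0, hi = 1)
  abs(train_accuracy - test_accuracy)
}

# One repetition of LOSO over all subjects on an already-normalized,
# already-subsampled task table. Returns a tibble of per-subject rows.
loso_one_repetition <- function(task, n_trees, source_holdout, seed) {
  feats <- feature_cols(task)
  subjects <- sort(unique(task$subject))
  purrr::map_dfr(seq_along(subjects), function(si) {
    held_out <- subjects[si]
    parts <- loso_split(task, held_out)
    train <- parts$train
    # Per training subject, set aside `source_holdout` points (stratified by
    # session) to estimate the source-domain risk on data unseen in fitting.
    holdout_idx <- with_seed(derive_seed(seed, 31L, si), {
      unlist(purrr::map(unique(train$subject), function(s) {
        rows <- which(train$subject == s)
        by_sess <- split(rows, train$session[rows])
        take <- vapply(by_sess, length, 1L)
        take <- round(source_holdout * take / sum(take))
        if (any(vapply(by_sess, length, 1L) <= take)) {
          abort(sprintf("Subject '%s' has too few task rows for a %d-point source holdout.",
                        s, source_holdout))
        }
        unlist(purrr::map2(by_sess, take, function(idx, t_) sample(idx, t_)),
               use.names = FALSE)
      }), use.names = FALSE)
    })
    holdout_idx <- sort(holdout_idx)
    fit_rows <- setdiff(seq_len(nrow(train)), holdout_idx)
    df <- function(tab, rows) {
      data.frame(label = factor(tab$label[rows], levels = LABELS),
                 as.matrix(tab[rows, feats, drop = FALSE]))
    }
    # ranger draws from the session RNG during fitting even with `seed`
    # set, so the fit/predict block runs under its own local seed
    accs <- with_seed(derive_seed(seed, 37L, si), {
      fit <- ranger::ranger(label ~ ., data = df(train, fit_rows),
                            num.trees = n_trees,
                            seed = derive_seed(seed, 37L, si),
                            num.threads = 1L)
      acc <- function(newdata) {
        mean(predict(fit, data = newdata, num.threads = 1L)$predictions ==
               newdata$label)
      }
      c(acc(df(train, holdout_idx)),
        acc(df(parts$test, seq_len(nrow(parts$test)))))
    })
    train_acc <- accs[1]
    test_acc <- accs[2]
    tibble::tibble(subject = held_out, n_test = nrow(parts$test),
                   train_accuracy = train_acc, test_accuracy = test_acc,
                   gap = gap(train_acc, test_acc))
  })
}

#' Leave-one-subject-out evaluation with repeated subsampling
#'
#' For each protocol repetition: normalize the table with `strategy`,
#' subsample task rows per cell, and for every held-out subject fit a
#' random-forest low/high-workload classifier on the remaining subjects'
#' rows minus a per-subject source holdout. Training accuracy (on the pooled
#' holdout) estimates the source-domain risk; test accuracy is measured on
#' the held-out subject; the gap is their absolute difference, averaged over
#' repetitions per subject.
#'
#' @inheritParams estimate_conditional_shift
#' @param n_trees Random-forest size for the workload classifier
#'   (default 30).
#' @param source_holdout Points per training subject set aside to estimate
#'   source-domain accuracy (default 200); refreshed each repetition.
#' @return A `loso_report` object: per-subject and pooled mean/sd of train
#'   accuracy, test accuracy and gap, plus the per-repetition detail table.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
evaluate_loso <- function(table, protocol = sampling_protocol(),
                          strategy = "none", n_trees = 30L,
                          source_holdout = 200L) {
  strategy <- rlang::arg_match(strategy, STRATEGIES)
  normalized <- normalize_features(table, strategy)
  reps <- seq_len(protocol$n_repetitions)
  detail <- purrr::map_dfr(reps, function(r) {
    sub <- subsample(normalized, protocol, r)
    dplyr::mutate(
      loso_one_repetition(sub, n_trees, source_holdout,
                          seed = protocol$base_seed + r),
      repetition = r, .before = 1)
  })
  per_subject <- detail |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      dplyr::across(c("train_accuracy", "test_accuracy", "gap"),
                    list(mean = mean, sd = ~ if (length(.x) > 1) sd(.x) else 0)),
      .groups = "drop")
  pooled <- detail |>
    dplyr::summarise(
      subject = "All",
      dplyr::across(c("train_accuracy", "test_accuracy", "gap"),
                    list(mean = mean, sd = ~ if (length(.x) > 1) sd(.x) else 0)))
  structure(list(
    per_subject = per_subject, pooled = pooled, detail = detail,
    metadata = list(strategy = strategy, n_trees = as.integer(n_trees),
                    source_holdout = as.integer(source_holdout),
                    protocol = unclass(protocol))
  ), class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat(sprintf("<loso_report> strategy '%s', %d subject(s), %d repetition(s)\n",
              x$metadata$strategy, nrow(x$per_subject),
              x$metadata$protocol$n_repetitions))
  cat(sprintf("  All: train %.3f +/- %.3f | test %.3f +/- %.3f | gap %.3f +/- %.3f\n",
              x$pooled$train_accuracy_mean, x$pooled$train_accuracy_sd,
              x$pooled$test_accuracy_mean, x$pooled$test_accuracy_sd,
              x$pooled$gap_mean, x$pooled$gap_sd))
  invisible(x)
}
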