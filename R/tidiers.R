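# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a disparity matrix
#'
#' @param x A `disparity_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per ordered subject pair: `subject_i`,
#'   `subject_j`, `mu_ij` (directed disagreement, `NA` on the diagonal) and
#'   `disparity` (the symmetric entry `D[i, j]`).
#' @export
tidy.disparity_matrix <- function(x, ...) {
  M <- length(x$subjects)
  tidyr::expand_grid(subject_i = x$subjects, subject_j = x$subjects) |>
    dplyr::mutate(mu_ij = as.vector(t(x$mu)),
                  disparity = as.vector(t(x$D)))
}

#' @rdname tidy.disparity_matrix
#' @export
glance.disparity_matrix <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$subjects), k = x$metadata$k,
                 aggregate = aggregate_disparity(x),
                 mean_diagonal = mean(diag(x$D)),
                 mean_off_diagonal = mean(x$D[upper.tri(x$D)]))
}

#' Tidy a divergence matrix
#'
#' @param x A `divergence_matrix`.
#' @param ... Unused.
#' @return A tibble per ordered pair with the stored `accuracy` entry, the
#'   complementary `error = 1 - accuracy`, and the theoretical H-divergence
#'   proxy `d_h = 2 * (1 - 2 * error)`.
#' @export
tidy.divergence_matrix <- function(x, ...) {
  tidyr::expand_grid(subject_i = x$subjects, subject_j = x$subjects) |>
    dplyr::mutate(accuracy = as.vector(t(x$H)),
                  error = 1 - .data$accuracy,
                  d_h = 2 * (1 - 2 * .data$error))
}

#' @rdname tidy.divergence_matrix
#' @export
glance.divergence_matrix <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$subjects),
                 n_trees = x$metadata$n_trees, n_folds = x$metadata$n_folds,
                 aggregate = aggregate_divergence(x),
                 mean_diagonal = mean(diag(x$H)),
                 mean_off_diagonal = mean(x$H[upper.tri(x$H)]))
}

#' Tidy a repeated shift estimate
#'
#' @param x A `shift_estimate` from [estimate_conditional_shift()] or
#'   [estimate_marginal_shift()].
#' @param ... Unused.
#' @return Tibble with `kind`, `strategy`, `repetition`, `value`.
#' @export
tidy.shift_estimate <- function(x, ...) {
  dplyr::mutate(x$aggregates, kind = x$metadata$kind,
                strategy = x$metadata$strategy, .before = 1)
}

#' @rdname tidy.shift_estimate
#' @export
glance.shift_estimate <- function(x, ...) {
  tibble::tibble(kind = x$metadata$kind, strategy = x$metadata$strategy,
                 mean = mean(x$aggregates$value),
                 sd = if (nrow(x$aggregates) > 1) sd(x$aggregates$value) else 0,
                 n_repetitions = nrow(x$aggregates))
}

#' Tidy a LOSO report
#'
#' @param x A `loso_report`.
#' @param ... Unused.
#' @return Per-subject rows plus an `"All"` row, with mean and sd of train
#'   accuracy, test accuracy and gap (the layout of a per-subject results
#'   table with three quantities per cell).
#' @export
tidy.loso_report <- function(x, ...) {
  dplyr::bind_rows(x$per_subject, x$pooled) |>
    dplyr::mutate(strategy = x$metadata$strategy, .before = 1)
}

#' @rdname tidy.loso_report
#' @export
glance.loso_report <- function(x, ...) {
  tibble::tibble(strategy = x$metadata$strategy,
                 n_subjects = nrow(x$per_subject),
                 n_repetitions = x$metadata$protocol$n_repetitions,
                 train_accuracy = x$pooled$train_accuracy_mean,
                 test_accuracy = x$pooled$test_accuracy_mean,
                 gap = x$pooled$gap_mean)
}

shift_heatmap <- function(m, value_name) {
  df <- tidyr::expand_grid(subject_i = factor(rownames(m), rownames(m)),
                           subject_j = factor(colnames(m), colnames(m))) |>
    dplyr::mutate(value = as.vector(t(m)))
  ggplot2::ggplot(df, ggplot2::aes(.data$subject_j, .data$subject_i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = value_name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a disparity matrix
#'
#' @param object A `disparity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disparity_matrix <- function(object, ...) {
  shift_heatmap(object$D, "disparity")
}

#' Heatmap of a divergence matrix
#'
#' @param object A `divergence_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_matrix <- function(object, ...) {
  shift_heatmap(object$H, "accuracy")
}

#' Boxplot of repeated shift-aggregate estimates
#'
#' @param object A `shift_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shift_estimate <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$strategy, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = sprintf("aggregate %s shift", object$metadata$kind),
                  x = "normalization strategy") +
    ggplot2::theme_minimal()
}

#' Per-subject generalization-gap boxplot
#'
#' @param object A `loso_report`.
#' @param ... Unused.
#' @return A ggplot object: one box of per-repetition gaps per held-out
#'   subject.
#' @export
autoplot.loso_report <- function(object, ...) {
  ggplot2::ggplot(object$detail,
                  ggplot2::aes(.data$subject, .data$gap)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "held-out subject", y = "generalization gap") +
    ggplot2::theme_minimal()
}

#' Bar plot of average cross-subject disparity per subject
#'
#' @param estimate A conditional `shift_estimate`.
#' @return A ggplot object with one bar per subject (column means of the
#'   mean disparity matrix).
#' @export
plot_subject_disparity <- function(estimate) {
  stopifnot(inherits(estimate, "shift_estimate"))
  df <- tibble::tibble(subject = estimate$subjects,
                       mean_disparity = unname(estimate$subject_means))
  ggplot2::ggplot(df, ggplot2::aes(.data$subject, .data$mean_disparity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "subject", y = "average cross-subject disparity") +
    ggplot2::theme_minimal()
}
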