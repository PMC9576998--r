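# Feature tables: one row per epoch, tagged by subject, session and phase
# ("task", "baseline1", "baseline2"), a two-level workload label on task rows
# ("low"/"high"), and F numeric feature columns.

#' Read a labeled multi-subject feature table
#'
#' Reads a delimited text file (comma- or tab-separated, auto-detected from
#' the header line) with columns `subject`, `session`, `phase`, optionally
#' `label`, and at least one numeric feature column, then validates it.
#' When no label column is present, labels on task rows are derived from the
#' session: each session corresponds to one workload level, the
#' lexicographically first session is `"low"` and the second `"high"`.
#'
#' @param path Path to the delimited file. A header row is mandatory.
#' @param schema Optional named character vector mapping the standard column
#'   names (`subject`, `session`, `phase`, `label`) to the column names used
#'   in the file, e.g. `c(subject = "participant")`.
#' @return A validated feature table: a [tibble::tibble()] with the metadata
#'   columns first, features after, row order preserved.
#' @seealso [validate_feature_table()], [write_feature_table()]
#' @export
read_feature_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path))
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA"))
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(tab)) {
        abort(sprintf("Schema column '%s' (for '%s') not found in '%s'.",
                      schema[[std]], std, path))
      }
    }
    tab <- dplyr::rename(tab, !!!rlang::set_names(unname(schema), names(schema)))
  }
  for (col in c("subject", "session", "phase")) {
    if (!col %in% names(tab)) {
      abort(sprintf("Required column '%s' is missing from '%s'.", col, path))
    }
  }
  tab <- dplyr::mutate(tab, dplyr::across(dplyr::all_of(
    intersect(c("subject", "session", "phase", "label"), names(tab))
  ), as.character))
  if (!"label" %in% names(tab)) {
    sessions <- sort(unique(tab$session))
    if (length(sessions) != 2L) {
      abort(sprintf(paste0(
        "No 'label' column and %d distinct sessions found; labels can only ",
        "be derived from sessions when there are exactly 2 (one per ",
        "workload level)."), length(sessions)))
    }
    tab$label <- ifelse(tab$phase == "task",
                        LABELS[match(tab$session, sessions)], NA_character_)
  }
  tab <- dplyr::relocate(tab, dplyr::all_of(META_COLS))
  validate_feature_table(tab)
}

#' Validate a feature table
#'
#' Checks the feature-table contract: metadata columns present; at least one
#' feature column, all numeric with no non-finite values; phases within
#' `task`/`baseline1`/`baseline2`; every task row labeled `low` or `high`
#' (baseline rows may have `NA` labels).
#'
#' @param table A data frame to validate.
#' @return The validated table as a tibble, invisibly unchanged.
#' @export
validate_feature_table <- function(table) {
  table <- tibble::as_tibble(table)
  for (col in setdiff(META_COLS, "label")) {
    if (!col %in% names(table)) {
      abort(sprintf("Required column '%s' is missing.", col))
    }
  }
  if (!"label" %in% names(table)) table$label <- NA_character_
  feats <- feature_cols(table)
  if (length(feats) < 1L) {
    abort("A feature table needs at least one feature column.")
  }
  for (fc in feats) {
    v <- table[[fc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      abort(sprintf("Feature column '%s' is not numeric (first bad row: %s).",
                    fc, bad %||% "?"))
    }
    if (anyNA(v) || any(!is.finite(v))) {
      abort(sprintf("Feature column '%s' contains non-finite values (row %d).",
                    fc, which(!is.finite(v))[1]))
    }
  }
  bad_phase <- setdiff(unique(table$phase), PHASES)
  if (length(bad_phase) > 0L) {
    abort(sprintf("Unknown phase value(s): %s.",
                  paste(sQuote(bad_phase), collapse = ", ")))
  }
  task <- table$phase == "task"
  if (any(task & (is.na(table$label) | !table$label %in% LABELS))) {
    abort(sprintf("Task row %d lacks a valid 'low'/'high' label.",
                  which(task & (is.na(table$label) | !table$label %in% LABELS))[1]))
  }
  table
}

#' Write a feature table to delimited text
#'
#' @param table A feature table.
#' @param path Output path; `.tsv` extension selects tab, anything else comma.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(table, path, delim = delim, na = "")
  invisible(path)
}

#' Split a feature table into one domain sample per subject
#'
#' A *domain* is one subject's data-generating distribution; its sample is
#' the subject's rows in the requested phase, as a feature matrix `X` and
#' (for task rows) a binary label vector `y` (0 = low, 1 = high workload).
#' Subjects are ordered lexicographically so that matrix axes built from the
#' result are comparable across runs.
#'
#' @param table A feature table.
#' @param phase Which phase to extract (default `"task"`).
#' @return A named list of `domain_sample` objects, one per subject, in
#'   lexicographic subject order. Each has fields `subject_id`, `X`
#'   (N x F matrix) and `y` (length-N integer vector, `NA` for unlabeled
#'   baseline rows).
#' @export
partition_by_subject <- function(table, phase = "task") {
  phase <- rlang::arg_match(phase, PHASES)
  subjects <- sort(unique(table$subject))
  if (length(subjects) == 0L) abort("Feature table has no rows.")
  sel <- table[table$phase == phase, , drop = FALSE]
  if (nrow(sel) == 0L) {
    abort(sprintf("No rows with phase '%s'.", phase))
  }
  missing <- setdiff(subjects, unique(sel$subject))
  if (length(missing) > 0L) {
    abort(sprintf("Phase '%s' is absent for subject(s): %s.",
                  phase, paste(missing, collapse = ", ")))
  }
  feats <- feature_cols(table)
  purrr::map(rlang::set_names(subjects), function(s) {
    rows <- sel[sel$subject == s, , drop = FALSE]
    domain_sample(s, as.matrix(rows[, feats, drop = FALSE]),
                  label_to_int(rows$label))
  })
}

#' Construct a domain sample
#'
#' @param subject_id Subject identifier.
#' @param X N x F numeric feature matrix.
#' @param y Length-N integer label vector in `{0, 1}` (may contain `NA` for
#'   unlabeled rows).
#' @return A `domain_sample` object.
#' @export
domain_sample <- function(subject_id, X, y = rep(NA_integer_, nrow(X))) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) abort("A domain sample needs at least one row.")
  if (length(y) != nrow(X)) abort("`y` length must match rows of `X`.")
  if (!all(is.na(y) | y %in% c(0L, 1L))) abort("Labels must be binary (0/1).")
  structure(list(subject_id = as.character(subject_id), X = X,
                 y = as.integer(y)),
            class = "domain_sample")
}

#' @export
print.domain_sample <- function(x, ...) {
  cat(sprintf("<domain_sample> subject %s: %d x %d, labels: %s\n",
              x$subject_id, nrow(x$X), ncol(x$X),
              if (all(is.na(x$y))) "none" else
                paste(table(factor(x$y, c(0, 1))), collapse = "/")))
  invisible(x)
}

#' Repeated-subsampling protocol
#'
#' The evaluation protocol draws, for each repetition, a fixed number of task
#' epochs per subject-session cell (without replacement) and repeats the
#' whole analysis over several such draws. Repetition `r` uses RNG seed
#' `base_seed + r`, so distinct repetitions see distinct partitions while the
#' full experiment stays reproducible.
#'
#' @param n_per_cell Task rows retained per (subject, session) cell
#'   (default 300).
#' @param n_repetitions Number of independent repetitions (default 30).
#' @param base_seed Base RNG seed (default 10).
#' @return A `sampling_protocol` object.
#' @export
sampling_protocol <- function(n_per_cell = 300L, n_repetitions = 30L,
                              base_seed = 10L) {
  stopifnot_scalar_number(n_per_cell, "n_per_cell", lo = 1)
  stopifnot_scalar_number(n_repetitions, "n_repetitions", lo = 1)
  stopifnot_scalar_number(base_seed, "base_seed")
  structure(list(n_per_cell = as.integer(n_per_cell),
                 n_repetitions = as.integer(n_repetitions),
                 base_seed = as.integer(base_seed)),
            class = "sampling_protocol")
}

#' Subsample task rows per subject-session cell
#'
#' Draws exactly `protocol$n_per_cell` task rows per (subject, session) cell,
#' uniformly without replacement, with seed `base_seed + repetition_index`.
#' Baseline rows pass through unchanged. Within a cell the retained rows keep
#' their original order, so a cell whose size equals `n_per_cell` is returned
#' whole.
#'
#' @param table A feature table.
#' @param protocol A [sampling_protocol()].
#' @param repetition_index Which repetition (1-based) is being drawn.
#' @return A feature table with `n_per_cell` task rows per cell.
#' @export
subsample <- function(table, protocol, repetition_index = 1L) {
  stopifnot(inherits(protocol, "sampling_protocol"))
  task <- which(table$phase == "task")
  cells <- split(task, paste(table$subject[task], table$session[task], sep = "\r"))
  cells <- cells[order(names(cells))]
  n <- protocol$n_per_cell
  undersized <- vapply(cells, length, 1L) < n
  if (any(undersized)) {
    bad <- names(cells)[undersized][1]
    abort(sprintf("Cell (subject=%s, session=%s) has %d task rows, fewer than n_per_cell=%d.",
                  sub("\r.*", "", bad), sub(".*\r", "", bad),
                  length(cells[[bad]]), n))
  }
  keep <- with_seed(protocol$base_seed + as.integer(repetition_index), {
    unlist(purrr::map(cells, function(idx) sort(sample(idx, n))),
           use.names = FALSE)
  })
  keep <- sort(c(keep, which(table$phase != "task")))
  table[keep, , drop = FALSE]
}

#' Split one domain sample into disjoint train and test parts
#'
#' Label-stratified: each class contributes `round(train_fraction * n_class)`
#' rows to the training part. The parts are disjoint and their union is the
#' input.
#'
#' @param domain A `domain_sample` with binary labels.
#' @param train_fraction Fraction of each class assigned to the training
#'   part, in (0, 1). Default 0.5.
#' @param seed RNG seed for the draw.
#' @return A list with elements `train` and `test`, both `domain_sample`s.
#' @export
split_disjoint <- function(domain, train_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(domain, "domain_sample"))
  stopifnot_scalar_number(train_fraction, "train_fraction", lo = 1e-9, hi = 1 - 1e-9)
  if (anyNA(domain$y)) abort("split_disjoint() needs fully labeled domains.")
  counts <- table(factor(domain$y, levels = c(0L, 1L)))
  if (any(counts < 2L)) {
    abort(sprintf("Each class needs >= 2 members to split; got %s.",
                  paste(counts, collapse = "/")))
  }
  idx_train <- with_seed(seed, {
    unlist(purrr::map(c(0L, 1L), function(cl) {
      idx <- which(domain$y == cl)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      sort(sample(idx, n_tr))
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(domain$X)), idx_train)
  list(
    train = domain_sample(domain$subject_id,
                          domain$X[idx_train, , drop = FALSE],
                          domain$y[idx_train]),
    test = domain_sample(domain$subject_id,
                         domain$X[idx_test, , drop = FALSE],
                         domain$y[idx_test])
  )
}
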