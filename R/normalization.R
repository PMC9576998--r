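# Subject-wise feature normalization: x' = (x - beta) / gamma, where beta and
# gamma are the per-feature mean and standard deviation over a reference
# segment of the same subject (task rows for z-score whitening, or one of the
# two baseline recordings).

STRATEGIES <- c("none", "zscore", "baseline1", "baseline2")

strategy_reference_phase <- function(strategy) {
  switch(strategy, zscore = "task", baseline1 = "baseline1",
         baseline2 = "baseline2",
         abort(sprintf("Strategy '%s' has no reference phase.", strategy)))
}

#' Fit per-subject normalization parameters
#'
#' Computes the per-feature sample mean (`beta`) and sample standard
#' deviation (`gamma`, ddof = 1) over one subject's rows in the reference
#' phase. `reference_phase = "task"` gives z-score (whitening) parameters;
#' `"baseline1"` / `"baseline2"` give baseline-referenced parameters.
#' Statistics are never pooled across subjects.
#'
#' @param table A feature table.
#' @param subject Subject id.
#' @param reference_phase One of `"task"`, `"baseline1"`, `"baseline2"`.
#' @param tol Degeneracy tolerance: any `gamma` at or below it is an error
#'   (a zero-variance feature usually means a broken channel). Default 1e-12.
#' @return A `norm_params` object with fields `subject_id`, `beta`, `gamma`.
#' @export
fit_params <- function(table, subject, reference_phase = "task", tol = 1e-12) {
  reference_phase <- rlang::arg_match(reference_phase, PHASES)
  rows <- table[table$subject == subject & table$phase == reference_phase, ,
                drop = FALSE]
  if (nrow(rows) < 2L) {
    abort(sprintf("Subject '%s' has %d row(s) in phase '%s'; need >= 2 to fit normalization parameters.",
                  subject, nrow(rows), reference_phase))
  }
  X <- as.matrix(rows[, feature_cols(table), drop = FALSE])
  beta <- colMeans(X)
  gamma <- apply(X, 2, sd)
  if (any(gamma <= tol)) {
    abort(sprintf("Feature '%s' is degenerate (sd <= %g) for subject '%s' in phase '%s'.",
                  colnames(X)[gamma <= tol][1], tol, subject, reference_phase))
  }
  structure(list(subject_id = as.character(subject), beta = beta,
                 gamma = gamma, reference_phase = reference_phase),
            class = "norm_params")
}

#' Apply a normalization strategy to the task rows of a feature table
#'
#' Transforms every task row with its own subject's parameters,
#' `x' = (x - beta) / gamma`, and drops baseline rows (downstream shift
#' estimators consume task rows only). `strategy = "none"` returns the task
#' rows unchanged.
#'
#' @param table A feature table.
#' @param params Named list of [fit_params()] results keyed by subject
#'   (ignored for `strategy = "none"`).
#' @param strategy One of `"none"`, `"zscore"`, `"baseline1"`, `"baseline2"`.
#' @return A feature table of task rows in the transformed space.
#' @export
apply_normalization <- function(table, params = NULL, strategy = "zscore") {
  strategy <- rlang::arg_match(strategy, STRATEGIES)
  task <- table[table$phase == "task", , drop = FALSE]
  if (strategy == "none") return(task)
  feats <- feature_cols(table)
  subjects <- unique(task$subject)
  missing <- setdiff(subjects, names(params))
  if (length(missing) > 0L) {
    abort(sprintf("No normalization parameters for subject(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  for (s in subjects) {
    p <- params[[s]]
    if (!identical(unname(length(p$beta)), length(feats))) {
      abort(sprintf("Parameter length mismatch for subject '%s'.", s))
    }
    idx <- which(task$subject == s)
    X <- as.matrix(task[idx, feats, drop = FALSE])
    task[idx, feats] <- sweep(sweep(X, 2, p$beta), 2, p$gamma, "/")
  }
  task
}

#' Normalize a feature table with a named strategy
#'
#' Convenience wrapper: fits per-subject parameters from the strategy's
#' reference phase ([fit_params()]) and applies them
#' ([apply_normalization()]).
#'
#' @inheritParams apply_normalization
#' @return A feature table of normalized task rows.
#' @export
normalize_features <- function(table, strategy = "zscore") {
  strategy <- rlang::arg_match(strategy, STRATEGIES)
  if (strategy == "none") return(apply_normalization(table, strategy = "none"))
  ref <- strategy_reference_phase(strategy)
  subjects <- sort(unique(table$subject[table$phase == "task"]))
  params <- purrr::map(rlang::set_names(subjects), fit_params, table = table,
                       reference_phase = ref)
  apply_normalization(table, params, strategy)
}

#' Serialize normalization parameters to JSON
#'
#' @param params Named list of [fit_params()] results keyed by subject.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_norm_params <- function(params, path) {
  out <- purrr::map(params, function(p) {
    list(subject = p$subject_id, reference_phase = p$reference_phase,
         beta = as.list(p$beta), gamma = as.list(p$gamma))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
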