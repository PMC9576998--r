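# Internal helpers shared across modules.

META_COLS <- c("subject", "session", "phase", "label")
PHASES <- c("task", "baseline1", "baseline2")
LABELS <- c("low", "high")

#' Feature column names of a feature table
#'
#' Every column of a feature table that is not one of the metadata columns
#' `subject`, `session`, `phase`, `label` is a feature.
#'
#' @param table A feature table (tibble).
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), META_COLS)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic steps in the package go through this.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

# Derive a child seed from a base seed and one or more small integer tags,
# staying well below .Machine$integer.max.
derive_seed <- function(base, ...) {
  tags <- c(...)
  s <- as.double(base) %% 1000003
  for (t in tags) s <- (s * 69069 + as.double(t)) %% 2147480000
  as.integer(s)
}

# Labels are stored as "low"/"high"; estimators work on 0/1.
label_to_int <- function(label) {
  match(label, LABELS) - 1L
}

int_to_label <- function(y) {
  LABELS[y + 1L]
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lo), format(hi)))
  }
  invisible(x)
}

frobenius <- function(m) sqrt(sum(m^2))
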