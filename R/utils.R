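# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on error types.
stop_kelp <- function(msg, class = "kelptrace_error") {
  rlang::abort(msg, class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_kelp(sprintf("`%s` must be a single finite number", name),
              class = "kelptrace_argument_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_kelp(sprintf("`%s` = %g is outside its valid range", name, x),
              class = "kelptrace_argument_error")
  }
  invisible(x)
}

# Canonical feature order: A-identifiers sorted by numeric suffix (A1..A115).
order_feature_ids <- function(ids) {
  ids[order(as.integer(sub("^A", "", ids)))]
}

# Columns of a cohort tibble that hold feature intensities.
cohort_feature_ids <- function(cohort) {
  setdiff(names(cohort), c("sample_id", "origin"))
}

# Extract the numeric intensity matrix (samples x features) from a cohort.
cohort_matrix <- function(cohort) {
  ids <- cohort_feature_ids(cohort)
  m <- as.matrix(cohort[ids])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$sample_id
  m
}

# Derive stage seeds from one global seed (kept well below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

# Full-precision number formatting for deterministic text artifacts.
format_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
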