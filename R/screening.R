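#' One-way fixed-effects ANOVA
#'
#' Classical one-way analysis of variance across k groups:
#' F = MS_between / MS_within with p from the F distribution on
#' (k - 1, N - k) degrees of freedom. Degenerate inputs follow the
#' conventions: if all values are identical, F = 0 and p = 1; if the
#' within-group mean square is zero while the between-group mean square is
#' positive, F = Inf and p = 0.
#'
#' @param values_by_group A list of numeric vectors, one per group, each with
#'   at least two finite values.
#' @return A one-row tibble: `f_stat`, `p_value`, `ms_between`, `mse`
#'   (within-group mean square), `df_between`, `df_within`, and
#'   `group_means` (list column).
#' @export
#' @examples
#' oneway_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
oneway_anova <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2L) {
    stop_kelp("`values_by_group` must be a list of >= 2 groups",
              class = "kelptrace_argument_error")
  }
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L)) {
    stop_kelp("every group needs at least 2 values",
              class = "kelptrace_argument_error")
  }
  values <- unlist(values_by_group, use.names = FALSE)
  if (any(!is.finite(values))) {
    stop_kelp("non-finite values in ANOVA input",
              class = "kelptrace_argument_error")
  }
  k <- length(values_by_group)
  n <- length(values)
  means <- vapply(values_by_group, mean, numeric(1L))
  grand <- mean(values)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(values_by_group,
                          function(v) sum((v - mean(v))^2), numeric(1L)))
  df_b <- k - 1L
  df_w <- n - k
  ms_b <- ss_between / df_b
  mse <- ss_within / df_w
  if (mse > 0) {
    f <- ms_b / mse
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  } else if (ms_b > 0) {
    f <- Inf
    p <- 0
  } else {
    f <- 0
    p <- 1
  }
  tibble::tibble(
    f_stat = f, p_value = p, ms_between = ms_b, mse = mse,
    df_between = df_b, df_within = df_w, group_means = list(means)
  )
}

# Column-wise one-way ANOVA over an intensity matrix (samples x features).
# Same statistic as oneway_anova(), vectorized across features.
anova_by_feature <- function(mat, labels) {
  groups <- sort(unique(labels))
  k <- length(groups)
  n <- nrow(mat)
  sizes <- vapply(groups, function(g) sum(labels == g), integer(1L))
  if (any(sizes < 2L)) {
    stop_kelp("every origin needs at least 2 samples",
              class = "kelptrace_argument_error")
  }
  group_means <- vapply(groups, function(g) colMeans(mat[labels == g, , drop = FALSE]),
                        numeric(ncol(mat)))  # features x k
  grand <- colMeans(mat)
  ss_between <- as.vector(group_means^2 %*% sizes) - n * grand^2
  ss_total <- colSums(mat^2) - n * grand^2
  ss_within <- pmax(ss_total - ss_between, 0)
  ss_between <- pmax(ss_between, 0)
  df_b <- k - 1L
  df_w <- n - k
  ms_b <- ss_between / df_b
  mse <- ss_within / df_w
  f <- ifelse(mse > 0, ms_b / mse, ifelse(ms_b > 0, Inf, 0))
  p <- ifelse(mse > 0, pf(ms_b / pmax(mse, .Machine$double.xmin), df_b, df_w,
                          lower.tail = FALSE),
              ifelse(ms_b > 0, 0, 1))
  list(f = f, p = p, mse = mse, df_within = df_w,
       group_means = group_means, sizes = sizes, groups = groups)
}

#' Duncan's multiple range test letter grouping
#'
#' Assigns compact letter displays to ranked group means using Duncan's
#' least significant ranges. For a stretch of p adjacent ranked means the
#' critical range is `q(1 - alpha_p, p, df) * sqrt(mse / n_h)` where
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` is Duncan's protection level, `q` the
#' studentized-range quantile, and `n_h` the harmonic mean group size. Two
#' groups share a letter exactly when they are not significantly different
#' (including by containment in a wider non-significant stretch). Letters
#' start at "a" for the largest mean.
#'
#' @param group_means Numeric vector of group means.
#' @param group_sizes Integer vector of group sizes (recycled if length 1).
#' @param mse Within-group mean square from the ANOVA.
#' @param df_within Residual degrees of freedom (> 0).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of letter strings, one per group, in input order.
#' @export
#' @examples
#' duncan_letters(c(8421.3, 5158.9, 4404.3), 30, mse = 300000, df_within = 87)
duncan_letters <- function(group_means, group_sizes, mse, df_within,
                           alpha = 0.05) {
  k <- length(group_means)
  if (df_within <= 0) {
    stop_kelp("`df_within` must be positive", class = "kelptrace_argument_error")
  }
  check_number(mse, "mse", lower = 0)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (length(group_sizes) == 1L) group_sizes <- rep(group_sizes, k)
  if (any(group_sizes < 2L)) {
    stop_kelp("group sizes must be >= 2", class = "kelptrace_argument_error")
  }
  if (k == 1L) return("a")

  n_h <- k / sum(1 / group_sizes)
  ranges <- vapply(2:k, function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    qtukey(1 - alpha_p, p, df_within) * sqrt(mse / n_h)
  }, numeric(1L))

  ord <- order(group_means, decreasing = TRUE)
  m <- group_means[ord]

  # direct non-significance of the stretch [i, j], then closure under
  # containment (a pair inside a non-significant stretch is non-significant)
  ns <- diag(TRUE, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      ns[i, j] <- (m[i] - m[j]) <= ranges[j - i]
    }
  }
  covered <- function(i, j) {
    for (a in seq_len(i)) for (b in seq(j, k)) if (ns[a, b]) return(TRUE)
    FALSE
  }

  # maximal non-significant stretches, top-down, become the letters
  letter_sets <- rep("", k)
  next_letter <- 1L
  j_prev <- 0L
  for (i in seq_len(k)) {
    j <- i
    while (j < k && covered(i, j + 1L)) j <- j + 1L
    if (j > j_prev) {  # not contained in the previous stretch
      lab <- letters[next_letter]
      next_letter <- next_letter + 1L
      for (g in i:j) letter_sets[g] <- paste0(letter_sets[g], lab)
      j_prev <- j
    }
  }
  out <- character(k)
  out[ord] <- letter_sets
  out
}

#' Screen VOC features by one-way ANOVA across origins
#'
#' Runs a per-feature one-way ANOVA of signal intensity across the three
#' origins, assigns Duncan letter groupings, and selects the features with
#' p < `alpha` (strict inequality, no multiple-testing correction by
#' default, mirroring per-feature significance reporting). An optional
#' Benjamini-Hochberg correction is available via `p_adjust = "BH"`.
#'
#' Statistics are computed on the full cohort, before any train/test
#' splitting; screen on a training subset instead if leakage-free selection
#' is wanted (pass `stratified_split()$train`).
#'
#' @param cohort A `voc_cohort` tibble (see [generate_cohort()]).
#' @param alpha Selection level; features with p < `alpha` are kept.
#' @param p_adjust Either `"none"` (default) or `"BH"`.
#' @return An object of class `voc_screen`: a list with `results` (per-feature
#'   tibble of F, p, mse, df, per-origin means and Duncan letters),
#'   `selected_ids` (canonical order), `alpha`, `p_adjust`, and `cohort`
#'   (the input reduced to the selected feature columns).
#' @export
#' @examples
#' sc <- screen_features(generate_cohort(voc_reference(), seed = 1))
#' length(sc$selected_ids)
screen_features <- function(cohort, alpha = 0.05, p_adjust = c("none", "BH")) {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  p_adjust <- match.arg(p_adjust)
  mat <- cohort_matrix(cohort)
  if (any(!is.finite(mat))) {
    stop_kelp("cohort intensities must be finite",
              class = "kelptrace_argument_error")
  }
  an <- anova_by_feature(mat, cohort$origin)

  letters_by_feature <- t(vapply(seq_len(ncol(mat)), function(j) {
    duncan_letters(an$group_means[j, ], an$sizes, an$mse[j], an$df_within,
                   alpha = if (alpha > 0 && alpha < 1) alpha else 0.05)
  }, character(length(an$groups))))

  p_sel <- if (p_adjust == "BH") stats::p.adjust(an$p, method = "BH") else an$p
  origin_names <- names(.kelp_origins)[match(an$groups, .kelp_origins)]
  results <- tibble::tibble(
    feature_id = colnames(mat),
    f_stat = unname(an$f),
    p_value = unname(an$p),
    p_selected = unname(p_sel),
    mse = unname(an$mse),
    df_within = an$df_within
  )
  for (i in seq_along(origin_names)) {
    results[[paste0("mean_", origin_names[i])]] <- an$group_means[, i]
    results[[paste0("letter_", origin_names[i])]] <- letters_by_feature[, i]
  }
  selected <- results$feature_id[p_sel < alpha]
  selected <- order_feature_ids(selected)
  reduced <- cohort[, c("sample_id", "origin", selected), drop = FALSE]
  class(reduced) <- class(cohort)

  structure(
    list(results = results, selected_ids = selected, alpha = alpha,
         p_adjust = p_adjust, cohort = reduced,
         screened_on = "full cohort (pre-split)"),
    class = "voc_screen"
  )
}

#' @export
print.voc_screen <- function(x, ...) {
  cat(sprintf("VOC screening: %d / %d features selected at p < %g (%s)\n",
              length(x$selected_ids), nrow(x$results), x$alpha,
              if (x$p_adjust == "none") "unadjusted" else x$p_adjust))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a screening report
#' @param x A `voc_screen` object.
#' @param ... Unused.
#' @return The per-feature results tibble with a `selected` logical column.
#' @method tidy voc_screen
#' @export
tidy.voc_screen <- function(x, ...) {
  dplyr::mutate(x$results, selected = .data$feature_id %in% x$selected_ids)
}

#' One-row summary of a screening report
#' @param x A `voc_screen` object.
#' @param ... Unused.
#' @method glance voc_screen
#' @export
glance.voc_screen <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$results),
    n_selected = length(x$selected_ids),
    alpha = x$alpha,
    p_adjust = x$p_adjust,
    n_samples = nrow(x$cohort)
  )
}

#' Serialize a screening report
#'
#' Writes the per-feature table as TSV and a JSON summary (alpha, selection
#' count, selected identifiers).
#'
#' @param screen A `voc_screen` object.
#' @param tsv_path,json_path Output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_screen_report <- function(screen, tsv_path, json_path) {
  readr::write_tsv(tidy(screen), tsv_path, progress = FALSE)
  jsonlite::write_json(
    list(alpha = screen$alpha, p_adjust = screen$p_adjust,
         n_selected = length(screen$selected_ids),
         selected_ids = screen$selected_ids),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(tsv_path)
}
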