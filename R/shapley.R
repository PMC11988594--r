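# Shapley attribution over a masking value function.
#
# The coalition game is played on a single trained model: features in the
# coalition S take the explained sample's values, features outside S are
# filled from a background (reference) dataset, and v(S) is the model's
# expected class-probability output over the background fill-ins. This is
# the interventional expectation commonly used to explain fixed models; no
# retraining per coalition is involved. v(empty) is the base value (the
# model's mean output over the background) and v(F) recovers the model's
# prediction, so attributions satisfy the efficiency axiom.

# Accept a kelp_cnn or any function mapping an input matrix to an output
# matrix (rows = samples, columns = classes).
as_predictor <- function(model) {
  if (inherits(model, "kelp_cnn")) {
    return(function(x) cnn_forward(model, x))
  }
  if (is.function(model)) {
    return(function(x) {
      out <- model(x)
      if (is.vector(out)) out <- matrix(out, nrow = nrow(x))
      out
    })
  }
  stop_kelp("`model` must be a kelp_cnn or a prediction function",
            class = "kelptrace_argument_error")
}

normalize_background <- function(background, d,
                                 mode = c("sample-average", "mean-vector")) {
  mode <- match.arg(mode)
  if (is.data.frame(background)) {
    background <- cohort_matrix(background)
  }
  if (is.vector(background)) background <- matrix(background, nrow = 1L)
  if (nrow(background) == 0L) {
    stop_kelp("background must contain at least one reference sample",
              class = "kelptrace_argument_error")
  }
  if (ncol(background) != d) {
    stop_kelp(sprintf("background has %d features; expected %d",
                      ncol(background), d),
              class = "kelptrace_argument_error")
  }
  if (mode == "mean-vector") {
    background <- matrix(colMeans(background), nrow = 1L,
                         dimnames = list(NULL, colnames(background)))
  }
  background
}

# Evaluate v(S) for many coalitions at once. `masks` is n_coal x m logical
# over the active feature indices; inactive features always keep background
# values. Returns an n_coal x K matrix of background-averaged outputs.
eval_coalitions <- function(predict_fun, x, masks, active, background,
                            chunk_rows = 30000L) {
  nb <- nrow(background)
  n_coal <- nrow(masks)
  per_chunk <- max(1L, chunk_rows %/% nb)
  out <- NULL
  for (start in seq(1L, n_coal, by = per_chunk)) {
    idx <- start:min(start + per_chunk - 1L, n_coal)
    big <- background[rep(seq_len(nb), times = length(idx)), , drop = FALSE]
    for (ii in seq_along(idx)) {
      on <- active[masks[idx[ii], ]]
      if (length(on) > 0L) {
        rows <- ((ii - 1L) * nb + 1L):(ii * nb)
        big[rows, on] <- matrix(x[on], nrow = nb, ncol = length(on), byrow = TRUE)
      }
    }
    pred <- predict_fun(big)
    v <- rowsum(pred, group = rep(seq_along(idx), each = nb)) / nb
    out <- rbind(out, v)
  }
  out
}

#' Masking value function for Shapley games
#'
#' Evaluates v(S): the model's expected output when features in `S` take the
#' explained sample's values and all other features are filled in from the
#' background. With `S` equal to the full feature set this is exactly the
#' model's prediction for `x`; with `S` empty it is the base value.
#'
#' @param model A `kelp_cnn` or a function mapping an input matrix to an
#'   output matrix.
#' @param x A single input vector.
#' @param S Integer vector of 1-based feature indices in the coalition (may
#'   be empty).
#' @param background Reference samples: a matrix, cohort tibble, or single
#'   vector.
#' @param mode `"sample-average"` (average masked predictions over all
#'   background rows; default) or `"mean-vector"` (collapse the background
#'   to its column means first).
#' @return A numeric vector with one expected output per model class.
#' @export
shap_value_function <- function(model, x, S, background,
                                mode = c("sample-average", "mean-vector")) {
  d <- length(x)
  if (length(S) > 0L && (any(S < 1L) || any(S > d))) {
    stop_kelp("coalition indices out of range", class = "kelptrace_argument_error")
  }
  bg <- normalize_background(background, d, mode)
  mask <- matrix(seq_len(d) %in% S, nrow = 1L)
  drop(eval_coalitions(as_predictor(model), x, mask, seq_len(d), bg))
}

shap_resolve_features <- function(features, d, feature_names) {
  if (is.null(features)) return(seq_len(d))
  if (is.character(features)) {
    if (is.null(feature_names)) {
      stop_kelp("named features given but the input has no feature names",
                class = "kelptrace_argument_error")
    }
    idx <- match(features, feature_names)
    if (anyNA(idx)) {
      stop_kelp(sprintf("unknown feature '%s'", features[is.na(idx)][1L]),
                class = "kelptrace_argument_error")
    }
    return(idx)
  }
  features <- as.integer(features)
  if (any(features < 1L) || any(features > d)) {
    stop_kelp("feature indices out of range", class = "kelptrace_argument_error")
  }
  features
}

shap_new <- function(phi, base_values, residual_raw, method, mode,
                     feature_ids, sample_ids, feature_values, class_names,
                     n_perm = NA_integer_, seed = NA_integer_) {
  structure(
    list(phi = phi, base_values = base_values, residual_raw = residual_raw,
         method = method, mode = mode, feature_ids = feature_ids,
         sample_ids = sample_ids, feature_values = feature_values,
         class_names = class_names, n_perm = n_perm, seed = seed),
    class = "kelp_shap"
  )
}

#' Exact Shapley values by subset enumeration
#'
#' Computes, for every active feature i and class c, the exact Shapley value
#' `phi_i = sum over S subset of F\\{i} of |S|!(|F|-|S|-1)!/|F|! *
#' (v(S + i) - v(S))` with v the masking value function. Enumeration costs
#' 2^|F| coalition evaluations, so at most 15 active features are allowed;
#' features outside `features` are permanently held at background values
#' (treated as absent from the game).
#'
#' @param model A `kelp_cnn` or prediction function.
#' @param x A single input vector, or a matrix of inputs (one row per
#'   explained sample).
#' @param background Reference samples (matrix, cohort tibble, or vector).
#' @param features Active features: integer indices or feature names;
#'   default all (requires input length <= 15).
#' @param mode Background mode, see [shap_value_function()].
#' @return An object of class `kelp_shap`: `phi` is an array
#'   (samples x active features x classes) in probability units;
#'   `base_values` the per-class value of the empty coalition;
#'   `residual_raw` the per-(sample, class) additivity residual
#'   |v(F) - base - sum(phi)| (below 1e-9 for this exact method).
#' @export
shap_exact <- function(model, x, background, features = NULL,
                       mode = c("sample-average", "mean-vector")) {
  mode <- match.arg(mode)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  d <- ncol(x)
  active <- shap_resolve_features(features, d, colnames(x))
  m <- length(active)
  if (m > 15L) {
    stop_kelp(paste0("exact enumeration over ", m, " features needs 2^", m,
                     " evaluations; use shap_permutation() for wide inputs"),
              class = "kelptrace_argument_error")
  }
  bg <- normalize_background(background, d, mode)
  predict_fun <- as_predictor(model)

  n_coal <- 2L^m
  coal_int <- 0:(n_coal - 1L)
  masks <- vapply(seq_len(m),
                  function(j) bitwAnd(coal_int, 2L^(j - 1L)) > 0L,
                  logical(n_coal))
  if (m == 1L) masks <- matrix(masks, ncol = 1L)
  sizes <- rowSums(masks)
  # Shapley kernel weights by coalition size, via lgamma for stability
  w_by_size <- exp(lgamma(0:(m - 1L) + 1) + lgamma(m - (0:(m - 1L))) - lgamma(m + 1))

  n_samples <- nrow(x)
  v1 <- eval_coalitions(predict_fun, x[1L, ], masks, active, bg)
  n_class <- ncol(v1)
  phi <- array(0, dim = c(n_samples, m, n_class))
  residual <- matrix(0, n_samples, n_class)
  base_values <- unname(v1[1L, ])

  for (s in seq_len(n_samples)) {
    v <- if (s == 1L) v1 else eval_coalitions(predict_fun, x[s, ], masks, active, bg)
    for (j in seq_len(m)) {
      idx0 <- which(!masks[, j])
      idx1 <- idx0 + 2L^(j - 1L)
      wts <- w_by_size[sizes[idx0] + 1L]
      phi[s, j, ] <- crossprod(v[idx1, , drop = FALSE] - v[idx0, , drop = FALSE], wts)
    }
    residual[s, ] <- abs(v[n_coal, ] - v[1L, ] - apply(phi[s, , , drop = FALSE], 3L, sum))
  }

  shap_new(phi, base_values, residual,
           method = "exact", mode = mode,
           feature_ids = if (!is.null(colnames(x))) colnames(x)[active] else
             paste0("f", active),
           sample_ids = if (!is.null(rownames(x))) rownames(x) else
             paste0("sample_", seq_len(n_samples)),
           feature_values = x[, active, drop = FALSE],
           class_names = names(.kelp_origins)[seq_len(n_class)])
}

# All permutations of 1..m (m small), one per row, by inserting m into
# every slot of each permutation of 1..(m-1).
all_permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, m * nrow(sub), m)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(m)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], m, after = pos - 1L)
    }
  }
  out
}

#' Shapley values by antithetic permutation sampling
#'
#' Unbiased Monte-Carlo estimator of the Shapley values: marginal
#' contributions `v(pre + i) - v(pre)` are averaged over seeded uniformly
#' random feature orderings, each sampled permutation being paired with its
#' reverse (antithetic sampling, which removes half the variance of the
#' ordering draw). When the active set is small enough that `n_perm` covers
#' all `|F|!` orderings, the full deduplicated enumeration is used and the
#' estimate is exact. Because marginal contributions telescope along each
#' ordering, the raw estimate already satisfies additivity up to floating
#' error; any residual is folded back proportionally to |phi| and the raw
#' residual is reported.
#'
#' @inheritParams shap_exact
#' @param n_perm Number of sampled permutations (each also contributes its
#'   reverse).
#' @param seed Integer seed for the permutation draw.
#' @return A `kelp_shap` object; see [shap_exact()].
#' @export
shap_permutation <- function(model, x, background, n_perm = 10L, seed = NULL,
                             features = NULL,
                             mode = c("sample-average", "mean-vector")) {
  mode <- match.arg(mode)
  check_number(n_perm, "n_perm", lower = 1)
  n_perm <- as.integer(n_perm)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  d <- ncol(x)
  active <- shap_resolve_features(features, d, colnames(x))
  m <- length(active)
  bg <- normalize_background(background, d, mode)
  predict_fun <- as_predictor(model)

  if (!is.null(seed)) set.seed(as.integer(seed))
  exhaustive <- m <= 6L && n_perm >= factorial(m)
  orderings <- if (exhaustive) {
    all_permutations(m)
  } else {
    sampled <- t(vapply(seq_len(n_perm), function(i) sample.int(m),
                        integer(m)))
    if (m == 1L) sampled <- matrix(sampled, ncol = 1L)
    rbind(sampled, sampled[, rev(seq_len(m)), drop = FALSE])
  }
  n_ord <- nrow(orderings)

  # prefix coalitions for every ordering: rows o*(m+1) + t
  masks <- matrix(FALSE, n_ord * (m + 1L), m)
  for (o in seq_len(n_ord)) {
    r0 <- (o - 1L) * (m + 1L)
    for (t in seq_len(m)) {
      masks[r0 + t + 1L, ] <- masks[r0 + t, ]
      masks[r0 + t + 1L, orderings[o, t]] <- TRUE
    }
  }

  n_samples <- nrow(x)
  phi <- NULL
  base_values <- NULL
  residual <- NULL
  for (s in seq_len(n_samples)) {
    v <- eval_coalitions(predict_fun, x[s, ], masks, active, bg)
    n_class <- ncol(v)
    if (is.null(phi)) {
      phi <- array(0, dim = c(n_samples, m, n_class))
      residual <- matrix(0, n_samples, n_class)
      base_values <- unname(v[1L, ])
    }
    marg <- matrix(0, m, n_class)
    for (o in seq_len(n_ord)) {
      r0 <- (o - 1L) * (m + 1L)
      dv <- v[r0 + 1L + seq_len(m), , drop = FALSE] -
        v[r0 + seq_len(m), , drop = FALSE]
      marg[orderings[o, ], ] <- marg[orderings[o, ], , drop = FALSE] + dv
    }
    ph <- marg / n_ord
    v_full <- v[m + 1L, ]
    res <- v_full - v[1L, ] - colSums(ph)
    residual[s, ] <- abs(res)
    for (cl in seq_len(n_class)) {
      tot <- sum(abs(ph[, cl]))
      ph[, cl] <- ph[, cl] + if (tot > 0) res[cl] * abs(ph[, cl]) / tot else
        res[cl] / m
    }
    phi[s, , ] <- ph
  }

  shap_new(phi, base_values, residual,
           method = if (exhaustive) "permutation-exhaustive" else "permutation",
           mode = mode,
           feature_ids = if (!is.null(colnames(x))) colnames(x)[active] else
             paste0("f", active),
           sample_ids = if (!is.null(rownames(x))) rownames(x) else
             paste0("sample_", seq_len(n_samples)),
           feature_values = x[, active, drop = FALSE],
           class_names = names(.kelp_origins)[seq_len(if (is.null(phi)) 0L else dim(phi)[3L])],
           n_perm = n_perm,
           seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @export
print.kelp_shap <- function(x, ...) {
  dims <- dim(x$phi)
  cat(sprintf("Shapley explanation (%s, %s background): %d sample(s) x %d feature(s) x %d class(es)\n",
              x$method, x$mode, dims[1L], dims[2L], dims[3L]))
  cat(sprintf("base values: %s; max additivity residual %.3g\n",
              paste(sprintf("%.4f", x$base_values), collapse = ", "),
              max(x$residual_raw)))
  invisible(x)
}

#' Global feature importance from an explanation
#'
#' Mean absolute Shapley value per feature and class over the explained
#' samples, plus the class-stacked total used for global ranking.
#'
#' @param expl A `kelp_shap` object.
#' @param top_n Optionally keep only the strongest `top_n` features.
#' @return A tibble: `feature_id`, one `mean_abs_<class>` column per class,
#'   `stacked`, and `rank` (1 = most important; ties keep feature order).
#' @export
shap_importance <- function(expl, top_n = NULL) {
  per_class <- apply(abs(expl$phi), c(2L, 3L), mean)
  if (is.null(dim(per_class))) per_class <- matrix(per_class, nrow = 1L)
  out <- tibble::tibble(feature_id = expl$feature_ids)
  for (cl in seq_along(expl$class_names)) {
    out[[paste0("mean_abs_", expl$class_names[cl])]] <- per_class[, cl]
  }
  out$stacked <- rowSums(per_class)
  out <- out[order(-out$stacked), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Local (force-plot) explanation of one prediction
#'
#' @param expl A `kelp_shap` object.
#' @param sample Sample index or id.
#' @param class Class index (1-based) or origin name.
#' @return A list of class `shap_force`: `base_value` (mean model output for
#'   the class over the background), `output` (base + sum of contributions),
#'   `contributions` (tibble sorted by |phi|, with the raw feature values),
#'   and bookkeeping fields.
#' @export
shap_local <- function(expl, sample = 1L, class = 1L) {
  if (is.character(sample)) sample <- match(sample, expl$sample_ids)
  if (is.character(class)) class <- match(class, expl$class_names)
  dims <- dim(expl$phi)
  if (is.na(sample) || sample < 1L || sample > dims[1L] ||
      is.na(class) || class < 1L || class > dims[3L]) {
    stop_kelp("invalid sample or class index", class = "kelptrace_argument_error")
  }
  phi <- expl$phi[sample, , class]
  contributions <- tibble::tibble(
    feature_id = expl$feature_ids,
    value = expl$feature_values[sample, ],
    phi = phi
  )
  contributions <- contributions[order(-abs(contributions$phi)), , drop = FALSE]
  structure(
    list(base_value = unname(expl$base_values[class]),
         output = unname(expl$base_values[class] + sum(phi)),
         contributions = contributions,
         sample_id = expl$sample_ids[sample],
         class_name = expl$class_names[class],
         residual_raw = expl$residual_raw[sample, class]),
    class = "shap_force"
  )
}

#' @export
print.shap_force <- function(x, ...) {
  cat(sprintf("%s | class %s: base %.4f -> output %.4f (%s base)\n",
              x$sample_id, x$class_name, x$base_value, x$output,
              if (x$output >= x$base_value) "right of" else "left of"))
  print(head(x$contributions, 5L))
  invisible(x)
}

#' Long-form Shapley values
#' @param x A `kelp_shap` object.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `class`, `feature_id`, `value`, `phi`.
#' @method tidy kelp_shap
#' @export
tidy.kelp_shap <- function(x, ...) {
  dims <- dim(x$phi)  # samples x features x classes
  n <- dims[1L]; m <- dims[2L]; k <- dims[3L]
  # row order: sample slowest, class middle, feature fastest
  s_idx <- rep(seq_len(n), each = k * m)
  f_idx <- rep(rep(seq_len(m), times = k), times = n)
  tibble::tibble(
    sample_id = x$sample_ids[s_idx],
    class = x$class_names[rep(rep(seq_len(k), each = m), times = n)],
    feature_id = x$feature_ids[f_idx],
    value = x$feature_values[cbind(s_idx, f_idx)],
    phi = as.vector(aperm(x$phi, c(2L, 3L, 1L)))
  )
}

#' One-row explanation summary
#' @param x A `kelp_shap` object.
#' @param ... Unused.
#' @method glance kelp_shap
#' @export
glance.kelp_shap <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    mode = x$mode,
    n_samples = dim(x$phi)[1L],
    n_features = dim(x$phi)[2L],
    n_classes = dim(x$phi)[3L],
    n_perm = x$n_perm,
    max_residual = max(x$residual_raw)
  )
}

#' Serialize an explanation
#'
#' Writes the long-form phi table as TSV plus a JSON header (method, seed,
#' permutations, base values, residuals).
#'
#' @param expl A `kelp_shap` object.
#' @param tsv_path,json_path Output paths.
#' @export
write_explanation <- function(expl, tsv_path, json_path) {
  readr::write_tsv(tidy(expl), tsv_path, progress = FALSE)
  jsonlite::write_json(
    list(method = expl$method, mode = expl$mode, n_perm = expl$n_perm,
         seed = expl$seed, base_values = as.list(
           setNames(expl$base_values, expl$class_names)),
         max_residual_raw = max(expl$residual_raw),
         top_stacked_features = shap_importance(expl, top_n = 5L)$feature_id),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(tsv_path)
}
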