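#' Generate a synthetic labeled cohort from reference distributions
#'
#' Draws a cohort of kelp samples whose per-feature, per-origin intensity
#' distributions match the reference table: for origin o and feature j,
#' `n_per_origin` values are drawn independently from
#' Normal(mean\[o, j\], (sd_scale * sd\[o, j\])^2). By default negative draws
#' are kept: truncating at zero would bias the realized means of the
#' wide-dispersion features upward (several have mean/SD near 0.5) and
#' distort the published significance pattern; set `clip_at_zero = TRUE` to
#' force physical non-negativity instead. Features are sampled
#' independently because the reference reports only marginal moments; real
#' GC-IMS monomer/dimer intensities covary, which this generator does not
#' emulate.
#'
#' @param ref A `voc_reference` tibble (see [voc_reference()]).
#' @param n_per_origin Samples per origin (default 30, the study cohort size).
#' @param seed Integer seed; fixed seeds give bit-identical cohorts.
#' @param clip_at_zero Clip negative draws to 0 (default `FALSE`;
#'   see Details).
#' @param sd_scale Positive multiplier on every SD, for stress-testing
#'   separability (default 1).
#' @param covariance Optional hook for correlated features: a full
#'   features x features covariance matrix (intensity units squared), or a
#'   named list of one matrix per origin (`rongcheng`, `dalian`, `xiapu`).
#'   When supplied, each origin's samples are drawn from a multivariate
#'   Normal with the reference means and this covariance (scaled by
#'   `sd_scale^2`), replacing the per-feature independent SDs. No covariance
#'   ships with the package — the reference table reports marginals only.
#'
#' @return A tibble of class `voc_cohort`: columns `sample_id`, `origin`
#'   (integer code 0 = Rongcheng, 1 = Dalian, 2 = Xiapu) and one numeric
#'   column per feature in canonical A1..A115 order.
#' @export
#' @examples
#' cohort <- generate_cohort(voc_reference(), seed = 1)
#' dim(cohort)
generate_cohort <- function(ref, n_per_origin = 30L, seed = NULL,
                            clip_at_zero = FALSE, sd_scale = 1,
                            covariance = NULL) {
  check_number(n_per_origin, "n_per_origin", lower = 2)
  check_number(sd_scale, "sd_scale", lower = 0, strict_lower = TRUE)
  n_per_origin <- as.integer(n_per_origin)
  stats_long <- origin_stats(ref)
  ids <- order_feature_ids(unique(stats_long$feature_id))

  if (!is.null(seed)) {
    check_number(seed, "seed")
    set.seed(as.integer(seed))
  }

  blocks <- lapply(names(.kelp_origins), function(o) {
    so <- stats_long[stats_long$origin == o, , drop = FALSE]
    so <- so[match(ids, so$feature_id), , drop = FALSE]
    if (anyNA(so$mean)) {
      stop_kelp(sprintf("reference is missing (feature, origin) entries for '%s'", o),
                class = "kelptrace_validation_error")
    }
    sigma_o <- if (is.null(covariance)) NULL else
      if (is.list(covariance)) covariance[[o]] else covariance
    if (is.null(sigma_o)) {
      # column-by-column in canonical order so draws are seed-stable
      m <- vapply(seq_along(ids), function(j) {
        rnorm(n_per_origin, mean = so$mean[j], sd = sd_scale * so$sd[j])
      }, numeric(n_per_origin))
    } else {
      if (!is.matrix(sigma_o) || any(dim(sigma_o) != length(ids))) {
        stop_kelp(sprintf("covariance for origin '%s' must be a %d x %d matrix",
                          o, length(ids), length(ids)),
                  class = "kelptrace_argument_error")
      }
      rlang::check_installed("MASS", reason = "for covariance-structured cohorts")
      m <- MASS::mvrnorm(n_per_origin, mu = so$mean,
                         Sigma = sd_scale^2 * sigma_o)
      if (n_per_origin == 1L) m <- matrix(m, nrow = 1L)
    }
    if (clip_at_zero) m[m < 0] <- 0
    m
  })

  mat <- do.call(rbind, blocks)
  colnames(mat) <- ids
  origin <- rep(unname(.kelp_origins), each = n_per_origin)
  sample_id <- sprintf("%s_%02d", rep(names(.kelp_origins), each = n_per_origin),
                       rep(seq_len(n_per_origin), times = 3L))
  cohort <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id, origin = origin),
    tibble::as_tibble(mat)
  )
  class(cohort) <- c("voc_cohort", class(tibble::tibble()))
  cohort
}

#' Write / read a cohort table
#'
#' Cohorts are stored as delimited text: `sample_id`, `origin` (0/1/2), then
#' one column per feature. Write-then-read round-trips the cohort exactly
#' (values are written with 17 significant digits).
#'
#' @param cohort A `voc_cohort` tibble.
#' @param path Output path (`.tsv` for tabs, otherwise comma-separated).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a `voc_cohort` tibble.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (j in cohort_feature_ids(cohort)) {
    out[[j]] <- vapply(out[[j]], format_num, character(1L))
  }
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_kelp(sprintf("cohort file not found: '%s'", path),
              class = "kelptrace_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE
  )
  if (!all(c("sample_id", "origin") %in% names(raw))) {
    stop_kelp("cohort file must start with 'sample_id' and 'origin' columns",
              class = "kelptrace_validation_error")
  }
  feat_cols <- setdiff(names(raw), c("sample_id", "origin"))
  cohort <- tibble::tibble(sample_id = raw$sample_id)
  origin_num <- suppressWarnings(as.numeric(raw$origin))
  if (anyNA(origin_num) || !all(origin_num %in% .kelp_origins)) {
    bad <- which(is.na(origin_num) | !(origin_num %in% .kelp_origins))[1L]
    stop_kelp(sprintf("invalid origin label at data row %d", bad),
              class = "kelptrace_validation_error")
  }
  cohort$origin <- as.integer(origin_num)
  for (j in feat_cols) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v)) {
      stop_kelp(sprintf("non-numeric cell at data row %d, column '%s'",
                        which(is.na(v))[1L], j),
                class = "kelptrace_validation_error")
    }
    cohort[[j]] <- v
  }
  class(cohort) <- c("voc_cohort", class(tibble::tibble()))
  cohort
}
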