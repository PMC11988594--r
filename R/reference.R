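#' Read and validate a GC-IMS VOC reference table
#'
#' Reads a delimited table of VOC features with per-origin signal-intensity
#' statistics (mean, standard deviation, Duncan letter for each of Rongcheng,
#' Dalian and Xiapu), an ANOVA p-value per feature, and compound annotations
#' (name, monomer/dimer form, chemical class, retention index, retention
#' time, drift time, odor descriptors). The table drives everything
#' downstream: the synthetic cohort generator draws from its per-origin
#' distributions and the screening stage reproduces its significance calls.
#'
#' Two cell layouts are accepted for the intensity statistics: split columns
#' (`mean_rongcheng`, `sd_rongcheng`, `letter_rongcheng`, ...) or combined
#' cells (`rongcheng` etc.) of the form `"8421.3 ± 728.6 ^a^"` which are
#' split on read. p-values printed as a bound (`"<0.001"`) are stored with
#' `p_value` set to half the bound and the bound kept in `p_below`;
#' significance comparisons always use the bound, never the placeholder.
#'
#' @param path Path to a tab- or comma-separated file (delimiter sniffed from
#'   the header line).
#' @param strict If `TRUE` (default), enforce the full reference contract:
#'   feature identifiers exactly cover A1..A115 and exactly 19 features are
#'   unidentified. Set to `FALSE` to load partial or user-modified tables
#'   (distributional invariants are still checked).
#'
#' @return A tibble of class `voc_reference` with one row per feature, in
#'   canonical A-identifier order, and columns `feature_id`, `compound_name`,
#'   `form`, `chem_class`, `ri`, `rt_sec`, `dt_au`,
#'   `mean_*`/`sd_*`/`letter_*` for the three origins, `p_value`, `p_below`
#'   and `odor_description`.
#' @seealso [voc_reference()] for the curated table shipped with the package,
#'   [summarize_voc_classes()], [count_significant()], [generate_cohort()].
#' @export
read_voc_reference <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop_kelp(sprintf("reference table not found: '%s'", path),
              class = "kelptrace_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE
  )
  names(raw) <- tolower(names(raw))

  required <- c("feature_id", "compound_name", "form", "chem_class", "p_value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop_kelp(paste0("reference table is missing columns: ",
                     paste(missing_cols, collapse = ", ")),
              class = "kelptrace_validation_error")
  }

  tab <- tibble::tibble(
    feature_id = raw$feature_id,
    compound_name = raw$compound_name,
    form = raw$form,
    chem_class = raw$chem_class,
    ri = parse_num(raw[["ri"]], "ri"),
    rt_sec = parse_num(raw[["rt_sec"]], "rt_sec"),
    dt_au = parse_num(raw[["dt_au"]], "dt_au")
  )

  for (o in names(.kelp_origins)) {
    split_cols <- paste0(c("mean_", "sd_", "letter_"), o)
    if (all(split_cols %in% names(raw))) {
      tab[[paste0("mean_", o)]] <- parse_num(raw[[split_cols[1L]]], split_cols[1L])
      tab[[paste0("sd_", o)]] <- parse_num(raw[[split_cols[2L]]], split_cols[2L])
      tab[[paste0("letter_", o)]] <- raw[[split_cols[3L]]]
    } else if (o %in% names(raw)) {
      parsed <- parse_mean_sd_cells(raw[[o]], raw$feature_id)
      tab[[paste0("mean_", o)]] <- parsed$mean
      tab[[paste0("sd_", o)]] <- parsed$sd
      tab[[paste0("letter_", o)]] <- parsed$letter
    } else {
      stop_kelp(sprintf("no intensity columns found for origin '%s'", o),
                class = "kelptrace_validation_error")
    }
  }

  p <- parse_p_values(raw$p_value, raw$feature_id)
  tab$p_value <- p$value
  tab$p_below <- p$below
  tab$odor_description <- if ("odor_description" %in% names(raw)) {
    raw$odor_description
  } else {
    rep("", nrow(raw))
  }

  tab <- tab[order(as.integer(sub("^A", "", tab$feature_id))), , drop = FALSE]
  validate_voc_reference(tab, strict = strict)
  class(tab) <- c("voc_reference", class(tibble::tibble()))
  tab
}

#' The curated kelp VOC reference table
#'
#' Loads the table shipped with the package: 115 VOC features measured by
#' GC-IMS in dried kelp from Rongcheng, Dalian and Xiapu (n = 30 per city),
#' with per-origin signal-intensity mean and standard deviation, Duncan
#' letter groupings, per-feature ANOVA p-values and odor descriptors.
#'
#' @return A `voc_reference` tibble with 115 rows; see [read_voc_reference()].
#' @export
#' @examples
#' ref <- voc_reference()
#' nrow(ref)
voc_reference <- function() {
  read_voc_reference(
    system.file("extdata", "kelp_voc_reference.tsv", package = "kelptrace",
                mustWork = TRUE)
  )
}

#' Write a VOC reference table to a delimited file
#'
#' Inverse of [read_voc_reference()]: writes the split-column layout;
#' below-threshold p-values are written back as bounds (e.g. `"<0.001"`) so
#' that write-then-read round-trips exactly.
#'
#' @param ref A `voc_reference` tibble.
#' @param path Output path; `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_voc_reference <- function(ref, path) {
  out <- as.data.frame(ref)
  out$p_value <- ifelse(is.na(ref$p_below),
                        vapply(ref$p_value, format_num, character(1L)),
                        paste0("<", vapply(ref$p_below, format_num, character(1L))))
  out$p_below <- NULL
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}

parse_num <- function(x, col) {
  if (is.null(x)) return(NA_real_)
  x[x == ""] <- NA_character_
  bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
  if (any(bad)) {
    stop_kelp(sprintf("non-numeric value '%s' in column '%s'", x[bad][1L], col),
              class = "kelptrace_validation_error")
  }
  as.numeric(x)
}

# Split "mean ± sd ^letter^" cells (the layout printed in GC-IMS reports).
parse_mean_sd_cells <- function(cells, ids) {
  pat <- "^\\s*([0-9]*\\.?[0-9]+)\\s*±\\s*([0-9]*\\.?[0-9]+)\\s*\\^?([a-z]*)\\^?\\s*$"
  ok <- grepl(pat, cells)
  if (any(!ok)) {
    stop_kelp(sprintf("unparseable mean ± SD cell '%s' (feature %s)",
                      cells[!ok][1L], ids[!ok][1L]),
              class = "kelptrace_validation_error")
  }
  list(
    mean = as.numeric(sub(pat, "\\1", cells)),
    sd = as.numeric(sub(pat, "\\2", cells)),
    letter = sub(pat, "\\3", cells)
  )
}

parse_p_values <- function(p, ids) {
  p <- trimws(p)
  below <- rep(NA_real_, length(p))
  value <- rep(NA_real_, length(p))
  bounded <- grepl("^<", p)
  if (any(bounded)) {
    b <- suppressWarnings(as.numeric(sub("^<", "", p[bounded])))
    below[bounded] <- b
    value[bounded] <- b / 2
  }
  plain <- suppressWarnings(as.numeric(p[!bounded]))
  value[!bounded] <- plain
  bad <- is.na(value)
  if (any(bad)) {
    stop_kelp(sprintf("unparseable p-value '%s' (feature %s)",
                      p[bad][1L], ids[bad][1L]),
              class = "kelptrace_validation_error")
  }
  list(value = value, below = below)
}

validate_voc_reference <- function(tab, strict = TRUE) {
  ids <- tab$feature_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop_kelp(sprintf("duplicate feature_id '%s'", dup[1L]),
              class = "kelptrace_validation_error")
  }
  if (!all(grepl("^A[0-9]+$", ids))) {
    bad <- ids[!grepl("^A[0-9]+$", ids)][1L]
    stop_kelp(sprintf("malformed feature_id '%s'", bad),
              class = "kelptrace_validation_error")
  }
  if (strict) {
    expected <- paste0("A", seq_len(115L))
    if (nrow(tab) != 115L) {
      stop_kelp(sprintf("expected 115 features, found %d", nrow(tab)),
                class = "kelptrace_validation_error")
    }
    if (!setequal(ids, expected)) {
      missing_ids <- setdiff(expected, ids)
      stop_kelp(paste0("feature identifiers do not cover A1..A115; missing: ",
                       paste(head(missing_ids, 5L), collapse = ", ")),
                class = "kelptrace_validation_error")
    }
    n_unid <- sum(tab$chem_class == "unidentified")
    if (n_unid != 19L) {
      stop_kelp(sprintf("expected 19 unidentified features, found %d", n_unid),
                class = "kelptrace_validation_error")
    }
  }

  if (!all(tab$form %in% c("monomer", "dimer", "single"))) {
    stop_kelp("`form` must be one of monomer/dimer/single",
              class = "kelptrace_validation_error")
  }
  classes <- c("acid", "pyrazine", "aldehyde", "alcohol", "ether", "furan",
               "ester", "ketone", "other", "unidentified")
  if (!all(tab$chem_class %in% classes)) {
    stop_kelp("unknown chem_class value",
              class = "kelptrace_validation_error")
  }

  for (o in names(.kelp_origins)) {
    m <- tab[[paste0("mean_", o)]]
    s <- tab[[paste0("sd_", o)]]
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop_kelp(sprintf("non-positive or missing mean intensity for origin '%s' (feature %s)",
                        o, ids[which(!is.finite(m) | m <= 0)][1L]),
                class = "kelptrace_validation_error")
    }
    if (any(!is.finite(s)) || any(s < 0)) {
      stop_kelp(sprintf("negative or missing SD for origin '%s'", o),
                class = "kelptrace_validation_error")
    }
  }
  if (any(tab$p_value <= 0 | tab$p_value > 1)) {
    stop_kelp("p-values must lie in (0, 1]",
              class = "kelptrace_validation_error")
  }

  # Monomer/dimer features of one compound must pair by name.
  identified <- tab[tab$chem_class != "unidentified", , drop = FALSE]
  md <- identified[identified$form %in% c("monomer", "dimer"), , drop = FALSE]
  if (nrow(md) > 0L) {
    forms_by_name <- split(md$form, md$compound_name)
    unpaired <- names(forms_by_name)[!vapply(
      forms_by_name, function(f) setequal(f, c("monomer", "dimer")), logical(1L)
    )]
    if (length(unpaired) > 0L) {
      stop_kelp(sprintf("monomer/dimer features of '%s' do not pair", unpaired[1L]),
                class = "kelptrace_validation_error")
    }
  }

  # Duncan letters must mark contiguous stretches of the mean-ranked origins.
  letters_mat <- cbind(tab$letter_rongcheng, tab$letter_dalian, tab$letter_xiapu)
  means_mat <- cbind(tab$mean_rongcheng, tab$mean_dalian, tab$mean_xiapu)
  for (i in seq_len(nrow(tab))) {
    ord <- order(means_mat[i, ], decreasing = TRUE)
    lets <- strsplit(letters_mat[i, ord], "")
    for (l in unique(unlist(lets))) {
      carrying <- which(vapply(lets, function(x) l %in% x, logical(1L)))
      if (length(carrying) > 1L &&
          !identical(carrying, seq(min(carrying), max(carrying)))) {
        stop_kelp(sprintf("inconsistent Duncan letters for feature %s", ids[i]),
                  class = "kelptrace_validation_error")
      }
    }
  }
  invisible(tab)
}

#' Per-origin distribution parameters in long form
#'
#' @param ref A `voc_reference` tibble.
#' @return A tibble with one row per (feature, origin): `feature_id`,
#'   `origin` (city name), `origin_code` (0/1/2), `mean`, `sd`, `letter`,
#'   `p_value`, `p_below`.
#' @export
origin_stats <- function(ref) {
  purrr::map_dfr(names(.kelp_origins), function(o) {
    tibble::tibble(
      feature_id = ref$feature_id,
      origin = o,
      origin_code = .kelp_origins[[o]],
      mean = ref[[paste0("mean_", o)]],
      sd = ref[[paste0("sd_", o)]],
      letter = ref[[paste0("letter_", o)]],
      p_value = ref$p_value,
      p_below = ref$p_below
    )
  }) |>
    dplyr::arrange(.data$feature_id, .data$origin_code)
}

#' Count compound species per chemical class
#'
#' Monomer and dimer signals of one compound are two features but a single
#' chemical species; unidentified features are excluded from species counts.
#'
#' @param ref A `voc_reference` tibble (possibly filtered).
#' @return A list with `class_counts` (tibble of `chem_class`, `n_species`,
#'   descending), `n_identified_features`, and `n_identified_species`.
#' @export
#' @examples
#' summarize_voc_classes(voc_reference())$n_identified_species
summarize_voc_classes <- function(ref) {
  identified <- ref[ref$chem_class != "unidentified", , drop = FALSE]
  species <- dplyr::distinct(
    tibble::as_tibble(identified)[, c("chem_class", "compound_name")]
  )
  counts <- species |>
    dplyr::count(.data$chem_class, name = "n_species") |>
    dplyr::arrange(dplyr::desc(.data$n_species), .data$chem_class)
  list(
    class_counts = counts,
    n_identified_features = nrow(identified),
    n_identified_species = nrow(species)
  )
}

#' Count features significant at a given level
#'
#' Uses the printed per-feature ANOVA p-values; features whose p-value is
#' recorded only as a bound (`p < b`) count as significant exactly when
#' `alpha >= b`.
#'
#' @param ref A `voc_reference` tibble.
#' @param alpha Significance level in (0, 1].
#' @return Integer count of features with p < `alpha`.
#' @export
#' @examples
#' count_significant(voc_reference(), 0.05)
count_significant <- function(ref, alpha = 0.05) {
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  sum(reference_significant(ref, alpha))
}

reference_significant <- function(ref, alpha) {
  ifelse(!is.na(ref$p_below), alpha >= ref$p_below, ref$p_value < alpha)
}
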