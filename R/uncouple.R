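# Lookup from the 3x3 (total_state, poly_state) grid to the uncoupling
# category. "Opposing" requires significance in BOTH fractions with opposite
# signs; genes significant nowhere are "null".
uncoupling_lookup <- function() {
  tibble::tribble(
    ~total_state, ~poly_state, ~category,
    "up",   "ns",   "total_up_only",
    "down", "ns",   "total_down_only",
    "ns",   "up",   "poly_up_only",
    "ns",   "down", "poly_down_only",
    "up",   "up",   "concordant_up",
    "down", "down", "concordant_down",
    "up",   "down", "opposing",
    "down", "up",   "opposing",
    "ns",   "ns",   "null"
  )
}

uncoupling_categories <- c(
  "total_up_only", "total_down_only", "poly_up_only", "poly_down_only",
  "concordant_up", "concordant_down", "opposing", "null"
)

de_state <- function(log2fc, fdr, threshold) {
  dplyr::case_when(
    fdr < threshold & log2fc > 0 ~ "up",
    fdr < threshold & log2fc < 0 ~ "down",
    .default = "ns"
  )
}

#' Classify transcriptional-translational uncoupling
#'
#' Combines per-fraction differential results into a per-gene (or
#' per-probeset) call describing in which fraction the injury response occurs
#' and in which direction. A fraction's state is `up`/`down` when
#' `FDR < fdr_threshold` (strictly) with the corresponding fold-change sign,
#' else `ns`; the category is a pure function of the two states via the 3x3
#' grid (see `uncoupling_lookup()`), with "opposing" meaning significant in
#' both fractions with opposite signs.
#'
#' @param de_total,de_poly Differential results sharing the same identifier
#'   universe (first column or `probeset_id`/`gene_id`), each with `log2fc`
#'   and `fdr`.
#' @param fdr_threshold Significance cutoff (strict `<`, default 0.05).
#' @return Tibble: id, per-fraction log2fc/fdr/state, category. Category
#'   counts (all 8 categories, zero-filled) are attached as attribute
#'   `"counts"` and available via [count_uncoupling()].
#' @export
classify_uncoupling <- function(de_total, de_poly, fdr_threshold = 0.05) {
  id_col <- intersect(c("gene_id", "probeset_id"), names(de_total))[1L]
  if (is.na(id_col)) id_col <- names(de_total)[1L]
  for (nm in c("log2fc", "fdr")) {
    require_columns(de_total, nm, "de_total")
    require_columns(de_poly, nm, "de_poly")
  }
  if (!id_col %in% names(de_poly)) {
    abort(sprintf("`de_poly` lacks the id column '%s'.", id_col))
  }
  ids_t <- de_total[[id_col]]
  ids_p <- de_poly[[id_col]]
  only_t <- setdiff(ids_t, ids_p)
  only_p <- setdiff(ids_p, ids_t)
  if (length(only_t) || length(only_p)) {
    abort(sprintf(
      "id universes differ: %d only in total (e.g. %s), %d only in polysome (e.g. %s).",
      length(only_t), paste(head(only_t, 3L), collapse = ", "),
      length(only_p), paste(head(only_p, 3L), collapse = ", ")))
  }

  tt <- tibble::tibble(
    id = ids_t,
    total_log2fc = de_total$log2fc,
    total_fdr = de_total$fdr
  )
  pp <- tibble::tibble(
    id = ids_p,
    poly_log2fc = de_poly$log2fc,
    poly_fdr = de_poly$fdr
  )
  calls <- dplyr::inner_join(tt, pp, by = "id") |>
    dplyr::mutate(
      total_state = de_state(.data$total_log2fc, .data$total_fdr, fdr_threshold),
      poly_state = de_state(.data$poly_log2fc, .data$poly_fdr, fdr_threshold)
    ) |>
    dplyr::left_join(uncoupling_lookup(), by = c("total_state", "poly_state")) |>
    dplyr::mutate(fdr_threshold = fdr_threshold)
  names(calls)[1L] <- id_col
  attr(calls, "counts") <- count_uncoupling(calls)
  calls
}

#' Tabulate uncoupling categories
#'
#' @param calls Output of [classify_uncoupling()].
#' @return Tibble with one row per category (all 8, zero-filled) and count
#'   `n`; counts sum to the classified universe size.
#' @export
count_uncoupling <- function(calls) {
  require_columns(calls, "category", "calls")
  calls |>
    dplyr::count(category = factor(.data$category, levels = uncoupling_categories),
                 .drop = FALSE) |>
    dplyr::mutate(category = as.character(.data$category))
}

#' Per-row z-scores across samples
#'
#' Standardizes each row of a normalized intensity table to mean 0 and sample
#' (n-1 denominator) standard deviation 1 across samples, the representation
#' used for expression heat maps. Constant rows cannot be standardized and
#' are dropped with a warning.
#'
#' @param data Intensity table (id column + numeric sample columns) or
#'   matrix.
#' @param rows Optional identifier subset to standardize (must be non-empty
#'   and present).
#' @return Tibble in the same layout with z-scores.
#' @export
zscore_matrix <- function(data, rows = NULL) {
  m <- as_intensity_matrix(data)
  if (!is.null(rows)) {
    if (length(rows) == 0L) abort("`rows` subset is empty.")
    missing <- setdiff(rows, rownames(m))
    if (length(missing)) {
      abort(sprintf("subset id(s) not found: %s.", paste(head(missing, 5L), collapse = ", ")))
    }
    m <- m[rows, , drop = FALSE]
  }
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant row(s) (sd = 0): %s.",
                 sum(sds == 0), paste(head(rownames(m)[sds == 0], 5L), collapse = ", ")))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(m) == 0L) abort("no non-constant rows to standardize.")
  z <- (m - rowMeans(m)) / sds
  matrix_to_tibble(z)
}

#' Marker-gene composition correlation
#'
#' Quality control for tissue composition: averages normalized marker-gene
#' intensities over replicates within each condition and reports the Pearson
#' correlation between the naive and injured marker profiles for one
#' fraction. A high correlation indicates the injury did not grossly change
#' cellular composition, so fraction-level differential signals are not
#' driven by cell-type shifts.
#'
#' @param normalized Normalized intensity table for one fraction.
#' @param samples Sample sheet covering its columns (`sample_id`,
#'   `condition`).
#' @param panel Marker panel tibble: `gene_id` (unique) and `cell_type`.
#' @param mapping Probeset-to-gene table used to locate marker probesets;
#'   multi-mappers excluded internally.
#' @param conditions Length-2 conditions correlated (default naive vs
#'   injured).
#' @return List: `overall` (one-row tibble with n_markers and Pearson `r`),
#'   `by_cell_type` (per-cell-type r), `profiles` (the averaged marker
#'   intensities).
#' @export
marker_composition_correlation <- function(normalized, samples, panel, mapping,
                                           conditions = c("naive", "injured")) {
  require_columns(panel, c("gene_id", "cell_type"), "panel")
  if (anyDuplicated(panel$gene_id)) abort("marker gene ids must be unique.")
  m <- as_intensity_matrix(normalized)
  require_columns(samples, c("sample_id", "condition"), "samples")
  map1 <- suppressMessages(map_probesets(mapping, target = "gene"))
  marker_map <- map1[map1$gene_id %in% panel$gene_id, , drop = FALSE]
  marker_map <- marker_map[marker_map$probeset_id %in% rownames(m), , drop = FALSE]
  found <- unique(marker_map$gene_id)
  if (length(found) < 3L) {
    abort(sprintf("fewer than 3 marker genes found in the data; missing: %s.",
                  paste(head(setdiff(panel$gene_id, found), 10L), collapse = ", ")))
  }
  cond <- samples$condition[match(colnames(m), samples$sample_id)]
  prof <- vapply(conditions, function(cc) {
    cols <- which(cond == cc)
    if (!length(cols)) abort(sprintf("condition '%s' absent from samples.", cc))
    rowMeans(m[marker_map$probeset_id, cols, drop = FALSE])
  }, numeric(nrow(marker_map)))
  profiles <- tibble::tibble(
    probeset_id = marker_map$probeset_id,
    gene_id = marker_map$gene_id,
    cell_type = panel$cell_type[match(marker_map$gene_id, panel$gene_id)]
  )
  profiles[[conditions[1L]]] <- prof[, 1L]
  profiles[[conditions[2L]]] <- prof[, 2L]

  overall <- tibble::tibble(
    n_markers = length(found),
    r = stats::cor(prof[, 1L], prof[, 2L], method = "pearson")
  )
  by_ct <- profiles |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= 3L) {
        stats::cor(.data[[conditions[1L]]], .data[[conditions[2L]]])
      } else NA_real_,
      .groups = "drop"
    )
  list(overall = overall, by_cell_type = by_ct, profiles = profiles)
}

#' Bar chart of uncoupling category counts
#' @param calls Output of [classify_uncoupling()] (or a counts tibble).
#' @return A ggplot object.
#' @export
plot_uncoupling_counts <- function(calls) {
  counts <- if ("category" %in% names(calls) && "n" %in% names(calls)) calls
            else count_uncoupling(calls)
  counts$category <- factor(counts$category, levels = uncoupling_categories)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "probesets / genes",
                  title = "Differential calls by fraction and direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
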