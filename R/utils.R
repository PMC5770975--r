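# Internal helpers shared across modules.

# Coerce an intensity table (id column + one numeric column per array) to a
# numeric matrix with probeset rownames. Accepts a tibble/data.frame whose
# first column is the identifier, or an already-formed numeric matrix.
as_intensity_matrix <- function(data, arg = "data") {
  if (is.matrix(data)) {
    if (!is.numeric(data)) abort(sprintf("`%s` matrix must be numeric.", arg))
    if (is.null(rownames(data))) {
      rownames(data) <- sprintf("row%06d", seq_len(nrow(data)))
    }
    return(data)
  }
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame or numeric matrix.", arg))
  }
  if (ncol(data) < 3L) {
    abort(sprintf("`%s` needs an id column plus at least 2 array columns.", arg))
  }
  ids <- as.character(data[[1L]])
  if (anyDuplicated(ids)) abort(sprintf("duplicated ids in `%s`.", arg))
  m <- as.matrix(data[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("`%s` array columns must all be numeric.", arg))
  rownames(m) <- ids
  m
}

matrix_to_tibble <- function(m, id_col = "probeset_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
}

# Deterministic per-stage seed derived from the master seed; keeps every
# generator stage reproducible independent of how many draws earlier stages
# consumed.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage * 104729L
}

require_columns <- function(data, cols, arg = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
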