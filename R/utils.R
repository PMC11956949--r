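# Internal helpers shared across modules.

ANNOT_COLS <- c("accession", "gene", "organism")

#' @importFrom rlang abort warn %||%
NULL

# Sample (intensity) columns of a protein table: everything that is not
# annotation.
sample_cols <- function(tbl) {
  setdiff(names(tbl), ANNOT_COLS)
}

# Extract the numeric intensity block as a matrix, rows named by accession.
intensity_matrix <- function(tbl) {
  sc <- sample_cols(tbl)
  m <- as.matrix(tbl[, sc, drop = FALSE])
  rownames(m) <- tbl$accession
  storage.mode(m) <- "double"
  m
}

# Replace the intensity block of `tbl` with matrix `m` (same shape).
set_intensities <- function(tbl, m) {
  sc <- sample_cols(tbl)
  stopifnot(ncol(m) == length(sc), nrow(m) == nrow(tbl))
  tbl[, sc] <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl
}

check_intensity_table <- function(tbl, arg = "intensities") {
  if (!is.data.frame(tbl)) {
    abort(sprintf("`%s` must be a data frame.", arg))
  }
  missing_cols <- setdiff(ANNOT_COLS, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` lacks required column(s): %s.",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(tbl$accession)) {
    abort(sprintf("`%s` has duplicated accessions.", arg))
  }
  sc <- sample_cols(tbl)
  if (anyDuplicated(sc)) {
    abort(sprintf("`%s` has duplicated sample columns.", arg))
  }
  if (length(sc) > 0 && nrow(tbl) > 0) {
    m <- as.matrix(tbl[, sc, drop = FALSE])
    if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0)) {
      abort(sprintf(
        "`%s` intensities must be nonnegative and finite (zero = not observed).",
        arg
      ))
    }
  }
  invisible(tbl)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  as.numeric(x)
}
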