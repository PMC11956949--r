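# Readers/writers for the tab-delimited protein-group table, the matrisome
# CSV, and audit sidecars.

#' Read a tab-delimited protein-group intensity table
#'
#' Expects a header row `accession`, `gene`, `organism` (case-insensitive;
#' `Accession`/`Gene`/`Organism` accepted) followed by one numeric column per
#' sample; zero means not observed.
#'
#' @param path File path.
#' @return Intensity tibble.
#' @export
read_intensity_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:3] <- tolower(names(tbl)[1:3])
  check_intensity_table(tbl)
  tbl
}

#' Write a protein-group intensity table as tab-delimited text
#'
#' @param tbl Intensity tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a matrisome annotation CSV
#'
#' Columns `gene`, `division`, `category`; duplicate genes are an error.
#'
#' @param path File path.
#' @return Annotation tibble.
#' @export
read_matrisome <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(ann) <- tolower(names(ann))
  check_matrisome_annotation(ann)
  ann
}

#' Write a matrisome annotation CSV
#'
#' @param annotation Annotation tibble (`gene`, `division`, `category`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrisome <- function(annotation, path) {
  check_matrisome_annotation(annotation)
  readr::write_csv(annotation[, c("gene", "division", "category")], path,
                   progress = FALSE)
  invisible(path)
}
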