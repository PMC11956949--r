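# Matrisome annotation and the per-category count / intensity accounting
# comparing newly synthesized ECM (eluates) with bulk ECM (inputs).

#' Annotate proteins against a matrisome lookup
#'
#' Matches gene symbols (exact, case-insensitive) against a matrisome
#' annotation table; unmatched genes are labeled `"non-matrisome"` with `NA`
#' division.
#'
#' @param proteins Protein table (needs a `gene` column) or a character
#'   vector of gene symbols.
#' @param annotation Tibble with columns `gene`, `division`, `category`
#'   (e.g. [make_matrisome_fixture()] or [read_matrisome()]).
#' @return Tibble `gene`, `category`, `division`, one row per input protein
#'   in input order.
#' @export
annotate_matrisome <- function(proteins, annotation) {
  genes <- if (is.data.frame(proteins)) proteins$gene else as.character(proteins)
  check_matrisome_annotation(annotation)
  key <- toupper(annotation$gene)
  idx <- match(toupper(genes), key)
  tibble::tibble(
    gene = genes,
    category = ifelse(is.na(idx), "non-matrisome", annotation$category[idx]),
    division = annotation$division[idx]
  )
}

check_matrisome_annotation <- function(annotation) {
  if (!all(c("gene", "division", "category") %in% names(annotation))) {
    abort("Annotation needs columns gene, division, category.")
  }
  if (anyDuplicated(toupper(annotation$gene))) {
    dups <- annotation$gene[duplicated(toupper(annotation$gene))]
    abort(sprintf(
      "Duplicate gene(s) in matrisome annotation: %s.",
      paste(unique(dups), collapse = ", ")
    ))
  }
  invisible(annotation)
}

#' Matrisome category summary of input vs eluate fractions
#'
#' For each matrisome category (plus `"non-matrisome"`), counts the protein
#' groups identified in each fraction (identified = at least one nonzero
#' intensity in that fraction's samples), sums their intensities, computes
#' each category's share of the fraction's total identified intensity, and
#' reports the eluate-minus-input count difference and eluate/input
#' intensity ratio.
#'
#' @param input_matrix,eluate_matrix Protein tables for the two fractions.
#' @param annotation Matrisome annotation tibble.
#' @return Tibble with one row per category: `category`, `division`,
#'   `n_input`, `n_eluate`, `intensity_input`, `intensity_eluate`,
#'   `prop_input`, `prop_eluate`, `count_diff` (eluate - input),
#'   `intensity_ratio` (eluate / input; NA when the input intensity is 0).
#' @export
category_summary <- function(input_matrix, eluate_matrix, annotation) {
  check_intensity_table(input_matrix, "input_matrix")
  check_intensity_table(eluate_matrix, "eluate_matrix")
  check_matrisome_annotation(annotation)

  fraction_stats <- function(tbl, suffix) {
    m <- intensity_matrix(tbl)
    ann <- annotate_matrisome(tbl, annotation)
    tibble::tibble(
      category = ann$category,
      identified = rowSums(m > 0) >= 1,
      intensity = rowSums(m)
    ) |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(
        "n_{suffix}" := sum(.data$identified),
        "intensity_{suffix}" := sum(.data$intensity[.data$identified]),
        .groups = "drop"
      )
  }

  cats <- matrisome_categories()
  skeleton <- tibble::tibble(
    category = c(names(cats), "non-matrisome"),
    division = c(unname(cats), NA_character_)
  )
  out <- skeleton |>
    dplyr::left_join(fraction_stats(input_matrix, "input"), by = "category") |>
    dplyr::left_join(fraction_stats(eluate_matrix, "eluate"), by = "category") |>
    dplyr::mutate(
      dplyr::across(c("n_input", "n_eluate"), ~ tidyr::replace_na(.x, 0L)),
      dplyr::across(
        c("intensity_input", "intensity_eluate"),
        ~ tidyr::replace_na(.x, 0)
      )
    ) |>
    dplyr::mutate(
      prop_input = .data$intensity_input / sum(.data$intensity_input),
      prop_eluate = .data$intensity_eluate / sum(.data$intensity_eluate),
      count_diff = .data$n_eluate - .data$n_input,
      intensity_ratio = dplyr::if_else(
        .data$intensity_input > 0,
        .data$intensity_eluate / .data$intensity_input,
        NA_real_
      )
    )
  out
}
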