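# Sum normalization over declared sample scopes, and the human/rat species
# selectivity summary.

#' Sum-normalize a protein intensity table within declared scopes
#'
#' Within each scope (a declared set of samples normalized together), every
#' sample's intensities are scaled by `Sum_average / Sum_sample`, where
#' `Sum_sample` is that sample's total intensity over the summed protein
#' subset and `Sum_average` is the mean of those totals across the scope.
#' After normalization, all per-sample totals over the summed subset within
#' a scope equal the scope's average original sum; zeros stay zero.
#'
#' Typical scopes for the three search workflows:
#' * comparison of labeled vs vehicle eluates: one scope per treatment group,
#'   sums over human proteins only;
#' * cross-model comparison of labeled eluates: a single scope over all
#'   those samples, sums over human proteins;
#' * inputs: a single scope over all input samples, sums over all (human and
#'   rat) proteins.
#'
#' @param intensities Protein table (`accession`, `gene`, `organism`, one
#'   column per sample).
#' @param scope Scope membership: a character vector of scope labels named by
#'   sample id, an unnamed vector parallel to the sample columns, or `NULL`
#'   (all samples in one scope).
#' @param summed_organisms Organisms whose proteins enter the per-sample
#'   sums (`NULL` = all proteins). All proteins are rescaled either way;
#'   only the scale-factor sums are restricted.
#' @return A tibble of the same shape with normalized intensities, carrying a
#'   `scale_factors` attribute (tibble: `sample_id`, `scope`, `sum_original`,
#'   `sum_average`, `scale_factor`); retrieve it with [scale_factors()].
#' @examples
#' tbl <- tibble::tibble(
#'   accession = c("P1", "P2", "P3"), gene = c("A", "B", "C"),
#'   organism = "human", s1 = c(2, 3, 5), s2 = c(6, 9, 15)
#' )
#' sum_normalize(tbl)
#' @export
sum_normalize <- function(intensities, scope = NULL, summed_organisms = NULL) {
  check_intensity_table(intensities)
  m <- intensity_matrix(intensities)
  samp <- colnames(m)
  if (is.null(scope)) {
    scope <- rep("all", length(samp))
    names(scope) <- samp
  } else if (is.null(names(scope))) {
    if (length(scope) != length(samp)) {
      abort("Unnamed `scope` must have one entry per sample column.")
    }
    names(scope) <- samp
  } else {
    missing <- setdiff(samp, names(scope))
    if (length(missing) > 0) {
      abort(sprintf(
        "`scope` lacks entries for sample(s): %s.",
        paste(missing, collapse = ", ")
      ))
    }
    scope <- scope[samp]
  }

  in_subset <- if (is.null(summed_organisms)) {
    rep(TRUE, nrow(intensities))
  } else {
    intensities$organism %in% summed_organisms
  }
  sums <- colSums(m[in_subset, , drop = FALSE])
  bad <- samp[sums <= 0]
  if (length(bad) > 0) {
    abort(sprintf(
      "Sample(s) with zero total over the summed subset: %s.",
      paste(bad, collapse = ", ")
    ))
  }
  sum_avg <- tapply(sums, scope, mean)[as.character(scope)]
  factors <- as.numeric(sum_avg) / sums
  norm <- sweep(m, 2, factors, `*`)

  out <- set_intensities(intensities, norm)
  attr(out, "scale_factors") <- tibble::tibble(
    sample_id = samp,
    scope = as.character(scope),
    sum_original = as.numeric(sums),
    sum_average = as.numeric(sum_avg),
    scale_factor = as.numeric(factors)
  )
  class(out) <- c("newsecm_normalized", class(out))
  out
}

#' Per-sample scale factors from a normalized table
#'
#' @param x A table returned by [sum_normalize()].
#' @return Tibble of per-sample sums and scale factors.
#' @export
scale_factors <- function(x) {
  sf <- attr(x, "scale_factors")
  if (is.null(sf)) abort("`x` carries no scale factors; was it sum-normalized?")
  sf
}

#' @export
tidy.newsecm_normalized <- function(x, ...) scale_factors(x)

#' Species-level eluate-vs-input intensity summary
#'
#' Totals the (un-normalized, original-value) intensities per organism in the
#' input and eluate fractions and reports the relative change
#' `(eluate - input) / input * 100` percent — the species-selectivity metric
#' of click-enrichment: labeled (cell-derived) species should be retained in
#' eluates while unlabeled scaffold species wash out.
#'
#' @param input_matrix,eluate_matrix Protein tables for the two fractions
#'   (same format as [simulate_lfq()] output).
#' @return Tibble with `organism`, `input_total`, `eluate_total`,
#'   `pct_change` (NA where the organism is absent from the input).
#' @export
species_intensity_summary <- function(input_matrix, eluate_matrix) {
  check_intensity_table(input_matrix, "input_matrix")
  check_intensity_table(eluate_matrix, "eluate_matrix")
  totals <- function(tbl, col) {
    m <- intensity_matrix(tbl)
    tibble::tibble(organism = tbl$organism, total = rowSums(m)) |>
      dplyr::group_by(.data$organism) |>
      dplyr::summarise("{col}" := sum(.data$total), .groups = "drop")
  }
  out <- dplyr::full_join(
    totals(input_matrix, "input_total"),
    totals(eluate_matrix, "eluate_total"),
    by = "organism"
  ) |>
    dplyr::mutate(
      pct_change = dplyr::if_else(
        !is.na(.data$input_total) & .data$input_total > 0,
        (.data$eluate_total - .data$input_total) / .data$input_total * 100,
        NA_real_
      )
    )
  out
}
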