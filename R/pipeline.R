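# End-to-end search workflows: normalization -> filtering/imputation ->
# differential statistics -> categorisation, plus a run report.

check_samples <- function(samples, intensities) {
  need <- c("sample_id", "model", "treatment", "fraction")
  if (!all(need %in% names(samples))) {
    abort(sprintf(
      "`samples` needs columns: %s.", paste(need, collapse = ", ")
    ))
  }
  missing <- setdiff(sample_cols(intensities), samples$sample_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "No metadata for sample(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  invisible(samples)
}

subset_samples <- function(intensities, ids) {
  intensities[, c(ANNOT_COLS, ids), drop = FALSE]
}

new_search_result <- function(table, venn, params, ...) {
  structure(
    list(table = table, venn = venn, params = params, ...),
    class = "newsecm_search"
  )
}

#' @export
print.newsecm_search <- function(x, ...) {
  cat(sprintf(
    "%s: %d proteins tested (%s vs %s)\n",
    x$params$workflow, nrow(x$table), x$params$group_a, x$params$group_b
  ))
  print(x$venn)
  invisible(x)
}

#' @export
tidy.newsecm_search <- function(x, ...) x$table

#' @export
glance.newsecm_search <- function(x, ...) {
  tibble::tibble(
    workflow = x$params$workflow,
    n_tested = nrow(x$table),
    n_high_a = sum(x$table$category == paste0("high_in_", x$params$group_a)),
    n_high_b = sum(x$table$category == paste0("high_in_", x$params$group_b)),
    n_ns = sum(x$table$category == "NS"),
    n_unfiltered = if (is.null(x$unfiltered)) 0L else nrow(x$unfiltered),
    n_permutations = x$params$n_permutations,
    exhaustive = x$params$exhaustive,
    seed = x$params$seed
  )
}

finish_differential <- function(fdr_tbl, meta, fc_threshold, q_threshold,
                                group_a, group_b) {
  tbl <- fdr_tbl |>
    dplyr::mutate(
      log2fc = .data$mean_a - .data$mean_b,
      fc = 2^.data$log2fc,
      category = classify_volcano(
        .data$log2fc, .data$q, fc_threshold, q_threshold,
        labels = paste0("high_in_", c(group_a, group_b))
      )
    ) |>
    dplyr::left_join(meta, by = "accession") |>
    dplyr::select(
      "accession", "gene", "organism", "mean_a", "mean_b",
      "log2fc", "fc", "t", "df", "p", "q", "category"
    )
  venn <- tbl |>
    dplyr::count(.data$category, name = "n") |>
    tidyr::complete(
      category = c(paste0("high_in_", c(group_a, group_b)), "NS"),
      fill = list(n = 0L)
    )
  list(table = tbl, venn = venn)
}

#' Search-1 within-model workflow: labeled vs vehicle eluates
#'
#' For the eluate samples of one culture model, compares the azido-sugar
#' (GalNAz) arm against vehicle: sum-normalizes each treatment group as its
#' own scope (sums over human proteins), removes proteins with fewer than
#' `min_nonzero` nonzero values in either group, log2-transforms, and runs
#' Welch t-tests with permutation-FDR q-values on proteins observed in every
#' sample. Proteins failing the filter are reported separately with their
#' per-group mean intensities. No imputation in this branch.
#'
#' @param intensities Protein table.
#' @param samples Sample metadata (`sample_id`, `model`, `treatment`,
#'   `fraction`).
#' @param model Culture model to analyse (`"dECM-tumor"` or `"tumoroid"`).
#' @param treatments Length-2 character: the A and B treatment arms.
#' @param min_nonzero Pre-filter threshold per group.
#' @param fc_threshold,q_threshold Volcano cut-offs.
#' @param n_permutations,s0 Passed to [permutation_fdr()].
#' @param summed_organisms Protein subset over which normalization sums are
#'   taken (default human).
#' @param seed Seed for the permutation plan.
#' @return A `newsecm_search` object: `table` (differential tibble), `venn`
#'   (category counts), `unfiltered` (group means of proteins that failed
#'   the filter), `scale_factors`, `params`.
#' @export
run_search1_within_model <- function(intensities, samples,
                                     model = "dECM-tumor",
                                     treatments = c("GalNAz", "vehicle"),
                                     min_nonzero = 2,
                                     fc_threshold = 1, q_threshold = 0.05,
                                     n_permutations = 250, s0 = 0,
                                     summed_organisms = "human",
                                     seed = 1L) {
  check_intensity_table(intensities)
  check_samples(samples, intensities)
  if (nrow(intensities) == 0) abort("Empty intensity table.")
  sel <- samples |>
    dplyr::filter(
      .data$model == !!model, .data$fraction == "eluate",
      .data$treatment %in% treatments,
      .data$sample_id %in% sample_cols(intensities)
    )
  for (tr in treatments) {
    if (!any(sel$treatment == tr)) {
      abort(sprintf("No eluate samples for treatment arm '%s'.", tr))
    }
  }
  sub <- subset_samples(intensities, sel$sample_id)
  groups <- stats::setNames(sel$treatment, sel$sample_id)

  norm <- sum_normalize(sub, scope = groups,
                        summed_organisms = summed_organisms)
  filt <- prefilter_min_nonzero(norm, groups, min_nonzero = min_nonzero)

  # proteins that cannot be assigned a p-value: report by group means
  dropped <- norm[!norm$accession %in% filt$accession, , drop = FALSE]
  unfiltered <- if (nrow(dropped) > 0) {
    md <- intensity_matrix(dropped)
    tibble::tibble(
      accession = dropped$accession, gene = dropped$gene,
      organism = dropped$organism,
      mean_a = rowMeans(md[, names(groups)[groups == treatments[1]],
                           drop = FALSE]),
      mean_b = rowMeans(md[, names(groups)[groups == treatments[2]],
                           drop = FALSE])
    )
  } else {
    NULL
  }

  logm <- log2_transform(filt)
  complete <- logm[stats::complete.cases(
    logm[, sample_cols(logm), drop = FALSE]
  ), , drop = FALSE]
  fdr <- permutation_fdr(complete, groups, n_permutations = n_permutations,
                         s0 = s0, seed = seed)
  res <- finish_differential(
    fdr, complete[, ANNOT_COLS], fc_threshold, q_threshold,
    treatments[1], treatments[2]
  )
  new_search_result(
    res$table, res$venn,
    params = list(
      workflow = "search1_within_model", model = model,
      group_a = treatments[1], group_b = treatments[2],
      min_nonzero = min_nonzero, fc_threshold = fc_threshold,
      q_threshold = q_threshold, s0 = s0,
      n_permutations = attr(fdr, "n_permutations"),
      exhaustive = attr(fdr, "exhaustive"),
      summed_organisms = summed_organisms, seed = seed
    ),
    unfiltered = unfiltered,
    scale_factors = scale_factors(norm)
  )
}

#' Search-1 cross-model workflow: labeled eluates, dECM-tumor vs tumoroid
#'
#' Normalizes the GalNAz eluate samples of both models together in a single
#' scope (sums over human proteins), log2-transforms, imputes left-censored
#' missing values with QRILC, then runs Welch t-tests with permutation-FDR
#' q-values and volcano categorisation.
#'
#' @inheritParams run_search1_within_model
#' @param models Length-2 character: the A and B culture models.
#' @param treatment Treatment arm whose eluates are compared.
#' @param tune_sigma QRILC sd multiplier.
#' @return A `newsecm_search` object (plus `imputation`, the
#'   `qrilc_imputed` parameters).
#' @export
run_search1_cross_model <- function(intensities, samples,
                                    models = c("dECM-tumor", "tumoroid"),
                                    treatment = "GalNAz",
                                    fc_threshold = 1, q_threshold = 0.05,
                                    n_permutations = 250, s0 = 0,
                                    tune_sigma = 1.0,
                                    summed_organisms = "human",
                                    seed = 1L) {
  check_intensity_table(intensities)
  check_samples(samples, intensities)
  sel <- samples |>
    dplyr::filter(
      .data$model %in% models, .data$fraction == "eluate",
      .data$treatment == !!treatment,
      .data$sample_id %in% sample_cols(intensities)
    )
  for (md in models) {
    if (!any(sel$model == md)) {
      abort(sprintf("No %s eluate samples for model '%s'.", treatment, md))
    }
  }
  sub <- subset_samples(intensities, sel$sample_id)
  groups <- stats::setNames(sel$model, sel$sample_id)

  norm <- sum_normalize(sub, scope = NULL,
                        summed_organisms = summed_organisms)
  logm <- log2_transform(norm)
  imp <- qrilc_impute(logm, tune_sigma = tune_sigma, seed = seed)
  fdr <- permutation_fdr(imp$data, groups, n_permutations = n_permutations,
                         s0 = s0, seed = seed)
  res <- finish_differential(
    fdr, imp$data[, ANNOT_COLS], fc_threshold, q_threshold,
    models[1], models[2]
  )
  new_search_result(
    res$table, res$venn,
    params = list(
      workflow = "search1_cross_model",
      group_a = models[1], group_b = models[2], treatment = treatment,
      fc_threshold = fc_threshold, q_threshold = q_threshold,
      s0 = s0, tune_sigma = tune_sigma,
      n_permutations = attr(fdr, "n_permutations"),
      exhaustive = attr(fdr, "exhaustive"),
      summed_organisms = summed_organisms, seed = seed
    ),
    imputation = imp$params,
    scale_factors = scale_factors(norm)
  )
}

#' Search-2 workflow: species selectivity on original values
#'
#' Totals human and rat protein intensities per fraction on the original
#' (un-normalized) values and reports the eluate-vs-input percent change per
#' species — the readout that labeled (human, cell-derived) proteins are
#' retained by the enrichment while unlabeled (rat, scaffold-derived)
#' proteins wash out.
#'
#' @param intensities Protein table covering both fractions.
#' @param samples Sample metadata.
#' @param model Optional: restrict to one culture model.
#' @return [species_intensity_summary()] tibble.
#' @export
run_search2_species <- function(intensities, samples, model = NULL) {
  check_intensity_table(intensities)
  check_samples(samples, intensities)
  if (any(is.na(intensities$organism)) ||
      !all(intensities$organism %in% c("human", "rat", "contaminant"))) {
    abort("Organism tags must be 'human', 'rat' or 'contaminant'.")
  }
  sel <- samples
  if (!is.null(model)) sel <- dplyr::filter(sel, .data$model == !!model)
  ids_in <- sel$sample_id[sel$fraction == "input"]
  ids_el <- sel$sample_id[sel$fraction == "eluate"]
  if (length(ids_in) == 0 || length(ids_el) == 0) {
    abort("Need samples in both the input and eluate fractions.")
  }
  species_intensity_summary(
    subset_samples(intensities, ids_in),
    subset_samples(intensities, ids_el)
  )
}

#' Search-3 workflow: normalize all input samples together
#'
#' Single-scope sum normalization of every input-fraction sample, with sums
#' over all (human and rat) proteins; the normalized table is exported for
#' downstream annotation.
#'
#' @param intensities Protein table.
#' @param samples Sample metadata.
#' @return List: `normalized` (tibble with scale factors), `summary`
#'   (per-sample totals before/after).
#' @export
run_search3_inputs <- function(intensities, samples) {
  check_intensity_table(intensities)
  check_samples(samples, intensities)
  ids <- samples$sample_id[samples$fraction == "input"]
  ids <- intersect(sample_cols(intensities), ids)
  if (length(ids) == 0) abort("No input-fraction samples found.")
  norm <- sum_normalize(subset_samples(intensities, ids), scope = NULL,
                        summed_organisms = NULL)
  sf <- scale_factors(norm)
  summary <- sf |>
    dplyr::mutate(
      sum_normalized = .data$sum_original * .data$scale_factor
    )
  list(normalized = norm, summary = summary)
}

#' Assemble a run report from workflow outputs
#'
#' Collects the outputs of one or more workflows into a single serialisable
#' report: differential category counts, species and matrisome summaries,
#' sample QC (pairwise correlations, Grubbs flags on per-sample protein-ID
#' counts), and the parameters and seeds that produced each result. Outlier
#' flags are advisory: nothing is removed.
#'
#' @param ... Named workflow outputs (`newsecm_search` objects, species or
#'   category summary tibbles).
#' @param intensities Optional protein table for sample-level QC.
#' @return List of class `newsecm_report`; write with [write_report()].
#' @export
report <- function(..., intensities = NULL) {
  parts <- list(...)
  if (length(parts) == 0) abort("Report needs at least one workflow output.")
  if (is.null(names(parts)) || any(names(parts) == "")) {
    abort("All report components must be named.")
  }
  out <- list(components = list(), qc = NULL)
  for (nm in names(parts)) {
    x <- parts[[nm]]
    out$components[[nm]] <- if (inherits(x, "newsecm_search")) {
      list(
        type = "differential",
        venn = as.data.frame(x$venn),
        n_tested = nrow(x$table),
        params = x$params
      )
    } else if (is.data.frame(x)) {
      list(type = "table", data = as.data.frame(x))
    } else {
      abort(sprintf("Cannot include component '%s' in a report.", nm))
    }
  }
  if (!is.null(intensities)) {
    check_intensity_table(intensities)
    m <- intensity_matrix(intensities)
    id_counts <- colSums(m > 0)
    # degenerate (zero-spread) ID counts are already encoded in the result
    # row (NA critical value), so the advisory warning is redundant here
    grubbs <- suppressWarnings(grubbs_outlier(id_counts))
    out$qc <- list(
      protein_ids_per_sample = as.list(id_counts),
      grubbs_on_id_counts = as.data.frame(grubbs),
      correlation = as.data.frame(sample_correlation(log2_transform(intensities)))
    )
  }
  class(out) <- "newsecm_report"
  out
}

#' Write a report as JSON and markdown
#'
#' @param rep A `newsecm_report`.
#' @param json_path Output JSON path.
#' @param md_path Optional markdown summary path.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(rep, json_path, md_path = NULL) {
  jsonlite::write_json(unclass(rep), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (!is.null(md_path)) {
    lines <- c("# newsECM analysis report", "")
    for (nm in names(rep$components)) {
      comp <- rep$components[[nm]]
      lines <- c(lines, sprintf("## %s (%s)", nm, comp$type), "")
      if (comp$type == "differential") {
        lines <- c(
          lines,
          sprintf("- proteins tested: %d", comp$n_tested),
          vapply(seq_len(nrow(comp$venn)), function(i) {
            sprintf("- %s: %d", comp$venn$category[i], comp$venn$n[i])
          }, character(1)),
          sprintf("- seed: %s", comp$params$seed), ""
        )
      }
    }
    writeLines(lines, md_path)
  }
  invisible(json_path)
}

#' Read a report back from JSON
#'
#' @param json_path Path written by [write_report()].
#' @return The report list.
#' @export
read_report <- function(json_path) {
  rep <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  class(rep) <- "newsecm_report"
  rep
}
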