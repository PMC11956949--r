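# Pre-filtering, log2 transform, QRILC left-censored imputation and
# back-transformation.

#' Pre-filter proteins by minimum nonzero observations per group
#'
#' Retains proteins with at least `min_nonzero` nonzero intensities in
#' *every* treatment group — proteins observed too sparsely to be assigned a
#' p-value are removed before testing (they can be summarised separately by
#' group means; see [run_search1_within_model()]).
#'
#' @param intensities Protein table.
#' @param group_labels Character vector of group labels, named by sample id
#'   (or unnamed, parallel to the sample columns).
#' @param min_nonzero Minimum nonzero values required in each group.
#' @return The filtered table, row order preserved.
#' @export
prefilter_min_nonzero <- function(intensities, group_labels, min_nonzero = 2) {
  check_intensity_table(intensities)
  m <- intensity_matrix(intensities)
  samp <- colnames(m)
  if (is.null(names(group_labels))) {
    if (length(group_labels) != length(samp)) {
      abort("Unnamed `group_labels` must have one entry per sample column.")
    }
    names(group_labels) <- samp
  }
  unknown <- setdiff(samp, names(group_labels))
  if (length(unknown) > 0) {
    abort(sprintf(
      "No group label for sample(s): %s.", paste(unknown, collapse = ", ")
    ))
  }
  group_labels <- group_labels[samp]
  keep <- rep(TRUE, nrow(m))
  for (g in unique(group_labels)) {
    nz <- rowSums(m[, group_labels == g, drop = FALSE] > 0)
    keep <- keep & nz >= min_nonzero
  }
  intensities[keep, , drop = FALSE]
}

#' Log2-transform a protein table, marking zeros as missing
#'
#' Positive intensities become log2 values; zeros (not observed) become `NA`.
#'
#' @param intensities Protein table with nonnegative values.
#' @return Tibble of the same shape with log2 values and `NA` for zeros.
#' @export
log2_transform <- function(intensities) {
  check_intensity_table(intensities)
  m <- intensity_matrix(intensities)
  lm2 <- ifelse(m > 0, log2(m), NA_real_)
  set_intensities(intensities, lm2)
}

#' QRILC imputation of left-censored missing values
#'
#' Imputes missing (left-censored) log2 intensities per sample by quantile
#' regression imputation of left-censored data: for each sample, the complete
#' underlying distribution's mean and sd are estimated by least-squares
#' regression of the observed order statistics on standard-normal quantiles
#' at plotting positions `(i - 0.375) / (n + 0.25)`, where the ranks `i`
#' start after the censored count (the observed values are treated as the
#' upper tail of a Normal whose lower tail was censored). Each missing entry
#' is then drawn from `Normal(mu, sd * tune_sigma)` truncated above at the
#' sample's minimum observed value.
#'
#' @param logmat Log2 table as returned by [log2_transform()] (`NA` =
#'   missing).
#' @param tune_sigma Multiplier on the estimated sd of the imputation
#'   distribution (default 1).
#' @param seed Integer seed; imputation is deterministic given the seed.
#' @return A list of class `qrilc_imputed` with elements `data` (complete
#'   table), `imputed` (long tibble `accession`, `sample_id` of imputed
#'   entries), and `params` (per-sample tibble: `mu`, `sigma`,
#'   `truncation_point`, `n_observed`, `n_missing`, `tune_sigma`, `seed`).
#' @export
qrilc_impute <- function(logmat, tune_sigma = 1.0, seed = 1L) {
  check_positive(tune_sigma, "tune_sigma")
  m <- intensity_matrix_allow_na(logmat)
  samp <- colnames(m)
  n_total <- nrow(m)

  params <- vector("list", length(samp))
  imputed_cells <- vector("list", length(samp))
  withr::with_seed(seed, {
    for (j in seq_along(samp)) {
      y <- m[, j]
      obs <- which(!is.na(y))
      n_obs <- length(obs)
      n_miss <- n_total - n_obs
      if (n_obs < 3) {
        abort(sprintf(
          "Sample '%s' has %d observed value(s); QRILC needs at least 3.",
          samp[j], n_obs
        ))
      }
      est <- qrilc_estimate(y[obs], n_miss)
      if (est$sigma <= 0) {
        abort(sprintf(
          "Non-positive sd estimate for sample '%s'; cannot impute.", samp[j]
        ))
      }
      trunc_point <- min(y[obs])
      if (n_miss > 0) {
        miss <- which(is.na(y))
        sd_imp <- est$sigma * tune_sigma
        # inverse-CDF draw from Normal(mu, sd_imp) truncated above at the
        # sample's minimum observed value
        p_upper <- stats::pnorm(trunc_point, est$mu, sd_imp)
        u <- stats::runif(n_miss, 0, p_upper)
        m[miss, j] <- stats::qnorm(u, est$mu, sd_imp)
        imputed_cells[[j]] <- tibble::tibble(
          accession = logmat$accession[miss], sample_id = samp[j]
        )
      }
      params[[j]] <- tibble::tibble(
        sample_id = samp[j], mu = est$mu, sigma = est$sigma,
        truncation_point = trunc_point, n_observed = n_obs,
        n_missing = n_miss, tune_sigma = tune_sigma, seed = as.integer(seed)
      )
    }
  })

  out <- list(
    data = set_intensities(logmat, m),
    imputed = dplyr::bind_rows(imputed_cells) %||%
      tibble::tibble(accession = character(0), sample_id = character(0)),
    params = dplyr::bind_rows(params)
  )
  if (nrow(out$imputed) == 0) {
    out$imputed <- tibble::tibble(
      accession = character(0), sample_id = character(0)
    )
  }
  class(out) <- "qrilc_imputed"
  out
}

# Estimate (mu, sigma) of the complete Normal from the observed upper tail of
# a left-censored sample: regress sorted observed values on standard-normal
# quantiles at Blom plotting positions whose ranks start after the censored
# count.
qrilc_estimate <- function(observed, n_missing) {
  y <- sort(observed)
  n <- length(y) + n_missing
  ranks <- (n_missing + 1):n
  q <- stats::qnorm((ranks - 0.375) / (n + 0.25))
  fit <- stats::lm.fit(cbind(1, q), y)
  list(mu = unname(fit$coefficients[1]), sigma = unname(fit$coefficients[2]))
}

#' @export
print.qrilc_imputed <- function(x, ...) {
  cat(sprintf(
    "QRILC-imputed log2 matrix: %d proteins x %d samples, %d imputed entries\n",
    nrow(x$data), nrow(x$params), nrow(x$imputed)
  ))
  print(x$params)
  invisible(x)
}

#' @export
tidy.qrilc_imputed <- function(x, ...) x$params

#' @export
glance.qrilc_imputed <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$data),
    n_samples = nrow(x$params),
    n_imputed = nrow(x$imputed),
    tune_sigma = x$params$tune_sigma[1],
    seed = x$params$seed[1]
  )
}

#' Back-transform log2 values to the decimal scale
#'
#' `value -> 2^value`, e.g. for plotting bar graphs of imputed intensities on
#' the original intensity scale. Accepts a log2 table or a `qrilc_imputed`
#' object (imputation flags are carried through as an attribute).
#'
#' @param x Log2 protein table or [qrilc_impute()] result.
#' @return Decimal-scale tibble.
#' @export
delog <- function(x) {
  if (inherits(x, "qrilc_imputed")) {
    out <- delog(x$data)
    attr(out, "imputed") <- x$imputed
    return(out)
  }
  m <- intensity_matrix_allow_na(x)
  set_intensities(x, 2^m)
}

# Like intensity_matrix() but NA entries (missing markers) are allowed.
intensity_matrix_allow_na <- function(tbl) {
  if (!is.data.frame(tbl) || !all(ANNOT_COLS %in% names(tbl))) {
    abort("Expected a protein table with accession/gene/organism columns.")
  }
  sc <- sample_cols(tbl)
  m <- as.matrix(tbl[, sc, drop = FALSE])
  rownames(m) <- tbl$accession
  storage.mode(m) <- "double"
  if (any(is.infinite(m), na.rm = TRUE)) {
    abort("Log2 table contains non-finite values other than NA.")
  }
  m
}
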