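# Differential statistics: Welch tests, permutation-based FDR q-values,
# geometric-mean fold changes, volcano categorisation, and the auxiliary
# tests (Pearson correlation, Grubbs, paired t, one-way ANOVA + Tukey).

#' Welch's two-sample t-test
#'
#' Two-tailed t-test not assuming equal variances:
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return One-row tibble: `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @examples
#' welch_t(c(10, 12, 14), c(20, 22, 24))
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2 || anyNA(a) || anyNA(b)) {
    abort("Each group needs >= 2 non-missing values.")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      warn("Both groups have zero variance and equal means; t = 0, p = 1.")
      return(tibble::tibble(
        mean_a = mean(a), mean_b = mean(b), t = 0, df = NA_real_, p = 1
      ))
    }
    abort("Both groups have zero variance but unequal means; t is undefined.")
  }
  se2a <- va / length(a)
  se2b <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  tibble::tibble(
    mean_a = mean(a), mean_b = mean(b),
    t = t, df = df, p = 2 * stats::pt(-abs(t), df)
  )
}

# Vectorised row-wise Welch statistics for a proteins x samples matrix.
# `s0` is the SAM-style fudge factor added to the standard error.
row_welch <- function(m, idx_a, idx_b, s0 = 0) {
  na <- length(idx_a)
  nb <- length(idx_b)
  ma <- rowMeans(m[, idx_a, drop = FALSE])
  mb <- rowMeans(m[, idx_b, drop = FALSE])
  va <- rowSums((m[, idx_a, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((m[, idx_b, drop = FALSE] - mb)^2) / (nb - 1)
  se2a <- va / na
  se2b <- vb / nb
  se <- sqrt(se2a + se2b)
  t <- (ma - mb) / (se + s0)
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  df[se2a + se2b == 0] <- NA_real_
  t[se2a + se2b == 0 & ma == mb] <- 0
  list(mean_a = ma, mean_b = mb, t = t, df = df,
       p = ifelse(is.na(df), as.numeric(ma == mb), 2 * stats::pt(-abs(t), df)))
}

# All distinct two-group label assignments (columns = indices of pseudo-group
# A) when their number is at most `limit`; otherwise NULL.
exhaustive_assignments <- function(n, n_a, limit = 1000) {
  if (choose(n, n_a) > limit) {
    return(NULL)
  }
  utils::combn(n, n_a)
}

#' Permutation-based FDR q-values for a two-group comparison
#'
#' Computes per-protein Welch t statistics and q-values by permuting group
#' labels, in the style of significance analysis of microarrays: at each
#' observed `|t|` threshold, the estimated FDR is the mean number of permuted
#' statistics at or above the threshold divided by the observed number at or
#' above it, clipped to `[0, 1]`; a protein's q-value is the smallest FDR at
#' which it is called significant, which makes q monotone non-decreasing in
#' the p-value rank. Label assignments are enumerated exhaustively when there
#' are at most `max_exhaustive` distinct ones, otherwise `n_permutations`
#' random reshuffles are drawn.
#'
#' @param mat Complete (no missing values) log2 table (protein tibble) or a
#'   numeric proteins x samples matrix.
#' @param labels Two-level group labels, named by sample id or parallel to
#'   the sample columns.
#' @param n_permutations Number of random permutations when exhaustive
#'   enumeration is not feasible.
#' @param s0 SAM-style fudge factor added to the per-protein standard error
#'   (default 0).
#' @param max_exhaustive Enumerate all distinct assignments when their count
#'   is at most this.
#' @param summary Aggregation of the permuted exceedance counts: `"mean"`
#'   (default) or `"median"`.
#' @param seed Seed for random permutations.
#' @return Tibble with one row per protein: `accession` (if available),
#'   `mean_a`, `mean_b`, `t`, `df`, `p`, `q`, plus attributes `n_permutations`
#'   and `exhaustive`.
#' @export
permutation_fdr <- function(mat, labels, n_permutations = 250, s0 = 0,
                            max_exhaustive = 1000,
                            summary = c("mean", "median"), seed = 1L) {
  summary <- match.arg(summary)
  if (is.data.frame(mat)) {
    accession <- mat$accession
    m <- intensity_matrix_allow_na(mat)
  } else {
    m <- as.matrix(mat)
    accession <- rownames(m) %||% sprintf("row%d", seq_len(nrow(m)))
  }
  if (anyNA(m)) abort("`mat` must be complete (impute first).")
  labels <- resolve_labels(labels, colnames(m), ncol(m))
  lev <- unique(labels)
  if (length(lev) != 2) abort("`labels` must have exactly two levels.")
  idx_a <- which(labels == lev[1])
  idx_b <- which(labels == lev[2])
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    abort("Each group needs >= 2 samples.")
  }

  n <- ncol(m)
  assign <- exhaustive_assignments(n, length(idx_a), max_exhaustive)
  exhaustive <- !is.null(assign)
  if (exhaustive && ncol(assign) < 2) {
    abort("Fewer than 2 distinct permutations possible.")
  }

  obs <- row_welch(m, idx_a, idx_b, s0 = s0)
  obs_abs <- abs(obs$t)

  perm_stats <- if (exhaustive) {
    vapply(seq_len(ncol(assign)), function(k) {
      ia <- assign[, k]
      abs(row_welch(m, ia, setdiff(seq_len(n), ia), s0 = s0)$t)
    }, numeric(nrow(m)))
  } else {
    withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(k) {
        ia <- sample.int(n, length(idx_a))
        abs(row_welch(m, ia, setdiff(seq_len(n), ia), s0 = s0)$t)
      }, numeric(nrow(m)))
    })
  }
  n_perm <- ncol(perm_stats)

  q <- sam_qvalues(obs_abs, perm_stats, summary, p = obs$p)

  out <- tibble::tibble(
    accession = accession,
    mean_a = obs$mean_a, mean_b = obs$mean_b,
    t = obs$t, df = obs$df, p = obs$p, q = q
  )
  attr(out, "group_a") <- lev[1]
  attr(out, "group_b") <- lev[2]
  attr(out, "n_permutations") <- n_perm
  attr(out, "exhaustive") <- exhaustive
  out
}

# q-values from observed |t| and a proteins x permutations matrix of
# permuted |t|. Counts use >= (inclusive) at each observed threshold. When
# p-values are supplied, q is additionally made monotone non-decreasing in
# the p-rank (the |t| order can differ from the p order because the Welch
# degrees of freedom vary across proteins).
sam_qvalues <- function(obs_abs, perm_stats, summary = "mean", p = NULL) {
  n_prot <- length(obs_abs)
  n_perm <- ncol(perm_stats)
  ord <- order(obs_abs, decreasing = TRUE)
  thresholds <- obs_abs[ord]
  # observed count at each threshold: number of observed |t| >= threshold
  sorted_obs <- sort(obs_abs)
  obs_count <- n_prot - findInterval(thresholds, sorted_obs, left.open = TRUE)
  # permuted exceedance counts via one sorted pool (mean) or per-permutation
  if (summary == "mean") {
    pool <- sort(as.numeric(perm_stats))
    exp_count <- (length(pool) -
      findInterval(thresholds, pool, left.open = TRUE)) / n_perm
  } else {
    per_perm <- apply(perm_stats, 2, function(col) {
      sc <- sort(col)
      length(sc) - findInterval(thresholds, sc, left.open = TRUE)
    })
    exp_count <- apply(matrix(per_perm, ncol = n_perm), 1, stats::median)
  }
  fdr <- pmin(pmax(exp_count / obs_count, 0), 1)
  # q_i = min FDR over thresholds at or below this protein's |t|
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(n_prot)
  q[ord] <- q_sorted
  if (!is.null(p)) {
    op <- order(p, decreasing = TRUE)
    q[op] <- cummin(q[op])
  }
  q
}

resolve_labels <- function(labels, samp, n) {
  labels <- as.character(labels)
  if (!is.null(names(labels)) && !is.null(samp)) {
    missing <- setdiff(samp, names(labels))
    if (length(missing) > 0) {
      abort(sprintf(
        "No label for sample(s): %s.", paste(missing, collapse = ", ")
      ))
    }
    labels <- labels[samp]
  } else if (length(labels) != n) {
    abort("`labels` must have one entry per sample.")
  }
  labels
}

#' Fold change of geometric means
#'
#' `FC = geomean(a) / geomean(b)`; its log2 equals the difference of mean
#' log2 values, so fold changes computed on imputed decimal intensities agree
#' with log2 differences computed on the imputed log2 matrix.
#'
#' @param a,b Positive numeric vectors (decimal scale, post-imputation).
#' @return One-row tibble: `fc`, `log2fc`.
#' @examples
#' geometric_fold_change(c(4, 16), c(1, 1)) # fc 8, log2fc 3
#' @export
geometric_fold_change <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    abort("All values must be > 0 (impute before computing fold changes).")
  }
  log2fc <- mean(log2(a)) - mean(log2(b))
  tibble::tibble(fc = 2^log2fc, log2fc = log2fc)
}

#' Categorise proteins for a volcano plot
#'
#' `high_in_A` when `log2fc > fc_threshold` and `q < q_threshold`;
#' `high_in_B` when `log2fc < -fc_threshold` and `q < q_threshold`;
#' otherwise non-significant. Boundary equalities fall into `NS`
#' (`q >= q_threshold` or `-fc_threshold <= log2fc <= fc_threshold`).
#'
#' @param log2fc,q Numeric vectors (recycled to common length).
#' @param fc_threshold,q_threshold Cut-offs (defaults 1 and 0.05).
#' @param labels Category names for the two significant sides (defaults
#'   `"high_in_A"`, `"high_in_B"`).
#' @return Character vector of categories (`labels[1]`, `labels[2]`, `"NS"`).
#' @export
classify_volcano <- function(log2fc, q, fc_threshold = 1, q_threshold = 0.05,
                             labels = c("high_in_A", "high_in_B")) {
  stopifnot(all(is.finite(log2fc)), all(is.finite(q)))
  dplyr::case_when(
    log2fc > fc_threshold & q < q_threshold ~ labels[1],
    log2fc < -fc_threshold & q < q_threshold ~ labels[2],
    TRUE ~ "NS"
  )
}

#' Pairwise Pearson correlation between samples
#'
#' Correlates every pair of sample columns over proteins present (non-missing)
#' in both, reporting r and the two-sided test p-value. Pairs with fewer than
#' 3 complete observations, or a zero-variance member, get `NA`.
#'
#' @param mat Protein table (log2 or decimal; `NA` allowed) or numeric
#'   matrix.
#' @return Long tibble `sample_a`, `sample_b`, `n`, `r`, `p`, including the
#'   unit diagonal; symmetric.
#' @export
sample_correlation <- function(mat) {
  m <- if (is.data.frame(mat)) intensity_matrix_allow_na(mat) else as.matrix(mat)
  samp <- colnames(m) %||% sprintf("s%d", seq_len(ncol(m)))
  colnames(m) <- samp
  pairs <- tidyr::expand_grid(sample_a = samp, sample_b = samp)
  res <- purrr::pmap_dfr(pairs, function(sample_a, sample_b) {
    x <- m[, sample_a]
    y <- m[, sample_b]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (sample_a == sample_b) {
      return(tibble::tibble(
        sample_a, sample_b, n = n, r = 1, p = 0
      ))
    }
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(
        sample_a, sample_b, n = n, r = NA_real_, p = NA_real_
      ))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(
      sample_a, sample_b, n = n,
      r = unname(ct$estimate), p = ct$p.value
    )
  })
  res
}

#' Grubbs's test for a single outlier
#'
#' Two-sided Grubbs statistic `G = max|x - mean| / sd` compared against the
#' t-based critical value at significance `alpha`:
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `outlier_index` (NA if none), `outlier_value`,
#'   `g`, `g_critical`, `alpha`.
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) abort("Grubbs's test needs at least 3 values.")
  s <- stats::sd(x)
  if (s == 0) {
    warn("Zero standard deviation; no outlier definable.")
    return(tibble::tibble(
      outlier_index = NA_integer_, outlier_value = NA_real_,
      g = 0, g_critical = NA_real_, alpha = alpha
    ))
  }
  dev <- abs(x - mean(x))
  g <- max(dev) / s
  tcrit <- stats::qt(1 - alpha / (2 * n), n - 2)
  g_crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  idx <- if (g > g_crit) which.max(dev) else NA_integer_
  tibble::tibble(
    outlier_index = idx,
    outlier_value = if (is.na(idx)) NA_real_ else x[idx],
    g = g, g_critical = g_crit, alpha = alpha
  )
}

#' Paired t-test
#'
#' One-sample t-test on within-pair differences, two-tailed. Degenerate
#' all-zero differences give `t = 0, p = 1` with a warning; zero-variance
#' nonzero differences are an error.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return One-row tibble: `mean_diff`, `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must be equal-length vectors with >= 2 pairs.")
  }
  d <- as.numeric(x) - as.numeric(y)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      warn("All pairs identical; t = 0, p = 1.")
      return(tibble::tibble(
        mean_diff = 0, t = 0, df = length(d) - 1, p = 1
      ))
    }
    abort("Zero variance of nonzero differences; paired t is degenerate.")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    mean_diff = unname(tt$estimate), t = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value
  )
}

#' One-way ANOVA with Tukey's multiple comparisons
#'
#' Standard one-way ANOVA across three or more groups, followed by Tukey's
#' honestly-significant-difference pairwise comparisons at the 0.95
#' confidence level.
#'
#' @param values Numeric vector of observations, or a list of numeric vectors
#'   (one per group, in which case `groups` is ignored).
#' @param groups Group labels parallel to `values`.
#' @param conf_level Confidence level for Tukey intervals (default 0.95).
#' @return List with `anova` (one-row tibble: `f`, `df_between`, `df_within`,
#'   `p`) and `tukey` (tibble of pairwise comparisons: `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, groups = NULL, conf_level = 0.95) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(
      names(values) %||% sprintf("g%d", seq_along(values)),
      lengths(values)
    )
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 3) {
    abort("anova_tukey needs >= 3 groups; use welch_t for two groups.")
  }
  if (any(table(groups) < 2)) abort("Each group needs >= 2 values.")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
  list(
    anova = tibble::tibble(
      f = s[["F value"]][1],
      df_between = s[["Df"]][1],
      df_within = s[["Df"]][2],
      p = s[["Pr(>F)"]][1]
    ),
    tukey = tibble::tibble(
      comparison = rownames(tuk),
      diff = unname(tuk[, "diff"]), lwr = unname(tuk[, "lwr"]),
      upr = unname(tuk[, "upr"]), p_adj = unname(tuk[, "p adj"])
    )
  )
}
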