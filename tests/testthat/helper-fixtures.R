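# Small fixture builders shared across test files.

# A protein table from a plain matrix (columns = samples).
protein_table <- function(m, organism = "human",
                          genes = sprintf("G%d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("s%d", seq_len(ncol(m)))
  organism <- rep_len(organism, nrow(m))
  dplyr::bind_cols(
    tibble::tibble(
      accession = sprintf("P%03d", seq_len(nrow(m))),
      gene = genes,
      organism = organism
    ),
    tibble::as_tibble(as.data.frame(m))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A single-sample log2 table with NAs for missing entries.
log_column_table <- function(values) {
  tibble::tibble(
    accession = sprintf("P%04d", seq_along(values)),
    gene = sprintf("G%d", seq_along(values)),
    organism = "human",
    s1 = values
  )
}

# Rasterize a filled disk independently of the package internals.
oracle_disk <- function(nrow, ncol, cx, cy, r) {
  out <- matrix(FALSE, nrow, ncol)
  for (i in seq_len(nrow)) {
    for (j in seq_len(ncol)) {
      if ((j - cx)^2 + (i - cy)^2 <= r^2) out[i, j] <- TRUE
    }
  }
  out
}

# Brute-force permutation-FDR oracle: enumerates all label assignments with
# nested loops and naive counting, entirely independent of the package path.
brute_force_q <- function(m, n_a) {
  n <- ncol(m)
  combos <- utils::combn(n, n_a)
  tstat <- function(ia) {
    ib <- setdiff(seq_len(n), ia)
    apply(m, 1, function(x) {
      unname(stats::t.test(x[ia], x[ib])$statistic)
    })
  }
  obs <- abs(tstat(seq_len(n_a)))
  pvals <- apply(m, 1, function(x) {
    stats::t.test(x[seq_len(n_a)], x[-seq_len(n_a)])$p.value
  })
  perm <- sapply(seq_len(ncol(combos)), function(k) abs(tstat(combos[, k])))
  q <- numeric(nrow(m))
  fdr_at <- function(th) {
    exp_count <- mean(apply(perm, 2, function(col) sum(col >= th)))
    min(max(exp_count / sum(obs >= th), 0), 1)
  }
  fdrs <- vapply(obs, fdr_at, numeric(1))
  for (i in seq_along(obs)) {
    q[i] <- min(fdrs[obs <= obs[i]])
  }
  # the q-value is monotone non-decreasing in the p-rank by definition
  for (i in seq_along(obs)) {
    q[i] <- min(q[pvals >= pvals[i]])
  }
  q
}
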