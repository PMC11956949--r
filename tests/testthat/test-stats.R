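# Differential statistics: Welch, permutation FDR, fold changes, volcano
# categories, correlation, Grubbs, paired t, ANOVA + Tukey.

test_that("welch_t matches the closed-form computation and base t.test", {
  res <- welch_t(c(10, 12, 14), c(20, 22, 24))
  expect_equal(res$t, -10 / sqrt(8 / 3), tolerance = 1e-9)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_equal(res$p, 2 * stats::pt(-abs(res$t), 4), tolerance = 1e-12)

  # independent cross-check against the standard implementation
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    ref <- stats::t.test(a, b)
    got <- welch_t(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t symmetry and degenerate contracts", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  ab <- welch_t(c(1, 4, 2), c(5, 3, 9))
  ba <- welch_t(c(5, 3, 9), c(1, 4, 2))
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)

  expect_warning(z <- welch_t(c(2, 2), c(2, 2)), "zero variance")
  expect_equal(z$p, 1)
  expect_error(welch_t(c(2, 2), c(3, 3)), "undefined")
})

test_that("geometric fold changes follow the log2-mean identity", {
  fc <- geometric_fold_change(c(4, 16), c(1, 1))
  expect_equal(fc$fc, 8)
  expect_equal(fc$log2fc, 3)

  same <- geometric_fold_change(c(2, 5), c(2, 5))
  expect_equal(same$fc, 1)

  set.seed(8)
  a <- rexp(6, 1e-3)
  b <- rexp(4, 1e-3)
  expect_equal(
    geometric_fold_change(a, b)$fc * geometric_fold_change(b, a)$fc, 1,
    tolerance = 1e-12
  )
  expect_equal(
    geometric_fold_change(a, b)$log2fc,
    mean(log2(a)) - mean(log2(b)),
    tolerance = 1e-12
  )
  expect_error(geometric_fold_change(c(1, 0), c(1, 1)), "> 0")
})

test_that("volcano categories respect inclusive boundaries", {
  expect_identical(classify_volcano(2, 0.01), "high_in_A")
  expect_identical(classify_volcano(-1.5, 0.2), "NS")
  expect_identical(classify_volcano(-1.5, 0.01), "high_in_B")
  # equalities fall into NS
  expect_identical(classify_volcano(1, 0.01), "NS")
  expect_identical(classify_volcano(-1, 0.01), "NS")
  expect_identical(classify_volcano(2, 0.05), "NS")
})

test_that("sample correlation matches the Pearson formula and handles edge cases", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  cc <- sample_correlation(m)
  expect_equal(cc$r[cc$sample_a == "a" & cc$sample_b == "b"], 0.8)

  dup <- cbind(x = c(1, 5, 2, 8), y = c(1, 5, 2, 8))
  expect_equal(
    sample_correlation(dup)$r[2], 1
  )
  neg <- cbind(x = c(1, 5, 2, 8), y = -c(1, 5, 2, 8))
  expect_equal(sample_correlation(neg)$r[2], -1)

  flat <- cbind(x = c(1, 2, 3), y = c(2, 2, 2))
  expect_true(is.na(sample_correlation(flat)$r[2]))
  # symmetric with unit diagonal
  set.seed(9)
  r <- sample_correlation(matrix(rnorm(30), 10, 3))
  wide <- matrix(r$r, 3, 3)
  expect_equal(wide, t(wide))
  expect_equal(diag(wide), rep(1, 3))
})

test_that("Grubbs's test flags the single gross outlier", {
  expect_warning(none <- grubbs_outlier(c(5, 5, 5, 5)), "Zero standard")
  expect_true(is.na(none$outlier_index))

  res <- grubbs_outlier(c(8, 9, 10, 50))
  # critical value from the t-based formula, n = 4, alpha = 0.05
  expect_equal(res$g_critical, 1.48125, tolerance = 1e-4)
  expect_gt(res$g, res$g_critical)
  expect_identical(res$outlier_value, 50)

  sym <- grubbs_outlier(c(1, 2, 3))
  expect_equal(sym$g, 1)
  expect_equal(sym$g_critical, 1.154305, tolerance = 1e-4)
  expect_true(is.na(sym$outlier_index))
})

test_that("paired t-test matches hand computation and symmetry", {
  expect_warning(same <- paired_t(c(1, 2, 3), c(1, 2, 3)), "identical")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  res <- paired_t(c(2, 3, 5), c(1, 2, 3)) # differences 1, 1, 2
  expect_equal(res$t, 4, tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-4, 2), tolerance = 1e-9)

  fl <- paired_t(c(1, 2, 3), c(2, 3, 5))
  expect_equal(fl$t, -res$t)
  expect_equal(fl$p, res$p)

  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "Zero variance")
})

test_that("one-way ANOVA and Tukey match an independently coded oracle", {
  # textbook-formula oracle
  oracle <- function(groups) {
    k <- length(groups)
    n <- lengths(groups)
    gm <- mean(unlist(groups))
    ssb <- sum(n * (vapply(groups, mean, 0) - gm)^2)
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
    dfb <- k - 1
    dfw <- sum(n) - k
    f <- (ssb / dfb) / (ssw / dfw)
    mse <- ssw / dfw
    pairs <- utils::combn(k, 2)
    padj <- apply(pairs, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      q <- abs(mean(groups[[i]]) - mean(groups[[j]])) /
        sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
      1 - stats::ptukey(q, k, dfw)
    })
    list(f = f, p = 1 - stats::pf(f, dfb, dfw), padj = padj)
  }

  set.seed(10)
  groups <- list(a = rnorm(3, 0), b = rnorm(3, 1), c = rnorm(3, 3))
  got <- anova_tukey(groups)
  ref <- oracle(groups)
  expect_equal(got$anova$f, ref$f, tolerance = 1e-8)
  expect_equal(got$anova$p, ref$p, tolerance = 1e-8)
  expect_equal(sort(got$tukey$p_adj), sort(ref$padj), tolerance = 1e-8)

  # identical groups: no between-group variance
  flat <- anova_tukey(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3), g3 = c(1, 2, 3)))
  expect_equal(flat$anova$f, 0)
  expect_equal(flat$anova$p, 1)

  # ordering contract: the deviant group differs from both identical ones
  ord <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 11, 12)))
  tk <- ord$tukey
  expect_gt(tk$p_adj[tk$comparison == "b-a"], 0.05)
  expect_lt(tk$p_adj[tk$comparison == "c-a"], 0.05)
  expect_lt(tk$p_adj[tk$comparison == "c-b"], 0.05)

  expect_error(anova_tukey(list(a = 1:3, b = 4:6)), ">= 3 groups")
})


test_that("exhaustive permutation q-values equal the brute-force oracle", {
  set.seed(12)
  for (rep in 1:3) {
    m <- matrix(rnorm(5 * 6), 5, 6)
    m[1, 1:3] <- m[1, 1:3] + 4 # one strong effect
    colnames(m) <- sprintf("s%d", 1:6)
    got <- permutation_fdr(m, rep(c("A", "B"), each = 3))
    expect_true(attr(got, "exhaustive"))
    expect_equal(attr(got, "n_permutations"), 20)
    expect_equal(got$q, brute_force_q(m, 3), tolerance = 1e-12)
  }
})

test_that("a statistic beyond every permuted value gets q = 0", {
  obs <- c(10, 1.2, 0.5)
  perm <- matrix(runif(30, 0, 2), 3, 10)
  q <- newsecm:::sam_qvalues(obs, perm)
  expect_identical(q[1], 0)
  expect_true(all(q >= 0 & q <= 1))
})

test_that("q-values are monotone non-decreasing in the p-rank", {
  set.seed(13)
  m <- matrix(rnorm(50 * 8), 50, 8)
  m[1:5, 1:4] <- m[1:5, 1:4] + 3
  res <- permutation_fdr(m, rep(c("A", "B"), each = 4), seed = 2)
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
})

test_that("permutation FDR is calibrated under a small global null", {
  set.seed(14)
  m <- matrix(rnorm(300 * 8), 300, 8)
  res <- permutation_fdr(m, rep(c("A", "B"), each = 4), seed = 3)
  expect_lte(mean(res$q < 0.05), 0.07)
})
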