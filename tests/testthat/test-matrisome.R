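# Matrisome annotation and category accounting.

test_that("annotation matches case-insensitively and flags duplicates", {
  fx <- make_matrisome_fixture(2)
  empty <- fx[0, ]
  ann <- annotate_matrisome(c("FOO", "BAR"), empty)
  expect_true(all(ann$category == "non-matrisome"))

  hit <- annotate_matrisome(c("REGU001", "regu002", "XYZ"), fx)
  expect_identical(hit$category[1:2], rep("ECM regulators", 2))
  expect_identical(hit$division[1:2], rep("matrisome-associated", 2))
  expect_identical(hit$category[3], "non-matrisome")

  dup <- rbind(fx, fx[1, ])
  expect_error(annotate_matrisome("COLS001", dup), "Duplicate")
})

test_that("category summary reproduces hand-computed counts and ratios", {
  fx <- make_matrisome_fixture(5)
  # eluate identifies 5 ECM-regulator genes, input only 2
  genes <- c(sprintf("REGU%03d", 1:5), sprintf("COLS%03d", 1:2), "OTHER1")
  inp <- protein_table(
    cbind(i1 = c(3, 4, 0, 0, 0, 60, 40, 10),
          i2 = c(2, 1, 0, 0, 0, 0, 0, 5)),
    genes = genes
  )
  elu <- protein_table(
    cbind(e1 = c(1, 2, 3, 4, 5, 16, 0, 2),
          e2 = c(1, 1, 1, 1, 1, 0, 10, 3)),
    genes = genes
  )
  cs <- category_summary(inp, elu, fx)
  reg <- cs[cs$category == "ECM regulators", ]
  expect_identical(reg$n_input, 2L)
  expect_identical(reg$n_eluate, 5L)
  expect_identical(reg$count_diff, 3L)

  col <- cs[cs$category == "collagens", ]
  expect_equal(col$intensity_input, 100)
  expect_equal(col$intensity_eluate, 26)
  expect_equal(col$intensity_ratio, 0.26)

  # proportions computed over all identified proteins, non-matrisome included
  expect_equal(sum(cs$prop_input), 1, tolerance = 1e-12)
  expect_equal(sum(cs$prop_eluate), 1, tolerance = 1e-12)
  expect_lte(sum(cs$prop_eluate[cs$category != "non-matrisome"]), 1)

  # identical fractions: zero differences, unit ratios where defined
  same <- category_summary(inp, inp, fx)
  expect_true(all(same$count_diff == 0))
  expect_true(all(same$intensity_ratio[!is.na(same$intensity_ratio)] == 1))
})

test_that("category counts partition the identified proteins", {
  sim <- simulate_lfq(n_proteins_human = 60, n_proteins_rat = 0,
                      n_per_group = 2, censor_quantile = 0.3, seed = 21)
  fx <- make_matrisome_fixture(4)
  # re-gene some simulated proteins into fixture categories
  tbl <- sim$intensities
  tbl$gene[1:24] <- fx$gene
  ids_in <- sim$samples$sample_id[sim$samples$fraction == "input"]
  ids_el <- sim$samples$sample_id[sim$samples$fraction == "eluate"]
  inp <- tbl[, c("accession", "gene", "organism", ids_in)]
  elu <- tbl[, c("accession", "gene", "organism", ids_el)]
  cs <- category_summary(inp, elu, fx)
  n_ident_inp <- sum(rowSums(as.matrix(inp[, ids_in]) > 0) >= 1)
  n_ident_elu <- sum(rowSums(as.matrix(elu[, ids_el]) > 0) >= 1)
  expect_identical(sum(cs$n_input), n_ident_inp)
  expect_identical(sum(cs$n_eluate), n_ident_elu)
})

test_that("a spiked category shows the largest eluate/input ratio", {
  fx <- make_matrisome_fixture(10)
  sim <- simulate_lfq(n_proteins_human = 60, n_proteins_rat = 0,
                      n_per_group = 3, censor_quantile = 0,
                      enrichment_log2fc = 0, seed = 31)
  tbl <- sim$intensities
  tbl$gene <- c(fx$gene) # 60 genes across the 6 categories
  ids_in <- sim$samples$sample_id[sim$samples$fraction == "input"]
  ids_el <- sim$samples$sample_id[sim$samples$fraction == "eluate"]
  # spike proteoglycans 10-fold in the eluate fraction
  spike <- grepl("^PROG", tbl$gene)
  tbl[spike, ids_el] <- tbl[spike, ids_el] * 10
  cs <- category_summary(
    tbl[, c("accession", "gene", "organism", ids_in)],
    tbl[, c("accession", "gene", "organism", ids_el)],
    fx
  )
  cs <- cs[!is.na(cs$intensity_ratio), ]
  expect_identical(
    cs$category[which.max(cs$intensity_ratio)], "proteoglycans"
  )
})

test_that("matrisome annotation round-trips through CSV", {
  fx <- make_matrisome_fixture(2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrisome(fx, path)
  back <- read_matrisome(path)
  expect_equal(as.data.frame(back), as.data.frame(fx))
})
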