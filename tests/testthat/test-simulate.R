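# Synthetic-data generators: LFQ tables, matrisome fixture, tissue images.

test_that("simulate_lfq is deterministic and honours degenerate settings", {
  cfg <- list(n_proteins_human = 40, n_proteins_rat = 10, n_per_group = 3,
              seed = 11)
  a <- do.call(simulate_lfq, cfg)
  b <- do.call(simulate_lfq, cfg)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$truth, b$truth)

  # zero noise, zero censoring, no differentials: all samples of a group
  # structure are identical up to machine precision and nothing is missing
  d <- simulate_lfq(
    n_proteins_human = 30, n_proteins_rat = 10, n_per_group = 3,
    within_protein_sd = 0, enrichment_log2fc = 0,
    frac_true_differential = 0, censor_quantile = 0, seed = 2
  )
  m <- as.matrix(d$intensities[, d$samples$sample_id])
  expect_true(all(abs(m - m[, 1]) < 1e-9 * m[, 1]))
  expect_identical(sum(m == 0), 0L)
  expect_identical(nrow(d$truth$censored), 0L)

  expect_error(simulate_lfq(n_per_group = 0), "n_per_group")
})

test_that("left-censoring zeroes exactly the lowest fraction of each sample", {
  sim <- simulate_lfq(
    n_proteins_human = 600, n_proteins_rat = 400, n_per_group = 2,
    censor_quantile = 0.2, seed = 7
  )
  m <- as.matrix(sim$intensities[, sim$samples$sample_id])
  # reconstruct the pre-censoring draw from the recorded censored values
  pre <- m
  cens <- sim$truth$censored
  for (k in seq_len(nrow(cens))) {
    pre[match(cens$accession[k], sim$intensities$accession),
        cens$sample_id[k]] <- cens$pre_censor_value[k]
  }
  for (j in seq_len(ncol(m))) {
    zeros <- which(m[, j] == 0)
    expect_length(zeros, floor(0.2 * 1000))
    # sort-and-count oracle: the zeroed entries are the lowest 20% of the
    # pre-censoring values of that sample
    expect_setequal(zeros, order(pre[, j])[seq_len(200)])
  }
  # emitted zeros are exactly the recorded censored entries
  zero_cells <- which(m == 0, arr.ind = TRUE)
  expect_equal(nrow(zero_cells), nrow(cens))
  expect_setequal(
    paste(sim$intensities$accession[zero_cells[, 1]],
          colnames(m)[zero_cells[, 2]]),
    paste(cens$accession, cens$sample_id)
  )
})

test_that("raising the enrichment raises the labeled-species eluate/input ratio", {
  ratio <- function(enr, seed) {
    sim <- simulate_lfq(
      n_proteins_human = 120, n_proteins_rat = 60, n_per_group = 3,
      enrichment_log2fc = enr, censor_quantile = 0.1, seed = seed
    )
    sp <- run_search2_species(sim$intensities, sim$samples)
    hum <- sp[sp$organism == "human", ]
    hum$eluate_total / hum$input_total
  }
  seeds <- 1:5
  r0 <- vapply(seeds, function(s) ratio(0, s), numeric(1))
  r2 <- vapply(seeds, function(s) ratio(2, s), numeric(1))
  r4 <- vapply(seeds, function(s) ratio(4, s), numeric(1))
  expect_true(mean(r2) > mean(r0))
  expect_true(mean(r4) > mean(r2))
})

test_that("matrisome fixture matches the published category scheme", {
  expect_identical(nrow(make_matrisome_fixture(0)), 0L)
  fx <- make_matrisome_fixture(3)
  expect_equal(nrow(fx), 18)
  expect_length(unique(fx$category), 6)
  expect_length(unique(fx$division), 2)
  core <- c("collagens", "ECM glycoproteins", "proteoglycans")
  expect_true(all(fx$division[fx$category %in% core] == "core matrisome"))
  expect_true(all(fx$division[!fx$category %in% core] ==
                    "matrisome-associated"))
  expect_false(anyDuplicated(fx$gene) > 0)
})

test_that("tissue image generator is deterministic with exact marker levels", {
  a <- simulate_tissue_image(n_nuclei = 40, seed = 9)
  b <- simulate_tissue_image(n_nuclei = 40, seed = 9)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_mask, b$truth_mask)

  # equal marker levels inside and outside make the red channel uniform
  u <- simulate_tissue_image(
    n_nuclei = 40, marker_inside_level = 77, marker_outside_level = 77,
    seed = 3
  )
  expect_identical(length(unique(as.vector(u$image[, , 1]))), 1L)

  expect_warning(z <- simulate_tissue_image(n_nuclei = 0, seed = 1),
                 "empty")
  expect_false(any(z$truth_mask))
})

test_that("a single nucleus produces a truth mask equal to its raster disk", {
  sim <- simulate_tissue_image(
    width = 128, height = 128, n_nuclei = 1, nucleus_radius_px = 20, seed = 4
  )
  # independent rasterization oracle at the drawn centre
  expect_equal(nrow(sim$nuclei), 1)
  oracle <- oracle_disk(128, 128, sim$nuclei$x[1], sim$nuclei$y[1], 20)
  expect_identical(sim$truth_mask, oracle)
  expect_equal(sum(sim$truth_mask), sum(oracle))
})
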