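# DAPI-map construction and region intensity statistics.

blank_image <- function(h = 64, w = 64) {
  array(0L, dim = c(h, w, 3))
}

test_that("degenerate blue channels yield empty maps", {
  img <- blank_image()
  expect_warning(map <- build_dapi_map(channel_image(img)), "All-zero")
  expect_identical(map$area, 0)
  expect_false(any(map$mask))

  # two tiny specks below the size filter
  img2 <- blank_image()
  img2[10, 10:12, 3] <- 255L
  img2[40, 40:42, 3] <- 255L
  map2 <- build_dapi_map(channel_image(img2), min_component_area = 30)
  expect_false(any(map2$mask))
})

test_that("size filtration uses 8-connectivity", {
  # a diagonal staircase of 40 pixels: one 8-connected component, but many
  # 4-connected fragments each far below the area threshold
  img <- blank_image(96, 96)
  for (k in 1:20) {
    img[10 + 2 * k, 10 + 2 * k, 3] <- 255L
    img[11 + 2 * k, 10 + 2 * k + 1, 3] <- 255L
  }
  map <- build_dapi_map(
    channel_image(img), min_component_area = 30, disk_radius = 1
  )
  expect_gt(map$area, 0)
})

test_that("one bright disk survives as (approximately) its own closing", {
  img <- blank_image(128, 128)
  disk <- oracle_disk(128, 128, 64, 64, 20)
  ch <- img[, , 3]
  ch[disk] <- 255L
  img[, , 3] <- ch
  map <- build_dapi_map(
    channel_image(img), min_component_area = 30, disk_radius = 3
  )
  # closing is extensive: the original disk is contained in the map
  expect_true(all(map$mask[disk]))
  # and can only add a thin boundary band (closing of a convex blob)
  expect_lte(map$area, sum(disk) + 2 * pi * 20 * 2)
})

test_that("dapi map construction is deterministic", {
  sim <- simulate_tissue_image(n_nuclei = 60, seed = 17)
  a <- build_dapi_map(sim)
  b <- build_dapi_map(sim)
  expect_identical(a$mask, b$mask)
})

test_that("region stats report normalized means and partition the image", {
  mask <- matrix(FALSE, 32, 32)
  mask[8:24, 8:24] <- TRUE
  img <- blank_image(32, 32)
  red <- matrix(0L, 32, 32)
  red[mask] <- 128L
  img[, , 1] <- red
  st <- region_channel_stats(channel_image(img), mask)
  r <- st[st$channel == "red", ]
  expect_equal(r$inside_mean, 128 / 255, tolerance = 1e-12)
  expect_equal(r$outside_mean, 0)
  g <- st[st$channel == "green", ]
  expect_equal(g$inside_mean, 0)
  expect_identical(r$inside_area + r$outside_area, length(mask))

  # full mask: outside undefined
  full <- matrix(TRUE, 32, 32)
  stf <- region_channel_stats(channel_image(img), full)
  expect_true(all(is.na(stf$outside_mean)))
  expect_identical(stf$outside_area[1], 0L)
  # empty mask: inside undefined
  ste <- region_channel_stats(channel_image(img), !full)
  expect_true(all(is.na(ste$inside_mean)))
})

test_that("normalized marker scores obey their invariances", {
  mask <- matrix(FALSE, 20, 20)
  mask[5:15, 5:15] <- TRUE
  img <- blank_image(20, 20)
  img[, , 1][mask] <- 60L
  img[, , 2][mask] <- 120L
  st <- region_channel_stats(channel_image(img), mask)

  # uniform marker v over the mask, normalized by area -> v / max_scale
  expect_equal(
    normalized_marker_intensity(st, "red", "area"), 60 / 255,
    tolerance = 1e-12
  )
  # channel-normalized score is invariant to global scaling
  img2 <- img
  img2[, , 1] <- img2[, , 1] * 2L
  img2[, , 2] <- img2[, , 2] * 2L
  st2 <- region_channel_stats(channel_image(img2), mask)
  expect_equal(
    normalized_marker_intensity(st, "red", "green"),
    normalized_marker_intensity(st2, "red", "green"),
    tolerance = 1e-12
  )
  # zero marker -> zero score
  expect_equal(normalized_marker_intensity(st, "blue", "area"), 0)
  expect_error(normalized_marker_intensity(st[st$channel != "red", ], "red"),
               "Unknown channel")
})

test_that("the DAPI map recovers the synthetic ground truth", {
  sim <- simulate_tissue_image(seed = 23)
  map <- build_dapi_map(sim)
  expect_gte(mask_jaccard(map, sim$truth_mask), 0.8)
  st <- region_channel_stats(sim, map)
  r <- st[st$channel == "red", ]
  expect_lt(abs(r$inside_mean - 150 / 255) / (150 / 255), 0.02)
  expect_lt(abs(r$outside_mean - 30 / 255) / (30 / 255), 0.02)
})

test_that("images round-trip through PNG files", {
  sim <- simulate_tissue_image(width = 64, height = 64, n_nuclei = 30,
                               seed = 2)
  path <- withr::local_tempfile(fileext = ".png")
  mpath <- withr::local_tempfile(fileext = ".png")
  write_tissue_image(sim, path, mpath)
  back <- read_channel_image(path)
  expect_identical(back$bit_depth, 8)
  expect_equal(back$image, sim$image, tolerance = 1e-12)
  mask <- png::readPNG(mpath) > 0.5
  expect_identical(unname(mask), unname(sim$truth_mask))
})
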