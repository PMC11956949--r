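# Synthetic-data generators: LFQ protein-group tables with known ground
# truth, matrisome annotation fixtures, and tissue-like fluorescence images.

#' Simulate a label-free protein-group intensity table
#'
#' Generates a two-species (human cells grown on a rat-derived scaffold)
#' label-free proteomics experiment: per-protein baseline log2 abundances are
#' drawn once from Normal(`baseline_log2_mean`, `baseline_log2_sd`); each
#' sample observes the protein with i.i.d. Gaussian noise
#' (`within_protein_sd`) on the log2 scale; intensities are `2^`(log2 value).
#' Three effects can be layered on top:
#'
#' * a global enrichment of `enrichment_log2fc` log2 units on every human
#'   (cell-derived, hence metabolically labeled) protein in azido-sugar
#'   (GalNAz) eluate samples — the capture effect of the click-enrichment;
#' * protein-specific true differentials: a fraction
#'   `frac_true_differential` of proteins gains `true_log2fc` log2 units
#'   along the contrast chosen by `differential_axis` ("treatment": GalNAz
#'   vs vehicle eluates; "model": dECM-tumor vs tumoroid samples);
#' * missing-not-at-random left-censoring: within each sample, the lowest
#'   `censor_quantile` fraction of intensities is set to zero.
#'
#' @param n_proteins_human,n_proteins_rat Number of simulated human / rat
#'   protein groups.
#' @param n_per_group Samples per (model, treatment, fraction) group.
#' @param groups Data frame with columns `model` (`"dECM-tumor"` or
#'   `"tumoroid"`), `treatment` (`"GalNAz"` or `"vehicle"`) and `fraction`
#'   (`"input"` or `"eluate"`); defaults to the full 2 x 2 x 2 design.
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd of per-protein
#'   baseline log2 intensities.
#' @param within_protein_sd Within-protein (between-sample) sd, log2 units.
#' @param enrichment_log2fc Log2 enrichment applied to human proteins in
#'   GalNAz eluate samples.
#' @param frac_true_differential Fraction of proteins that are truly
#'   differential along `differential_axis`.
#' @param true_log2fc Log2 effect size of the true differentials.
#' @param differential_axis `"treatment"` or `"model"`: the contrast along
#'   which the spiked differentials act.
#' @param censor_quantile Fraction of each sample's lowest intensities set to
#'   zero (missing-not-at-random, left-censored). In `[0, 1)`.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A list with elements:
#'   * `intensities`: tibble with `accession`, `gene`, `organism` and one
#'     intensity column per sample (zero = not observed);
#'   * `samples`: tibble of sample metadata (`sample_id`, `model`,
#'     `treatment`, `fraction`);
#'   * `truth`: list with `proteins` (per-protein true mean, differential
#'     flag/effect, organism) and `censored` (long tibble of
#'     accession/sample pairs set to zero, with the pre-censoring value).
#' @examples
#' sim <- simulate_lfq(n_proteins_human = 50, n_proteins_rat = 20,
#'                     n_per_group = 3, seed = 1)
#' dim(sim$intensities)
#' @export
simulate_lfq <- function(n_proteins_human = 800,
                         n_proteins_rat = 400,
                         n_per_group = 5,
                         groups = default_lfq_groups(),
                         baseline_log2_mean = 25,
                         baseline_log2_sd = 2,
                         within_protein_sd = 0.5,
                         enrichment_log2fc = 4.5,
                         frac_true_differential = 0,
                         true_log2fc = 3,
                         differential_axis = c("treatment", "model"),
                         censor_quantile = 0.2,
                         seed = 1L) {
  n_proteins_human <- check_count(n_proteins_human, "n_proteins_human")
  n_proteins_rat <- check_count(n_proteins_rat, "n_proteins_rat", min = 0)
  n_per_group <- check_count(n_per_group, "n_per_group")
  check_positive(baseline_log2_sd, "baseline_log2_sd")
  if (within_protein_sd < 0) abort("`within_protein_sd` must be >= 0.")
  if (censor_quantile < 0 || censor_quantile >= 1) {
    abort("`censor_quantile` must be in [0, 1).")
  }
  if (frac_true_differential < 0 || frac_true_differential > 1) {
    abort("`frac_true_differential` must be in [0, 1].")
  }
  differential_axis <- match.arg(differential_axis)
  stopifnot(all(c("model", "treatment", "fraction") %in% names(groups)))

  samples <- tidyr::uncount(tibble::as_tibble(groups), n_per_group) |>
    dplyr::group_by(.data$model, .data$treatment, .data$fraction) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      sample_id = sprintf(
        "%s_%s_%s_%d",
        gsub("-", "", .data$model), .data$treatment, .data$fraction,
        .data$replicate
      )
    ) |>
    dplyr::select("sample_id", "model", "treatment", "fraction")

  n_prot <- n_proteins_human + n_proteins_rat
  organism <- rep(c("human", "rat"), c(n_proteins_human, n_proteins_rat))
  accession <- sprintf("P%05d_%s", seq_len(n_prot), toupper(substr(organism, 1, 3)))
  gene <- sprintf("GENE%04d", seq_len(n_prot))

  withr::with_seed(seed, {
    base_mu <- stats::rnorm(n_prot, baseline_log2_mean, baseline_log2_sd)
    n_diff <- round(frac_true_differential * n_prot)
    diff_idx <- if (n_diff > 0) sample.int(n_prot, n_diff) else integer(0)
    is_diff <- seq_len(n_prot) %in% diff_idx

    # which samples receive each effect
    enriched_samp <- samples$treatment == "GalNAz" & samples$fraction == "eluate"
    diff_samp <- switch(differential_axis,
      treatment = enriched_samp,
      model = samples$model == "dECM-tumor"
    )

    n_samp <- nrow(samples)
    mu <- matrix(base_mu, n_prot, n_samp)
    mu[organism == "human", enriched_samp] <-
      mu[organism == "human", enriched_samp] + enrichment_log2fc
    mu[is_diff, diff_samp] <- mu[is_diff, diff_samp] + true_log2fc

    log2_vals <- mu + matrix(
      stats::rnorm(n_prot * n_samp, 0, within_protein_sd), n_prot, n_samp
    )
    vals <- 2^log2_vals

    # per-sample rank-based left-censoring: the lowest q fraction goes missing
    n_censor <- floor(censor_quantile * n_prot)
    censored <- matrix(FALSE, n_prot, n_samp)
    if (n_censor > 0) {
      for (j in seq_len(n_samp)) {
        censored[order(vals[, j])[seq_len(n_censor)], j] <- TRUE
      }
    }
    pre_censor <- vals
    vals[censored] <- 0
  })

  colnames(vals) <- samples$sample_id
  intensities <- dplyr::bind_cols(
    tibble::tibble(accession = accession, gene = gene, organism = organism),
    tibble::as_tibble(vals)
  )

  censored_long <- tibble::tibble(
    accession = accession[row(censored)[censored]],
    sample_id = samples$sample_id[col(censored)[censored]],
    pre_censor_value = pre_censor[censored]
  )

  truth <- list(
    proteins = tibble::tibble(
      accession = accession,
      gene = gene,
      organism = organism,
      true_mean_log2 = base_mu,
      is_differential = is_diff,
      true_log2fc = ifelse(is_diff, true_log2fc, 0),
      differential_axis = differential_axis
    ),
    censored = censored_long
  )

  list(intensities = intensities, samples = samples, truth = truth)
}

#' Default 2 x 2 x 2 experimental design for [simulate_lfq()]
#'
#' @return Tibble of the eight (model, treatment, fraction) groups.
#' @export
default_lfq_groups <- function() {
  tidyr::expand_grid(
    model = c("dECM-tumor", "tumoroid"),
    treatment = c("GalNAz", "vehicle"),
    fraction = c("input", "eluate")
  )
}

#' Synthetic matrisome annotation fixture
#'
#' Builds a gene -> division/category lookup with `n_per_category` synthetic
#' gene symbols in each of the six matrisome categories. Collagens, ECM
#' glycoproteins and proteoglycans belong to the core matrisome; ECM
#' regulators, ECM-affiliated proteins and secreted factors are
#' matrisome-associated. The symbols are synthetic; a real matrisome list can
#' be supplied to the annotation functions via [read_matrisome()].
#'
#' @param n_per_category Genes per category (>= 0).
#' @return Tibble with columns `gene`, `division`, `category`.
#' @export
make_matrisome_fixture <- function(n_per_category = 5) {
  n_per_category <- check_count(n_per_category, "n_per_category", min = 0)
  cats <- matrisome_categories()
  if (n_per_category == 0) {
    return(tibble::tibble(
      gene = character(0), division = character(0), category = character(0)
    ))
  }
  prefix <- c(
    "collagens" = "COLS",
    "ECM glycoproteins" = "GLYP",
    "proteoglycans" = "PROG",
    "ECM regulators" = "REGU",
    "ECM-affiliated proteins" = "AFFI",
    "secreted factors" = "SECF"
  )
  tidyr::expand_grid(category = names(cats), i = seq_len(n_per_category)) |>
    dplyr::mutate(
      gene = sprintf("%s%03d", unname(prefix[.data$category]), .data$i),
      division = unname(cats[.data$category])
    ) |>
    dplyr::select("gene", "division", "category")
}

#' The six matrisome categories and their divisions
#'
#' @return Named character vector mapping category to division
#'   (`"core matrisome"` or `"matrisome-associated"`).
#' @export
matrisome_categories <- function() {
  c(
    "collagens" = "core matrisome",
    "ECM glycoproteins" = "core matrisome",
    "proteoglycans" = "core matrisome",
    "ECM regulators" = "matrisome-associated",
    "ECM-affiliated proteins" = "matrisome-associated",
    "secreted factors" = "matrisome-associated"
  )
}

# Rasterize a filled disk of radius r centred at (cx, cy) into logical matrix
# dims (pixel centres at integer coordinates).
raster_disk <- function(nrow, ncol, cx, cy, r) {
  xx <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  yy <- matrix(seq_len(nrow), nrow, ncol)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

#' Simulate a tissue-like RGB fluorescence image with known ground truth
#'
#' Emulates a DAPI-stained tissue section: a disk-shaped tissue region is
#' densely seeded with bright nuclei in the blue channel, placed on a
#' jittered grid (plus a ring lining the boundary) so adjacent nuclei
#' overlap and the union of nucleus disks — the ground-truth tissue mask —
#' covers the region almost everywhere. The red and green (marker) channels
#' are uniform at `marker_inside_level` within `truth_mask` and
#' `marker_outside_level` outside, so region statistics have exact expected
#' values.
#'
#' @param width,height Image dimensions in pixels.
#' @param n_nuclei Number of nuclei to draw (placed inside the tissue
#'   region). `0` yields an empty mask with a warning.
#' @param nucleus_radius_px Nucleus radius in pixels (>= 1).
#' @param tissue_radius_frac Tissue-region radius as a fraction of the
#'   smaller image dimension.
#' @param nucleus_level Blue-channel intensity of nuclei.
#' @param background_level Blue-channel background intensity.
#' @param marker_inside_level,marker_outside_level Red/green channel levels
#'   inside and outside the tissue region.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed for the nucleus-placement jitter.
#' @return A list with `image` (height x width x 3 integer array, channels
#'   R, G, B), `bit_depth`, `truth_mask` (logical height x width matrix: the
#'   union of the rasterized nucleus disks, i.e. the nuclei-covered tissue
#'   region the marker levels are keyed to), and `nuclei` (tibble of drawn
#'   centres and radius).
#' @export
simulate_tissue_image <- function(width = 256, height = 256,
                                  n_nuclei = 800,
                                  nucleus_radius_px = 6,
                                  tissue_radius_frac = 0.35,
                                  nucleus_level = 220,
                                  background_level = 8,
                                  marker_inside_level = 150,
                                  marker_outside_level = 30,
                                  bit_depth = 8,
                                  seed = 1L) {
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  max_scale <- 2^bit_depth - 1
  levels <- c(
    nucleus_level, background_level,
    marker_inside_level, marker_outside_level
  )
  if (any(levels < 0) || any(levels > max_scale)) {
    abort("Channel levels must lie within the bit depth range.")
  }
  if (nucleus_radius_px < 1) abort("`nucleus_radius_px` must be >= 1.")
  n_nuclei <- check_count(n_nuclei, "n_nuclei", min = 0)

  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  tissue_r <- tissue_radius_frac * min(width, height)
  truth_mask <- matrix(FALSE, height, width)
  nuclei <- data.frame(x = numeric(0), y = numeric(0))

  blue <- matrix(background_level, height, width)
  if (n_nuclei == 0) {
    warn("n_nuclei = 0: truth_mask is empty and the blue channel has no nuclei.")
  } else {
    # jittered grid with spacing equal to the nucleus radius, centres kept
    # at least one radius inside the tissue boundary: overlapping nuclei
    # tile the region densely (the union of disks of radius r centred
    # densely in a disk of radius R - r is almost exactly the disk of
    # radius R), as in a confluent tissue section
    spacing <- nucleus_radius_px
    reach <- tissue_r - nucleus_radius_px
    gx <- seq(cx - reach, cx + reach, by = spacing)
    gy <- seq(cy - reach, cy + reach, by = spacing)
    grid <- expand.grid(x = gx, y = gy)
    inside <- (grid$x - cx)^2 + (grid$y - cy)^2 <= reach^2
    grid <- grid[inside, , drop = FALSE]
    # a ring of nuclei lining the tissue boundary, so the union of disks
    # reaches the boundary everywhere (a square lattice alone stops short
    # of the circle between lattice points)
    n_ring <- max(8, ceiling(2 * pi * reach / (spacing / 2)))
    theta <- seq(0, 2 * pi, length.out = n_ring + 1)[-1]
    ring <- data.frame(
      x = cx + reach * cos(theta), y = cy + reach * sin(theta)
    )
    centres <- rbind(ring, grid)
    withr::with_seed(seed, {
      idx <- if (nrow(centres) <= n_nuclei) {
        seq_len(nrow(centres))
      } else {
        sample.int(nrow(centres), n_nuclei)
      }
      jit <- nucleus_radius_px / 8
      xs <- centres$x[idx] + stats::runif(length(idx), -jit, jit)
      ys <- centres$y[idx] + stats::runif(length(idx), -jit, jit)
    })
    for (k in seq_along(xs)) {
      truth_mask <- truth_mask |
        raster_disk(height, width, xs[k], ys[k], nucleus_radius_px)
    }
    blue[truth_mask] <- nucleus_level
    nuclei <- data.frame(x = xs, y = ys)
  }

  marker <- matrix(marker_outside_level, height, width)
  marker[truth_mask] <- marker_inside_level

  img <- array(0L, dim = c(height, width, 3))
  img[, , 1] <- as.integer(round(marker))
  img[, , 2] <- as.integer(round(marker))
  img[, , 3] <- as.integer(round(blue))

  list(
    image = img, bit_depth = bit_depth, truth_mask = truth_mask,
    nuclei = tibble::tibble(nuclei, radius = rep(nucleus_radius_px,
                                                 nrow(nuclei)))
  )
}

#' Write a simulated image (and its truth mask) as PNG files
#'
#' @param sim Result of [simulate_tissue_image()].
#' @param image_path Output PNG path for the RGB image.
#' @param mask_path Optional output PNG path for the binary truth mask.
#' @return `image_path`, invisibly.
#' @export
write_tissue_image <- function(sim, image_path, mask_path = NULL) {
  max_scale <- 2^sim$bit_depth - 1
  png::writePNG(sim$image / max_scale, image_path)
  if (!is.null(mask_path)) {
    png::writePNG(sim$truth_mask * 1.0, mask_path)
  }
  invisible(image_path)
}
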