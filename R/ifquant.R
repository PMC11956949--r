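# DAPI-map immunofluorescence quantification: build a binary tissue mask
# from the blue (DAPI) channel, then report per-channel mean intensities
# inside and outside the mask.

#' Construct a channel image object
#'
#' @param image height x width x 3 numeric array (channels R, G, B) of
#'   unsigned intensities within the bit-depth range.
#' @param bit_depth 8 or 16.
#' @return List of class `channel_image` with `image` and `bit_depth`.
#' @export
channel_image <- function(image, bit_depth = 8) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("`image` must be a height x width x 3 array (R, G, B).")
  }
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  if (any(image < 0) || any(image > 2^bit_depth - 1)) {
    abort("Pixel values must lie within the bit-depth range.")
  }
  structure(list(image = image, bit_depth = as.numeric(bit_depth)),
            class = "channel_image")
}

as_channel_image <- function(x) {
  if (inherits(x, "channel_image")) {
    return(x)
  }
  if (is.list(x) && !is.null(x$image) && !is.null(x$bit_depth)) {
    return(channel_image(x$image, x$bit_depth)) # simulate_tissue_image output
  }
  if (is.array(x) && length(dim(x)) == 3) {
    return(channel_image(x, if (max(x) > 255) 16 else 8))
  }
  abort("Cannot interpret `x` as an RGB channel image.")
}

#' Read an RGB image from a PNG or TIFF file
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`); 8- or 16-bit RGB.
#' @return A `channel_image`.
#' @export
read_channel_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    bits <- attr(arr, "info")$bit.depth %||% 8
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample") %||% 8
  } else {
    abort(sprintf("Unsupported image extension: '%s'.", ext))
  }
  if (length(dim(arr)) == 2) abort("Expected an RGB image, got one channel.")
  arr <- arr[, , 1:3, drop = FALSE] # drop alpha if present
  channel_image(round(arr * (2^bits - 1)), bits)
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1) {
    return(lab)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_pairs <- function(a, b) {
    for (k in seq_along(a)) {
      ra <- find(a[k])
      rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  nr <- nrow(lab)
  nc <- ncol(lab)
  for (off in list(c(1, 1), c(1, -1))) {
    ri <- seq_len(nr - 1)
    ci <- if (off[2] == 1) seq_len(nc - 1) else 2:nc
    a <- lab[ri, ci]
    b <- lab[ri + 1, ci + off[2]]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) union_pairs(a[sel], b[sel])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Build a DAPI map (binary tissue mask) from the blue channel
#'
#' The fixed pipeline: (1) balance the blue channel by a linear percentile
#' contrast stretch (clip at the `stretch_quantiles`, rescale to full
#' range); (2) binarize at `threshold_fraction` times the balanced channel's
#' maximum; (3) remove connected components (8-connectivity) smaller than
#' `min_component_area` pixels; (4) morphological closing (dilation then
#' erosion) with a disk structuring element of radius `disk_radius`, which
#' connects the nucleus blobs into an approximation of the underlying
#' tissue.
#'
#' @param img A `channel_image`, a [simulate_tissue_image()] result, or a
#'   height x width x 3 array.
#' @param threshold_fraction Threshold as a fraction of the balanced
#'   channel's maximum (default 0.20).
#' @param min_component_area Minimum blob area in pixels (default 30).
#' @param disk_radius Disk radius in pixels for the closing (default 3).
#' @param stretch_quantiles Lower/upper clip quantiles of the contrast
#'   stretch (default `c(0.01, 0.99)`).
#' @return List of class `dapi_map`: `mask` (logical matrix), `area`
#'   (pixels inside), and `params`.
#' @export
build_dapi_map <- function(img, threshold_fraction = 0.20,
                           min_component_area = 30, disk_radius = 3,
                           stretch_quantiles = c(0.01, 0.99)) {
  img <- as_channel_image(img)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must be in (0, 1).")
  }
  if (disk_radius < 1) abort("`disk_radius` must be >= 1.")
  if (min_component_area < 0) abort("`min_component_area` must be >= 0.")
  params <- list(
    threshold_fraction = threshold_fraction,
    min_component_area = min_component_area,
    disk_radius = disk_radius,
    stretch_quantiles = stretch_quantiles
  )
  blue <- img$image[, , 3]

  if (max(blue) == 0) {
    warn("All-zero blue channel; DAPI map is empty.")
    mask <- matrix(FALSE, nrow(blue), ncol(blue))
    return(structure(list(mask = mask, area = 0, params = params),
                     class = "dapi_map"))
  }

  # (1) percentile contrast stretch
  qs <- stats::quantile(blue, stretch_quantiles, names = FALSE)
  if (qs[2] > qs[1]) {
    balanced <- (pmin(pmax(blue, qs[1]), qs[2]) - qs[1]) / (qs[2] - qs[1])
  } else {
    balanced <- blue / max(blue)
  }

  # (2) threshold at a fraction of the balanced maximum
  mask <- balanced >= threshold_fraction * max(balanced)

  # (3) size filtration, 8-connectivity
  if (min_component_area > 0 && any(mask)) {
    lab <- label_components_8(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_area)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }

  # (4) closing: dilation then erosion with a disk
  if (any(mask)) {
    brush <- EBImage::makeBrush(2 * disk_radius + 1, shape = "disc")
    closed <- EBImage::erode(EBImage::dilate(mask * 1, brush), brush)
    mask <- matrix(closed > 0, nrow(mask), ncol(mask))
  }

  structure(list(mask = mask, area = sum(mask), params = params),
            class = "dapi_map")
}

#' @export
print.dapi_map <- function(x, ...) {
  cat(sprintf(
    "DAPI map: %d x %d, area inside = %d px (%.1f%%)\n",
    nrow(x$mask), ncol(x$mask), x$area,
    100 * x$area / length(x$mask)
  ))
  invisible(x)
}

#' Per-channel mean intensities inside and outside a DAPI map
#'
#' Means are on the normalized 0-1 scale (`value / (2^bit_depth - 1)`).
#' An empty mask yields `NA` inside means; a full mask yields `NA` outside
#' means. Inside and outside areas always partition the image.
#'
#' @param img A `channel_image` (or coercible).
#' @param map A `dapi_map` (or a logical matrix of matching shape).
#' @return Tibble with one row per channel (`red`, `green`, `blue`):
#'   `inside_mean`, `outside_mean`, `inside_area`, `outside_area`.
#' @export
region_channel_stats <- function(img, map) {
  img <- as_channel_image(img)
  mask <- if (inherits(map, "dapi_map")) map$mask else map
  if (!is.logical(mask)) mask <- mask > 0
  if (!all(dim(mask) == dim(img$image)[1:2])) {
    abort("Mask shape does not match the image.")
  }
  max_scale <- 2^img$bit_depth - 1
  inside_area <- sum(mask)
  outside_area <- length(mask) - inside_area
  purrr::map_dfr(
    c(red = 1, green = 2, blue = 3),
    function(k) {
      ch <- img$image[, , k] / max_scale
      tibble::tibble(
        inside_mean = if (inside_area > 0) mean(ch[mask]) else NA_real_,
        outside_mean = if (outside_area > 0) mean(ch[!mask]) else NA_real_,
        inside_area = inside_area,
        outside_area = outside_area
      )
    },
    .id = "channel"
  )
}

#' Normalized marker intensity score
#'
#' The marker channel's summed intensity inside the DAPI map divided by a
#' normalizer: the mask area (`normalizer = "area"`, giving the mean
#' normalized intensity over the tissue) or another channel's inside mean
#' (`normalizer = "red"/"green"/"blue"`, e.g. a marker normalized by
#' E-cadherin), making the score invariant to global illumination scaling.
#'
#' @param stats Tibble from [region_channel_stats()].
#' @param channel Marker channel name (`"red"`, `"green"`, `"blue"`).
#' @param normalizer `"area"` or another channel name.
#' @return Numeric score.
#' @export
normalized_marker_intensity <- function(stats, channel,
                                        normalizer = "area") {
  row <- stats[stats$channel == channel, ]
  if (nrow(row) != 1) abort(sprintf("Unknown channel '%s'.", channel))
  inside_sum <- row$inside_mean * row$inside_area
  if (normalizer == "area") {
    if (row$inside_area == 0) abort("Zero mask area; score undefined.")
    return(inside_sum / row$inside_area)
  }
  nrow_ <- stats[stats$channel == normalizer, ]
  if (nrow(nrow_) != 1) abort(sprintf("Unknown normalizer '%s'.", normalizer))
  denom <- nrow_$inside_mean
  if (is.na(denom) || denom == 0) abort("Zero or undefined normalizer.")
  inside_sum / denom
}

#' Jaccard index between two binary masks
#'
#' @param a,b Logical matrices of equal shape (or `dapi_map` objects).
#' @return Intersection-over-union in `[0, 1]` (1 when both masks are empty).
#' @export
mask_jaccard <- function(a, b) {
  if (inherits(a, "dapi_map")) a <- a$mask
  if (inherits(b, "dapi_map")) b <- b$mask
  stopifnot(all(dim(a) == dim(b)))
  uni <- sum(a | b)
  if (uni == 0) {
    return(1)
  }
  sum(a & b) / uni
}

#' Write a DAPI map as a binary PNG
#'
#' @param map A `dapi_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_dapi_map <- function(map, path) {
  png::writePNG(map$mask * 1.0, path)
  invisible(path)
}
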