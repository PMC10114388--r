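#' @title Two-channel elastin content estimation
#' @description
#' In multiphoton images of ligament, fibrillar collagen emits
#' second-harmonic-generation (SHG) light (displayed blue) and elastin
#' autofluoresces (displayed green). The elastin content of a field of view
#' is estimated as the ratio of green pixels to the total of blue and green
#' pixels after binarizing each channel. Because the original microscopy
#' images are not deposited, a synthetic generator produces co-registered
#' two-channel images with a known true elastin pixel fraction for
#' validating the estimator.
#' @name image_content
NULL

#' Construct a two-channel (collagen, elastin) image
#'
#' @param collagen_channel,elastin_channel Equal-shape nonnegative numeric
#'   matrices: the SHG/"blue" collagen channel and the
#'   autofluorescence/"green" elastin channel.
#' @return A `ligafem_channels` object.
#' @export
channel_image <- function(collagen_channel, elastin_channel) {
  if (!is.matrix(collagen_channel) || !is.matrix(elastin_channel) ||
      !all(dim(collagen_channel) == dim(elastin_channel))) {
    rlang::abort("channels must be matrices of identical shape",
                 class = "ligafem_image_error")
  }
  if (any(!is.finite(collagen_channel)) || any(!is.finite(elastin_channel)) ||
      any(collagen_channel < 0) || any(elastin_channel < 0)) {
    rlang::abort("channel intensities must be finite and nonnegative",
                 class = "ligafem_image_error")
  }
  structure(list(collagen = collagen_channel, elastin = elastin_channel),
            class = "ligafem_channels")
}

#' Estimate elastin content by the pixel-ratio rule
#'
#' Binarizes each channel at its threshold (a pixel is positive when its
#' intensity strictly exceeds the threshold). Pixels positive in both
#' channels are assigned to the brighter channel, ties going to collagen.
#' The content estimate is `green / (green + blue)` over the classified
#' pixel counts.
#'
#' @param img A `ligafem_channels` object.
#' @param threshold_collagen,threshold_elastin Nonnegative binarization
#'   thresholds for the collagen (blue) and elastin (green) channels.
#' @return The estimated elastin pixel fraction.
#' @export
#' @examples
#' img <- channel_image(matrix(c(1, 1, 0, 0), 2), matrix(c(0, 0, 1, 0), 2))
#' estimate_content(img) # 1 green of 3 positive
estimate_content <- function(img, threshold_collagen = 0, threshold_elastin = 0) {
  stopifnot(inherits(img, "ligafem_channels"))
  if (threshold_collagen < 0 || threshold_elastin < 0) {
    rlang::abort("thresholds must be nonnegative", class = "ligafem_image_error")
  }
  blue <- img$collagen > threshold_collagen
  green <- img$elastin > threshold_elastin
  both <- blue & green
  # overlap goes to the brighter channel; tie -> collagen
  green_wins <- both & (img$elastin > img$collagen)
  n_green <- sum((green & !blue) | green_wins)
  n_blue <- sum(blue & !green_wins)
  if (n_green + n_blue == 0L) {
    rlang::abort("no pixel exceeds either threshold; content undefined",
                 class = "ligafem_image_error")
  }
  n_green / (n_green + n_blue)
}

# separable Gaussian blur via EBImage
smooth_field <- function(x, sigma) {
  if (sigma <= 0) return(x)
  as.matrix(EBImage::gblur(EBImage::Image(x), sigma = sigma))
}

#' Generate a synthetic two-channel ligament image
#'
#' Builds a blob-textured foreground (thresholded smoothed Gaussian random
#' field), partitions the foreground pixels into elastin and collagen so
#' that the elastin share of the foreground equals `true_fraction` to
#' within one pixel (whole blobs are assigned greedily, then one blob is
#' split pixel-wise to hit the count), paints each class into its channel,
#' and adds Gaussian noise clipped at zero.
#'
#' @param shape Image dimensions `c(nrow, ncol)`.
#' @param true_fraction Target elastin share of the foreground, in `[0, 1]`.
#' @param blob_scale Gaussian smoothing radius (pixels) controlling blob
#'   size.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (foreground intensity is 1).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param coverage Foreground area fraction of the image.
#' @return A `ligafem_channels` object with attributes `true_fraction`
#'   (realised foreground share) and `seed`.
#' @export
#' @examples
#' img <- generate_synthetic_channels(c(64, 64), 0.2, seed = 1)
#' estimate_content(img, 0.5, 0.5)
generate_synthetic_channels <- function(shape, true_fraction, blob_scale = 4,
                                        noise_sd = 0, seed = 1, coverage = 0.35) {
  if (!is.numeric(true_fraction) || true_fraction < 0 || true_fraction > 1) {
    rlang::abort("true_fraction must lie in [0, 1]", class = "ligafem_image_error")
  }
  if (length(shape) != 2L || any(shape < 4L)) {
    rlang::abort("shape must be two dimensions of at least 4 pixels",
                 class = "ligafem_image_error")
  }
  set.seed(seed)
  field <- smooth_field(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
                        blob_scale)
  cut <- stats::quantile(field, 1 - coverage)
  fg <- field > cut
  n_fg <- sum(fg)
  if (n_fg < 2L) {
    rlang::abort("foreground too small at this shape/coverage",
                 class = "ligafem_image_error")
  }
  target <- round(true_fraction * n_fg)

  labels <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labels <- matrix(as.integer(labels), shape[1], shape[2])
  blob_ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  sizes <- tabulate(labels[labels > 0L])[blob_ids]
  ord <- blob_ids[order(sizes, blob_ids)]

  elastin_mask <- matrix(FALSE, shape[1], shape[2])
  assigned <- 0L
  for (b in ord) {
    if (assigned >= target) break
    px <- which(labels == b)
    if (assigned + length(px) <= target) {
      elastin_mask[px] <- TRUE
      assigned <- assigned + length(px)
    } else {
      # split this blob pixel-wise to hit the target count exactly
      take <- target - assigned
      elastin_mask[px[seq_len(take)]] <- TRUE
      assigned <- target
    }
  }

  collagen <- matrix(0, shape[1], shape[2])
  elastin <- matrix(0, shape[1], shape[2])
  collagen[fg & !elastin_mask] <- 1
  elastin[elastin_mask] <- 1
  if (noise_sd > 0) {
    collagen <- pmax(collagen + matrix(stats::rnorm(prod(shape), 0, noise_sd),
                                       shape[1], shape[2]), 0)
    elastin <- pmax(elastin + matrix(stats::rnorm(prod(shape), 0, noise_sd),
                                     shape[1], shape[2]), 0)
  }
  img <- channel_image(collagen, elastin)
  attr(img, "true_fraction") <- assigned / n_fg
  attr(img, "seed") <- seed
  img
}

#' Read a two-channel TIFF as a channel image
#'
#' Accepts either one multi-channel/multi-frame TIFF (channel order:
#' collagen then elastin) or two single-channel TIFF paths.
#'
#' @param path Path to the two-channel TIFF, or the collagen-channel TIFF
#'   when `path_elastin` is given.
#' @param path_elastin Optional path to the elastin-channel TIFF.
#' @return A `ligafem_channels` object with intensities as stored
#'   (0-1 normalised by the TIFF reader).
#' @export
read_channel_tiff <- function(path, path_elastin = NULL) {
  if (!is.null(path_elastin)) {
    blue <- tiff::readTIFF(path)
    green <- tiff::readTIFF(path_elastin)
  } else {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (is.list(frames) && length(frames) >= 2L) {
      blue <- frames[[1]]; green <- frames[[2]]
    } else {
      arr <- if (is.list(frames)) frames[[1]] else frames
      if (length(dim(arr)) != 3L || dim(arr)[3] < 2L) {
        rlang::abort("TIFF does not contain two channels",
                     class = "ligafem_image_error")
      }
      blue <- arr[, , 1]; green <- arr[, , 2]
    }
  }
  drop_to_matrix <- function(x) {
    if (length(dim(x)) == 3L) x <- x[, , 1]
    as.matrix(x)
  }
  channel_image(drop_to_matrix(blue), drop_to_matrix(green))
}
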