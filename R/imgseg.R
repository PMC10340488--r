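# Handcrafted WBC nuclei segmentation: color constancy -> CMYK Magenta and
# HSV Saturation -> Hadamard product -> bilateral smoothing -> Otsu
# binarization -> morphological refinement (closing, hole filling, area
# filter).

#' Validate an RGB image array
#'
#' An RGB image is a numeric array of dimension `c(height, width, 3)` holding
#' 8-bit intensities in `[0, 255]` (row-major raster, origin at the top-left
#' corner).
#'
#' @param image object to validate.
#' @return The image, invisibly, if valid; otherwise an error is thrown.
#' @keywords internal
validate_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be a height x width x 3 array", call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop("image must have positive height and width", call. = FALSE)
  if (anyNA(image) || any(!is.finite(image)))
    stop("image contains NA or non-finite intensities", call. = FALSE)
  if (min(image) < 0 || max(image) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  invisible(image)
}

validate_channel <- function(channel) {
  if (!is.matrix(channel) || !is.numeric(channel))
    stop("channel map must be a numeric matrix", call. = FALSE)
  if (anyNA(channel) || any(!is.finite(channel)))
    stop("channel map contains NA or non-finite values", call. = FALSE)
  if (min(channel) < 0 || max(channel) > 1)
    stop("channel map values must lie in [0, 1]", call. = FALSE)
  invisible(channel)
}

validate_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (anyNA(mask)) stop("mask contains NA", call. = FALSE)
  invisible(mask)
}

#' Segmentation pipeline configuration
#'
#' Bundles the tunable parameters of the handcrafted segmentation pipeline.
#'
#' @param bilateral_diameter window diameter of the bilateral filter, in
#'   pixels (odd integer).
#' @param bilateral_sigma_color range (intensity) sigma of the bilateral
#'   filter, on the `[0, 1]` channel scale.
#' @param bilateral_sigma_space spatial sigma of the bilateral filter, pixels.
#' @param closing_radius radius of the disk structuring element used by
#'   morphological closing, pixels.
#' @param min_area minimum connected-component area kept by the area filter,
#'   in pixels. The default `NA` resolves at run time to 0.1 percent of the image
#'   pixel count, which keeps behaviour stable across image sizes.
#' @param grayscale_weights luma coefficients `(wR, wG, wB)` defining the
#'   grayscale mean used by [color_constancy()]; must sum to 1. Default
#'   ITU-R BT.601.
#' @return An object of class `seg_config` (a named list).
#' @export
#' @examples
#' cfg <- seg_config(closing_radius = 2)
#' cfg$min_area # NA -> resolved per image
seg_config <- function(bilateral_diameter = 9,
                       bilateral_sigma_color = 0.1,
                       bilateral_sigma_space = 5,
                       closing_radius = 3,
                       min_area = NA_real_,
                       grayscale_weights = c(0.299, 0.587, 0.114)) {
  stopifnot(length(grayscale_weights) == 3)
  if (abs(sum(grayscale_weights) - 1) > 1e-9)
    stop("grayscale_weights must sum to 1", call. = FALSE)
  num_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      stop(sprintf("%s must be a positive number", nm), call. = FALSE)
  }
  num_pos(bilateral_diameter, "bilateral_diameter")
  num_pos(bilateral_sigma_color, "bilateral_sigma_color")
  num_pos(bilateral_sigma_space, "bilateral_sigma_space")
  num_pos(closing_radius, "closing_radius")
  if (!is.na(min_area)) num_pos(min_area, "min_area")
  structure(list(bilateral_diameter = as.integer(bilateral_diameter),
                 bilateral_sigma_color = bilateral_sigma_color,
                 bilateral_sigma_space = bilateral_sigma_space,
                 closing_radius = as.integer(closing_radius),
                 min_area = min_area,
                 grayscale_weights = as.numeric(grayscale_weights)),
            class = "seg_config")
}

resolve_min_area <- function(config, n_pixels) {
  if (is.na(config$min_area)) max(1, round(0.001 * n_pixels)) else config$min_area
}

#' Read or write a segmentation config as flat YAML
#'
#' Every [seg_config()] field is a top-level key; `grayscale_weights` is a
#' length-3 sequence.
#'
#' @param path YAML file path.
#' @return `read_seg_config()` returns a `seg_config`;
#'   `write_seg_config()` returns `path` invisibly.
#' @export
read_seg_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config serialization requires the 'yaml' package", call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$min_area) && is.character(vals$min_area)) vals$min_area <- NA_real_
  do.call(seg_config, vals)
}

#' @rdname read_seg_config
#' @param config a [seg_config()].
#' @export
write_seg_config <- function(config, path) {
  stopifnot(inherits(config, "seg_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config serialization requires the 'yaml' package", call. = FALSE)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Color constancy normalization
#'
#' Rescales every RGB channel by the ratio of the image's grayscale mean to
#' that channel's mean, homogenizing stain and illumination differences
#' between acquisitions. Before clipping, each output channel mean equals the
#' input grayscale mean.
#'
#' @param image RGB image array (`height x width x 3`, values in 0--255).
#' @param weights luma coefficients defining the grayscale mean; default
#'   ITU-R BT.601.
#' @param clip if `TRUE` (default) the result is clamped to `[0, 255]` and
#'   rounded half-up to integers; `FALSE` returns the unclipped rescaling
#'   (useful for checking mean conservation).
#' @return An RGB image array of the same dimensions.
#' @export
#' @examples
#' img <- array(128, c(4, 4, 3))
#' identical(color_constancy(img), img) # gray images are fixed points
color_constancy <- function(image, weights = c(0.299, 0.587, 0.114),
                            clip = TRUE) {
  validate_rgb(image)
  stopifnot(length(weights) == 3)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("grayscale weights must sum to 1", call. = FALSE)
  ch_means <- c(mean(image[, , 1]), mean(image[, , 2]), mean(image[, , 3]))
  if (any(ch_means == 0)) {
    bad <- c("R", "G", "B")[which(ch_means == 0)]
    stop(sprintf("degenerate channel: mean of %s is zero, color-constancy weight undefined",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  gray_mean <- sum(weights * ch_means)
  out <- image
  for (c in 1:3) out[, , c] <- image[, , c] * (gray_mean / ch_means[c])
  if (clip) out <- floor(pmin(pmax(out, 0), 255) + 0.5)
  out
}

#' Extract the CMYK Magenta channel
#'
#' Naive device conversion: with normalized `(r, g, b)` in `[0, 1]`,
#' `K = 1 - max(r, g, b)` and `M = (1 - g - K) / (1 - K)` when `K < 1`,
#' else 0. Purple-stained nuclei score high on Magenta.
#'
#' @param image RGB image array.
#' @return A numeric matrix in `[0, 1]` with the image's spatial dimensions.
#' @export
extract_magenta <- function(image) {
  validate_rgb(image)
  r <- image[, , 1] / 255; g <- image[, , 2] / 255; b <- image[, , 3] / 255
  mx <- pmax(r, g, b)
  m <- ifelse(mx > 0, (mx - g) / mx, 0)
  matrix(pmin(pmax(m, 0), 1), dim(image)[1], dim(image)[2])
}

#' Extract the HSV Saturation channel
#'
#' `S = (max - min) / max` over the normalized RGB triple when `max > 0`,
#' else 0. Stained nuclei are strongly chromatic, hence high-saturation.
#'
#' @param image RGB image array.
#' @return A numeric matrix in `[0, 1]`.
#' @export
extract_saturation <- function(image) {
  validate_rgb(image)
  r <- image[, , 1] / 255; g <- image[, , 2] / 255; b <- image[, , 3] / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  matrix(pmin(pmax(s, 0), 1), dim(image)[1], dim(image)[2])
}

#' Hadamard (elementwise) product of two channel maps
#'
#' Multiplying the Magenta and Saturation maps concentrates response on
#' pixels that are high in both -- the purple nucleus -- and suppresses the
#' pinkish background and red cells, which are low in at least one factor.
#'
#' @param m,s channel maps (numeric matrices in `[0, 1]`) of equal shape.
#' @return Their elementwise product, a channel map.
#' @export
hadamard_enhance <- function(m, s) {
  validate_channel(m); validate_channel(s)
  if (!identical(dim(m), dim(s)))
    stop("dimension mismatch between channel maps", call. = FALSE)
  m * s
}

#' Bilateral (edge-preserving) smoothing
#'
#' Classic bilateral filter: each output pixel is a normalized average of its
#' neighbours within a square window, weighted by a spatial Gaussian and a
#' range Gaussian on intensity difference. Noise inside homogeneous regions
#' is averaged away while step edges, whose intensity jump exceeds the range
#' sigma, are preserved.
#'
#' @param channel channel map (numeric matrix in `[0, 1]`).
#' @param config a [seg_config()]; uses `bilateral_diameter`,
#'   `bilateral_sigma_color`, `bilateral_sigma_space`.
#' @return Smoothed channel map; constant inputs are fixed points and the
#'   output range never exceeds the input range.
#' @export
bilateral_smooth <- function(channel, config = seg_config()) {
  validate_channel(channel)
  if (config$bilateral_sigma_color <= 0 || config$bilateral_sigma_space <= 0)
    stop("bilateral sigmas must be positive", call. = FALSE)
  d <- config$bilateral_diameter
  rad <- d %/% 2L
  if (rad < 1L) return(channel)
  h <- nrow(channel); w <- ncol(channel)
  sc2 <- 2 * config$bilateral_sigma_color^2
  ss2 <- 2 * config$bilateral_sigma_space^2
  # replicate-pad, then accumulate shifted copies weighted by space x range
  hp <- h + 2L * rad; wp <- w + 2L * rad
  ridx <- pmin(pmax(seq_len(hp) - rad, 1L), h)
  cidx <- pmin(pmax(seq_len(wp) - rad, 1L), w)
  pad <- channel[ridx, cidx, drop = FALSE]
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (dy in -rad:rad) {
    for (dx in -rad:rad) {
      if (dy * dy + dx * dx > rad * rad) next   # disk-shaped support
      wsp <- exp(-(dy * dy + dx * dx) / ss2)
      shifted <- pad[(rad + 1L + dy):(rad + h + dy),
                     (rad + 1L + dx):(rad + w + dx), drop = FALSE]
      wr <- exp(-((shifted - channel)^2) / sc2) * wsp
      num <- num + wr * shifted
      den <- den + wr
    }
  }
  out <- num / den
  pmin(pmax(out, min(channel)), max(channel))
}

#' Otsu binarization
#'
#' Global Otsu threshold on a 256-bin histogram of the `[0, 1]` channel
#' (8-bit quantization). The threshold maximizes the between-class variance;
#' ties are broken toward the lowest maximizing bin. Foreground is the
#' population *above* the threshold -- in the Magenta x Saturation product the
#' nuclei are bright.
#'
#' @param channel channel map (numeric matrix in `[0, 1]`).
#' @return A logical mask, `TRUE` = foreground. For a constant image an
#'   all-`FALSE` mask is returned with a warning (degenerate histogram).
#' @export
otsu_binarize <- function(channel) {
  validate_channel(channel)
  q <- as.integer(floor(channel * 255 + 0.5))   # 0..255 bins
  if (min(q) == max(q)) {
    warning("degenerate histogram: constant image, returning empty mask")
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  }
  counts <- tabulate(q + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)              # class-0 weight for threshold t = bin
  mu <- cumsum(p * levels)        # class-0 first moment
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254 (foreground = bins > t)
  t <- 1:255
  w0 <- omega[t]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[t][valid])^2 / (w0[valid] * w1[valid])
  t_star <- which.max(sigma_b) - 1L   # lowest maximizer, on the 0..254 scale
  matrix(q > t_star, nrow(channel), ncol(channel))
}

#' Morphological refinement of a binary mask
#'
#' Three steps: (1) morphological closing with a disk structuring element,
#' which bridges small gaps and removes small dark intrusions; (2) hole
#' filling -- background components not connected to the image border become
#' foreground; (3) an area filter removing connected components (8-connected)
#' smaller than `min_area` pixels.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param config a [seg_config()]; uses `closing_radius` and `min_area`
#'   (`NA` resolves to 0.1 percent of the pixel count).
#' @return Refined logical mask: every surviving component has area at least
#'   `min_area` and contains no holes.
#' @export
refine_mask <- function(mask, config = seg_config()) {
  validate_mask(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  brush <- EBImage::makeBrush(2L * config$closing_radius + 1L, shape = "disc")
  m <- EBImage::closing(m, brush)
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  min_area <- resolve_min_area(config, length(mask))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < min_area)
    if (length(drop)) m[lab %in% drop] <- 0
  }
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

#' Handcrafted WBC nuclei segmentation
#'
#' Runs the full handcrafted pipeline on an RGB blood-smear image:
#' color constancy, Magenta and Saturation extraction, Hadamard product,
#' bilateral smoothing, Otsu binarization, and morphological refinement
#' (closing, hole filling, area filter).
#'
#' @param image RGB image array (`height x width x 3`, 0--255).
#' @param config a [seg_config()].
#' @return A list of class `wbc_segmentation` with elements `mask` (logical
#'   matrix) and `masked` (the input image with the background zeroed).
#' @export
#' @examples
#' sm <- make_smear(smear_params(image_size = 96, n_rbc = 4, seed = 1))
#' seg <- segment_handcrafted(sm$image)
#' mean(seg$mask == sm$mask)
segment_handcrafted <- function(image, config = seg_config()) {
  validate_rgb(image)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  cc   <- stage("color_constancy", color_constancy(image, config$grayscale_weights))
  m    <- stage("extract_magenta", extract_magenta(cc))
  s    <- stage("extract_saturation", extract_saturation(cc))
  prod <- stage("hadamard_enhance", hadamard_enhance(m, s))
  sm   <- stage("bilateral_smooth", bilateral_smooth(prod, config))
  bin  <- withCallingHandlers(
    stage("otsu_binarize", otsu_binarize(sm)),
    warning = function(w) invokeRestart("muffleWarning"))
  mask <- stage("refine_mask", refine_mask(bin, config))
  masked <- image * as.numeric(rep(mask, 3))
  dim(masked) <- dim(image)
  structure(list(mask = mask, masked = masked), class = "wbc_segmentation")
}

#' @export
print.wbc_segmentation <- function(x, ...) {
  cat(sprintf("Handcrafted WBC nuclei segmentation: %d x %d, %d foreground px (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}
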