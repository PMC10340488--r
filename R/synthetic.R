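# Deterministic synthetic fixtures: stained-blood-smear lookalikes with
# exact ground-truth nucleus masks, and Gaussian 3-class logit clouds with
# controlled separability.

#' Parameters of the synthetic blood-smear generator
#'
#' The generator emulates the appearance that drives the handcrafted
#' pipeline: a pinkish background, disk-shaped red blood cells whose
#' Magenta x Saturation product is low, and purple nucleus blobs whose
#' product is high. Nucleus shapes are radial-frequency-perturbed ellipses,
#' so hole filling and closing do non-trivial work downstream.
#'
#' @param image_size canvas side, pixels (square image).
#' @param n_nuclei number of nucleus blobs.
#' @param nucleus_radius_range `c(min, max)` base radius of a nucleus, px.
#' @param nucleus_color mean RGB of nuclei (purple: high Magenta and
#'   Saturation).
#' @param n_rbc number of red blood cell disks.
#' @param rbc_radius_range `c(min, max)` red-cell radius, px.
#' @param rbc_color mean RGB of red cells (pink: low Magenta x Saturation).
#' @param background_color mean RGB of the background plasma.
#' @param color_jitter_sd per-object RGB jitter standard deviation
#'   (intensity units).
#' @param noise_sd per-pixel Gaussian noise standard deviation (intensity
#'   units).
#' @param hard_mode if `TRUE`, nuclei are drawn washed-out (low saturation,
#'   close to the background), emulating the nearly translucent nuclei found
#'   in some acquisitions; a stress preset, not the default condition.
#' @param seed integer seed; the generator is a pure function of its
#'   parameters including the seed.
#' @return An object of class `smear_params`.
#' @export
smear_params <- function(image_size = 128,
                         n_nuclei = 1,
                         nucleus_radius_range = c(14, 22),
                         nucleus_color = c(115, 35, 150),
                         n_rbc = 12,
                         rbc_radius_range = c(8, 13),
                         rbc_color = c(235, 160, 170),
                         background_color = c(245, 228, 215),
                         color_jitter_sd = 8,
                         noise_sd = 3,
                         hard_mode = FALSE,
                         seed = 1L) {
  p <- list(image_size = as.integer(image_size), n_nuclei = as.integer(n_nuclei),
            nucleus_radius_range = nucleus_radius_range,
            nucleus_color = nucleus_color, n_rbc = as.integer(n_rbc),
            rbc_radius_range = rbc_radius_range, rbc_color = rbc_color,
            background_color = background_color,
            color_jitter_sd = color_jitter_sd, noise_sd = noise_sd,
            hard_mode = isTRUE(hard_mode), seed = as.integer(seed))
  if (p$image_size < 16) stop("image_size too small", call. = FALSE)
  if (any(c(p$nucleus_color, p$rbc_color, p$background_color) < 0) ||
      any(c(p$nucleus_color, p$rbc_color, p$background_color) > 255))
    stop("colors must be within [0, 255]", call. = FALSE)
  if (p$n_nuclei > 0 &&
      2 * (1.45 * max(p$nucleus_radius_range) + 2) > p$image_size)
    stop("nuclei do not fit inside the canvas", call. = FALSE)
  if (p$hard_mode) p$nucleus_color <- c(200, 170, 210)
  structure(p, class = "smear_params")
}

# coverage in [0,1] of a radial blob r(theta) centered at (cy, cx);
# also returns the exact (un-anti-aliased) membership used for GT
radial_blob <- function(h, w, cy, cx, r0, ax = 1, ay = 1, amps = NULL,
                        phases = NULL) {
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- (y - cy) / ay; dx <- (x - cx) / ax
  dist <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)
  r <- r0
  if (!is.null(amps))
    for (k in seq_along(amps))
      r <- r + r0 * amps[k] * cos((k + 1) * theta + phases[k])
  list(coverage = pmin(pmax(r + 0.5 - dist, 0), 1), inside = dist <= r)
}

#' Generate a synthetic blood smear with ground truth
#'
#' Draws the background, anti-aliased red-cell disks, and irregular nucleus
#' blobs (drawn last, hence never occluded), then adds Gaussian pixel noise.
#' The ground-truth mask is the exact union of the nucleus blobs, before
#' anti-aliasing and noise.
#'
#' @param params a [smear_params()].
#' @return A list of class `wbc_smear`: `image` (RGB array, 0--255), `mask`
#'   (logical matrix) and `params`.
#' @export
#' @examples
#' sm <- make_smear(smear_params(image_size = 96, seed = 7))
#' dim(sm$image); sum(sm$mask) > 0
make_smear <- function(params = smear_params()) {
  stopifnot(inherits(params, "smear_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  s <- params$image_size
  img <- array(0, c(s, s, 3))
  for (c in 1:3)
    img[, , c] <- params$background_color[c] +
      matrix(stats::rnorm(1, 0, params$color_jitter_sd), s, s)
  paint <- function(img, cov, col) {
    for (c in 1:3) img[, , c] <- img[, , c] * (1 - cov) + col[c] * cov
    img
  }
  # red blood cells: plain anti-aliased disks, may overlap each other
  for (i in seq_len(params$n_rbc)) {
    r <- stats::runif(1, params$rbc_radius_range[1], params$rbc_radius_range[2])
    cy <- stats::runif(1, 1, s); cx <- stats::runif(1, 1, s)
    col <- params$rbc_color + stats::rnorm(3, 0, params$color_jitter_sd)
    blob <- radial_blob(s, s, cy, cx, r)
    img <- paint(img, blob$coverage, col)
  }
  # nuclei: perturbed ellipses, drawn last; GT is their exact union
  mask <- matrix(FALSE, s, s)
  rmax <- params$nucleus_radius_range[2]
  for (i in seq_len(params$n_nuclei)) {
    r <- stats::runif(1, params$nucleus_radius_range[1],
                      params$nucleus_radius_range[2])
    margin <- rmax * 1.45 + 2
    cy <- stats::runif(1, margin, s - margin)
    cx <- stats::runif(1, margin, s - margin)
    ax <- stats::runif(1, 0.8, 1.2); ay <- stats::runif(1, 0.8, 1.2)
    amps <- stats::runif(3, 0.02, 0.08)
    phases <- stats::runif(3, 0, 2 * pi)
    col <- params$nucleus_color + stats::rnorm(3, 0, params$color_jitter_sd)
    blob <- radial_blob(s, s, cy, cx, r, ax, ay, amps, phases)
    img <- paint(img, blob$coverage, col)
    mask <- mask | blob$inside
  }
  img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
  img <- floor(pmin(pmax(img, 0), 255) + 0.5)
  structure(list(image = img, mask = mask, params = params),
            class = "wbc_smear")
}

#' @export
print.wbc_smear <- function(x, ...) {
  cat(sprintf("Synthetic smear %dx%d: %d nuclei, %d red cells, %d GT px\n",
              nrow(x$mask), ncol(x$mask), x$params$n_nuclei, x$params$n_rbc,
              sum(x$mask)))
  invisible(x)
}

#' Parameters of the synthetic logit-cloud generator
#'
#' @param centroids 3 x 3 numeric matrix, one row per class, giving the
#'   class centroid in logit space `(L1, L2, L3)`. The default places each
#'   class's own logit high, as a trained classifier would.
#' @param spread_sd isotropic within-class standard deviation (one value, or
#'   one per class).
#' @param n_per_class samples per class.
#' @param seed integer seed.
#' @return An object of class `logit_sim_params`.
#' @export
logit_sim_params <- function(centroids = rbind(c(6, -2, -2),
                                               c(-2, 6, -2),
                                               c(-2, -2, 6)),
                             spread_sd = 1,
                             n_per_class = 100,
                             seed = 1L) {
  centroids <- as.matrix(centroids)
  if (!all(dim(centroids) == c(3, 3)))
    stop("centroids must be a 3 x 3 matrix (class x logit)", call. = FALSE)
  if (anyDuplicated(centroids, MARGIN = 1))
    stop("centroids must be distinct", call. = FALSE)
  spread_sd <- rep_len(spread_sd, 3)
  if (any(spread_sd <= 0)) stop("spread_sd must be positive", call. = FALSE)
  structure(list(centroids = centroids, spread_sd = spread_sd,
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed)),
            class = "logit_sim_params")
}

#' Generate a synthetic 3-class logit cloud
#'
#' Per class, draws `n_per_class` samples from an isotropic Gaussian around
#' the class centroid in `(L1, L2, L3)` logit space.
#'
#' @param params a [logit_sim_params()].
#' @return A data frame with columns `L1`, `L2`, `L3`, `label` (integer class
#'   in 1..3).
#' @export
#' @examples
#' lg <- make_logits(logit_sim_params(n_per_class = 50, seed = 3))
#' table(lg$label)
make_logits <- function(params = logit_sim_params()) {
  stopifnot(inherits(params, "logit_sim_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  out <- lapply(1:3, function(k) {
    n <- params$n_per_class
    pts <- matrix(stats::rnorm(3 * n, sd = params$spread_sd[k]), n, 3,
                  byrow = TRUE)
    sweep(pts, 2, params$centroids[k, ], `+`)
  })
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("L1", "L2", "L3")
  df$label <- rep(1:3, each = params$n_per_class)
  df
}

#' Write paired image/mask fixture directories
#'
#' Generates `n` synthetic smears and writes them in the dataset layout the
#' training harness reads: `images/NNN.png` and `masks/NNN.png` matched by
#' filename.
#'
#' @param dir output directory (created if needed).
#' @param n number of smears.
#' @param params base [smear_params()]; smear `i` uses `seed + i - 1`.
#' @return The directory path, invisibly.
#' @export
write_fixtures <- function(dir, n = 8, params = smear_params()) {
  img_dir <- file.path(dir, "images"); msk_dir <- file.path(dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    p <- params; p$seed <- params$seed + i - 1L
    sm <- make_smear(p)
    fn <- sprintf("%03d.png", i)
    write_image(sm$image, file.path(img_dir, fn))
    write_mask(sm$mask, file.path(msk_dir, fn))
  }
  invisible(dir)
}

# save/restore the global RNG state so generators are pure functions of
# their seed without clobbering the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
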