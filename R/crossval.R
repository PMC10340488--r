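# 10-fold cross-validation harness with on-the-fly augmentation.

#' Build a k-fold plan
#'
#' Randomly shuffles the sample indices and partitions them into `n_folds`
#' folds whose sizes differ by at most one.
#'
#' @param n number of samples.
#' @param n_folds number of folds (default 10).
#' @param seed shuffle seed.
#' @return An object of class `fold_plan` with `assignments` (fold index per
#'   sample), `n_folds` and `seed`.
#' @export
#' @examples
#' table(fold_plan(25, 10, seed = 3)$assignments)
fold_plan <- function(n, n_folds = 10L, seed = 1L) {
  if (n < n_folds)
    stop("fewer samples than folds", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assignments <- integer(n)
  assignments[sample.int(n)] <- rep(seq_len(n_folds), length.out = n)
  structure(list(assignments = assignments, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Augmentation policy
#'
#' On-the-fly training augmentation: vertical flip, horizontal flip, random
#' 90-degree rotation and transposition each with probability `p_geom`;
#' random gamma, CLAHE and Gaussian noise each with probability `p_photo`;
#' and a deterministic resize to `resize` pixels. Augmentation applies to
#' training samples only; validation images receive only the resize.
#'
#' @param p_geom probability of each geometric transform.
#' @param p_photo probability of each photometric transform.
#' @param gamma_range multiplicative gamma range.
#' @param noise_sd Gaussian noise SD, intensity units.
#' @param resize output side length in pixels, or `NA` to keep the input
#'   size.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(p_geom = 0.5, p_photo = 0.2,
                           gamma_range = c(0.8, 1.2), noise_sd = 5,
                           resize = NA_integer_) {
  structure(list(p_geom = p_geom, p_photo = p_photo,
                 gamma_range = gamma_range, noise_sd = noise_sd,
                 resize = resize),
            class = "augment_policy")
}

# apply the policy to one image/mask pair using the current RNG stream
apply_augment <- function(image, mask, policy) {
  stopifnot(inherits(policy, "augment_policy"))
  flip_rows <- function(a) if (length(dim(a)) == 3) a[rev(seq_len(nrow(a))), , , drop = FALSE] else a[rev(seq_len(nrow(a))), , drop = FALSE]
  flip_cols <- function(a) if (length(dim(a)) == 3) a[, rev(seq_len(ncol(a))), , drop = FALSE] else a[, rev(seq_len(ncol(a))), drop = FALSE]
  tr <- function(a) if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
  if (stats::runif(1) < policy$p_geom) { image <- flip_rows(image); mask <- flip_rows(mask) }
  if (stats::runif(1) < policy$p_geom) { image <- flip_cols(image); mask <- flip_cols(mask) }
  if (stats::runif(1) < policy$p_geom) {
    k <- sample(1:3, 1)
    for (i in seq_len(k)) { image <- flip_cols(tr(image)); mask <- flip_cols(tr(mask)) }
  }
  if (stats::runif(1) < policy$p_geom) { image <- tr(image); mask <- tr(mask) }
  if (stats::runif(1) < policy$p_photo) {
    g <- stats::runif(1, policy$gamma_range[1], policy$gamma_range[2])
    image <- 255 * (image / 255)^g
  }
  if (stats::runif(1) < policy$p_photo) image <- apply_clahe(image)
  if (stats::runif(1) < policy$p_photo)
    image <- image + array(stats::rnorm(length(image), 0, policy$noise_sd),
                           dim(image))
  image <- pmin(pmax(image, 0), 255)
  if (!is.na(policy$resize) &&
      !all(dim(mask) == c(policy$resize, policy$resize))) {
    image <- resize_rgb(image, policy$resize, policy$resize)
    mask <- as.matrix(EBImage::resize(matrix(as.numeric(mask), nrow(mask)),
                                      w = policy$resize,
                                      h = policy$resize)) > 0.5
  }
  list(image = image, mask = mask)
}

# contrast-limited adaptive histogram equalization, per channel
apply_clahe <- function(image) {
  out <- image
  for (c in 1:3) {
    ch <- image[, , c] / 255
    res <- tryCatch(EBImage::clahe(ch, nx = 4, ny = 4),
                    error = function(e) ch)
    out[, , c] <- pmin(pmax(as.matrix(res), 0), 1) * 255
  }
  out
}

#' Cross-validated U-Net training
#'
#' Trains one U-Net per fold on the other folds and scores the held-out
#' fold, recording per-epoch loss and IoU curves for both sets.
#'
#' @param images,masks lists of paired RGB images and logical masks.
#' @param spec a [unet_spec()].
#' @param loss a [loss_params()].
#' @param plan a [fold_plan()] for `length(images)` samples; default is a
#'   10-fold plan seeded by `seed`.
#' @param augment an [augment_policy()] applied to training samples only, or
#'   `NULL`.
#' @param epochs,lr,batch_size passed to [wbc_unet()].
#' @param seed master seed; fold `k` trains with seed `seed + k`.
#' @param verbose passed to [wbc_unet()].
#' @return An object of class `wbc_unet_cv`: the plan, per-fold fitted
#'   models, per-fold history curves and per-fold held-out metric means.
#' @export
train_crossval <- function(images, masks, spec = unet_spec(),
                           loss = loss_params(), plan = NULL,
                           augment = augment_policy(), epochs = 50,
                           lr = 1e-3, batch_size = 8L, seed = 1L,
                           verbose = 0) {
  n <- length(images)
  if (is.null(plan)) plan <- fold_plan(n, 10L, seed)
  if (length(plan$assignments) != n)
    stop("fold plan does not match the sample count", call. = FALSE)
  folds <- seq_len(plan$n_folds)
  fits <- vector("list", plan$n_folds)
  held_out <- vector("list", plan$n_folds)
  for (k in folds) {
    tr <- which(plan$assignments != k)
    te <- which(plan$assignments == k)
    fit <- wbc_unet(images[tr], masks[tr], spec = spec, loss = loss,
                    epochs = epochs, lr = lr, batch_size = batch_size,
                    seed = seed + k, augment = augment,
                    validation = list(images = images[te], masks = masks[te]),
                    verbose = verbose)
    fits[[k]] <- fit
    preds <- lapply(te, function(i) predict(fit, images[[i]]))
    held_out[[k]] <- evaluate_batch(preds, masks[te])$aggregate
  }
  structure(list(plan = plan, fits = fits,
                 histories = lapply(fits, `[[`, "history"),
                 held_out = do.call(rbind, held_out)),
            class = "wbc_unet_cv")
}

#' @export
print.wbc_unet_cv <- function(x, ...) {
  cat(sprintf("Cross-validated U-Net: %d folds\n", x$plan$n_folds))
  cat("mean held-out metrics:\n")
  print(round(colMeans(x$held_out), 4))
  invisible(x)
}

#' Load a paired image/mask dataset from disk
#'
#' Reads the `images/` and `masks/` subdirectories of `dir`, matched by
#' filename, in the layout written by [write_fixtures()].
#'
#' @param dir dataset directory.
#' @return List with `images` and `masks` lists and `names`.
#' @export
read_dataset <- function(dir) {
  files <- sort(intersect(list.files(file.path(dir, "images"), "\\.png$"),
                          list.files(file.path(dir, "masks"), "\\.png$")))
  if (!length(files)) stop("no paired images/masks found", call. = FALSE)
  list(images = lapply(files, function(f) read_image(file.path(dir, "images", f))),
       masks = lapply(files, function(f) read_mask(file.path(dir, "masks", f))),
       names = files)
}
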