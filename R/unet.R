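# U-Net segmenter: five-level encoder-decoder with strided-convolution
# downsampling, instance normalization, Mish activations, dropout, skip
# connections, a sigmoid head, trained with Adam on the Unified Focal Loss
# with plateau-based learning-rate reduction.

#' U-Net architecture specification
#'
#' @param in_channels input channels (3 for RGB).
#' @param channels feature widths per level, shallow to deep.
#' @param strides downsampling stride entering each level; 1 at the first
#'   level and 2 afterwards, so the bottleneck sees a 16-fold spatial
#'   reduction.
#' @param dropout_p dropout probability applied after each activation
#'   during training.
#' @param out_channels output channels (1: foreground probability).
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(in_channels = 3L,
                      channels = c(32L, 64L, 128L, 256L, 512L),
                      strides = c(1L, 2L, 2L, 2L, 2L),
                      dropout_p = 0.5,
                      out_channels = 1L) {
  if (length(channels) != length(strides))
    stop("channels and strides must have equal length", call. = FALSE)
  if (!all(strides %in% c(1L, 2L)))
    stop("strides must be 1 or 2", call. = FALSE)
  if (prod(strides) != 16L)
    stop("strides must give a 16-fold bottleneck reduction", call. = FALSE)
  if (dropout_p < 0 || dropout_p >= 1)
    stop("dropout_p must lie in [0, 1)", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 channels = as.integer(channels),
                 strides = as.integer(strides),
                 levels = length(channels),
                 dropout_p = dropout_p,
                 out_channels = as.integer(out_channels)),
            class = "unet_spec")
}

#' @export
print.unet_spec <- function(x, ...) {
  cat(sprintf("U-Net spec: %d -> [%s] -> %d, strides (%s), dropout %.2f\n",
              x$in_channels, paste(x$channels, collapse = ", "),
              x$out_channels, paste(x$strides, collapse = ","), x$dropout_p))
  invisible(x)
}

# He-uniform initialization for one conv layer
init_conv <- function(cin, cout, k) {
  fan_in <- k * k * cin
  bound <- sqrt(6 / fan_in)
  list(W = matrix(stats::runif(cout * k * k * cin, -bound, bound),
                  cout, k * k * cin),
       b = numeric(cout))
}

#' Initialize U-Net weights
#'
#' Builds the parameter set of the network described by a [unet_spec()]:
#' per encoder level one strided 3x3 convolution block
#' (conv + instance norm + Mish + dropout), per decoder level a 2x
#' nearest-neighbour upsampling, concatenation with the encoder skip, and a
#' 3x3 convolution block, then a final 1x1 convolution with sigmoid.
#' Weights use He-uniform initialization from the current RNG stream.
#'
#' @param spec a [unet_spec()].
#' @return Named list of parameter arrays.
#' @keywords internal
unet_init <- function(spec) {
  L <- spec$levels
  ch <- spec$channels
  params <- list()
  cin <- spec$in_channels
  for (i in seq_len(L)) {
    cv <- init_conv(cin, ch[i], 3L)
    params[[sprintf("enc%d_W", i)]] <- cv$W
    params[[sprintf("enc%d_b", i)]] <- cv$b
    params[[sprintf("enc%d_g", i)]] <- rep(1, ch[i])
    params[[sprintf("enc%d_be", i)]] <- rep(0, ch[i])
    cin <- ch[i]
  }
  for (i in rev(seq_len(L - 1L))) {
    cv <- init_conv(ch[i + 1L] + ch[i], ch[i], 3L)
    params[[sprintf("dec%d_W", i)]] <- cv$W
    params[[sprintf("dec%d_b", i)]] <- cv$b
    params[[sprintf("dec%d_g", i)]] <- rep(1, ch[i])
    params[[sprintf("dec%d_be", i)]] <- rep(0, ch[i])
  }
  cv <- init_conv(ch[1], spec$out_channels, 1L)
  params$head_W <- cv$W
  params$head_b <- cv$b
  params
}

# one conv + instance-norm + mish + dropout block
block_forward <- function(t, params, prefix, stride, dropout_p, training) {
  cv <- conv_forward(t, params[[paste0(prefix, "_W")]],
                     params[[paste0(prefix, "_b")]], 3L, stride)
  nm <- instnorm_forward(cv$out, params[[paste0(prefix, "_g")]],
                         params[[paste0(prefix, "_be")]])
  ac <- mish_forward(nm$out)
  dp <- dropout_forward(ac$out, dropout_p, training)
  list(out = dp$out,
       cache = list(cv = cv$cache, nm = nm$cache, ac = ac$cache,
                    dp = dp$cache))
}

block_backward <- function(dout, cache, grads, prefix) {
  d <- dropout_backward(dout, cache$dp)$dx
  d <- mish_backward(d, cache$ac)$dx
  nb <- instnorm_backward(d, cache$nm)
  grads[[paste0(prefix, "_g")]] <- nb$dgamma
  grads[[paste0(prefix, "_be")]] <- nb$dbeta
  cb <- conv_backward(nb$dx, cache$cv)
  grads[[paste0(prefix, "_W")]] <- cb$dW
  grads[[paste0(prefix, "_b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

# forward pass; x is an H x W x C x N array, H and W divisible by 16
unet_forward <- function(params, spec, x, training = FALSE) {
  d <- dim(x)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input spatial size must be divisible by 16 (the bottleneck stride product)",
         call. = FALSE)
  t <- nn_pack(x)
  L <- spec$levels
  caches <- vector("list", 2L * L + 1L)
  skips <- vector("list", L)
  for (i in seq_len(L)) {
    bl <- block_forward(t, params, sprintf("enc%d", i), spec$strides[i],
                        spec$dropout_p, training)
    t <- bl$out
    caches[[i]] <- bl$cache
    skips[[i]] <- t
  }
  for (i in rev(seq_len(L - 1L))) {
    up <- upsample_forward(t)
    cc <- concat_forward(up$out, skips[[i]])
    bl <- block_forward(cc$out, params, sprintf("dec%d", i), 1L,
                        spec$dropout_p, training)
    t <- bl$out
    caches[[2L * L - i]] <- list(up = up$cache, cc = cc$cache,
                                 bl = bl$cache)
  }
  hd <- conv_forward(t, params$head_W, params$head_b, 1L, 1L)
  caches[[2L * L]] <- hd$cache
  logits <- hd$out
  prob <- sigmoid(logits$m)
  caches[[2L * L + 1L]] <- prob
  probs <- nn_unpack(list(m = prob, h = logits$h, w = logits$w,
                          c = logits$c, n = logits$n))
  list(prob = probs, caches = caches, shape = logits[c("h", "w", "c", "n")])
}

# backward pass from dL/dprob; returns gradients for every parameter
unet_backward <- function(params, spec, fwd, dprob) {
  L <- spec$levels
  caches <- fwd$caches
  prob <- caches[[2L * L + 1L]]
  dp <- nn_pack(dprob)
  dlogits <- list(m = dp$m * prob * (1 - prob), h = dp$h, w = dp$w,
                  c = dp$c, n = dp$n)
  grads <- list()
  cb <- conv_backward(dlogits, caches[[2L * L]])
  grads$head_W <- cb$dW; grads$head_b <- cb$db
  d <- cb$dx
  dskips <- vector("list", L)
  for (i in seq_len(L - 1L)) {
    cache <- caches[[2L * L - i]]
    bb <- block_backward(d, cache$bl, grads, sprintf("dec%d", i))
    grads <- bb$grads
    sp <- concat_backward(bb$dx, cache$cc)
    dskips[[i]] <- sp$db
    d <- upsample_backward(sp$da, cache$up)$dx
  }
  for (i in rev(seq_len(L))) {
    if (i < L && !is.null(dskips[[i]]))
      d <- list(m = d$m + dskips[[i]]$m, h = d$h, w = d$w, c = d$c, n = d$n)
    bb <- block_backward(d, caches[[i]], grads, sprintf("enc%d", i))
    grads <- bb$grads
    d <- bb$dx
  }
  grads
}

#' Fit the U-Net nucleus segmenter
#'
#' Trains the encoder-decoder segmenter on paired images and masks with the
#' Unified Focal Loss, Adam, and a reduce-on-plateau learning-rate schedule.
#' All randomness (weight initialization, shuffling, dropout, augmentation)
#' is driven by `seed`, so a fit is reproducible.
#'
#' @param images list of RGB image arrays (equal sizes, divisible by 16), or
#'   an `H x W x 3 x N` array.
#' @param masks list of logical masks matching the images.
#' @param spec a [unet_spec()].
#' @param loss a [loss_params()].
#' @param epochs training epochs.
#' @param lr initial Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed.
#' @param augment augmentation policy from [augment_policy()], or `NULL`
#'   for none.
#' @param validation optional list `list(images =, masks =)` scored each
#'   epoch.
#' @param lr_patience epochs without loss improvement before the learning
#'   rate is halved.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return An object of class `wbc_unet`: fitted parameters, the spec, loss
#'   settings and a per-epoch `history` data frame (loss and soft IoU on the
#'   training set, plus validation columns when supplied).
#' @export
#' @examples
#' \donttest{
#' fx <- lapply(1:4, function(i)
#'   make_smear(smear_params(image_size = 32, n_rbc = 3,
#'                           nucleus_radius_range = c(6, 9), seed = i)))
#' fit <- wbc_unet(lapply(fx, `[[`, "image"), lapply(fx, `[[`, "mask"),
#'                 spec = unet_spec(channels = c(4, 8, 8, 16, 16),
#'                                  dropout_p = 0),
#'                 epochs = 5, verbose = 0)
#' fit
#' }
wbc_unet <- function(images, masks, spec = unet_spec(),
                     loss = loss_params(), epochs = 50, lr = 1e-3,
                     batch_size = 8L, seed = 1L, augment = NULL,
                     validation = NULL, lr_patience = 10L, verbose = 0) {
  if (is.array(images)) images <- array_to_list(images)
  if (is.array(masks)) masks <- array_to_list(masks)
  n <- length(images)
  if (n < 1L || n != length(masks))
    stop("images and masks must be non-empty lists of equal length",
         call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- unet_init(spec)
  state <- adam_init(params)
  cur_lr <- lr
  best <- Inf; stall <- 0L
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_iou <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1L, n)]
      pair <- assemble_batch(images[ids], masks[ids], augment)
      fwd <- unet_forward(params, spec, pair$x, training = TRUE)
      pr <- fwd$prob[, , 1, , drop = FALSE]
      lo <- unified_focal_loss(pr, pair$y, loss)
      g <- ufl_grad(pr, pair$y, loss)
      dprob <- array(0, dim(fwd$prob)); dprob[, , 1, ] <- g
      grads <- unet_backward(params, spec, fwd, dprob)
      upd <- adam_step(params, grads, state, cur_lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + lo
      ep_iou <- ep_iou + soft_iou(pr, pair$y)
      nb <- nb + 1L
    }
    row <- data.frame(epoch = ep, lr = cur_lr, train_loss = ep_loss / nb,
                      train_iou = ep_iou / nb)
    if (!is.null(validation)) {
      vb <- assemble_batch(validation$images, validation$masks, NULL)
      vf <- unet_forward(params, spec, vb$x, training = FALSE)
      vp <- vf$prob[, , 1, , drop = FALSE]
      row$val_loss <- unified_focal_loss(vp, vb$y, loss)
      row$val_iou <- soft_iou(vp, vb$y)
    }
    hist[[ep]] <- row
    monitor <- if (!is.null(validation)) row$val_loss else row$train_loss
    if (monitor < best - 1e-6) { best <- monitor; stall <- 0L }
    else {
      stall <- stall + 1L
      if (stall >= lr_patience) { cur_lr <- cur_lr / 2; stall <- 0L }
    }
    if (verbose > 0 && ep %% verbose == 0)
      message(sprintf("epoch %d: loss %.4f iou %.4f lr %.2e", ep,
                      row$train_loss, row$train_iou, cur_lr))
  }
  structure(list(params = params, spec = spec, loss = loss,
                 history = do.call(rbind, hist), seed = seed,
                 n_train = n),
            class = "wbc_unet")
}

soft_iou <- function(p, y) {
  y <- as.numeric(y)
  inter <- sum(p * y)
  union <- sum(p) + sum(y) - inter
  if (union == 0) 1 else inter / union
}

array_to_list <- function(a) {
  d <- dim(a)
  if (length(d) == 3L) return(list(a))
  lapply(seq_len(d[length(d)]), function(i)
    if (length(d) == 4L) a[, , , i] else a[, , i])
}

# stack image/mask lists into batch arrays, applying augmentation per sample
assemble_batch <- function(images, masks, augment) {
  n <- length(images)
  if (!is.null(augment)) {
    for (i in seq_len(n)) {
      au <- apply_augment(images[[i]], masks[[i]], augment)
      images[[i]] <- au$image; masks[[i]] <- au$mask
    }
  }
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], 3, n))
  y <- array(0, c(d[1], d[2], 1, n))
  for (i in seq_len(n)) {
    x[, , , i] <- images[[i]] / 255
    y[, , 1, i] <- as.numeric(masks[[i]])
  }
  list(x = x, y = y[, , 1, , drop = FALSE])
}

#' @export
print.wbc_unet <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("U-Net nucleus segmenter: %d training images, %d epochs\n",
              x$n_train, nrow(x$history)))
  print(x$spec)
  cat(sprintf("final train loss %.4f, train IoU %.4f\n",
              last$train_loss, last$train_iou))
  invisible(x)
}

#' @export
plot.wbc_unet <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss", ...)
  if (!is.null(h$val_loss)) graphics::lines(h$epoch, h$val_loss, lty = 2)
  plot(h$epoch, h$train_iou, type = "l", xlab = "epoch", ylab = "IoU",
       ylim = c(0, 1), ...)
  if (!is.null(h$val_iou)) graphics::lines(h$epoch, h$val_iou, lty = 2)
  invisible(x)
}

#' Predict a nucleus mask with a fitted U-Net
#'
#' Runs the network on an image (resized to the nearest multiple-of-16
#' shape if needed), thresholds the foreground probability at 0.5, and
#' restores the original shape.
#'
#' @param object a fitted [wbc_unet()] model.
#' @param image RGB image array (0--255).
#' @param threshold probability cut for foreground.
#' @param ... unused.
#' @return Logical mask of the image's spatial shape.
#' @export
predict.wbc_unet <- function(object, image, threshold = 0.5, ...) {
  validate_rgb(image)
  d <- dim(image)
  h16 <- max(16L, as.integer(round(d[1] / 16)) * 16L)
  w16 <- max(16L, as.integer(round(d[2] / 16)) * 16L)
  xin <- image
  if (h16 != d[1] || w16 != d[2])
    xin <- resize_rgb(image, h16, w16)
  x <- array(xin / 255, c(h16, w16, 3, 1))
  fwd <- unet_forward(object$params, object$spec, x, training = FALSE)
  prob <- fwd$prob[, , 1, 1]
  if (h16 != d[1] || w16 != d[2])
    prob <- as.matrix(EBImage::resize(prob, w = d[1], h = d[2]))
  matrix(prob > threshold, d[1], d[2])
}

resize_rgb <- function(image, h, w) {
  out <- array(0, c(h, w, 3))
  for (c in 1:3)
    out[, , c] <- as.matrix(EBImage::resize(image[, , c], w = h, h = w))
  pmin(pmax(out, 0), 255)
}
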