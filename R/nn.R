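# Minimal CNN engine used by the U-Net segmenter. Feature maps are stored
# as C x (H*W*N) matrices (channels in rows; columns ordered sample-major,
# positions column-major within a sample), so convolutions reduce to one
# BLAS matrix multiply per layer via im2col. Only what the U-Net needs is
# implemented: 3x3 convolutions with stride 1 or 2, 1x1 convolutions,
# instance normalization, Mish, dropout, nearest-neighbour 2x upsampling
# and channel concatenation, all with hand-derived backward passes.

# ---- tensor helpers --------------------------------------------------------

# pack an H x W x C x N array into the internal C x (H*W*N) matrix
nn_pack <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  m <- aperm(x, c(3, 1, 2, 4))
  dim(m) <- c(d[3], d[1] * d[2] * d[4])
  list(m = m, h = d[1], w = d[2], c = d[3], n = d[4])
}

# unpack back to H x W x C x N
nn_unpack <- function(t) {
  a <- t$m
  dim(a) <- c(t$c, t$h, t$w, t$n)
  aperm(a, c(2, 3, 1, 4))
}

# cache of index maps keyed by shape, shared across forward/backward calls
.nn_cache <- new.env(parent = emptyenv())

# neighbour map for k x k conv with given stride and 'same' padding:
# matrix (k*k) x P_out of input positions (0 = zero pad), plus output size
conv_geom <- function(h, w, k, stride) {
  key <- sprintf("geom_%d_%d_%d_%d", h, w, k, stride)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  pad <- (k - 1L) %/% 2L
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  io <- rep(seq_len(ho), times = wo)           # output rows, col-major
  jo <- rep(seq_len(wo), each = ho)
  nb <- matrix(0L, k * k, ho * wo)
  tap <- 1L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      ii <- (io - 1L) * stride + ki - pad
      jj <- (jo - 1L) * stride + kj - pad
      ok <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
      nb[tap, ] <- ifelse(ok, ii + (jj - 1L) * h, 0L)
      tap <- tap + 1L
    }
  }
  out <- list(nb = nb, ho = ho, wo = wo)
  .nn_cache[[key]] <- out
  out
}

# full gather index into c(as.vector(m), 0): rows (tap-major, channel
# fastest) x columns (sample-major positions)
conv_index <- function(h, w, cin, n, k, stride) {
  key <- sprintf("idx_%d_%d_%d_%d_%d_%d", h, w, cin, n, k, stride)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  g <- conv_geom(h, w, k, stride)
  P <- g$ho * g$wo; hw <- h * w
  sentinel <- cin * hw * n + 1L
  # per-sample index for one channel, expanded over channels and samples
  base <- g$nb                                   # (k2) x P, 0 = pad
  k2 <- nrow(base)
  idx1 <- matrix(0L, k2 * cin, P)
  for (c in seq_len(cin))
    idx1[seq(c, by = cin, length.out = k2), ] <-
      ifelse(base == 0L, sentinel, c + (base - 1L) * cin)
  idx <- integer(k2 * cin * P * n)
  len <- k2 * cin * P
  for (s in seq_len(n)) {
    off <- (s - 1L) * cin * hw
    blk <- ifelse(idx1 == sentinel, sentinel, idx1 + off)
    idx[((s - 1L) * len + 1L):(s * len)] <- blk
  }
  keep <- idx != sentinel
  scatter <- Matrix::sparseMatrix(i = idx[keep], j = which(keep), x = 1,
                                  dims = c(sentinel - 1L, length(idx)))
  out <- list(idx = idx, k2c = k2 * cin, ho = g$ho, wo = g$wo,
              sentinel = sentinel, scatter = scatter)
  .nn_cache[[key]] <- out
  out
}

# ---- layers ----------------------------------------------------------------

conv_forward <- function(t, W, b, k, stride) {
  ci <- conv_index(t$h, t$w, t$c, t$n, k, stride)
  xv <- c(t$m, 0)
  Xcol <- xv[ci$idx]
  dim(Xcol) <- c(ci$k2c, ci$ho * ci$wo * t$n)
  Y <- W %*% Xcol + b
  list(out = list(m = Y, h = ci$ho, w = ci$wo, c = nrow(W), n = t$n),
       cache = list(Xcol = Xcol, W = W, k = k, stride = stride,
                    in_shape = t[c("h", "w", "c", "n")], ci = ci))
}

conv_backward <- function(dout, cache) {
  dY <- dout$m
  dW <- tcrossprod(dY, cache$Xcol)
  db <- rowSums(dY)
  dXcol <- crossprod(cache$W, dY)
  s <- cache$in_shape
  dx <- as.numeric(cache$ci$scatter %*% as.vector(dXcol))
  dim(dx) <- c(s$c, s$h * s$w * s$n)
  list(dx = list(m = dx, h = s$h, w = s$w, c = s$c, n = s$n),
       dW = dW, db = db)
}

# per-(channel, sample) mean over positions: returns C x N
group_mean <- function(m, hw, n) {
  dim(m) <- c(nrow(m), hw, n)
  out <- colMeans(aperm(m, c(2, 1, 3)))
  dim(out) <- c(dim(m)[1], n)
  out
}

expand_groups <- function(g, hw) g[, rep(seq_len(ncol(g)), each = hw), drop = FALSE]

instnorm_forward <- function(t, gamma, beta, eps = 1e-5) {
  hw <- t$h * t$w
  mu <- group_mean(t$m, hw, t$n)
  xc <- t$m - expand_groups(mu, hw)
  v <- group_mean(xc * xc, hw, t$n)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * expand_groups(inv_sd, hw)
  y <- gamma * xhat + beta
  list(out = list(m = y, h = t$h, w = t$w, c = t$c, n = t$n),
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma,
                    hw = hw, n = t$n))
}

instnorm_backward <- function(dout, cache) {
  dy <- dout$m
  hw <- cache$hw; n <- cache$n
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  m1 <- group_mean(dxhat, hw, n)
  m2 <- group_mean(dxhat * cache$xhat, hw, n)
  dx <- (dxhat - expand_groups(m1, hw) -
           cache$xhat * expand_groups(m2, hw)) *
    expand_groups(cache$inv_sd, hw)
  list(dx = list(m = dx, h = dout$h, w = dout$w, c = dout$c, n = dout$n),
       dgamma = dgamma, dbeta = dbeta)
}

mish_forward <- function(t) {
  list(out = list(m = mish(t$m), h = t$h, w = t$w, c = t$c, n = t$n),
       cache = t$m)
}

mish_backward <- function(dout, cache) {
  list(dx = list(m = dout$m * mish_grad(cache), h = dout$h, w = dout$w,
                 c = dout$c, n = dout$n))
}

dropout_forward <- function(t, p, training) {
  if (!training || p <= 0) return(list(out = t, cache = NULL))
  keep <- (matrix(stats::runif(length(t$m)), nrow(t$m)) >= p) / (1 - p)
  list(out = list(m = t$m * keep, h = t$h, w = t$w, c = t$c, n = t$n),
       cache = keep)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache)) return(list(dx = dout))
  list(dx = list(m = dout$m * cache, h = dout$h, w = dout$w, c = dout$c,
                 n = dout$n))
}

# nearest-neighbour 2x upsampling; columns are re-gathered per sample
upsample_index <- function(h, w, n) {
  key <- sprintf("up_%d_%d_%d", h, w, n)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  ho <- 2L * h; wo <- 2L * w
  io <- rep(seq_len(ho), times = wo); jo <- rep(seq_len(wo), each = ho)
  src <- ((io + 1L) %/% 2L) + (((jo + 1L) %/% 2L) - 1L) * h   # per sample
  idx <- as.vector(outer(src, (seq_len(n) - 1L) * h * w, `+`))
  # inverse: the 4 de-interleaved output subsets, each aligned with the
  # input grid, for a scatter-free backward pass
  ii <- rep(seq_len(h), times = w); jj <- rep(seq_len(w), each = h)
  off <- rep((seq_len(n) - 1L) * ho * wo, each = h * w)
  inv <- lapply(0:3, function(q) {
    a <- q %% 2L; b <- q %/% 2L
    rep((2L * ii - 1L + a) + (2L * jj - 2L + b) * ho, times = n) + off
  })
  out <- list(idx = idx, inv = inv)
  .nn_cache[[key]] <- out
  out
}

upsample_forward <- function(t) {
  ui <- upsample_index(t$h, t$w, t$n)
  list(out = list(m = t$m[, ui$idx, drop = FALSE], h = 2L * t$h,
                  w = 2L * t$w, c = t$c, n = t$n),
       cache = list(h = t$h, w = t$w, n = t$n, inv = ui$inv))
}

upsample_backward <- function(dout, cache) {
  m <- dout$m[, cache$inv[[1]], drop = FALSE] +
    dout$m[, cache$inv[[2]], drop = FALSE] +
    dout$m[, cache$inv[[3]], drop = FALSE] +
    dout$m[, cache$inv[[4]], drop = FALSE]
  list(dx = list(m = m, h = cache$h, w = cache$w, c = dout$c,
                 n = cache$n))
}

concat_forward <- function(a, b) {
  stopifnot(a$h == b$h, a$w == b$w, a$n == b$n)
  list(out = list(m = rbind(a$m, b$m), h = a$h, w = a$w, c = a$c + b$c,
                  n = a$n),
       cache = c(a$c, b$c))
}

concat_backward <- function(dout, cache) {
  list(da = list(m = dout$m[seq_len(cache[1]), , drop = FALSE], h = dout$h,
                 w = dout$w, c = cache[1], n = dout$n),
       db = list(m = dout$m[cache[1] + seq_len(cache[2]), , drop = FALSE],
                 h = dout$h, w = dout$w, c = cache[2], n = dout$n))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
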