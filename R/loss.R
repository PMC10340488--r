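# Mish activation and the Unified Focal Loss (a lambda-mixture of a
# modified focal term and a modified focal Tversky term).

#' Mish activation
#'
#' `mish(x) = x * tanh(log(1 + exp(x)))`, a smooth, non-monotonic activation
#' bounded below by about -0.309 and asymptotically the identity for large
#' `x`. Evaluated through a numerically stable softplus, so it is finite for
#' any finite input.
#'
#' @param x numeric vector/array (applied elementwise).
#' @return Numeric of the same shape.
#' @export
#' @examples
#' mish(0)          # 0
#' mish(30) - 30    # ~0: identity asymptote
mish <- function(x) {
  x * tanh(softplus(x))
}

# stable softplus: log(1 + exp(x)) without overflow
softplus <- function(x) {
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out
}

# elementwise derivative of mish, used by backprop
mish_grad <- function(x) {
  sp <- softplus(x)
  t <- tanh(sp)
  sig <- 1 / (1 + exp(-x))
  t + x * (1 - t * t) * sig
}

#' Unified Focal Loss parameters
#'
#' @param delta class-weighting parameter in `[0, 1]`: weights the positive
#'   class in the focal term and false negatives in the Tversky index.
#' @param gamma focusing exponent, `>= 0`: suppresses easy background in
#'   both terms.
#' @param lambda mixture weight in `[0, 1]` between the distribution-based
#'   focal term (`lambda = 1`) and the region-based focal Tversky term
#'   (`lambda = 0`).
#' @param focal_exponent `"as_printed"` uses `(1 - p_t)^(1 - gamma)` in the
#'   focal term; `"conventional"` uses the usual `(1 - p_t)^gamma`.
#' @param n_classes number of classes in the Tversky sum; this binary
#'   implementation sums soft counts over foreground and background, so 2.
#' @return An object of class `loss_params`.
#' @export
loss_params <- function(delta = 0.6, gamma = 0.5, lambda = 0.5,
                        focal_exponent = c("as_printed", "conventional"),
                        n_classes = 2L) {
  focal_exponent <- match.arg(focal_exponent)
  if (!is.numeric(delta) || delta < 0 || delta > 1)
    stop("delta must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(gamma) || gamma < 0)
    stop("gamma must be >= 0", call. = FALSE)
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  if (n_classes != 2L)
    stop("binary segmentation head: n_classes must be 2", call. = FALSE)
  structure(list(delta = delta, gamma = gamma, lambda = lambda,
                 focal_exponent = focal_exponent, n_classes = 2L),
            class = "loss_params")
}

# soft Tversky index for one class; pred/target on that class's probability
tversky_index <- function(p, y, delta) {
  tp <- sum(p * y); fn <- sum((1 - p) * y); fp <- sum(p * (1 - y))
  den <- tp + delta * fn + (1 - delta) * fp
  if (den == 0) 1 else tp / den
}

#' Unified Focal Loss
#'
#' `lambda * L_focal + (1 - lambda) * L_focalTversky`, where the focal term
#' is the mean over pixels of `delta * (1 - p_t)^(1 - gamma) * (-log p_t)`
#' (`p_t` the predicted probability of the true class) and the focal Tversky
#' term sums `(1 - mTI_c)^gamma` over the foreground and background classes,
#' with `mTI = TP / (TP + delta FN + (1 - delta) FP)` on soft counts.
#'
#' @param pred numeric array of foreground probabilities in `[0, 1]`.
#' @param gt logical (or 0/1 numeric) ground truth of the same shape.
#' @param params a [loss_params()].
#' @return Non-negative scalar loss; exactly 0 for a hard perfect prediction.
#' @export
#' @examples
#' gt <- matrix(c(1, 0, 0, 0), 2, 2)
#' unified_focal_loss(gt, gt) # 0
unified_focal_loss <- function(pred, gt, params = loss_params()) {
  stopifnot(inherits(params, "loss_params"))
  p <- as.numeric(pred); y <- as.numeric(gt)
  if (length(p) != length(y)) stop("shape mismatch", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("pred must lie in [0, 1]", call. = FALSE)
  eps <- 1e-7
  e_foc <- if (params$focal_exponent == "as_printed") 1 - params$gamma else params$gamma
  pt <- y * p + (1 - y) * (1 - p)
  l_focal <- mean(params$delta * (1 - pt)^e_foc * (-log(pmax(pt, eps))))
  ti_fg <- tversky_index(p, y, params$delta)
  ti_bg <- tversky_index(1 - p, 1 - y, params$delta)
  l_tversky <- (1 - ti_fg)^params$gamma + (1 - ti_bg)^params$gamma
  params$lambda * l_focal + (1 - params$lambda) * l_tversky
}

# gradient of unified_focal_loss w.r.t. pred (same shape as pred);
# probabilities are clamped away from {0,1} so the gradient stays finite
ufl_grad <- function(pred, gt, params = loss_params()) {
  p <- as.numeric(pred); y <- as.numeric(gt)
  n <- length(p)
  eps <- 1e-6
  pc <- pmin(pmax(p, eps), 1 - eps)
  e_foc <- if (params$focal_exponent == "as_printed") 1 - params$gamma else params$gamma
  u <- y * pc + (1 - y) * (1 - pc)          # p_t
  dfdu <- params$delta *
    (e_foc * (1 - u)^(e_foc - 1) * log(u) - (1 - u)^e_foc / u)
  dfocal <- dfdu * (2 * y - 1) / n
  grad_ti <- function(pcl, ycl, sign) {
    tp <- sum(pcl * ycl); fn <- sum((1 - pcl) * ycl); fp <- sum(pcl * (1 - ycl))
    den <- tp + params$delta * fn + (1 - params$delta) * fp
    if (den == 0) return(numeric(n))
    ti <- tp / den
    dti <- (ycl * den - tp * (1 - params$delta)) / den^2
    one_m <- max(1 - ti, 1e-8)
    -params$gamma * one_m^(params$gamma - 1) * dti * sign
  }
  dtv <- grad_ti(pc, y, 1) + grad_ti(1 - pc, 1 - y, -1)
  g <- params$lambda * dfocal + (1 - params$lambda) * dtv
  dim(g) <- dim(pred)
  g
}
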