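# Ensemble mask fusion: pixelwise logical AND of the handcrafted and deep
# masks, followed by an area opening. AND keeps only pixels both segmenters
# agree on, so false positives can only decrease; the cost is recall, which
# is accepted as designed behaviour.

#' Fuse two nucleus masks by logical AND
#'
#' `fused = handcrafted AND deep`, then connected components (8-connected)
#' smaller than `open_min_area` pixels are removed (area opening). The output
#' is always a subset of each input, so against any ground truth the fused
#' mask has no more false positives than either input.
#'
#' @param handcrafted,deep logical masks of equal shape.
#' @param open_min_area minimum component area kept after the AND, pixels;
#'   `NA` (default) resolves to 0.1 percent of the pixel count, matching the
#'   handcrafted pipeline's area filter.
#' @return Logical mask.
#' @export
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
#' b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
#' fuse_masks(a, b, open_min_area = 0)
fuse_masks <- function(handcrafted, deep, open_min_area = NA_real_) {
  validate_mask(handcrafted); validate_mask(deep)
  if (!identical(dim(handcrafted), dim(deep)))
    stop("dimension mismatch between masks", call. = FALSE)
  if (!is.na(open_min_area) && open_min_area < 0)
    stop("open_min_area must be >= 0", call. = FALSE)
  fused <- handcrafted & deep
  if (is.na(open_min_area))
    open_min_area <- max(1, round(0.001 * length(fused)))
  if (open_min_area > 0 && any(fused)) {
    lab <- EBImage::bwlabel(matrix(as.numeric(fused), nrow(fused), ncol(fused)))
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < open_min_area)
    if (length(drop)) fused[lab %in% drop] <- FALSE
  }
  fused
}
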