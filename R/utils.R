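# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Row-wise softmax for a logits matrix.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic entry points route their seed through this so that a fixed
# seed reproduces results bit-for-bit without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Mean intensity of an image array (h x w x 3) or matrix, in [0, 1].
mean_intensity <- function(img) mean(img)

# Luminance (simple channel average) of an h x w x 3 array.
to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
}

# Block-mean resize of a matrix to gh x gw using bin averaging ("squish":
# every source pixel maps to one destination cell regardless of aspect).
block_mean <- function(m, gh, gw) {
  h <- nrow(m); w <- ncol(m)
  ri <- floor((seq_len(h) - 1L) * gh / h) + 1L
  ci <- floor((seq_len(w) - 1L) * gw / w) + 1L
  # rowsum over rows, then over columns
  a <- rowsum(m, ri, reorder = TRUE)
  a <- a / as.vector(table(ri))
  b <- t(rowsum(t(a), ci, reorder = TRUE))
  b <- sweep(b, 2L, as.vector(table(ci)), "/")
  b
}

# Map an image of arbitrary height/width onto the extractor's reference
# geometry. "squish" bin-averages directly; "crop" centre-crops to the
# reference aspect first; "pad" zero-pads to the reference aspect first.
conform_image <- function(img, aspect = 9 / 16, mode = c("squish", "crop", "pad")) {
  mode <- match.arg(mode)
  if (mode == "squish") return(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  target_h <- w * aspect
  if (mode == "crop") {
    if (h > target_h) {
      keep <- max(1L, round(target_h))
      top <- floor((h - keep) / 2) + 1L
      img <- img[top:(top + keep - 1L), , , drop = FALSE]
    } else if (h < target_h) {
      keep_w <- max(1L, round(h / aspect))
      left <- floor((w - keep_w) / 2) + 1L
      img <- img[, left:(left + keep_w - 1L), , drop = FALSE]
    }
  } else { # pad
    if (h < target_h) {
      pad <- as.integer(ceiling(target_h)) - h
      z <- array(0, dim = c(pad, w, dim(img)[3L]))
      img <- abind_rows(img, z)
    }
  }
  img
}

# Minimal row-wise array bind (avoids an abind dependency).
abind_rows <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1L] + dim(b)[1L], dim(a)[2L], dim(a)[3L]))
  out[seq_len(dim(a)[1L]), , ] <- a
  out[dim(a)[1L] + seq_len(dim(b)[1L]), , ] <- b
  out
}

# Hue/saturation/value from an h x w x 3 array, vectorised. Returns a list
# of three matrices. Hue in [0, 1).
rgb_to_hsv_mats <- function(img) {
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  rm_ <- nz & (mx == r)
  gm <- nz & (mx == g) & !rm_
  bm <- nz & (mx == b) & !rm_ & !gm
  h[rm_] <- ((g[rm_] - b[rm_]) / d[rm_]) %% 6
  h[gm] <- (b[gm] - r[gm]) / d[gm] + 2
  h[bm] <- (r[bm] - g[bm]) / d[bm] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, v = mx)
}

hsv_to_rgb1 <- function(h, s, v) {
  # single colour; returns length-3 vector
  grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))[, 1L] / 255
}
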