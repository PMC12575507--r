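# Separable resampling implemented as weight-matrix products:
# out = Wy %*% img %*% t(Wx). Keeps everything deterministic and exact to
# test, and fast enough for per-frame use.

# Catmull-Rom cubic kernel (a = -0.5); partition of unity.
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# Weight matrix (n_out x n_in) for bicubic sampling with the package's pure
# multiplicative coordinate convention: output coordinate u samples input
# coordinate u / factor, so a feature at input x lands at x * factor.
bicubic_weights <- function(n_in, n_out) {
  src <- (0:(n_out - 1)) * (n_in / n_out)
  base <- floor(src)
  W <- matrix(0, n_out, n_in)
  for (k in -1:2) {
    idx <- base + k
    w <- cubic_kernel(src - idx)
    idx_c <- pmin(pmax(idx, 0), n_in - 1)          # replicate borders
    W[cbind(seq_len(n_out), idx_c + 1)] <- W[cbind(seq_len(n_out), idx_c + 1)] + w
  }
  W
}

# Weight matrix for area-average downsampling: output pixel i averages the
# input interval [i * r, (i + 1) * r), r = n_in / n_out.
area_weights <- function(n_in, n_out) {
  r <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * r
    hi <- i * r
    j0 <- floor(lo); j1 <- min(ceiling(hi) - 1, n_in - 1)
    js <- j0:j1
    cover <- pmin(js + 1, hi) - pmax(js, lo)
    W[i, js + 1] <- cover / r
  }
  W
}

resample_matrix <- function(img, Wy, Wx) {
  Wy %*% img %*% t(Wx)
}

# Fast f x f block-mean decimation (trailing remainder rows/cols dropped).
block_average <- function(img, f) {
  f <- as.integer(f)
  h <- (nrow(img) %/% f) * f; w <- (ncol(img) %/% f) * f
  m <- img[seq_len(h), seq_len(w), drop = FALSE]
  m <- matrix(colMeans(matrix(m, f)), h %/% f, w)
  t(matrix(colMeans(matrix(t(m), f)), w %/% f, h %/% f))
}

#' Upscale an image crop by an integer factor
#'
#' The preprocessing stage applied to low-resolution grid crops before
#' keypoint extraction. Output size is exactly `factor` times the input size
#' per axis. The default method is deterministic bicubic resampling; `method`
#' also accepts any function `(image, factor) -> image` honoring the same
#' size contract, e.g. a learned super-resolution model.
#'
#' @param crop grayscale image matrix (rows = y).
#' @param factor integer upscale factor (>= 1).
#' @param method "bicubic" or a function `(image, factor)`.
#' @return upscaled image matrix of size `factor * dim(crop)`.
#' @export
upscale <- function(crop, factor = 4L, method = "bicubic") {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    stop("upscale: factor must be an integer >= 1", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (is.function(method)) {
    out <- method(crop, factor)
    if (!all(dim(out) == factor * dim(crop))) {
      stop("upscale: external upscaler violated the size contract", call. = FALSE)
    }
    return(out)
  }
  if (!identical(method, "bicubic")) {
    stop("upscale: unknown method", call. = FALSE)
  }
  if (factor == 1L) return(crop)
  Wy <- bicubic_weights(nrow(crop), nrow(crop) * factor)
  Wx <- bicubic_weights(ncol(crop), ncol(crop) * factor)
  out <- resample_matrix(crop, Wy, Wx)
  pmin(pmax(out, 0), 1)
}
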