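# Grid detection and cropping. The pipeline's detector slot is pluggable:
# an oracle detector (returns the ground-truth label box, optionally
# jittered), a classical contrast/connected-component detector, or any
# external callable with the same contract -- the stereo acceptance rule and
# crop bookkeeping are identical for all of them.

#' Detector configuration
#'
#' @param kind "oracle", "classical", or "external".
#' @param jitter_px oracle only: Gaussian sigma (px) applied to the truth box.
#' @param threshold classical only: intensity threshold; NULL = Otsu.
#' @param min_area classical only: minimum component area, px.
#' @param max_area classical only: maximum component area, px.
#' @param aspect_range classical only: accepted bbox aspect-ratio range.
#' @param nms apply non-maximum suppression across detections (off by default).
#' @param fn external only: function `(image) -> list of detections`.
#' @return a `detector_config` list.
#' @export
detector_config <- function(kind = c("classical", "oracle", "external"),
                            jitter_px = 0, threshold = NULL, min_area = 60,
                            max_area = 30000, aspect_range = c(0.4, 2.5),
                            nms = FALSE, fn = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, jitter_px = jitter_px, threshold = threshold,
                 min_area = min_area, max_area = max_area,
                 aspect_range = aspect_range, nms = nms, fn = fn),
            class = "detector_config")
}

make_detection <- function(bbox, score, width, height) {
  x0 <- max(bbox[1], 0); y0 <- max(bbox[2], 0)
  x1 <- min(bbox[1] + bbox[3], width - 1); y1 <- min(bbox[2] + bbox[4], height - 1)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  list(bbox = c(x_min = unname(x0), y_min = unname(y0),
                w = unname(x1 - x0), h = unname(y1 - y0)),
       score = min(max(score, 0), 1))
}

#' Detect the electrode grid in one grayscale frame
#'
#' Returns zero or more scored detections, sorted by decreasing score (ties
#' broken by decreasing area, then position, for determinism). The classical
#' detector thresholds the sheet-vs-background contrast (Otsu by default),
#' labels connected components, and keeps components passing area and
#' aspect-ratio filters; its score is the component's fill fraction.
#'
#' @param image grayscale matrix in [0, 1].
#' @param detector a [detector_config()].
#' @param truth_bbox ground-truth bbox (oracle detector only).
#' @param seed seed for the oracle jitter.
#' @return list of detections, each with `bbox` = (x_min, y_min, w, h) and
#'   `score` in [0, 1].
#' @export
detect_grid <- function(image, detector = detector_config(), truth_bbox = NULL,
                        seed = 1L) {
  h <- nrow(image); w <- ncol(image)
  dets <- list()
  if (detector$kind == "oracle") {
    if (is.null(truth_bbox)) stop("detect_grid: oracle detector needs truth_bbox",
                                  call. = FALSE)
    bb <- as.numeric(truth_bbox)
    if (detector$jitter_px > 0) {
      bb <- bb + with_seed(seed, rnorm(4, 0, detector$jitter_px))
    }
    d <- make_detection(bb, 1.0, w, h)
    if (!is.null(d)) dets <- list(d)
  } else if (detector$kind == "external") {
    dets <- detector$fn(image)
  } else {
    # threshold/label at half resolution on large frames; component geometry
    # is rescaled, which costs at most one pixel of bbox precision (the crop
    # margin absorbs it)
    f <- if (min(h, w) >= 256) 2L else 1L
    small <- if (f > 1L) block_average(image, f) else image
    sm <- as.matrix(EBImage::gblur(small, sigma = 1))
    th <- detector$threshold
    if (is.null(th)) th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
    mask <- sm > th
    lab <- EBImage::bwlabel(EBImage::Image(mask))
    lab <- as.matrix(EBImage::imageData(lab))
    nlab <- max(lab)
    if (nlab > 0) {
      for (k in seq_len(nlab)) {
        pix <- which(lab == k, arr.ind = TRUE)
        area <- nrow(pix) * f^2
        if (area < detector$min_area || area > detector$max_area) next
        y0 <- (min(pix[, 1]) - 1) * f; y1 <- (max(pix[, 1])) * f - 1
        x0 <- (min(pix[, 2]) - 1) * f; x1 <- (max(pix[, 2])) * f - 1
        bw <- x1 - x0 + 1; bh <- y1 - y0 + 1
        aspect <- bw / bh
        if (aspect < detector$aspect_range[1] || aspect > detector$aspect_range[2]) next
        d <- make_detection(c(x0, y0, bw, bh), area / (bw * bh), w, h)
        if (!is.null(d)) dets[[length(dets) + 1]] <- d
      }
    }
  }
  if (!length(dets)) return(list())
  sc <- vapply(dets, `[[`, 0, "score")
  ar <- vapply(dets, function(d) d$bbox[3] * d$bbox[4], 0)
  xm <- vapply(dets, function(d) d$bbox[1], 0)
  dets <- dets[order(-sc, -ar, xm)]
  if (isTRUE(detector$nms) && length(dets) > 1) {
    keep <- rep(TRUE, length(dets))
    for (i in seq_along(dets)) {
      if (!keep[i]) next
      for (j in seq_along(dets)) {
        if (j <= i || !keep[j]) next
        if (bbox_iou(dets[[i]]$bbox, dets[[j]]$bbox) > 0.5) keep[j] <- FALSE
      }
    }
    dets <- dets[keep]
  }
  dets
}

#' Intersection-over-union of two bounding boxes
#' @param a,b boxes as (x_min, y_min, w, h).
#' @return IoU in [0, 1].
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) 0 else unname(inter / union)
}

#' Stereo acceptance rule
#'
#' A stereo frame pair is accepted only when exactly one bounding box was
#' detected in each view; otherwise it is rejected with the first failing
#' side's reason.
#'
#' @param dets_left,dets_right detection lists from [detect_grid()].
#' @return list with `accepted` (logical), and either `left`/`right`
#'   (the single detections) or `reason` in none-left/none-right/
#'   multiple-left/multiple-right.
#' @export
accept_stereo <- function(dets_left, dets_right) {
  if (length(dets_left) == 0) return(list(accepted = FALSE, reason = "none-left"))
  if (length(dets_right) == 0) return(list(accepted = FALSE, reason = "none-right"))
  if (length(dets_left) > 1) return(list(accepted = FALSE, reason = "multiple-left"))
  if (length(dets_right) > 1) return(list(accepted = FALSE, reason = "multiple-right"))
  list(accepted = TRUE, left = dets_left[[1]], right = dets_right[[1]])
}

#' Crop a frame around a detection
#'
#' Expands the detection box by `margin` pixels (default 10% of the larger
#' box side, at least 2 px, so keypoints at the sheet edge survive cropping),
#' clamps to the image, and returns the crop plus the exact integer
#' bookkeeping mapping crop coordinates back to full-frame coordinates.
#'
#' @param image grayscale matrix.
#' @param det a detection from [detect_grid()].
#' @param margin margin in pixels; NULL = default rule.
#' @return a `crop_record`: `crop` (matrix), `offset` = (x, y) full-frame
#'   pixel of crop pixel (0, 0), `margin`.
#' @export
crop_frame <- function(image, det, margin = NULL) {
  h <- nrow(image); w <- ncol(image)
  bb <- det$bbox
  if (bb[1] > w - 1 || bb[2] > h - 1 || bb[1] + bb[3] < 0 || bb[2] + bb[4] < 0) {
    stop("crop_frame: bbox fully outside image", call. = FALSE)
  }
  if (is.null(margin)) margin <- max(2, ceiling(0.1 * max(bb[3], bb[4])))
  x0 <- max(0L, as.integer(floor(bb[1] - margin)))
  y0 <- max(0L, as.integer(floor(bb[2] - margin)))
  x1 <- min(w - 1L, as.integer(ceiling(bb[1] + bb[3] + margin)))
  y1 <- min(h - 1L, as.integer(ceiling(bb[2] + bb[4] + margin)))
  structure(list(crop = image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE],
                 offset = c(x = x0, y = y0), margin = margin),
            class = "crop_record")
}

#' Map crop-frame points to full-frame coordinates (and back)
#' @param rec a `crop_record`.
#' @param points Nx2 matrix of crop-frame pixel coordinates.
#' @param inverse map full-frame points into the crop frame instead.
#' @return Nx2 matrix.
#' @export
crop_to_full <- function(rec, points, inverse = FALSE) {
  points <- matrix(as.numeric(points), ncol = 2)
  s <- if (inverse) -1 else 1
  cbind(x = points[, 1] + s * rec$offset[1], y = points[, 2] + s * rec$offset[2])
}
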