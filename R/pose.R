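# Classical 2D pose path: Laplacian-of-Gaussian (difference-of-Gaussian)
# blob detection for the electrode disks, elongated-component detection for
# the cable tails, then assignment of detected centers to physical electrode
# indices by fitting a projective map of the canonical grid plane and using
# the tails to resolve the grid's 4-fold rotational ambiguity.

#' An ordered 68-keypoint set
#'
#' Ordering is fixed: electrodes 1..64 row-major, then tails 65..68. The
#' `frame` tag records which pixel frame the coordinates live in.
#'
#' @param points Nx2 matrix of subpixel coordinates.
#' @param visible logical vector.
#' @param frame one of "crop", "upscaled-crop", "full".
#' @return a `keypoint_set`.
#' @export
keypoint_set <- function(points, visible, frame = c("full", "crop", "upscaled-crop")) {
  frame <- match.arg(frame)
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) != length(visible)) {
    stop("keypoint_set: points and visibility length mismatch", call. = FALSE)
  }
  if (any(visible & !is.finite(points[, 1]))) {
    stop("keypoint_set: visible points must be finite", call. = FALSE)
  }
  structure(list(points = points, visible = as.logical(visible), frame = frame),
            class = "keypoint_set")
}

# ---- candidate detection ---------------------------------------------------

local_maxima <- function(resp, min_strength) {
  h <- nrow(resp); w <- ncol(resp)
  if (h < 3 || w < 3) return(NULL)
  ctr <- resp[2:(h - 1), 2:(w - 1)]
  ismax <- ctr >= resp[1:(h - 2), 2:(w - 1)] & ctr > resp[3:h, 2:(w - 1)] &
    ctr >= resp[2:(h - 1), 1:(w - 2)] & ctr > resp[2:(h - 1), 3:w] &
    ctr >= resp[1:(h - 2), 1:(w - 2)] & ctr > resp[3:h, 3:w] &
    ctr >= resp[1:(h - 2), 3:w] & ctr > resp[3:h, 1:(w - 2)] &
    ctr > min_strength
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
        strength = ctr[cbind(idx[, 1], idx[, 2])])
}

# Subpixel refinement: 2D quadratic fit of the response in the 3x3 patch
# around an integer peak.
refine_subpixel <- function(resp, row, col) {
  h <- nrow(resp); w <- ncol(resp)
  if (row < 2 || row > h - 1 || col < 2 || col > w - 1) return(c(col - 1, row - 1))
  p <- resp[(row - 1):(row + 1), (col - 1):(col + 1)]
  gx <- (p[2, 3] - p[2, 1]) / 2; gy <- (p[3, 2] - p[1, 2]) / 2
  hxx <- p[2, 3] - 2 * p[2, 2] + p[2, 1]
  hyy <- p[3, 2] - 2 * p[2, 2] + p[1, 2]
  hxy <- (p[3, 3] - p[3, 1] - p[1, 3] + p[1, 1]) / 4
  det_h <- hxx * hyy - hxy^2
  if (abs(det_h) < 1e-12) return(c(col - 1, row - 1))
  dx <- -(hyy * gx - hxy * gy) / det_h
  dy <- -(hxx * gy - hxy * gx) / det_h
  if (abs(dx) > 1 || abs(dy) > 1) { dx <- 0; dy <- 0 }
  c(col - 1 + dx, row - 1 + dy)
}

#' Detect disk and tail keypoint candidates in an upscaled crop
#'
#' Disk candidates are difference-of-Gaussian (approximate scale-normalized
#' Laplacian) extrema at the expected disk scale (derived from the crop size,
#' which bounds the grid), refined to subpixel by a quadratic fit of the
#' response peak, and restricted to the sheet support. Tail candidates are
#' centroids of the bright elongated components that a morphological opening
#' removes from the object mask (the cables). Deterministic.
#'
#' @param upscaled grayscale image matrix (the x4-upscaled crop).
#' @param spec a [grid_spec()] (sets the expected disk-to-grid size ratio).
#' @param n_max maximum number of disk candidates kept.
#' @return a `candidate_set`: `disks` (x, y, strength) and `tails`
#'   (x, y, strength) matrices, possibly empty.
#' @export
detect_keypoint_candidates <- function(upscaled, spec = grid_spec(), n_max = 90L) {
  h <- nrow(upscaled); w <- ncol(upscaled)
  extent <- spec$pitch * max(spec$rows - 1, spec$cols - 1) +
    2 * spec$sheet_margin + spec$disk_diameter
  r_est <- max(1.2, min(w, h) * (spec$disk_diameter / 2) / (extent * 1.12))
  empty <- structure(list(disks = matrix(0, 0, 3, dimnames = list(NULL, c("x", "y", "strength"))),
                          tails = matrix(0, 0, 3, dimnames = list(NULL, c("x", "y", "strength")))),
                     class = "candidate_set")
  if (h < 8 || w < 8 || diff(range(upscaled)) < 1e-6) return(empty)

  # object-support mask: the opening removes the thin cables, leaving the
  # sheet with its disks; disk blobs must lie inside it, cable candidates in
  # what the opening removed
  th <- EBImage::otsu(EBImage::Image(upscaled), range = c(0, 1))
  mask <- upscaled > th
  brush <- EBImage::makeBrush(2L * max(1L, round(0.75 * r_est)) + 1L, "disc")
  opened <- as.matrix(EBImage::imageData(EBImage::opening(EBImage::Image(mask), brush))) > 0

  # single-scale DoG at the size-derived disk radius (the crop bounds the
  # grid, so the radius estimate is tight)
  s1 <- r_est / sqrt(2)
  g1 <- as.matrix(EBImage::gblur(upscaled, sigma = s1))
  g2 <- as.matrix(EBImage::gblur(upscaled, sigma = 1.6 * s1))
  resp <- g1 - g2                          # bright blobs -> positive DoG
  cands <- NULL
  mx <- local_maxima(resp, min_strength = max(resp) * 0.08)
  if (!is.null(mx)) {
    on_sheet <- opened[cbind(mx[, "row"], mx[, "col"])]
    mx <- mx[on_sheet, , drop = FALSE]
    if (nrow(mx)) {
      pts <- t(apply(mx, 1, function(m) refine_subpixel(resp, m[1], m[2])))
      cands <- cbind(pts, mx[, 3])
    }
  }
  if (is.null(cands) || !nrow(cands)) return(empty)
  # deduplicate: keep the strongest within one estimated radius
  ord <- order(-cands[, 3])
  cands <- cands[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    if (!keep[i]) next
    d2 <- (cands[, 1] - cands[i, 1])^2 + (cands[, 2] - cands[i, 2])^2
    dup <- which(d2 < r_est^2)
    keep[dup[dup > i]] <- FALSE
  }
  disks <- cands[keep, , drop = FALSE][seq_len(min(sum(keep), n_max)), , drop = FALSE]
  colnames(disks) <- c("x", "y", "strength")

  # subpixel refinement by intensity centroid of disk-level pixels: the DoG
  # peak of a border disk is pulled outward by the sheet/background edge,
  # while the centroid of pixels above the sheet-vs-disk threshold is not
  # only worthwhile when the disk interior is resolved; below ~5 px radius
  # blur merges disks and sheet and the DoG peak is the better estimate
  obj <- upscaled[opened]
  if (length(obj) > 16 && r_est >= 5) {
    th2 <- EBImage::otsu(EBImage::Image(matrix(obj, ncol = 1)), range = c(0, 1))
    rad <- 1.4 * r_est
    for (i in seq_len(nrow(disks))) {
      x <- disks[i, 1]; y <- disks[i, 2]
      xs <- max(0, floor(x - rad)):min(w - 1, ceiling(x + rad))
      ys <- max(0, floor(y - rad)):min(h - 1, ceiling(y + rad))
      W <- pmax(upscaled[ys + 1, xs + 1, drop = FALSE] - th2, 0)
      X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      Y <- matrix(ys, length(ys), length(xs))
      W[(X - x)^2 + (Y - y)^2 > rad^2] <- 0
      sw <- sum(W)
      if (sw > 1e-9) {
        disks[i, 1] <- sum(W * X) / sw
        disks[i, 2] <- sum(W * Y) / sw
      }
    }
  }

  # tails: bright elongated components removed by the opening
  tails <- detect_tail_candidates(mask, opened, r_est)
  structure(list(disks = disks, tails = tails), class = "candidate_set")
}

# Tails are thin structures protruding from the sheet: a morphological
# opening sized just above the cable half-width removes them from the
# thresholded object mask, and the large elongated components of the
# residual are the cables. Their centroids are the tail candidates.
detect_tail_candidates <- function(mask, opened, r_est) {
  none <- matrix(0, 0, 3, dimnames = list(NULL, c("x", "y", "strength")))
  resid <- mask & !opened
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(resid))))
  nlab <- max(lab)
  if (nlab == 0) return(none)
  out <- NULL
  for (k in seq_len(nlab)) {
    pix <- which(lab == k, arr.ind = TRUE)
    if (nrow(pix) < 8 * r_est) next            # edge slivers are small
    xs <- pix[, 2] - 1; ys <- pix[, 1] - 1
    cv <- stats::cov(cbind(xs, ys))
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] <= 1e-9) ev[2] <- 1e-9
    elong <- ev[1] / ev[2]
    if (elong < 4) next
    out <- rbind(out, c(mean(xs), mean(ys), elong))
  }
  if (is.null(out)) return(none)
  colnames(out) <- c("x", "y", "strength")
  out
}

# ---- homography fitting ----------------------------------------------------

# Direct linear transform homography from >= 4 point pairs (rows of src/dst).
fit_homography <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  hvec <- svd(A, nu = 0, nv = 9)$v[, 9]
  matrix(hvec, 3, 3, byrow = TRUE)
}

apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

# Candidate corner quadrilaterals: the largest-area 4-subsets of the convex
# hull, each ordered with the same cycle orientation as the canonical corner
# cycle. The grid is always seen from the front, so through a y-down pixel
# frame the canonical cycle always traverses with negative signed area --
# orientation is a geometric constant, never a scored hypothesis (a
# reflected assignment would score identically on the symmetric lattice).
# Several quads are returned because a stray candidate on the hull can
# displace a true corner; the caller scores them by lattice inlier count.
find_corners <- function(pts, n_quads = 5L) {
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[hull, , drop = FALSE]
  if (nrow(hp) > 14) {
    # keep the hull points farthest from the centroid (corners are extremes),
    # preserving the cyclic hull order
    ctr <- colMeans(pts)
    d2 <- (hp[, 1] - ctr[1])^2 + (hp[, 2] - ctr[2])^2
    hp <- hp[sort(order(-d2)[1:14]), , drop = FALSE]
  }
  nh <- nrow(hp)
  if (nh < 4) return(NULL)
  combs <- utils::combn(nh, 4)
  areas <- vapply(seq_len(ncol(combs)), function(j) {
    q <- hp[combs[, j], , drop = FALSE]            # hull order preserved
    abs(sum(q[, 1] * q[c(2:4, 1), 2] - q[c(2:4, 1), 1] * q[, 2])) / 2
  }, 0)
  top <- order(-areas)[seq_len(min(n_quads, length(areas)))]
  lapply(top, function(j) {
    q <- hp[combs[, j], , drop = FALSE]
    signed <- sum(q[, 1] * q[c(2:4, 1), 2] - q[c(2:4, 1), 1] * q[, 2]) / 2
    if (signed > 0) q <- q[4:1, , drop = FALSE]
    q
  })
}

canonical_corners <- function(spec) {
  p <- spec$pitch
  rbind(c(0, 0), c((spec$cols - 1) * p, 0),
        c((spec$cols - 1) * p, (spec$rows - 1) * p), c(0, (spec$rows - 1) * p))
}

#' Solve a one-to-one minimum-cost assignment
#'
#' Thin wrapper over the Hungarian solver used to match predicted electrode
#' positions to detected candidates. Rows may outnumber columns; unassignable
#' rows get NA. Ties are broken deterministically by the solver's fixed
#' pivoting plus a lexicographic cost perturbation smaller than any real
#' cost difference.
#'
#' @param cost numeric cost matrix (rows = electrodes, cols = candidates).
#' @return integer vector: for each row, the assigned column (or NA).
#' @export
match_one_to_one <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nc == 0) return(rep(NA_integer_, nr))
  if (nr > nc) {
    pad <- matrix(max(cost) + 1, nr, nr - nc)
    sol <- clue::solve_LSAP(cbind(cost, pad))
    out <- as.integer(sol)
    out[out > nc] <- NA_integer_
    out
  } else {
    as.integer(clue::solve_LSAP(cost))
  }
}

#' Assign detected candidates to physical electrode indices
#'
#' Fits a projective mapping from the canonical grid plane to the image from
#' robustly chosen corner correspondences, scores the four rotational
#' hypotheses (0/90/180/270 degrees) by inlier count, resolves the remaining
#' rotational ambiguity with the tail candidates (the square electrode
#' pattern alone cannot distinguish 90-degree rotations), refines the fit by
#' least squares over inliers, and finally assigns candidates to electrodes
#' by one-to-one minimum-cost matching. Unmatched electrodes are marked
#' invisible. Tail keypoints are placed at their refined projective
#' predictions, visible when a tail candidate supports them.
#'
#' @param cands a `candidate_set` from [detect_keypoint_candidates()].
#' @param spec a [grid_spec()].
#' @param frame frame tag for the returned keypoints.
#' @param gate matching gate as a fraction of the projected pitch.
#' @return a [keypoint_set()] in the candidates' pixel frame.
#' @export
assign_indices <- function(cands, spec = grid_spec(),
                           frame = "upscaled-crop", gate = 0.45) {
  disks <- cands$disks
  if (nrow(disks) < 4) {
    stop("assign_indices: need at least 4 disk candidates", call. = FALSE)
  }
  quads <- find_corners(disks[, 1:2, drop = FALSE])
  if (is.null(quads)) stop("assign_indices: degenerate candidate geometry",
                           call. = FALSE)
  can <- canonical_corners(spec)
  el_can <- grid_plane_points(spec)[seq_len(spec$rows * spec$cols), , drop = FALSE]
  tail_can <- spec$tail_offsets

  count_inliers <- function(pred, tol) {
    nn <- vapply(seq_len(nrow(pred)), function(i) {
      min((disks[, 1] - pred[i, 1])^2 + (disks[, 2] - pred[i, 2])^2)
    }, 0)
    sum(nn < tol^2)
  }
  refine_H <- function(H, passes = 1L) {
    pred <- apply_homography(H, el_can)
    spacing <- sqrt(sum((pred[2, ] - pred[1, ])^2))
    tol <- max(2, 0.3 * spacing)
    for (pass in seq_len(passes)) {
      nn_idx <- vapply(seq_len(nrow(pred)), function(i) {
        which.min((disks[, 1] - pred[i, 1])^2 + (disks[, 2] - pred[i, 2])^2)
      }, 0L)
      d <- sqrt((disks[nn_idx, 1] - pred[, 1])^2 + (disks[nn_idx, 2] - pred[, 2])^2)
      ok <- d < tol & !duplicated(nn_idx)
      if (sum(ok) < 6) break
      H <- fit_homography(el_can[ok, , drop = FALSE],
                          disks[nn_idx[ok], 1:2, drop = FALSE])
      pred <- apply_homography(H, el_can)
    }
    list(H = H, pred = pred, tol = tol, inliers = count_inliers(pred, tol))
  }
  score_rot <- function(corners, rot) {
    # cyclic shift: canonical corner k maps to observed corner k+rot; one
    # least-squares refinement pass before scoring, so a noisy corner point
    # cannot sink the correct hypothesis
    H <- fit_homography(can, corners[((seq_len(4) - 1 + rot) %% 4) + 1, , drop = FALSE])
    refine_H(H, passes = 1L)
  }
  # pick the corner quad whose best rotation explains the most candidates
  quad_hyps <- lapply(quads, function(q) lapply(0:3, function(r) score_rot(q, r)))
  quad_best <- vapply(quad_hyps, function(hs) max(vapply(hs, `[[`, 0, "inliers")), 0)
  hyp <- quad_hyps[[which.max(quad_best)]]
  inl <- vapply(hyp, `[[`, 0, "inliers")
  top <- max(inl)
  tied <- which(inl >= top - max(1, 0.05 * top))
  if (length(tied) > 1) {
    if (nrow(cands$tails) == 0) {
      stop("assign_indices: rotation ambiguous and no tail candidates (the grid's 4-fold symmetry cannot be resolved)",
           call. = FALSE)
    }
    tail_score <- vapply(tied, function(k) {
      predt <- apply_homography(hyp[[k]]$H, tail_can)
      mean(vapply(seq_len(nrow(predt)), function(i) {
        sqrt(min((cands$tails[, 1] - predt[i, 1])^2 +
                   (cands$tails[, 2] - predt[i, 2])^2))
      }, 0))
    }, 0)
    best <- tied[which.min(tail_score)]
  } else {
    best <- tied[1]
  }
  fin <- refine_H(hyp[[best]]$H, passes = 2L)
  H <- fin$H
  pred <- fin$pred
  # quality gate: a fit that cannot explain most of the lattice would emit
  # silently misindexed electrodes; reject the frame instead
  if (fin$inliers < max(6, round(0.6 * nrow(el_can)))) {
    stop("assign_indices: lattice fit unreliable (too few inlier candidates)",
         call. = FALSE)
  }

  spacing <- sqrt(sum((pred[2, ] - pred[1, ])^2))
  gate_px <- max(2, gate * spacing)
  cost <- outer(seq_len(nrow(pred)), seq_len(nrow(disks)),
                function(i, j) sqrt((pred[i, 1] - disks[j, 1])^2 +
                                      (pred[i, 2] - disks[j, 2])^2))
  # dummy columns at the gate cost: electrodes preferring a dummy are unmatched
  aug <- cbind(cost, matrix(gate_px, nrow(pred), nrow(pred)))
  sol <- match_one_to_one(aug)
  ne <- spec$rows * spec$cols
  pts <- matrix(NA_real_, n_keypoints(spec), 2)
  vis <- rep(FALSE, n_keypoints(spec))
  for (i in seq_len(ne)) {
    j <- sol[i]
    if (!is.na(j) && j <= nrow(disks) && cost[i, j] < gate_px) {
      pts[i, ] <- disks[j, 1:2]
      vis[i] <- TRUE
    }
  }
  if (spec$n_tails > 0) {
    predt <- apply_homography(H, tail_can)
    for (k in seq_len(spec$n_tails)) {
      i <- ne + k
      pts[i, ] <- predt[k, ]
      if (nrow(cands$tails) > 0) {
        dmin <- sqrt(min((cands$tails[, 1] - predt[k, 1])^2 +
                           (cands$tails[, 2] - predt[k, 2])^2))
        vis[i] <- dmin < 1.5 * spacing
      }
    }
  }
  keypoint_set(pts, vis, frame)
}

#' Map keypoints from the upscaled crop back to the full frame
#'
#' Inverse of the crop + upscale bookkeeping: `x_full = x_up / factor +
#' offset_x`. Invisible points stay invisible and untransformed.
#'
#' @param kps a `keypoint_set` with frame "upscaled-crop".
#' @param rec the `crop_record` the crop came from.
#' @param factor the upscale factor used.
#' @return a `keypoint_set` with frame "full".
#' @export
to_full_frame <- function(kps, rec, factor) {
  if (kps$frame != "upscaled-crop") {
    stop("to_full_frame: keypoints must be in the upscaled-crop frame", call. = FALSE)
  }
  pts <- kps$points
  sel <- kps$visible
  pts[sel, 1] <- pts[sel, 1] / factor + rec$offset[1]
  pts[sel, 2] <- pts[sel, 2] / factor + rec$offset[2]
  keypoint_set(pts, kps$visible, "full")
}

#' Run the classical 2D pose path on one view
#'
#' detect -> crop -> upscale -> candidates -> index assignment -> full-frame
#' coordinates. An oracle pose plugin (`kind = "oracle"`) instead returns the
#' ground-truth projections, for isolating downstream stages.
#'
#' @param image grayscale frame.
#' @param det a single detection (from the acceptance rule).
#' @param spec a [grid_spec()].
#' @param factor upscale factor (default 4).
#' @param upscaler "bicubic" or a function, see [upscale()].
#' @param pose_kind "classical" or "oracle".
#' @param truth optional `labeled_frame` (oracle pose or diagnostics).
#' @return a `keypoint_set` in full-frame coordinates.
#' @export
estimate_pose_2d <- function(image, det, spec = grid_spec(), factor = 4L,
                             upscaler = "bicubic",
                             pose_kind = c("classical", "oracle"), truth = NULL) {
  pose_kind <- match.arg(pose_kind)
  if (pose_kind == "oracle") {
    if (is.null(truth)) stop("estimate_pose_2d: oracle pose needs truth", call. = FALSE)
    return(keypoint_set(truth$keypoints, truth$visible, "full"))
  }
  rec <- crop_frame(image, det)
  up <- upscale(rec$crop, factor, method = upscaler)
  cands <- detect_keypoint_candidates(up, spec)
  kps <- assign_indices(cands, spec)
  to_full_frame(kps, rec, factor)
}
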