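#' @importFrom stats rnorm runif median sd quantile
#' @importFrom utils write.csv read.csv head tail
NULL

# ---- rigid poses -----------------------------------------------------------

#' Rigid pose (rotation + translation)
#'
#' A rigid transform mapping points from a source frame into a target frame:
#' `x_target = R x_source + t`. Rotations must be proper orthonormal matrices.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation numeric length-3 translation in meters.
#' @return An object of class `rigid_pose` with elements `R` and `t`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    stop("rigid_pose: non-finite rotation or translation", call. = FALSE)
  }
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3) {
    stop("rigid_pose: rotation must be 3x3 and translation length 3", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rigid_pose: rotation is not orthonormal (tol 1e-9)", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rigid_pose: rotation must have determinant +1", call. = FALSE)
  }
  structure(list(R = rotation, t = translation), class = "rigid_pose")
}

#' Rotation matrix about a coordinate axis
#' @param axis one of "x", "y", "z".
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Apply a rigid pose to points
#' @param pose a [rigid_pose()].
#' @param points numeric Nx3 matrix (or length-3 vector) of points.
#' @return Nx3 matrix of transformed points (or length-3 vector for one point).
#' @export
pose_apply <- function(pose, points) {
  one <- is.null(dim(points))
  pts <- if (one) matrix(points, 1, 3) else as.matrix(points)
  out <- pts %*% t(pose$R)
  out <- sweep(out, 2, pose$t, "+")
  if (one) drop(out) else out
}

#' Invert a rigid pose
#' @param pose a [rigid_pose()].
#' @return the inverse `rigid_pose`.
#' @export
pose_inverse <- function(pose) {
  rigid_pose(t(pose$R), -drop(t(pose$R) %*% pose$t))
}

#' Compose two rigid poses
#'
#' Returns the pose equivalent to applying `b` first, then `a`.
#' @param a,b [rigid_pose()] objects.
#' @return composed `rigid_pose`.
#' @export
pose_compose <- function(a, b) {
  rigid_pose(a$R %*% b$R, drop(a$R %*% b$t) + a$t)
}

# ---- intrinsics and distortion --------------------------------------------

#' Pinhole camera intrinsics
#'
#' Pixel convention throughout the package: 0-based coordinates with (0, 0)
#' at the center of the top-left pixel, +x right, +y down.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels (inside the sensor).
#' @param width,height sensor size in pixels.
#' @return object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width = 640L, height = 480L) {
  vals <- c(fx, fy, cx, cy, width, height)
  if (!all(is.finite(vals))) stop("camera_intrinsics: non-finite field", call. = FALSE)
  if (fx <= 0 || fy <= 0) stop("camera_intrinsics: focal lengths must be > 0", call. = FALSE)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height) {
    stop("camera_intrinsics: principal point outside sensor", call. = FALSE)
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' Lens distortion coefficients
#'
#' Radial (k1, k2, k3) + tangential (p1, p2) model applied in normalized
#' image coordinates. All zero means an ideal pinhole.
#'
#' @param k1,k2,k3 radial terms (dimensionless).
#' @param p1,p2 tangential terms (dimensionless).
#' @return object of class `distortion_coeffs`.
#' @export
distortion_coeffs <- function(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  vals <- c(k1, k2, k3, p1, p2)
  if (!all(is.finite(vals))) stop("distortion_coeffs: non-finite coefficient", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2),
            class = "distortion_coeffs")
}

is_zero_distortion <- function(dist) {
  all(abs(c(dist$k1, dist$k2, dist$k3, dist$p1, dist$p2)) == 0)
}

# Forward distortion in normalized coordinates (vectorized).
distort_normalized <- function(dist, xn, yn) {
  r2 <- xn^2 + yn^2
  radial <- 1 + dist$k1 * r2 + dist$k2 * r2^2 + dist$k3 * r2^3
  xd <- xn * radial + 2 * dist$p1 * xn * yn + dist$p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + dist$p1 * (r2 + 2 * yn^2) + 2 * dist$p2 * xn * yn
  cbind(xd, yd)
}

# Inverse distortion by fixed-point iteration (20 iterations or 1e-10).
undistort_normalized <- function(dist, xd, yd) {
  xn <- xd; yn <- yd
  for (i in seq_len(20L)) {
    r2 <- xn^2 + yn^2
    radial <- 1 + dist$k1 * r2 + dist$k2 * r2^2 + dist$k3 * r2^3
    dx <- 2 * dist$p1 * xn * yn + dist$p2 * (r2 + 2 * xn^2)
    dy <- dist$p1 * (r2 + 2 * yn^2) + 2 * dist$p2 * xn * yn
    xn_new <- (xd - dx) / radial
    yn_new <- (yd - dy) / radial
    delta <- max(abs(xn_new - xn), abs(yn_new - yn))
    xn <- xn_new; yn <- yn_new
    if (delta < 1e-10) break
  }
  cbind(xn, yn)
}

# ---- projection ------------------------------------------------------------

#' Project world points into a camera
#'
#' Points are expressed in world coordinates; `cam_pose` is the pose of the
#' camera in the world (so a world point `X` maps to camera coordinates
#' `R^T (X - t)`). Returns distorted pixel coordinates in the 0-based image
#' frame plus a visibility flag: visible iff the point is in front of the
#' camera (z > 0) and its pixel falls inside the sensor.
#'
#' @param intr [camera_intrinsics()].
#' @param dist [distortion_coeffs()].
#' @param cam_pose [rigid_pose()] of the camera in the world frame.
#' @param points Nx3 matrix (or length-3 vector) of world points, meters.
#' @return list with `pixels` (Nx2), `visible` (logical N), `depth` (N).
#' @export
project <- function(intr, dist, cam_pose, points) {
  one <- is.null(dim(points))
  pts <- if (one) matrix(points, 1, 3) else as.matrix(points)
  if (!all(is.finite(pts))) stop("project: non-finite input point", call. = FALSE)
  pc <- pose_apply(pose_inverse(cam_pose), pts)
  z <- pc[, 3]
  front <- z > 0
  xn <- ifelse(front, pc[, 1] / z, NA_real_)
  yn <- ifelse(front, pc[, 2] / z, NA_real_)
  d <- distort_normalized(dist, xn, yn)
  px <- intr$fx * d[, 1] + intr$cx
  py <- intr$fy * d[, 2] + intr$cy
  inb <- front & px >= -0.5 & px <= intr$width - 0.5 &
    py >= -0.5 & py <= intr$height - 0.5
  inb[is.na(inb)] <- FALSE
  out <- list(pixels = cbind(x = px, y = py), visible = inb, depth = z)
  out
}

# ---- stereo rig ------------------------------------------------------------

#' Calibrated stereo rig
#'
#' @param left,right [camera_intrinsics()] for the two views.
#' @param dist_left,dist_right [distortion_coeffs()].
#' @param right_in_left [rigid_pose()] mapping right-camera coordinates into
#'   the left-camera frame; its translation is the baseline vector (meters).
#' @return object of class `stereo_rig`.
#' @export
stereo_rig <- function(left, right, dist_left = distortion_coeffs(),
                       dist_right = distortion_coeffs(),
                       right_in_left = rigid_pose(diag(3), c(0.098, 0, 0))) {
  b <- sqrt(sum(right_in_left$t^2))
  if (b <= 0) stop("stereo_rig: baseline length must be > 0", call. = FALSE)
  structure(list(left = left, right = right,
                 dist_left = dist_left, dist_right = dist_right,
                 right_in_left = right_in_left, rectified = FALSE),
            class = "stereo_rig")
}

#' Default virtual stereo rig
#'
#' A 640x480 fronto-parallel grayscale stereo pair with a 98 mm baseline and
#' 450 px focal length (roughly 71 degrees horizontal field of view): at the
#' closest working distance (40 cm) the electrode grid with its tails just
#' fits inside both views across a 32 cm wide working area, and grid crops
#' span roughly 22-60 px over 90-40 cm.
#'
#' @param fx focal length in pixels (applied to both axes and both views).
#' @param baseline stereo baseline in meters.
#' @param width,height sensor size in pixels.
#' @param dist_left,dist_right optional [distortion_coeffs()].
#' @return a `stereo_rig`.
#' @export
default_rig <- function(fx = 450, baseline = 0.098, width = 640L, height = 480L,
                        dist_left = distortion_coeffs(),
                        dist_right = distortion_coeffs()) {
  intr <- camera_intrinsics(fx, fx, (width - 1) / 2, (height - 1) / 2, width, height)
  rig <- stereo_rig(intr, intr, dist_left, dist_right,
                    rigid_pose(diag(3), c(baseline, 0, 0)))
  rig
}

baseline_length <- function(rig) sqrt(sum(rig$right_in_left$t^2))

#' Camera poses of a rig in the world frame
#'
#' The package's world frame is the left camera frame (right-handed,
#' +z forward), so the left camera pose is the identity.
#' @param rig a `stereo_rig`.
#' @return list with `left` and `right` [rigid_pose()]s.
#' @export
rig_camera_poses <- function(rig) {
  list(left = rigid_pose(), right = rig$right_in_left)
}

# ---- rectification ---------------------------------------------------------

#' Compute the rectifying transform of a stereo rig
#'
#' Builds per-view rectifying rotations (new x-axis along the baseline, in
#' the style of Fusiello's algorithm) and shared rectified intrinsics: both
#' rectified views get identical fx, fy, cx, cy and zero distortion, so
#' epipolar lines are horizontal and triangulation reduces to a disparity.
#'
#' @param rig a `stereo_rig`.
#' @return a rectified `stereo_rig` with extra fields `R_rect_left`,
#'   `R_rect_right` (rotations from the original camera frames into the
#'   rectified frames) and `source` (the original rig).
#' @export
rectify_rig <- function(rig) {
  t_rl <- rig$right_in_left$t
  b <- sqrt(sum(t_rl^2))
  e1 <- t_rl / b
  e2 <- c(-e1[2], e1[1], 0)
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-12) {  # baseline along z: pick y axis
    e2 <- c(0, 1, 0)
  } else {
    e2 <- e2 / n2
  }
  # ensure right-handed with z roughly forward
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  if (e3[3] < 0) { e2 <- -e2; e3 <- -e3 }
  R_rect <- rbind(e1, e2, e3)            # left-cam coords -> rectified coords
  rownames(R_rect) <- NULL
  R_rect_right <- R_rect %*% rig$right_in_left$R
  f <- mean(c(rig$left$fx, rig$left$fy, rig$right$fx, rig$right$fy))
  cx <- mean(c(rig$left$cx, rig$right$cx))
  cy <- mean(c(rig$left$cy, rig$right$cy))
  w <- max(rig$left$width, rig$right$width)
  h <- max(rig$left$height, rig$right$height)
  intr <- camera_intrinsics(f, f, cx, cy, w, h)
  out <- stereo_rig(intr, intr, distortion_coeffs(), distortion_coeffs(),
                    rigid_pose(diag(3), c(b, 0, 0)))
  out$rectified <- TRUE
  out$R_rect_left <- R_rect
  out$R_rect_right <- R_rect_right
  out$source <- rig
  out
}

#' Map image points from an original view into the rectified frame
#'
#' @param rect a rectified rig from [rectify_rig()].
#' @param pixels Nx2 pixel coordinates in the original (distorted) view.
#' @param side "left" or "right".
#' @return Nx2 rectified pixel coordinates.
#' @export
rectify_points <- function(rect, pixels, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(isTRUE(rect$rectified))
  src <- rect$source
  intr <- if (side == "left") src$left else src$right
  dist <- if (side == "left") src$dist_left else src$dist_right
  Rr <- if (side == "left") rect$R_rect_left else rect$R_rect_right
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  nd <- undistort_normalized(dist,
                             (pixels[, 1] - intr$cx) / intr$fx,
                             (pixels[, 2] - intr$cy) / intr$fy)
  rays <- cbind(nd[, 1], nd[, 2], 1) %*% t(Rr)
  cbind(x = rect$left$fx * rays[, 1] / rays[, 3] + rect$left$cx,
        y = rect$left$fy * rays[, 2] / rays[, 3] + rect$left$cy)
}

# Inverse of rectify_points: rectified pixel -> original distorted pixel.
unrectify_points <- function(rect, pixels, side = c("left", "right")) {
  side <- match.arg(side)
  src <- rect$source
  intr <- if (side == "left") src$left else src$right
  dist <- if (side == "left") src$dist_left else src$dist_right
  Rr <- if (side == "left") rect$R_rect_left else rect$R_rect_right
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  xn <- (pixels[, 1] - rect$left$cx) / rect$left$fx
  yn <- (pixels[, 2] - rect$left$cy) / rect$left$fy
  rays <- cbind(xn, yn, 1) %*% Rr       # = t(Rr^T) applied to rows
  xs <- rays[, 1] / rays[, 3]
  ys <- rays[, 2] / rays[, 3]
  d <- distort_normalized(dist, xs, ys)
  cbind(x = intr$fx * d[, 1] + intr$cx, y = intr$fy * d[, 2] + intr$cy)
}

# Bilinear sampling of image `img` (matrix rows=y) at 0-based (x, y);
# outside samples return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 0 & x0 <= w - 2 & y0 >= 0 & y0 <= h - 2
  # clamp indices for safe lookup, then mask
  xc <- pmin(pmax(x0, 0), w - 2); yc <- pmin(pmax(y0, 0), h - 2)
  i00 <- (xc) * h + yc + 1          # column-major index of (row yc+1, col xc+1)
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[i00 + h] +
    (1 - fx) * fy * img[i00 + 1] +
    fx * fy * img[i00 + h + 1]
  v[!inside] <- fill
  v
}

#' Undistort and rectify a stereo frame pair
#'
#' Remaps both images into the rectified model of [rectify_rig()] so that
#' corresponding scene points share a row coordinate, and returns the pixel
#' remapping record so ground-truth labels can be mapped identically (with
#' [rectify_points()]).
#'
#' @param rig a `stereo_rig` (unrectified).
#' @param frame_left,frame_right grayscale image matrices (rows = y) whose
#'   sizes match the rig's declared sensor sizes.
#' @return list with `left`, `right` (rectified images), `rig` (rectified
#'   rig), and `maps` (per-view source-coordinate lookup matrices `x`, `y`).
#' @export
undistort_rectify <- function(rig, frame_left, frame_right) {
  if (nrow(frame_left) != rig$left$height || ncol(frame_left) != rig$left$width ||
      nrow(frame_right) != rig$right$height || ncol(frame_right) != rig$right$width) {
    stop("undistort_rectify: image size does not match rig sensor size", call. = FALSE)
  }
  rect <- rectify_rig(rig)
  h <- rect$left$height; w <- rect$left$width
  grid_x <- matrix(rep(0:(w - 1), each = h), h, w)
  grid_y <- matrix(rep(0:(h - 1), times = w), h, w)
  out <- list()
  maps <- list()
  for (side in c("left", "right")) {
    src_xy <- unrectify_points(rect, cbind(as.vector(grid_x), as.vector(grid_y)), side)
    mx <- matrix(src_xy[, 1], h, w); my <- matrix(src_xy[, 2], h, w)
    img <- if (side == "left") frame_left else frame_right
    out[[side]] <- matrix(bilinear_sample(img, as.vector(mx), as.vector(my)), h, w)
    maps[[side]] <- list(x = mx, y = my)
  }
  list(left = out$left, right = out$right, rig = rect, maps = maps)
}

# ---- triangulation ---------------------------------------------------------

#' Triangulate a rectified stereo correspondence
#'
#' Closed-form disparity triangulation for a rectified rig: depth
#' `z = f * b / (x_left - x_right)`. The returned point is expressed in the
#' left rectified camera frame (the package world frame).
#'
#' @param rect_rig a rectified `stereo_rig`.
#' @param pix_left,pix_right length-2 pixel coordinates (or Nx2 matrices).
#' @return length-3 point in meters (or Nx3 matrix).
#' @export
triangulate <- function(rect_rig, pix_left, pix_right) {
  if (!isTRUE(rect_rig$rectified) && !is_zero_distortion(rect_rig$dist_left)) {
    stop("triangulate: rig must be rectified", call. = FALSE)
  }
  one <- is.null(dim(pix_left))
  pl <- matrix(as.numeric(pix_left), ncol = 2)
  pr <- matrix(as.numeric(pix_right), ncol = 2)
  d <- pl[, 1] - pr[, 1]
  if (any(d <= 0)) {
    stop("triangulate: disparity <= 0 (point at or behind infinity)", call. = FALSE)
  }
  intr <- rect_rig$left
  b <- baseline_length(rect_rig)
  z <- intr$fx * b / d
  x <- (pl[, 1] - intr$cx) * z / intr$fx
  y <- ((pl[, 2] + pr[, 2]) / 2 - intr$cy) * z / intr$fy
  out <- cbind(x = x, y = y, z = z)
  if (one) drop(out) else out
}
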