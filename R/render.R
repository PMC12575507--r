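# Programmatic stereo renderer for the electrode grid: rasterizes the
# projected silicone sheet, per-electrode disks and cable tails with
# supersampled anti-aliasing and Lambertian-style shading, then applies
# Gaussian blur and additive sensor noise. Ground-truth labels are the exact
# projections, never read back from pixels.

derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 2147480000) * 7919 + k * 104729) %% 2147483629 + 1
}

#' Rendering settings for synthetic scenes
#'
#' Appearance randomization ranges emulate what varies between recordings:
#' background, lighting direction, material intensities, optical blur and
#' sensor noise. All intensities are on the [0, 1] grayscale scale.
#'
#' @param background list with `mode` in flat/gradient/textured-noise and an
#'   intensity range `min`, `max`.
#' @param lighting list with `azimuth` and `elevation` ranges (radians) for
#'   the directional light and an `ambient` level in [0, 1].
#' @param disk_intensity,sheet_intensity lists with `mean` and `sd`.
#' @param cable_intensity scalar intensity of the tail cables.
#' @param blur_sigma optical Gaussian blur, pixels.
#' @param noise_sigma additive sensor noise standard deviation, intensity units.
#' @param seed integer master seed; rendering is deterministic given it.
#' @param supersample anti-aliasing supersampling factor per axis.
#' @return object of class `render_settings`.
#' @export
render_settings <- function(background = list(mode = "flat", min = 0.10, max = 0.30),
                            lighting = list(azimuth = c(0, 2 * pi),
                                            elevation = c(0.7, 1.3),
                                            ambient = 0.75),
                            disk_intensity = list(mean = 0.85, sd = 0.02),
                            sheet_intensity = list(mean = 0.45, sd = 0.02),
                            cable_intensity = 0.75,
                            blur_sigma = 0.7, noise_sigma = 0.02,
                            seed = 1L, supersample = 4L) {
  vals <- c(background$min, background$max, disk_intensity$mean,
            sheet_intensity$mean, cable_intensity, lighting$ambient)
  if (any(vals < 0 | vals > 1)) {
    stop("render_settings: intensities must lie in [0, 1]", call. = FALSE)
  }
  if (blur_sigma < 0 || noise_sigma < 0) {
    stop("render_settings: blur_sigma and noise_sigma must be >= 0", call. = FALSE)
  }
  if (!background$mode %in% c("flat", "gradient", "textured-noise")) {
    stop("render_settings: unknown background mode", call. = FALSE)
  }
  structure(list(background = background, lighting = lighting,
                 disk_intensity = disk_intensity, sheet_intensity = sheet_intensity,
                 cable_intensity = cable_intensity, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 supersample = as.integer(supersample)),
            class = "render_settings")
}

runif1 <- function(range) if (length(range) == 1) range else runif(1, range[1], range[2])

# Draw one appearance (shared by both stereo views) from the settings.
sample_appearance <- function(settings) {
  with_seed(derive_seed(settings$seed, 1L), {
    az <- runif1(settings$lighting$azimuth)
    el <- runif1(settings$lighting$elevation)
    light <- c(cos(el) * cos(az), cos(el) * sin(az), -sin(el))
    light <- light / sqrt(sum(light^2))
    list(
      bg_level = runif1(c(settings$background$min, settings$background$max)),
      bg_angle = runif(1, 0, 2 * pi),
      bg_seed = derive_seed(settings$seed, 2L),
      light = light,   # direction the light travels (world frame, +z forward)
      ambient = settings$lighting$ambient,
      disk_level = min(max(rnorm(1, settings$disk_intensity$mean,
                                 settings$disk_intensity$sd), 0), 1),
      sheet_level = min(max(rnorm(1, settings$sheet_intensity$mean,
                                  settings$sheet_intensity$sd), 0), 1),
      cable_level = settings$cable_intensity)
  })
}

# Local tangent frame and outward normal at every electrode of a grid state.
surface_frames <- function(state) {
  spec <- state$spec
  r <- spec$rows; cc <- spec$cols
  pts <- state$points3d
  idx <- function(rr, c2) (rr - 1) * cc + c2
  e1 <- matrix(0, r * cc, 3); e2 <- matrix(0, r * cc, 3); nrm <- matrix(0, r * cc, 3)
  for (rr in seq_len(r)) for (c2 in seq_len(cc)) {
    i <- idx(rr, c2)
    cx1 <- pts[idx(rr, min(c2 + 1, cc)), ] - pts[idx(rr, max(c2 - 1, 1)), ]
    cy1 <- pts[idx(min(rr + 1, r), c2), ] - pts[idx(max(rr - 1, 1), c2), ]
    u <- cx1 / sqrt(sum(cx1^2))
    v0 <- cy1 - sum(cy1 * u) * u
    v <- v0 / sqrt(sum(v0^2))
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    e1[i, ] <- u; e2[i, ] <- v; nrm[i, ] <- n
  }
  list(e1 = e1, e2 = e2, normal = nrm)
}

# Sheet boundary polygon (3D): outer electrode ring offset outward by the
# sheet margin within the local tangent plane.
sheet_boundary_3d <- function(state, frames = surface_frames(state)) {
  spec <- state$spec
  r <- spec$rows; cc <- spec$cols
  idx <- function(rr, c2) (rr - 1) * cc + c2
  ring <- c(idx(1, seq_len(cc)),
            if (r >= 2) idx(seq(2, r), cc),
            if (r >= 2) idx(r, rev(seq_len(cc - 1))),
            if (r >= 3) idx(rev(seq(2, r - 1)), 1))
  pts <- state$points3d[ring, , drop = FALSE]
  n <- nrow(pts)
  ctr <- colMeans(state$points3d[seq_len(r * cc), , drop = FALSE])
  out <- pts
  for (k in seq_len(n)) {
    tangent <- pts[(k %% n) + 1, ] - pts[((k - 2) %% n) + 1, ]
    nv <- frames$normal[ring[k], ]
    o <- c(tangent[2] * nv[3] - tangent[3] * nv[2],
           tangent[3] * nv[1] - tangent[1] * nv[3],
           tangent[1] * nv[2] - tangent[2] * nv[1])
    o <- o / sqrt(sum(o^2))
    if (sum(o * (pts[k, ] - ctr)) < 0) o <- -o
    out[k, ] <- pts[k, ] + o * spec$sheet_margin
  }
  out
}

# Cable segments (3D): one straight cable per tail keypoint, centered so it
# starts at the sheet edge and runs outward.
cable_segments_3d <- function(state, cable_length = 0.012, cable_radius = 1.0e-3) {
  spec <- state$spec
  if (spec$n_tails == 0) return(list())
  ne <- spec$rows * spec$cols
  segs <- vector("list", spec$n_tails)
  for (k in seq_len(spec$n_tails)) {
    tp <- state$points3d[ne + k, ]
    d2 <- rowSums(sweep(state$points3d[seq_len(ne), , drop = FALSE], 2, tp, "-")^2)
    anchor <- state$points3d[which.min(d2), ]
    dir <- tp - anchor
    dir <- dir / sqrt(sum(dir^2))
    start <- tp - dir * max(spec$disk_diameter - spec$sheet_margin, 5e-4)
    segs[[k]] <- list(a = start, b = start + dir * cable_length, r = cable_radius)
  }
  segs
}

# Vectorized even-odd point-in-polygon test.
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((poly_y[i] > py) != (poly_y[j] > py)) &
      (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

lambert_shade <- function(normal, view_dir, light, ambient) {
  n <- normal
  if (sum(n * view_dir) > 0) n <- -n        # orient toward camera
  ambient + (1 - ambient) * max(0, -sum(n * light))
}

# Full-frame background image for one view.
render_background <- function(intr, app, mode) {
  h <- intr$height; w <- intr$width
  if (mode == "flat") {
    matrix(app$bg_level, h, w)
  } else if (mode == "gradient") {
    xs <- matrix(rep(0:(w - 1), each = h), h, w) / max(w - 1, 1)
    ys <- matrix(rep(0:(h - 1), times = w), h, w) / max(h - 1, 1)
    ramp <- xs * cos(app$bg_angle) + ys * sin(app$bg_angle)
    ramp <- (ramp - min(ramp)) / max(max(ramp) - min(ramp), 1e-12)
    matrix(app$bg_level * 0.6 + app$bg_level * 0.8 * ramp, h, w)
  } else {  # textured-noise: coarse noise field upsampled smoothly
    ch <- max(8L, ceiling(h / 20)); cw <- max(8L, ceiling(w / 20))
    coarse <- with_seed(app$bg_seed, matrix(runif(ch * cw, 0.7, 1.3), ch, cw))
    field <- resample_matrix(coarse, bicubic_weights(ch, h), bicubic_weights(cw, w))
    pmin(pmax(app$bg_level * field, 0), 1)
  }
}

# Render one view of a grid state. Returns a labeled frame.
render_view <- function(intr, dist, cam_pose, state, settings, app,
                        noise_seed = NULL) {
  spec <- state$spec
  ne <- spec$rows * spec$cols
  proj <- project(intr, dist, cam_pose, state$points3d)
  frames <- surface_frames(state)
  boundary3d <- sheet_boundary_3d(state, frames)
  cables <- cable_segments_3d(state)
  cam_inv <- pose_inverse(cam_pose)

  proj_pt <- function(p) project(intr, dist, cam_pose, p)$pixels
  poly <- proj_pt(boundary3d)
  depth_b <- pose_apply(cam_inv, boundary3d)[, 3]
  if (all(!proj$visible) || any(depth_b <= 0)) {
    return(structure(list(image = NULL, empty = TRUE), class = "labeled_frame"))
  }

  # disk ellipse affine frames (projected)
  centers <- proj$pixels[seq_len(ne), , drop = FALSE]
  rdisk <- spec$disk_diameter / 2
  a1 <- proj_pt(state$points3d[seq_len(ne), ] + rdisk * frames$e1) - centers
  a2 <- proj_pt(state$points3d[seq_len(ne), ] + rdisk * frames$e2) - centers

  # projected cable geometry
  cable_px <- lapply(cables, function(sg) {
    za <- pose_apply(cam_inv, sg$a)[3]
    list(a = drop(proj_pt(sg$a)), b = drop(proj_pt(sg$b)),
         r = intr$fx * sg$r / max(za, 1e-6))
  })

  # raster region covering sheet, disks and cables
  all_x <- c(poly[, 1], centers[, 1] + abs(a1[, 1]) + abs(a2[, 1]),
             centers[, 1] - abs(a1[, 1]) - abs(a2[, 1]),
             unlist(lapply(cable_px, function(s) c(s$a[1], s$b[1]))))
  all_y <- c(poly[, 2], centers[, 2] + abs(a1[, 2]) + abs(a2[, 2]),
             centers[, 2] - abs(a1[, 2]) - abs(a2[, 2]),
             unlist(lapply(cable_px, function(s) c(s$a[2], s$b[2]))))
  pad <- 2 + 3 * settings$blur_sigma
  x0 <- max(0L, floor(min(all_x) - pad)); x1 <- min(intr$width - 1L, ceiling(max(all_x) + pad))
  y0 <- max(0L, floor(min(all_y) - pad)); y1 <- min(intr$height - 1L, ceiling(max(all_y) + pad))

  img <- render_background(intr, app, settings$background$mode)

  if (x1 >= x0 && y1 >= y0) {
    S <- settings$supersample
    rw <- x1 - x0 + 1L; rh <- y1 - y0 + 1L
    sx <- x0 - 0.5 + (seq_len(rw * S) - 0.5) / S
    sy <- y0 - 0.5 + (seq_len(rh * S) - 0.5) / S
    PX <- matrix(rep(sx, each = rh * S), rh * S, rw * S)
    PY <- matrix(rep(sy, times = rw * S), rh * S, rw * S)
    px <- as.vector(PX); py <- as.vector(PY)

    view_dir_of <- function(p3) {
      v <- pose_apply(cam_inv, p3); v / sqrt(sum(v^2))
    }
    sheet_n <- colMeans(frames$normal)
    sheet_shade <- lambert_shade(sheet_n / sqrt(sum(sheet_n^2)),
                                 view_dir_of(colMeans(state$points3d[seq_len(ne), ])),
                                 app$light, app$ambient)

    canvas <- rep(NA_real_, length(px))
    inside_sheet <- point_in_polygon(px, py, poly[, 1], poly[, 2])
    canvas[inside_sheet] <- app$sheet_level * sheet_shade

    for (sgi in seq_along(cable_px)) {
      sg <- cable_px[[sgi]]
      lo_x <- min(sg$a[1], sg$b[1]) - sg$r - 1; hi_x <- max(sg$a[1], sg$b[1]) + sg$r + 1
      lo_y <- min(sg$a[2], sg$b[2]) - sg$r - 1; hi_y <- max(sg$a[2], sg$b[2]) + sg$r + 1
      sel <- which(px >= lo_x & px <= hi_x & py >= lo_y & py <= hi_y)
      if (!length(sel)) next
      dx <- sg$b[1] - sg$a[1]; dy <- sg$b[2] - sg$a[2]
      L2 <- dx^2 + dy^2
      t_ <- pmin(pmax(((px[sel] - sg$a[1]) * dx + (py[sel] - sg$a[2]) * dy) / L2, 0), 1)
      d2 <- (px[sel] - (sg$a[1] + t_ * dx))^2 + (py[sel] - (sg$a[2] + t_ * dy))^2
      hit <- sel[d2 <= sg$r^2]
      canvas[hit] <- app$cable_level * sheet_shade
    }

    for (i in seq_len(ne)) {
      if (!is.finite(centers[i, 1])) next
      M <- cbind(a1[i, ], a2[i, ])
      dM <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
      if (abs(dM) < 1e-12) next
      ext <- abs(M[1, 1]) + abs(M[1, 2]) + 1
      eyt <- abs(M[2, 1]) + abs(M[2, 2]) + 1
      sel <- which(px >= centers[i, 1] - ext & px <= centers[i, 1] + ext &
                     py >= centers[i, 2] - eyt & py <= centers[i, 2] + eyt)
      if (!length(sel)) next
      rx <- px[sel] - centers[i, 1]; ry <- py[sel] - centers[i, 2]
      s1 <- (M[2, 2] * rx - M[1, 2] * ry) / dM
      s2 <- (-M[2, 1] * rx + M[1, 1] * ry) / dM
      hit <- sel[s1^2 + s2^2 <= 1]
      shade <- lambert_shade(frames$normal[i, ], view_dir_of(state$points3d[i, ]),
                             app$light, app$ambient)
      canvas[hit] <- app$disk_level * shade
    }

    # composite: block-average supersamples where geometry was drawn
    cov <- matrix(as.numeric(!is.na(canvas)), rh * S, rw * S)
    val <- matrix(ifelse(is.na(canvas), 0, canvas), rh * S, rw * S)
    block_avg <- function(m) {
      m2 <- matrix(colMeans(matrix(m, S)), rh, rw * S)       # average rows
      t(matrix(colMeans(matrix(t(m2), S)), rw, rh))          # average cols
    }
    cov_p <- block_avg(cov); val_p <- block_avg(val)
    sub <- img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
    sub <- sub * (1 - cov_p) + val_p
    img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- sub

    if (settings$blur_sigma > 0) {
      bw <- ceiling(3 * settings$blur_sigma)
      yb0 <- max(0L, y0 - bw); yb1 <- min(intr$height - 1L, y1 + bw)
      xb0 <- max(0L, x0 - bw); xb1 <- min(intr$width - 1L, x1 + bw)
      reg <- img[(yb0 + 1):(yb1 + 1), (xb0 + 1):(xb1 + 1), drop = FALSE]
      reg <- as.matrix(EBImage::gblur(reg, sigma = settings$blur_sigma))
      img[(yb0 + 1):(yb1 + 1), (xb0 + 1):(xb1 + 1)] <- reg
    }
  }

  if (settings$noise_sigma > 0) {
    ns <- if (is.null(noise_seed)) derive_seed(settings$seed, 3L) else noise_seed
    img <- img + with_seed(ns, matrix(rnorm(length(img), 0, settings$noise_sigma),
                                      nrow(img), ncol(img)))
  }
  img <- pmin(pmax(img, 0), 1)

  bx0 <- max(min(all_x) - 1, 0); bx1 <- min(max(all_x) + 1, intr$width - 1)
  by0 <- max(min(all_y) - 1, 0); by1 <- min(max(all_y) + 1, intr$height - 1)
  structure(list(image = img,
                 bbox = c(x_min = bx0, y_min = by0, w = bx1 - bx0, h = by1 - by0),
                 keypoints = proj$pixels, visible = proj$visible,
                 truth = list(state = state, intr = intr),
                 empty = FALSE),
            class = "labeled_frame")
}

#' Render a stereo pair of labeled frames
#'
#' Renders the grid into both views of the rig with a shared appearance draw
#' (lighting, background, material intensities) and per-view sensor noise.
#' Keypoint labels are exact projections of the grid state. Deterministic
#' given `settings$seed`; `noise_seed` optionally re-draws only the sensor
#' noise (emulating repeated recordings of a static scene).
#'
#' @param rig a `stereo_rig`.
#' @param state a `grid_state` in the world (left camera) frame.
#' @param settings a [render_settings()].
#' @param noise_seed optional integer overriding the sensor-noise substream.
#' @return list with `left` and `right` labeled frames.
#' @export
render_stereo <- function(rig, state, settings = render_settings(),
                          noise_seed = NULL) {
  app <- sample_appearance(settings)
  poses <- rig_camera_poses(rig)
  ns <- if (is.null(noise_seed)) derive_seed(settings$seed, 3L) else noise_seed
  left <- render_view(rig$left, rig$dist_left, poses$left, state, settings, app,
                      noise_seed = derive_seed(ns, 11L))
  right <- render_view(rig$right, rig$dist_right, poses$right, state, settings, app,
                       noise_seed = derive_seed(ns, 12L))
  if (isTRUE(left$empty) && isTRUE(right$empty)) {
    stop("render_stereo: grid fully outside both camera frusta (empty scene)",
         call. = FALSE)
  }
  list(left = left, right = right)
}
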