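# Multi-scale training-corpus generation and measurement-grid scene layout.

#' Add sensor noise to a rendered frame
#'
#' Emulates repeated recordings of a static scene: the clean render stays
#' fixed and only the additive sensor noise is redrawn.
#' @param frame a `labeled_frame`.
#' @param sigma noise standard deviation in intensity units.
#' @param seed integer seed.
#' @return the frame with noisy image.
#' @export
add_sensor_noise <- function(frame, sigma, seed) {
  if (sigma <= 0) return(frame)
  img <- frame$image
  img <- img + with_seed(seed, matrix(rnorm(length(img), 0, sigma),
                                      nrow(img), ncol(img)))
  frame$image <- pmin(pmax(img, 0), 1)
  frame
}

#' Downscale a labeled frame, rescaling its labels exactly
#'
#' Area-average resampling to `floor(scale * size)` pixels per axis;
#' keypoints and bounding box are multiplied by the realized per-axis ratio
#' (e.g. 26/80 for an 80 px image at scale 0.33, not 0.33 itself), so labels
#' stay consistent with the image they accompany.
#'
#' @param frame a `labeled_frame`.
#' @param scale fraction in (0, 1].
#' @return the downscaled `labeled_frame`.
#' @export
downscale_with_labels <- function(frame, scale) {
  if (scale <= 0 || scale > 1) stop("downscale_with_labels: scale must be in (0, 1]",
                                    call. = FALSE)
  if (scale == 1) return(frame)
  h <- nrow(frame$image); w <- ncol(frame$image)
  h2 <- floor(scale * h); w2 <- floor(scale * w)
  if (h2 < 8 || w2 < 8) stop("downscale_with_labels: output smaller than 8 px",
                             call. = FALSE)
  ry <- h2 / h; rx <- w2 / w
  out <- frame
  out$image <- resample_matrix(frame$image, area_weights(h, h2), area_weights(w, w2))
  out$keypoints <- cbind(x = frame$keypoints[, 1] * rx, y = frame$keypoints[, 2] * ry)
  out$bbox <- c(x_min = unname(frame$bbox[1]) * rx, y_min = unname(frame$bbox[2]) * ry,
                w = unname(frame$bbox[3]) * rx, h = unname(frame$bbox[4]) * ry)
  out$scale <- c(rx = rx, ry = ry)
  out
}

# ---- image and label file I/O ---------------------------------------------

#' Write a grayscale image as 8-bit PNG
#' @param img matrix in [0, 1], rows = y.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a grayscale image (PNG or PGM)
#' @param path file path.
#' @return matrix in [0, 1], rows = y.
#' @export
read_image <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  while (length(tokens) < 4) {
    line <- readLines(con, n = 1)
    line <- sub("#.*", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
  }
  if (tokens[1] != "P5") stop("read_pgm: only binary (P5) PGM supported", call. = FALSE)
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3]); mx <- as.integer(tokens[4])
  raw <- readBin(con, "integer", n = w * h, size = 1, signed = FALSE)
  matrix(raw / mx, h, w, byrow = TRUE)
}

#' Write a keypoint label file
#'
#' One text line per object: class index, normalized bbox center x/y and
#' width/height, then 68 triplets of normalized keypoint x, y and a 0/1/2
#' visibility flag (0 = not labeled is unused here; 1 = labeled invisible,
#' 2 = labeled visible) -- the common single-stage-detector pose label
#' convention, so generated corpora can train third-party models directly.
#'
#' @param frame a `labeled_frame`.
#' @param path output path.
#' @param class_index object class, default 0.
#' @return the path, invisibly.
#' @export
write_label_file <- function(frame, path, class_index = 0L) {
  w <- ncol(frame$image); h <- nrow(frame$image)
  b <- frame$bbox
  vals <- c(class_index,
            (b[1] + b[3] / 2) / w, (b[2] + b[4] / 2) / h, b[3] / w, b[4] / h,
            as.vector(t(cbind(frame$keypoints[, 1] / w, frame$keypoints[, 2] / h,
                              ifelse(frame$visible, 2, 1)))))
  writeLines(paste(formatC(vals, format = "g", digits = 10), collapse = " "), path)
  invisible(path)
}

#' Read a keypoint label file
#'
#' @param path label file path.
#' @param n_keypoints expected keypoint count (68 for the default grid).
#' @return list of objects, each with `class`, `bbox` (normalized center
#'   format), `keypoints` (normalized), `visible`.
#' @export
read_label_file <- function(path, n_keypoints = 68L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    expected <- 5 + 3 * n_keypoints
    if (length(vals) != expected || any(!is.finite(vals))) {
      stop(sprintf("read_label_file: malformed label on line %d (expected %d finite fields, got %d)",
                   i, expected, length(vals)), call. = FALSE)
    }
    kp <- matrix(vals[-(1:5)], ncol = 3, byrow = TRUE)
    list(class = as.integer(vals[1]), bbox = vals[2:5],
         keypoints = kp[, 1:2, drop = FALSE], visible = kp[, 3] >= 2)
  })
}

# ---- super-resolution corpus ----------------------------------------------

# Random grid-filling render used for corpus entries: a square virtual view
# of a randomly posed, randomly deformed grid.
corpus_base_render <- function(size, spec, seed) {
  pars <- with_seed(seed, list(
    tilt_x = runif(1, -0.6, 0.6), tilt_y = runif(1, -0.6, 0.6),
    roll = runif(1, 0, 2 * pi),
    bend = runif(1, -10, 10) * (runif(1) < 0.7),
    amp = runif(1, 0, 0.0012) * (runif(1) < 0.7),
    bg_mode = sample(c("flat", "gradient", "textured-noise"), 1),
    dseed = sample.int(1e6, 1)))
  # trailing 180-degree x-flip turns the grid's front face (its +z normal)
  # toward the camera; the tilts then wobble it about face-on
  Rpose <- rotation_about("z", pars$roll) %*%
    rotation_about("x", pars$tilt_x) %*% rotation_about("y", pars$tilt_y) %*%
    rotation_about("x", pi)
  z <- 0.5
  extent <- spec$pitch * max(spec$rows - 1, spec$cols - 1) + 2 * spec$sheet_margin +
    2 * spec$disk_diameter
  f <- 0.80 * size * z / extent
  intr <- camera_intrinsics(f, f, (size - 1) / 2, (size - 1) / 2, size, size)
  ctr <- c(spec$pitch * (spec$cols - 1) / 2, spec$pitch * (spec$rows - 1) / 2, 0)
  pose <- rigid_pose(Rpose, c(0, 0, z) - drop(Rpose %*% ctr))
  state <- canonical_grid(spec, pose)
  if (pars$bend != 0 || pars$amp > 0) {
    state <- deform(state, deform_params(bend_curvature = pars$bend,
                                         field_amplitude = pars$amp),
                    seed = pars$dseed)
  }
  settings <- render_settings(seed = derive_seed(seed, 7L))
  settings$background$mode <- pars$bg_mode
  app <- sample_appearance(settings)
  render_view(intr, distortion_coeffs(), rigid_pose(), state, settings, app,
              noise_seed = derive_seed(seed, 8L))
}

#' Generate a multi-scale super-resolution training corpus
#'
#' Writes `n_base` base renders (square sizes drawn uniformly in
#' `size_range`) plus one downscaled image + label pair per (base, scale),
#' mirroring a corpus whose resolutions span 26x26 to 260x260 px when the
#' base range is [80, 260] and scales include 0.33. With `dry_run = TRUE`
#' nothing is rendered or written; only the manifest bookkeeping is computed
#' (the entry count is exactly `n_base * length(scales)` either way).
#'
#' @param n_base number of base renders (>= 1).
#' @param scales fractions in (0, 1], e.g. `c(1, 0.75, 0.5, 0.33)`.
#' @param sink output directory.
#' @param seed integer seed.
#' @param spec a [grid_spec()].
#' @param size_range inclusive integer range of base render sizes, pixels.
#' @param dry_run if TRUE, compute the manifest without rendering.
#' @return a `corpus_manifest` list with `entries` data.frame, `counts` per
#'   scale, `total`, and `seed`.
#' @export
make_sr_corpus <- function(n_base, scales = c(1, 0.75, 0.5, 0.33), sink = NULL,
                           seed = 1L, spec = grid_spec(),
                           size_range = c(80L, 260L), dry_run = FALSE) {
  if (n_base < 1) stop("make_sr_corpus: n_base must be >= 1", call. = FALSE)
  if (!length(scales)) stop("make_sr_corpus: scales must be non-empty", call. = FALSE)
  if (!dry_run) {
    if (is.null(sink)) stop("make_sr_corpus: sink directory required", call. = FALSE)
    dir.create(sink, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(sink)) stop("make_sr_corpus: cannot create sink directory",
                                call. = FALSE)
  }
  span <- size_range[2] - size_range[1] + 1L
  sizes <- with_seed(derive_seed(seed, 21L),
                     size_range[1] + sample.int(span, n_base, replace = TRUE) - 1L)
  base_id <- rep(seq_len(n_base), each = length(scales))
  scale_v <- rep(scales, times = n_base)
  img_path <- file.path(if (is.null(sink)) "." else sink,
                        sprintf("base%05d_s%03.0f.png", base_id, scale_v * 100))
  entries <- data.frame(
    image = img_path, label = sub("\\.png$", ".txt", img_path),
    scale = scale_v, base_id = base_id,
    size_px = ifelse(scale_v == 1, sizes[base_id], floor(scale_v * sizes[base_id])),
    stringsAsFactors = FALSE)
  if (!dry_run) {
    k <- 0L
    for (b in seq_len(n_base)) {
      frame <- corpus_base_render(sizes[b], spec, derive_seed(seed, 100L + b))
      for (s in scales) {
        k <- k + 1L
        fr <- downscale_with_labels(frame, s)
        write_image_png(fr$image, entries$image[k])
        write_label_file(fr, entries$label[k])
      }
    }
  }
  manifest <- list(entries = entries,
                   counts = as.list(table(entries$scale)),
                   total = nrow(entries), n_base = n_base,
                   scales = scales, seed = seed)
  class(manifest) <- "corpus_manifest"
  if (!dry_run) {
    meta <- manifest
    meta$entries <- NULL
    jsonlite::write_json(c(meta, list(entries = entries)),
                         file.path(sink, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}

# ---- measurement-grid scenes ----------------------------------------------

#' Measurement-grid layout
#'
#' The evaluation protocol's predefined positions: a lateral x depth grid in
#' front of the cameras covering a 32 cm wide, 50 cm deep working area over
#' 40-90 cm viewing distance (30 positions by default). The reference
#' position is the closest central one.
#'
#' @param depths depth values in meters.
#' @param n_lateral lateral position count per depth.
#' @param width lateral working-area width in meters.
#' @return a `measurement_layout` list.
#' @export
measurement_layout <- function(depths = seq(40, 90, by = 10) / 100,
                               n_lateral = 5L, width = 0.32) {
  if (any(depths <= 0) || !all(is.finite(depths))) {
    stop("measurement_layout: depth range must lie in (0, Inf)", call. = FALSE)
  }
  structure(list(depths = sort(depths), n_lateral = as.integer(n_lateral),
                 width = width), class = "measurement_layout")
}

#' Generate the measurement-grid scene states
#'
#' Places the (flat) grid at every layout position with its sheet normal
#' aimed at the left camera, as the physical grid was oriented to face the
#' cameras directly at each position. The first returned position is the
#' reference: the closest central one.
#'
#' @param layout a [measurement_layout()].
#' @param spec a [grid_spec()].
#' @return list of entries with `id`, `depth`, `lateral`, `center` (3-vector)
#'   and `state` (a `grid_state`); entry 1 is the reference position.
#' @export
make_measurement_scenes <- function(layout = measurement_layout(),
                                    spec = grid_spec()) {
  xs <- if (layout$n_lateral == 1) 0 else
    seq(-layout$width / 2, layout$width / 2, length.out = layout$n_lateral)
  ctr_g <- c(spec$pitch * (spec$cols - 1) / 2, spec$pitch * (spec$rows - 1) / 2, 0)
  scenes <- list()
  for (di in seq_along(layout$depths)) for (xi in seq_along(xs)) {
    pos <- c(xs[xi], 0, layout$depths[di])
    ez <- -pos / sqrt(sum(pos^2))              # grid normal aimed at left camera
    ex <- c(1, 0, 0) - sum(c(1, 0, 0) * ez) * ez
    ex <- ex / sqrt(sum(ex^2))
    ey <- c(ez[2] * ex[3] - ez[3] * ex[2], ez[3] * ex[1] - ez[1] * ex[3],
            ez[1] * ex[2] - ez[2] * ex[1])
    R <- cbind(ex, ey, ez)
    pose <- rigid_pose(R, pos - drop(R %*% ctr_g))
    scenes[[length(scenes) + 1]] <- list(
      id = sprintf("d%02.0f_x%+04.0f", layout$depths[di] * 100, xs[xi] * 100),
      depth = layout$depths[di], lateral = xs[xi], center = pos,
      state = canonical_grid(spec, pose))
  }
  # reference first: closest depth, most central lateral position
  depth_v <- vapply(scenes, `[[`, 0, "depth")
  lat_v <- abs(vapply(scenes, `[[`, 0, "lateral"))
  ref <- order(depth_v, lat_v)[1]
  scenes <- c(scenes[ref], scenes[-ref])
  for (i in seq_along(scenes)) scenes[[i]]$is_reference <- i == 1
  scenes
}
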