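# Synthetic renderer, label bookkeeping, corpus and measurement scenes.

test_that("flat grid at 40 cm is fully visible in both views", {
  pair <- pair_40cm()
  expect_equal(sum(pair$left$visible), 68)
  expect_equal(sum(pair$right$visible), 68)
  # bbox contains every visible keypoint
  for (f in pair) {
    b <- f$bbox
    kp <- f$keypoints[f$visible, , drop = FALSE]
    expect_true(all(kp[, 1] >= b[1] - 1e-9 & kp[, 1] <= b[1] + b[3] + 1e-9))
    expect_true(all(kp[, 2] >= b[2] - 1e-9 & kp[, 2] <= b[2] + b[4] + 1e-9))
  }
})

test_that("noiseless flat-lit render has exact material intensities", {
  rig <- test_rig()
  pair <- render_stereo(rig, scene_at(0.40)$state, clean_settings())
  f <- pair$left
  kp <- f$keypoints
  centers <- f$image[cbind(round(kp[1:64, 2]) + 1, round(kp[1:64, 1]) + 1)]
  expect_true(all(abs(centers - 0.85) < 1e-9))
  # one disk-diameter outside the sheet: pure background
  b <- f$bbox
  expect_equal(f$image[round(b[2]) - 8, round(b[1]) - 8], 0.2, tolerance = 1e-12)
})

test_that("rendering is deterministic given the seed", {
  rig <- test_rig()
  st <- scene_at(0.50)$state
  a <- render_stereo(rig, st, render_settings(seed = 9))
  b <- render_stereo(rig, st, render_settings(seed = 9))
  expect_identical(a$left$image, b$left$image)
  expect_identical(a$right$image, b$right$image)
  c <- render_stereo(rig, st, render_settings(seed = 10))
  expect_gt(max(abs(c$left$image - a$left$image)), 0)
})

test_that("a grid behind the cameras raises an empty-scene error", {
  rig <- test_rig()
  st <- canonical_grid(grid_spec(), rigid_pose(diag(3), c(0, 0, -0.5)))
  expect_error(render_stereo(rig, st, render_settings()), "empty scene|frusta")
})

test_that("rendered disk centroids match the stored keypoint labels", {
  # tail-free spec isolates disk rendering from cable pixels
  spec <- grid_spec(rows = 3, cols = 3, pitch = 0.012, disk_diameter = 0.004,
                    n_tails = 0)
  rig <- test_rig()
  for (z in c(0.45, 0.60)) {
    f <- render_stereo(rig, scene_at(z, spec)$state, clean_settings())$left
    kp <- f$keypoints
    errs <- vapply(1:9, function(i) {
      cx <- kp[i, 1]; cy <- kp[i, 2]; r <- 5
      xs <- (round(cx) - r):(round(cx) + r)
      ys <- (round(cy) - r):(round(cy) + r)
      w <- pmax(f$image[ys + 1, xs + 1] - 0.45, 0)
      wx <- sum(w * matrix(xs, length(ys), length(xs), byrow = TRUE)) / sum(w)
      wy <- sum(w * matrix(ys, length(ys), length(xs))) / sum(w)
      sqrt((wx - cx)^2 + (wy - cy)^2)
    }, 0)
    expect_lt(max(errs), 0.3)
  }
})

test_that("downscaling rescales image and labels consistently", {
  set.seed(2)
  img80 <- matrix(runif(80 * 80), 80, 80)
  kp <- cbind(runif(68, 5, 75), runif(68, 5, 75))
  fr <- fake_frame(img80, kp, c(x_min = 4, y_min = 4, w = 72, h = 72))

  # the worked example: 80 x 80 at scale 0.33 -> 26 x 26
  out <- downscale_with_labels(fr, 0.33)
  expect_equal(dim(out$image), c(26, 26))
  expect_equal(out$keypoints[, 1], kp[, 1] * 26 / 80, tolerance = 1e-12)

  # identity at scale 1
  expect_identical(downscale_with_labels(fr, 1), fr)

  # exact ratio bookkeeping at 260 -> 130
  img260 <- matrix(runif(260 * 260), 260, 260)
  u <- runif(10); v <- runif(10)
  fr2 <- fake_frame(img260, cbind(260 * u, 260 * v),
                    c(x_min = 0, y_min = 0, w = 259, h = 259),
                    visible = rep(TRUE, 10))
  out2 <- downscale_with_labels(fr2, 0.5)
  expect_equal(dim(out2$image), c(130, 130))
  expect_lt(max(abs(out2$keypoints - cbind(130 * u, 130 * v))), 1e-9)

  # too-small outputs are rejected
  expect_error(downscale_with_labels(fr, 0.05), "8 px")
  expect_error(downscale_with_labels(fr, 1.5), "scale")
})

test_that("downscaled labels agree with a focal-length-scaled camera", {
  rig <- test_rig()
  f <- render_stereo(rig, scene_at(0.40)$state, clean_settings())$left
  s <- 0.5
  out <- downscale_with_labels(f, s)
  rx <- out$scale["rx"]; ry <- out$scale["ry"]
  intr <- rig$left
  intr2 <- camera_intrinsics(intr$fx * rx, intr$fy * ry, intr$cx * rx,
                             intr$cy * ry, ceiling(intr$width * rx),
                             ceiling(intr$height * ry))
  proj <- project(intr2, distortion_coeffs(), rigid_pose(),
                  scene_at(0.40)$state$points3d)
  expect_lt(max(abs(out$keypoints - proj$pixels)), 0.51)
})

test_that("area-average downscale preserves the image mean", {
  set.seed(4)
  img <- matrix(runif(90 * 70), 90, 70)
  fr <- fake_frame(img, cbind(1, 1), c(x_min = 0, y_min = 0, w = 69, h = 89))
  out <- downscale_with_labels(fr, 0.5)
  expect_equal(mean(out$image), mean(img[1:90, 1:70]), tolerance = 0.01)
})

test_that("corpus generation writes exactly n_base x n_scales entries", {
  dir <- file.path(tempdir(), "corpus_test")
  man <- make_sr_corpus(n_base = 6, scales = c(1, 0.75, 0.5, 0.33), sink = dir,
                        seed = 3, size_range = c(80L, 80L))
  expect_equal(man$total, 24)
  expect_equal(nrow(man$entries), 24)
  expect_true(all(file.exists(man$entries$image)))
  expect_true(all(file.exists(man$entries$label)))
  # an 80 px base at scale 0.33 gives the 26 px corpus floor
  expect_equal(min(man$entries$size_px), 26)
  expect_equal(max(man$entries$size_px), 80)
  # labels re-read consistently
  lab <- read_label_file(man$entries$label[1])
  expect_equal(nrow(lab[[1]]$keypoints), 68)
  img <- read_image(man$entries$image[1])
  expect_equal(dim(img), c(80, 80))
  unlink(dir, recursive = TRUE)
})

test_that("corpus manifest bookkeeping is exact without rendering", {
  man <- make_sr_corpus(n_base = 123, scales = c(1, 0.75, 0.5, 0.33),
                        dry_run = TRUE)
  expect_equal(man$total, 123 * 4)
  expect_error(make_sr_corpus(0, c(1)), "n_base")
  expect_error(make_sr_corpus(3, numeric(0)), "scales")
})

test_that("measurement layout spans the working area and depth range", {
  scenes <- make_measurement_scenes()
  expect_equal(length(scenes), 30)
  depths <- vapply(scenes, `[[`, 0, "depth")
  expect_equal(range(depths), c(0.40, 0.90))
  # reference: closest central position
  expect_true(scenes[[1]]$is_reference)
  expect_equal(scenes[[1]]$depth, 0.40)
  expect_equal(scenes[[1]]$lateral, 0)
  # single-cell layout is its own reference
  one <- make_measurement_scenes(measurement_layout(depths = 0.40, n_lateral = 1))
  expect_equal(length(one), 1)
  expect_true(one[[1]]$is_reference)
  expect_error(measurement_layout(depths = c(-0.4, 0.9)), "depth")
})

test_that("every measurement scene faces the left camera", {
  scenes <- make_measurement_scenes()
  for (sc in scenes) {
    normal <- sc$state$pose$R[, 3]
    to_cam <- -sc$center / sqrt(sum(sc$center^2))
    ang <- acos(min(1, sum(normal * to_cam)))
    expect_lt(ang, 1e-6)
  }
})

test_that("labels and images survive a write-read round trip", {
  pair <- pair_40cm()
  d <- tempfile(); dir.create(d)
  ip <- file.path(d, "f.png"); lp <- file.path(d, "f.txt")
  write_image_png(pair$left$image, ip)
  write_label_file(pair$left, lp)
  img <- read_image(ip)
  expect_equal(dim(img), dim(pair$left$image))
  expect_lt(max(abs(img - pair$left$image)), 1 / 255)
  lab <- read_label_file(lp)[[1]]
  w <- ncol(pair$left$image); h <- nrow(pair$left$image)
  expect_lt(max(abs(lab$keypoints[, 1] * w - pair$left$keypoints[, 1])), 1e-4 * w)
  expect_equal(lab$visible, unname(pair$left$visible))
  unlink(d, recursive = TRUE)
})
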