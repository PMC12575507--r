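# Upscaling, keypoint candidates, electrode index assignment and the
# crop/upscale coordinate bookkeeping.

test_that("upscale honors the exact size contract", {
  set.seed(1)
  crop <- matrix(runif(26 * 26), 26, 26)
  up <- upscale(crop, 4)
  expect_equal(dim(up), c(104, 104))
  expect_identical(upscale(crop, 1), crop)
  # resampling preserves constants
  flat <- matrix(0.37, 20, 20)
  expect_lt(max(abs(upscale(flat, 4) - 0.37)), 1e-12)
  expect_error(upscale(crop, 0), "factor")
  expect_error(upscale(crop, 2.5), "factor")
})

test_that("an external upscaler hook is applied and size-checked", {
  crop <- matrix(runif(10 * 12), 10, 12)
  nn <- function(img, f) img[rep(seq_len(nrow(img)), each = f),
                             rep(seq_len(ncol(img)), each = f)]
  up <- upscale(crop, 3, method = nn)
  expect_equal(dim(up), c(30, 36))
  expect_equal(up[1, 1], crop[1, 1])
  bad <- function(img, f) img
  expect_error(upscale(crop, 3, method = bad), "contract")
})

test_that("candidate detection finds nearly all disks on a clean crop", {
  rig <- test_rig()
  pair <- render_stereo(rig, scene_at(0.40)$state, clean_settings())
  dets <- detect_grid(pair$left$image, detector_config("classical"))
  rec <- crop_frame(pair$left$image, dets[[1]])
  up <- upscale(rec$crop, 4)
  cands <- detect_keypoint_candidates(up, grid_spec())
  expect_gte(nrow(cands$disks), 60)
  truth_up <- sweep(pair$left$keypoints[1:64, ], 2, rec$offset, "-") * 4
  nn <- apply(cands$disks[, 1:2, drop = FALSE], 1, function(p) {
    min(sqrt((truth_up[, 1] - p[1])^2 + (truth_up[, 2] - p[2])^2))
  })
  expect_lt(max(nn), 1.0)
  expect_gte(nrow(cands$tails), 1)
})

test_that("candidate detection is deterministic and empty on blank input", {
  blank <- matrix(0.3, 120, 120)
  out <- detect_keypoint_candidates(blank)
  expect_equal(nrow(out$disks), 0)
  expect_equal(nrow(out$tails), 0)
  pair <- pair_40cm()
  dets <- detect_grid(pair$left$image, detector_config("classical"))
  up <- upscale(crop_frame(pair$left$image, dets[[1]])$crop, 4)
  a <- detect_keypoint_candidates(up)
  b <- detect_keypoint_candidates(up)
  expect_identical(a, b)
})

# Exact synthetic candidates: canonical grid mapped through a similarity
# transform into a fake crop frame.
synthetic_candidates <- function(spec = grid_spec(), angle = 0.15, scale = 5000,
                                 shift = c(60, 60), jitter = 0, seed = 1) {
  p2 <- gridsight:::grid_plane_points(spec)
  # front-face viewing convention: image y runs opposite the grid's row axis
  Rm <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  pts <- sweep(p2 %*% diag(c(1, -1)) %*% t(Rm) * scale, 2, shift, "+")
  if (jitter > 0) {
    set.seed(seed)
    pts <- pts + matrix(rnorm(length(pts), 0, jitter), ncol = 2)
  }
  ne <- spec$rows * spec$cols
  structure(list(
    disks = cbind(x = pts[seq_len(ne), 1], y = pts[seq_len(ne), 2], strength = 1),
    tails = if (spec$n_tails > 0)
      cbind(x = pts[-seq_len(ne), 1], y = pts[-seq_len(ne), 2], strength = 1)
    else matrix(0, 0, 3, dimnames = list(NULL, c("x", "y", "strength")))),
    class = "candidate_set")
}

test_that("exact candidates are assigned in ground-truth order", {
  spec <- grid_spec()
  cands <- synthetic_candidates(spec)
  kps <- assign_indices(cands, spec)
  expect_equal(nrow(kps$points), 68)
  expect_true(all(kps$visible))
  expect_lt(max(abs(kps$points[1:64, ] - cands$disks[, 1:2])), 1e-6)
  expect_lt(max(abs(kps$points[65:68, ] - cands$tails[, 1:2])), 1e-3)
})

test_that("index assignment is equivariant under crop-plane rotations", {
  spec <- grid_spec()
  base <- synthetic_candidates(spec, jitter = 0.3, seed = 5)
  ref <- assign_indices(base, spec)
  ctr <- c(60, 60)
  for (ang in c(pi / 2, pi, 3 * pi / 2)) {
    Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    rot <- base
    rot$disks[, 1:2] <- sweep(sweep(base$disks[, 1:2], 2, ctr, "-") %*% t(Rm), 2, ctr, "+")
    rot$tails[, 1:2] <- sweep(sweep(base$tails[, 1:2], 2, ctr, "-") %*% t(Rm), 2, ctr, "+")
    out <- assign_indices(rot, spec)
    # electrode i must land on the rotated position of electrode i
    expected <- sweep(sweep(ref$points[1:64, ], 2, ctr, "-") %*% t(Rm), 2, ctr, "+")
    expect_lt(max(abs(out$points[1:64, ] - expected)), 1e-6)
  }
})

test_that("a square grid without tails is reported as ambiguous", {
  spec <- grid_spec()
  cands <- synthetic_candidates(spec)
  cands$tails <- matrix(0, 0, 3, dimnames = list(NULL, c("x", "y", "strength")))
  expect_error(assign_indices(cands, spec), "ambiguous")
  expect_error(assign_indices(structure(list(disks = cands$disks[1:3, ],
                                             tails = cands$tails),
                                        class = "candidate_set"), spec),
               "4 disk candidates")
})

test_that("spurious and missing candidates degrade gracefully", {
  spec <- grid_spec()
  cands <- synthetic_candidates(spec, jitter = 0.2, seed = 9)
  # drop 4 electrodes, add 3 spurious points inside the sheet area
  drop <- c(10, 23, 41, 55)
  cands$disks <- cands$disks[-drop, ]
  spur <- cbind(x = c(72, 95, 55), y = c(72, 95, 100), strength = 0.5)
  cands$disks <- rbind(cands$disks, spur)
  kps <- assign_indices(cands, spec)
  expect_false(any(kps$visible[drop]))
  truth <- synthetic_candidates(spec, jitter = 0.2, seed = 9)$disks
  vis <- setdiff(which(kps$visible[1:64]), drop)
  expect_lt(max(abs(kps$points[vis, ] - truth[vis, 1:2])), 1e-6)
})

test_that("one-to-one matching equals the brute-force optimum", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(4:7, 1); m <- n + sample(0:2, 1)
    cost <- matrix(runif(n * m, 0, 10), n, m)
    sol <- match_one_to_one(cost)
    got <- sum(cost[cbind(seq_len(n), sol)])
    expect_equal(got, brute_force_assignment_cost(cost), tolerance = 1e-12)
  }
})

test_that("full-frame mapping inverts the crop/upscale bookkeeping", {
  rec <- structure(list(crop = matrix(0, 10, 10), offset = c(x = 98, y = 98),
                        margin = 2), class = "crop_record")
  kps <- keypoint_set(rbind(c(8, 8), c(NA, NA)), c(TRUE, FALSE), "upscaled-crop")
  out <- to_full_frame(kps, rec, 4)
  expect_equal(unname(out$points[1, ]), c(100, 100))
  expect_equal(out$frame, "full")
  # invisible points stay invisible and untouched
  expect_false(out$visible[2])
  expect_true(all(is.na(out$points[2, ])))
  # frame-tag contract
  expect_error(to_full_frame(out, rec, 4), "upscaled-crop")
  # round trip
  pts <- cbind(runif(5, 0, 40), runif(5, 0, 40))
  k2 <- keypoint_set(pts, rep(TRUE, 5), "upscaled-crop")
  f2 <- to_full_frame(k2, rec, 4)
  back <- cbind((f2$points[, 1] - 98) * 4, (f2$points[, 2] - 98) * 4)
  expect_lt(max(abs(back - pts)), 1e-12)
})

test_that("classical 2D pose recovers ground truth within a pixel", {
  rig <- test_rig()
  for (z in c(0.40, 0.60)) {
    pair <- render_stereo(rig, scene_at(z)$state, clean_settings())
    dets <- detect_grid(pair$left$image, detector_config("classical"))
    kps <- estimate_pose_2d(pair$left$image, dets[[1]], grid_spec())
    expect_equal(nrow(kps$points), 68)
    vis <- which(kps$visible[1:64])
    expect_gte(length(vis), 61)
    err <- sqrt(rowSums((kps$points[vis, ] - pair$left$keypoints[vis, ])^2))
    expect_gte(mean(err < 1.0), 0.95)
  }
})

test_that("oracle pose plugin returns the stored labels", {
  pair <- pair_40cm()
  dets <- detect_grid(pair$left$image, detector_config("classical"))
  kps <- estimate_pose_2d(pair$left$image, dets[[1]], grid_spec(),
                          pose_kind = "oracle", truth = pair$left)
  expect_equal(kps$points, unname(pair$left$keypoints), tolerance = 1e-12)
})
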