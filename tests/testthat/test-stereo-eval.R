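# Triangulation of keypoint sets, outlier filtering, false-positive
# statistics, the relative-pose error protocol and the experiment harness.

test_that("exact stereo keypoints triangulate back to the grid state", {
  rig <- test_rig()
  st <- scene_at(0.45)$state
  kp <- truth_keypoints(rig, st)
  m <- triangulate_grid(rig, kp$left, kp$right)
  expect_true(all(m$valid))
  expect_lt(max(abs(m$points3d - st$points3d)), 1e-6)
})

test_that("per-index invisibility propagates without touching the rest", {
  rig <- test_rig()
  st <- scene_at(0.45)$state
  kp <- truth_keypoints(rig, st)
  kp$right$visible[5] <- FALSE
  m <- triangulate_grid(rig, kp$left, kp$right)
  expect_false(m$valid[5])
  expect_true(all(is.na(m$points3d[5, ])))
  expect_true(all(m$valid[-5]))
  expect_lt(max(abs(m$points3d[-5, ] - st$points3d[-5, ])), 1e-6)

  kp$left$visible[] <- FALSE
  expect_error(triangulate_grid(rig, kp$left, kp$right), "fewer than 4")
})

test_that("triangulation under pixel noise matches first-order propagation", {
  # the 600 px worked-example rig: the closed-form bound is stated for it
  rig <- default_rig(fx = 600)
  rig$rectified <- TRUE
  st <- scene_at(0.40)$state
  kp <- truth_keypoints(rig, st)
  sigma <- 0.5
  errs <- numeric(50); zerrs <- numeric(50)
  for (s in 1:50) {
    set.seed(400 + s)
    kl <- kp$left; kr <- kp$right
    kl$points <- kl$points + matrix(rnorm(136, 0, sigma), ncol = 2)
    kr$points <- kr$points + matrix(rnorm(136, 0, sigma), ncol = 2)
    m <- triangulate_grid(rig, kl, kr)
    d <- m$points3d - st$points3d
    errs[s] <- mean(sqrt(rowSums(d^2)))
    zerrs[s] <- mean(abs(d[, 3]))
  }
  expect_lt(mean(errs), 0.002)   # < 2 mm mean 3D error at 40 cm
  # closed form: sd(z) = z^2 * sigma_d / (f b), sigma_d = sqrt(2) sigma,
  # and E|dz| = sqrt(2/pi) sd(z)
  z <- 0.40
  theo <- sqrt(2 / pi) * z^2 * sqrt(2) * sigma / (rig$left$fx * 0.098)
  expect_lt(abs(mean(zerrs) - theo) / theo, 0.25)
})

test_that("median filter rejects displaced measurements, strict boundary", {
  base <- matrix(rep(c(0, 0, 0.4), each = 68), 68, 3)
  same <- replicate(10, fake_measurement(base), simplify = FALSE)
  out <- median_outlier_filter(same)
  expect_length(out$kept, 10)
  expect_length(out$rejected, 0)

  displaced <- fake_measurement(base + rep(c(0.15, 0, 0), each = 68))
  out2 <- median_outlier_filter(c(same[1:9], list(displaced)))
  expect_length(out2$rejected, 1)
  expect_equal(length(out2$kept) + length(out2$rejected), 10)

  # exactly at the threshold: kept (strict > rejects)
  at_thresh <- fake_measurement(base + rep(c(0.10, 0, 0), each = 68))
  out3 <- median_outlier_filter(c(same[1:9], list(at_thresh)))
  expect_length(out3$rejected, 0)
  expect_error(median_outlier_filter(list()), "1 measurement")
})

test_that("false-positive rate is rejected/considered with a defined 0/0", {
  expect_equal(as.numeric(false_positive_rate(150, 9)), 0.06)
  expect_equal(as.numeric(false_positive_rate(100, 0)), 0)
  expect_equal(as.numeric(false_positive_rate(100, 100)), 1)
  expect_warning(r <- false_positive_rate(0, 0), "0 considered")
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  expect_error(false_positive_rate(5, 6), "rejected")
})

test_that("relative-pose error matches its definition and an independent oracle", {
  n <- 68
  set.seed(21)
  ref_t <- matrix(rnorm(3 * n, sd = 0.02), n, 3) + rep(c(0, 0, 0.4), each = n)
  pos_t <- ref_t + rep(c(0.05, 0, 0.2), each = n)
  ref_m <- ref_t + matrix(rnorm(3 * n, sd = 1e-3), n, 3)
  pos_m <- pos_t + matrix(rnorm(3 * n, sd = 1e-3), n, 3)
  err <- relative_pose_error(fake_measurement(ref_m), fake_measurement(pos_m),
                             fake_measurement(ref_t), fake_measurement(pos_t))
  # independent re-implementation, element by element
  oracle <- vapply(seq_len(n), function(i) {
    dm <- sqrt(sum((pos_m[i, ] - ref_m[i, ])^2))
    dt <- sqrt(sum((pos_t[i, ] - ref_t[i, ])^2))
    abs(dm - dt)
  }, 0)
  expect_lt(max(abs(err - oracle)), 1e-12)

  # perfect measurement: zero error
  zero <- relative_pose_error(fake_measurement(ref_t), fake_measurement(pos_t),
                              fake_measurement(ref_t), fake_measurement(pos_t))
  expect_true(all(zero == 0))

  # worked example: truth displacement 100 mm, measured 101 mm -> 1 mm
  a <- matrix(rep(c(0, 0, 0.4), each = 1), 1, 3)
  b <- a + c(0, 0, 0.100)
  bm <- a + c(0, 0, 0.101)
  e1 <- relative_pose_error(fake_measurement(a, TRUE), fake_measurement(bm, TRUE),
                            fake_measurement(a, TRUE), fake_measurement(b, TRUE))
  expect_equal(e1, 0.001, tolerance = 1e-12)

  # mismatched validity masks are a contract error
  bad <- fake_measurement(ref_m, valid = c(FALSE, rep(TRUE, n - 1)))
  expect_error(relative_pose_error(bad, fake_measurement(pos_m),
                                   fake_measurement(ref_t), fake_measurement(pos_t)),
               "validity")
})

test_that("electrode heatmap normalizes to a unit maximum", {
  uni <- electrode_heatmap(rep(2.5, 64))
  expect_true(all(uni == 1))
  single <- electrode_heatmap(c(3, rep(0, 63)))
  expect_equal(single[1, 1], 1)
  expect_equal(sum(single), 1)
  set.seed(8)
  e <- runif(64)
  hm <- electrode_heatmap(e)
  expect_equal(as.vector(t(hm)), e / max(e), tolerance = 1e-12)
  expect_equal(max(hm), 1)
  zero <- electrode_heatmap(rep(0, 64))
  expect_true(attr(zero, "all_zero"))
  expect_true(all(zero == 0))
  expect_error(electrode_heatmap(rep(1, 10)), "per electrode")
})

small_config <- function(...) {
  cfg <- default_config()
  cfg$experiment$depths <- c(0.40, 0.60)
  cfg$experiment$n_lateral <- 1L
  cfg$experiment$frames_per_position <- 2L
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], mods[[nm]])
  cfg
}

test_that("zero-noise oracle run has vanishing relative errors", {
  cfg <- small_config(detector = list(kind = "oracle"),
                      pose = list(kind = "oracle"),
                      render = list(noise_sigma = 0))
  rep <- run_experiment(cfg, seed = 2)
  pp <- rep$per_position
  expect_true(all(pp$mean_error_m[!pp$is_reference] < 1e-6))
  expect_equal(pp$mean_error_m[pp$is_reference], 0)
})

test_that("experiment runs are reproducible and conserve frame counts", {
  cfg <- small_config()
  a <- run_experiment(cfg, seed = 7)
  b <- run_experiment(cfg, seed = 7)
  expect_equal(a$per_position, b$per_position, tolerance = 1e-12)
  expect_equal(a$totals, b$totals)
  pp <- a$per_position
  # conservation at both filtering stages
  expect_true(all(pp$n_considered + pp$n_rejected_detect == pp$n_frames))
  expect_true(all(pp$n_kept + pp$n_rejected_outlier == pp$n_considered))
})

test_that("experiment report writes CSV and JSON artifacts", {
  cfg <- small_config()
  rep <- run_experiment(cfg, seed = 3)
  d <- tempfile(); dir.create(d)
  report_to_files(rep, d)
  expect_true(file.exists(file.path(d, "per_position.csv")))
  expect_true(file.exists(file.path(d, "report.json")))
  hm <- as.matrix(read.csv(file.path(d, "heatmap.csv"), header = FALSE))
  expect_equal(dim(hm), c(8, 8))
  back <- read.csv(file.path(d, "per_position.csv"))
  expect_equal(nrow(back), nrow(rep$per_position))
  unlink(d, recursive = TRUE)
})
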