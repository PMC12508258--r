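test_that("detect_particles handles blank and constructed images exactly", {
  p <- detection_params(
    threshold = 10, measure_dilate_px = 0,
    presmooth_sigma = 0
  )

  expect_equal(nrow(detect_particles(matrix(0, 32, 32), p)), 0)
  expect_error(detect_particles(matrix(numeric(0), 0, 0), p), "empty")
  expect_error(
    detect_particles(matrix(0, 8, 8), detection_params()),
    "threshold"
  )

  # two 12-px blobs and one 5-px blob above threshold -> 2 particles
  img <- matrix(0, 40, 40)
  img[2:5, 2:4] <- 50 # 12 px
  img[20:23, 20:22] <- 50 # 12 px
  img[30, 30:34] <- 50 # 5 px
  det <- detect_particles(img, p)
  expect_equal(nrow(det), 2)
  expect_equal(sort(det$area_px), c(12, 12))

  # 12-px ring enclosing a 2-px hole: fill_holes gives area 14
  ring <- matrix(0, 20, 20)
  ring[5:7, 5:8] <- 50 # 3 x 4 box
  ring[6, 6:7] <- 0 # 2-px interior hole (ring now 10 px)
  ring[4, 6:7] <- 50 # 2 extra rim pixels -> 12-px ring
  expect_equal(sum(ring > 0), 12)
  det_ring <- detect_particles(ring, p)
  expect_equal(nrow(det_ring), 1)
  expect_equal(det_ring$area_px, 14)
  no_fill <- detection_params(
    threshold = 10, fill_holes = FALSE,
    measure_dilate_px = 0, presmooth_sigma = 0
  )
  expect_equal(detect_particles(ring, no_fill)$area_px, 12)
})

test_that("segmentation matches a brute-force flood fill on random images", {
  p <- detection_params(
    threshold = 120, min_size_px = 4, fill_holes = FALSE,
    separate_touching = FALSE, measure_dilate_px = 0,
    presmooth_sigma = 0
  )
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(sample.int(200, 64 * 64, replace = TRUE), 64, 64)
    det <- detect_particles(img, p)
    oracle <- oracle_detect(img, 120, 4)
    expect_equal(nrow(det), length(oracle))
    got <- lapply(det$mask, sort)
    want <- lapply(oracle, sort)
    expect_setequal(
      vapply(got, paste, character(1), collapse = ","),
      vapply(want, paste, character(1), collapse = ",")
    )
  }
})

test_that("particle counts are non-increasing in the threshold", {
  cfg <- field_config(fov_px = c(128, 128), ev_per_fov = 60)
  f <- sample_field(cfg, seed = 1)
  f <- simulate_staining(f, stain_method("TSA"), seed = 2)
  img <- render_image(f, optics_config(), seed = 3)
  thresholds <- quantile(img, c(0.9, 0.95, 0.99, 0.995, 0.999))
  counts <- vapply(thresholds, function(t) {
    nrow(detect_particles(
      img,
      detection_params(threshold = t, separate_touching = FALSE)
    ))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("particle masks are pairwise disjoint", {
  cfg <- field_config(fov_px = c(192, 192), ev_per_fov = 120)
  f <- sample_field(cfg, seed = 4)
  f <- simulate_staining(f, stain_method("TSA"), seed = 5)
  img <- render_image(f, optics_config(), seed = 6)
  det <- detect_particles(img, detection_params(threshold = 130))
  all_px <- unlist(det$mask)
  expect_equal(length(all_px), length(unique(all_px)))
  expect_true(all(det$area_px >= 10))
})

test_that("threshold calibration satisfies the control criterion", {
  # all-zero control: minimal grid value, zero detections
  zero_cal <- calibrate_threshold(matrix(0, 32, 32))
  expect_equal(zero_cal$threshold, 0)
  expect_equal(zero_cal$control_counts, 0L)

  # 15 equal blobs at 100: calibrated threshold excludes all of them
  ctrl <- matrix(0, 200, 200)
  centres <- expand.grid(r = seq(10, 190, 50), c = seq(10, 190, 60))
  for (i in seq_len(15)) {
    r <- centres$r[i]
    cc <- centres$c[i]
    ctrl[r:(r + 3), cc:(cc + 2)] <- 100
  }
  cal <- calibrate_threshold(ctrl, detection_params(measure_dilate_px = 0))
  expect_gte(cal$threshold, 100)
  p <- detection_params(threshold = cal$threshold)
  expect_equal(nrow(detect_particles(ctrl, p)), 0)

  # every calibration control stays under the bound afterwards
  cfg <- field_config(fov_px = c(192, 192), ev_per_fov = 0)
  ctrls <- lapply(1:3, function(i) {
    f <- sample_field(cfg, seed = i)
    f <- simulate_staining(f, stain_method("TSA"), seed = i)
    render_image(f, optics_config(), seed = i)
  })
  sim_cal <- calibrate_threshold(ctrls)
  expect_true(all(sim_cal$control_counts < 10))
})

test_that("calibrated thresholds transfer to held-out control substrates", {
  res <- run_control_calibration_experiment(
    seed = 7, n_fov = 4,
    field = field_config(fov_px = c(256, 256))
  )
  expect_true(all(res$control_counts < 10))
  expect_lt(res$heldout_count, 10)
})

test_that("maxima counting reproduces prominence semantics", {
  expect_equal(count_maxima(matrix(5, 16, 16), 0), 0)

  # two Gaussian peaks of 200 over a 50 saddle
  xs <- seq(-10, 10, length.out = 41)
  g <- function(mu) 200 * exp(-(xs - mu)^2 / 4)
  prof <- pmax(g(-5), g(5))
  img <- matrix(rep(prof, each = 21), 21, 41)
  expect_equal(count_maxima(img, 100), 2)
  expect_lte(count_maxima(img, 300), 1)

  # tolerance 0 on distinct-valued noise: counts strict local maxima
  set.seed(42)
  noise <- matrix(rnorm(15 * 15), 15, 15)
  n_strict <- 0
  for (i in 1:15) {
    for (j in 1:15) {
      nb <- noise[
        max(1, i - 1):min(15, i + 1),
        max(1, j - 1):min(15, j + 1)
      ]
      if (noise[i, j] == max(nb)) n_strict <- n_strict + 1
    }
  }
  expect_equal(count_maxima(noise, 0), n_strict)
})

test_that("maxima counting matches the brute-force prominence oracle", {
  # distinct pixel values: per-summit prominence is then unambiguous
  # (plateau/tie semantics are pinned by the constructed cases above)
  for (s in 1:10) {
    set.seed(s + 100)
    img <- matrix(sample.int(10000, 12 * 12), 12, 12)
    for (tol in c(0, 5, 15, 30)) {
      expect_equal(
        count_maxima(img, tol),
        oracle_count_maxima(img, tol),
        info = sprintf("seed %d tol %d", s, tol)
      )
    }
  }
})

test_that("noise-tolerance calibration bounds control maxima counts", {
  cfg <- field_config(fov_px = c(256, 256), ev_per_fov = 0)
  ctrls <- lapply(1:3, function(i) {
    f <- sample_field(cfg, seed = i + 20)
    f <- simulate_staining(f, stain_method("TSA"), seed = i + 20)
    render_image(f, optics_config(), seed = i + 20)
  })
  cal <- calibrate_noise_tolerance(ctrls)
  expect_lt(sum(cal$control_counts), 10) # pooled substrate bound
  # smallest admissible tolerance: one grid step lower violates the bound
  pers <- lapply(ctrls, maxima_persistences)
  grid <- sort(unique(unlist(pers)))
  below <- grid[grid < cal$noise_tolerance]
  if (length(below) > 0) {
    pooled_below <- sum(vapply(
      pers, function(p) sum(p > max(below)), integer(1)
    ))
    expect_gte(pooled_below, 10)
  }
})

test_that("detected counts scale with plating concentration", {
  count_at <- function(scale, seed) {
    # sparse base density so the [8x] field stays spatially resolvable;
    # no NSB, whose additive floor is a separate (tested) effect
    cfg <- field_config(
      fov_px = c(360, 360), ev_per_fov = 30,
      concentration_scale = scale, nsb_per_fov = 0
    )
    f <- sample_field(cfg, seed = seed)
    f <- simulate_staining(f, stain_method("TSA"), seed = seed + 1)
    img <- render_image(f, optics_config(), seed = seed + 2)
    nrow(detect_particles(img, detection_params(threshold = 130)))
  }
  n1 <- mean(vapply(1:4, function(s) count_at(1, 30 + s), integer(1)))
  n8 <- mean(vapply(1:4, function(s) count_at(8, 60 + s), integer(1)))
  expect_lt(abs(n8 / n1 - 8) / 8, 0.25)
})
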