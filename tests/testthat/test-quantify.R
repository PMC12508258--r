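test_that("intensity distributions and dynamic ranges follow the definitions", {
  expect_equal(dynamic_range(c(5, 5, 5)), 0)
  expect_equal(dynamic_range(c(48, 96)), 48)
  expect_error(intensity_distribution(numeric(0)))

  d <- intensity_distribution(c(1, 2, 3, 100), truncation = c(0, 0.9))
  expect_equal(d$dynamic_range, 2) # 100 truncated away
  expect_equal(d$n, 4)

  # translation invariance
  v <- rlnorm(200, 5, 1)
  expect_equal(dynamic_range(v + 1000), dynamic_range(v))
})

test_that("normalized mean intensity divides by area and time", {
  expect_equal(normalized_mean_intensity(100, 10, 1), 10)
  expect_equal(normalized_mean_intensity(100, 10, 2), 5)
  expect_error(normalized_mean_intensity(100, 0, 1), "positive")
  expect_error(normalized_mean_intensity(100, 10, 0), "positive")
})

test_that("normalized intensity is exposure-invariant in expectation", {
  # same emitting cell imaged at tau and 2 tau: integrated scales with
  # exposure, so integrated / area / exposure stays put
  cfg <- field_config(
    fov_px = c(128, 128), ev_per_fov = 0, nsb_per_fov = 0,
    markers = list(STEAM = copy_lognormal()),
    cells = cell_population(n_ctc = 3, n_wbc = 0)
  )
  f <- sample_field(cfg, seed = 1)
  f <- simulate_staining(f, stain_method("TSA"), "STEAM", seed = 2)
  norm_at <- function(expo, seed) {
    op <- optics_config(exposure = expo, read_noise_sd = 0)
    img <- render_image(f, op, seed = seed)
    det <- detect_particles(img, detection_params(
      threshold = op$offset + 30 * expo / 300,
      aggregate_area_px = Inf, separate_touching = FALSE,
      min_size_px = 30
    ))
    mean(normalized_mean_intensity(det$integrated, det$area_px, expo))
  }
  n1 <- mean(vapply(1:4, function(s) norm_at(300, s), numeric(1)))
  n2 <- mean(vapply(1:4, function(s) norm_at(600, s + 10), numeric(1)))
  expect_lt(abs(n2 / n1 - 1), 0.2)
})

test_that("fold changes reproduce the printed amplification arithmetic", {
  expect_equal(fold_change(607, 95), 6.4)
  expect_equal(fold_change(607, 143), 4.2)
  expect_equal(fold_change(5, 5), 1)
  expect_error(fold_change(1, 0), "positive")
  # reciprocity holds exactly before rounding
  expect_equal(
    fold_change(607, 95, digits = NULL) * fold_change(95, 607, digits = NULL),
    1
  )
  # dynamic-range ratio rounds to 3
  expect_equal(round(fold_change(7150, 2200, digits = NULL)), 3)
})

test_that("integrated intensity equals the brute-force mask sum", {
  img <- matrix(0, 24, 24)
  img[10:11, 10:11] <- 1
  p <- detection_params(
    threshold = 0.5, min_size_px = 1,
    measure_dilate_px = 0, presmooth_sigma = 0
  )
  det <- detect_particles(img, p)
  expect_equal(det$integrated, 4) # 4 px of 1, zero background

  # random image: aperture sum matches direct indexing
  set.seed(9)
  img2 <- matrix(runif(24 * 24, 100, 200), 24, 24)
  m <- det$mask[[1]]
  remeasured <- measure_particles(det, img2, dilate_px = 0)
  bg <- attr(remeasured, "background")
  expect_equal(remeasured$integrated, sum(img2[m]) - bg * length(m))
  # detected-particle totals never exceed the above-background total
  expect_lte(
    sum(pmax(remeasured$integrated, 0)),
    sum(img2) - min(img2) * length(img2)
  )
})

test_that("population intensity ordering DS < PSS < TSA survives detection", {
  res <- run_amplification_experiment(
    seed = 3, n_fov = 1,
    field = field_config(fov_px = c(256, 256), ev_per_fov = 250)
  )
  s <- res$summary
  expect_lt(
    s$mean_integrated[s$method == "DS"],
    s$mean_integrated[s$method == "PSS"]
  )
  expect_lt(
    s$mean_integrated[s$method == "PSS"],
    s$mean_integrated[s$method == "TSA"]
  )
})

test_that("stability profiles recover the bleaching law from masks at t0", {
  op <- optics_config(read_noise_sd = 0, background_rate = 0.005)
  cfg <- field_config(
    fov_px = c(256, 256), ev_per_fov = 120,
    nsb_per_fov = 0
  )
  f <- sample_field(cfg, seed = 70)
  k <- 0.4
  f <- simulate_staining(f, stain_method("TSA", bleach_rate = k), seed = 71)
  ts <- render_timeseries(f, op, timepoints = c(0, 1, 3, 5), seed = 72)
  prof <- stability_profile(ts, params = detection_params(threshold = 120))
  expect_equal(prof$summary$retention[1], 1)
  for (j in 2:4) {
    t <- prof$summary$timepoint[j]
    expect_lt(abs(prof$summary$retention[j] - exp(-k * t)), 0.08)
  }
  # histograms share bin edges and cover every timepoint
  expect_equal(
    nrow(prof$histograms),
    4 * (length(prof$bin_edges) - 1)
  )

  # zero-bleach series: retention about 1 throughout
  f0 <- simulate_staining(
    f, stain_method("TSA", bleach_rate = 0),
    seed = 73
  )
  ts0 <- render_timeseries(f0, op, timepoints = c(0, 5), seed = 74)
  prof0 <- stability_profile(ts0, params = detection_params(threshold = 120))
  expect_lt(abs(prof0$summary$retention[2] - 1), 0.05)
})

test_that("per-FOV count summaries use the standard sample formulas", {
  cf <- counts_per_fov(c(2300, 2200, 2400, 2100))
  s <- glance(cf)
  expect_equal(s$mean, 2250)
  expect_equal(s$sd, sd(c(2300, 2200, 2400, 2100)))

  empty <- counts_per_fov(list(
    empty_a = tibble::tibble(id = integer()),
    empty_b = tibble::tibble(id = integer())
  ))
  expect_equal(glance(empty)$mean, 0)
  expect_equal(glance(empty)$sd, 0)
})
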