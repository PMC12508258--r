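test_that("field sampling is deterministic and respects the configuration", {
  cfg <- field_config(ev_per_fov = 60, nsb_per_fov = 5)
  f1 <- sample_field(cfg, seed = 7)
  f2 <- sample_field(cfg, seed = 7)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  # zero-rate Poisson: no particles at all
  empty <- sample_field(
    field_config(ev_per_fov = 0, nsb_per_fov = 0),
    seed = 1
  )
  expect_equal(nrow(empty), 0)

  # particle centres inside the FOV
  expect_true(all(f1$x >= 0.5 & f1$x <= cfg$fov_px[2] + 0.5))
  expect_true(all(f1$y >= 0.5 & f1$y <= cfg$fov_px[1] + 0.5))
  expect_true(all(f1$copies_CD63[f1$kind == "NSB"] == 0))
})

test_that("expected EV counts scale with the plating concentration", {
  cfg1 <- field_config(ev_per_fov = 100, nsb_per_fov = 0)
  cfg8 <- field_config(
    ev_per_fov = 100, concentration_scale = 8,
    nsb_per_fov = 0
  )
  n1 <- vapply(
    1:200, function(s) nrow(sample_field(cfg1, seed = s)), integer(1)
  )
  n8 <- vapply(
    1:200, function(s) nrow(sample_field(cfg8, seed = s + 1000)), integer(1)
  )
  ratio <- mean(n8) / mean(n1)
  expect_gt(ratio, 7.2)
  expect_lt(ratio, 8.8)
})

test_that("staining model obeys its degenerate and asymptotic contracts", {
  cfg <- field_config(
    ev_per_fov = 50,
    markers = list(CD63 = copy_fixed(0))
  )
  f <- sample_field(cfg, seed = 1)
  for (m in c("DS", "PSS", "TSA")) {
    sf <- simulate_staining(f, stain_method(m), seed = 2)
    expect_true(all(sf$rate[sf$kind == "EV"] == 0))
  }

  # deterministic DS: label efficiency 1, one fluor per primary
  cfg2 <- field_config(ev_per_fov = 50, markers = list(CD63 = copy_lognormal()))
  f2 <- sample_field(cfg2, seed = 3)
  ds <- stain_method("DS",
    label_efficiency = 1, fluors_per_primary = 1,
    photon_rate_per_fluor = 0.1
  )
  sf2 <- simulate_staining(f2, ds, seed = 4)
  ev <- sf2$kind == "EV"
  expect_equal(sf2$rate[ev], sf2$copies_CD63[ev] * 0.1)

  expect_error(
    simulate_staining(f2, ds, marker = "nope", seed = 1),
    "unknown marker 'nope'"
  )
})

test_that("TSA amplification converges to tyramide_mean x secondaries", {
  cfg <- field_config(
    ev_per_fov = 10000,
    markers = list(CD63 = copy_fixed(20)), nsb_per_fov = 0
  )
  f <- sample_field(cfg, seed = 5)
  tsa <- stain_method("TSA")
  ds <- stain_method("DS")
  r_tsa <- simulate_staining(f, tsa, seed = 6)$rate
  r_ds <- simulate_staining(f, ds, seed = 7)$rate
  expected <- tsa$tyramide_mean * tsa$secondaries_per_primary
  observed <- mean(r_tsa) / mean(r_ds)
  expect_lt(abs(observed - expected) / expected, 0.05)
})

test_that("method ordering DS < PSS < TSA holds on matched fields", {
  cfg <- field_config(ev_per_fov = 2000, nsb_per_fov = 0)
  f <- sample_field(cfg, seed = 8)
  means <- vapply(c("DS", "PSS", "TSA"), function(m) {
    mean(simulate_staining(f, stain_method(m), seed = 9)$rate)
  }, numeric(1))
  expect_lt(means[["DS"]], means[["PSS"]])
  expect_lt(means[["PSS"]], means[["TSA"]])
})

test_that("rendering conserves photons and responds linearly to exposure", {
  op <- optics_config(read_noise_sd = 0, background_rate = 0, offset = 50)
  cfg <- field_config(
    fov_px = c(128, 128), ev_per_fov = 40,
    nsb_per_fov = 0
  )
  f <- sample_field(cfg, seed = 10)
  f <- simulate_staining(f, stain_method("TSA"), seed = 11)

  # all rates zero, no noise, no background -> flat image at offset
  f0 <- f
  f0$rate <- 0
  img0 <- render_image(f0, op, seed = 12)
  expect_true(all(img0 == op$offset))

  # photon conservation within 3 sigma of the Poisson total
  img <- render_image(f, op, seed = 13)
  total <- sum(img) - op$offset * length(img)
  expected <- op$gain * op$exposure * sum(f$rate)
  sd3 <- 3 * op$gain * sqrt(expected / op$gain)
  expect_lt(abs(total - expected), sd3 + 3 * length(img) * 0.5)

  # doubling the exposure doubles the expected above-offset signal
  op2 <- op
  op2$exposure <- 2 * op$exposure
  img2 <- render_image(f, op2, seed = 14)
  total2 <- sum(img2) - op$offset * length(img2)
  expect_lt(abs(total2 / total - 2), 0.1)
})

test_that("per-particle expected signal is monotone in the generative knobs", {
  cfg <- function(c) {
    field_config(
      ev_per_fov = 4000,
      markers = list(CD63 = copy_fixed(c)), nsb_per_fov = 0
    )
  }
  mean_rate <- function(copies, eff = 0.8, tyr = 4, seed = 20) {
    f <- sample_field(cfg(copies), seed = seed)
    s <- stain_method("TSA", label_efficiency = eff, tyramide_mean = tyr)
    mean(simulate_staining(f, s, seed = seed + 1)$rate)
  }
  expect_lt(mean_rate(10), mean_rate(30))
  expect_lt(mean_rate(20, eff = 0.4), mean_rate(20, eff = 0.9))
  expect_lt(mean_rate(20, tyr = 2), mean_rate(20, tyr = 6))
})

test_that("bleaching decays the rendered signal as exp(-kt)", {
  op <- optics_config(read_noise_sd = 0, background_rate = 0.005)
  cfg <- field_config(
    fov_px = c(256, 256), ev_per_fov = 150,
    nsb_per_fov = 0
  )
  f <- sample_field(cfg, seed = 30)
  k <- 0.5
  f <- simulate_staining(
    f, stain_method("PSS", bleach_rate = k),
    seed = 31
  )
  ts <- render_timeseries(f, op, timepoints = c(0, 1, 3), seed = 32)
  above <- function(j) {
    img <- frame(ts, 1, j)
    sum(img) - op$offset * length(img) -
      op$gain * op$background_rate * op$exposure * length(img)
  }
  for (j in 2:3) {
    t <- ts$timepoints[j]
    expect_lt(abs(above(j) / above(1) - exp(-k * t)), 0.05)
  }

  expect_error(
    render_timeseries(f, op, timepoints = c(1, 0, 3), seed = 1),
    "ascending"
  )

  # zero bleach: statistically identical frames
  f0 <- simulate_staining(
    f, stain_method("PSS", bleach_rate = 0),
    seed = 33
  )
  ts0 <- render_timeseries(f0, op, timepoints = c(0, 5), seed = 34)
  r <- sum(frame(ts0, 1, 2)) / sum(frame(ts0, 1, 1))
  expect_lt(abs(r - 1), 0.01)
})

test_that("direct staining of EVs loses most signal within one minute", {
  op <- optics_config(read_noise_sd = 0, background_rate = 0.005)
  cfg <- field_config(
    fov_px = c(256, 256), ev_per_fov = 150,
    nsb_per_fov = 0
  )
  f <- sample_field(cfg, seed = 40)
  f <- simulate_staining(f, stain_method("DS"), seed = 41)
  ts <- render_timeseries(f, op, timepoints = c(0, 1), seed = 42)
  above <- function(j) {
    img <- frame(ts, 1, j)
    sum(img) - op$offset * length(img) -
      op$gain * op$background_rate * op$exposure * length(img)
  }
  expect_lt(above(2) / above(1), 0.5)
})

test_that("two-plex cross-reaction frequency follows the effective fraction", {
  cfg <- field_config(
    ev_per_fov = 10000, nsb_per_fov = 0,
    markers = list(A = copy_lognormal(), B = copy_lognormal())
  )
  f <- sample_field(cfg, seed = 50)
  tsa <- stain_method("TSA")

  mk <- function(fr, quench, qe = 0.5, seed = 51) {
    tp <- twoplex_config(
      channel_a_marker = "A", channel_b_marker = "B",
      cross_react_fraction = fr, quench_applied = quench,
      quench_efficiency = qe
    )
    simulate_twoplex(f, tsa, tsa, tp, seed = seed, render = FALSE)$truth
  }

  expect_equal(sum(mk(0, FALSE)$spurious), 0)
  expect_equal(sum(mk(0.5, TRUE, qe = 1)$spurious), 0)

  tr <- mk(0.2, FALSE)
  frac <- mean(tr$spurious[tr$kind == "EV" & tr$rate_a > 0])
  expect_lt(abs(frac - 0.2), 0.02)

  expect_error(
    twoplex_config(channel_a_marker = "A", channel_b_marker = "A"),
    "distinct"
  )
})

test_that("calibration substrates contain isolated single-antibody events", {
  op <- optics_config(read_noise_sd = 0, background_rate = 0)
  cal0 <- make_calibration_substrate(op, stain_method("TSA"), 0,
    fov_px = c(64, 64), seed = 1
  )
  expect_true(all(cal0$image == op$offset))

  cal <- make_calibration_substrate(op, stain_method("TSA"), 50,
    fov_px = c(256, 256), seed = 2
  )
  expect_equal(nrow(cal$truth), 50)
  # photon conservation of the event field
  total <- sum(cal$image) - op$offset * length(cal$image)
  expected <- op$gain * op$exposure * sum(cal$truth$rate)
  expect_lt(abs(total - expected) / expected, 0.05)

  expect_warning(
    make_calibration_substrate(op, stain_method("TSA"), 5000,
      fov_px = c(64, 64), seed = 3
    ),
    "spacing"
  )
})

test_that("rendered stacks and ground truth are bit-identical across reruns", {
  cfg <- field_config(fov_px = c(96, 96), ev_per_fov = 30)
  f1 <- sample_field(cfg, seed = 60)
  f2 <- sample_field(cfg, seed = 60)
  s1 <- simulate_staining(f1, stain_method("TSA"), seed = 61)
  s2 <- simulate_staining(f2, stain_method("TSA"), seed = 61)
  i1 <- render_image(s1, optics_config(), seed = 62)
  i2 <- render_image(s2, optics_config(), seed = 62)
  expect_identical(i1, i2)
})
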