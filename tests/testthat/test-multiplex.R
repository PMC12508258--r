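test_that("matching handles trivial configurations", {
  a <- toy_particles(c(10, 50), c(10, 50))
  b <- toy_particles(c(100, 140), c(100, 140))
  m <- match_particles(a, b, 3)
  expect_equal(nrow(m$pairs), 0)
  expect_setequal(m$unmatched_a, 1:2)
  expect_setequal(m$unmatched_b, 1:2)

  ident <- match_particles(a, a, 3)
  expect_equal(nrow(ident$pairs), 2)
  expect_true(all(ident$pairs$distance == 0))

  expect_error(match_particles(a, b, -1), ">= 0")
})

test_that("greedy matching agrees with exhaustive assignment", {
  # the ambiguous 3-vs-3 case: one b sits between two a's
  a <- toy_particles(c(10, 13, 30), c(10, 10, 30))
  b <- toy_particles(c(11.4, 29, 50), c(10, 30, 50))
  m <- match_particles(a, b, 3)
  o <- oracle_match(a$x, a$y, b$x, b$y, 3)
  expect_equal(nrow(m$pairs), o$n)
  expect_equal(
    sort(paste(m$pairs$a_id, m$pairs$b_id)),
    sort(paste(o$pairs$a, o$pairs$b))
  )

  # randomized well-separated pairs plus unmatched extras
  for (s in 1:15) {
    set.seed(s)
    n_pairs <- sample(1:3, 1)
    centres_x <- seq(10, 90, length.out = 4)[1:n_pairs]
    centres_y <- seq(10, 90, length.out = 4)[1:n_pairs]
    ax <- centres_x + runif(n_pairs, -0.8, 0.8)
    ay <- centres_y + runif(n_pairs, -0.8, 0.8)
    bx <- centres_x + runif(n_pairs, -0.8, 0.8)
    by <- centres_y + runif(n_pairs, -0.8, 0.8)
    # extras far away
    ax <- c(ax, 150)
    ay <- c(ay, 150)
    bx <- c(bx, 200, 210)
    by <- c(by, 200, 210)
    m <- match_particles(toy_particles(ax, ay), toy_particles(bx, by), 3)
    o <- oracle_match(ax, ay, bx, by, 3)
    expect_equal(nrow(m$pairs), o$n, info = paste("seed", s))
    expect_equal(sum(m$pairs$distance), o$total, tolerance = 1e-8)
  }
})

test_that("matching is stable under particle permutation", {
  set.seed(5)
  ax <- runif(8, 0, 100)
  ay <- runif(8, 0, 100)
  bx <- ax + runif(8, -1, 1)
  by <- ay + runif(8, -1, 1)
  a <- toy_particles(ax, ay)
  b <- toy_particles(bx, by)
  m1 <- match_particles(a, b, 3)
  perm <- sample(8)
  a2 <- a[perm, ]
  m2 <- match_particles(a2, b, 3)
  expect_equal(
    dplyr::arrange(m1$pairs, a_id)[c("a_id", "b_id")],
    dplyr::arrange(m2$pairs, a_id)[c("a_id", "b_id")]
  )
})

test_that("positivity classes partition the detections", {
  a <- toy_particles(
    c(seq(5, 95, 10), 110, 120), c(seq(5, 95, 10), 110, 120)
  )
  b_match <- toy_particles(
    c(seq(5, 95, 10) + 0.5, 140, 150, 160),
    c(seq(5, 95, 10), 140, 150, 160)
  )
  res <- classify_positivity(match_particles(a, b_match, 3))
  expect_equal(res$n_total, res$n_a_only + res$n_b_only + res$n_double)
  expect_equal(
    res$pct_a_only + res$pct_b_only + res$pct_double, 100,
    tolerance = 1e-9
  )
  expect_equal(res$n_double, 10)
  expect_equal(res$n_a_only, 2)
  expect_equal(res$n_b_only, 3)

  # swapping channels swaps a/b and keeps doubles
  swapped <- classify_positivity(match_particles(b_match, a, 3))
  expect_equal(swapped$n_a_only, res$n_b_only)
  expect_equal(swapped$n_b_only, res$n_a_only)
  expect_equal(swapped$n_double, res$n_double)

  # forced arithmetic: 10/10/10 -> 33.3% each
  far <- function(k) toy_particles(seq(5, 95, 10) + 200 * k, rep(5, 10) + 200 * k)
  aa <- dplyr::bind_rows(toy_particles(seq(5, 95, 10), seq(5, 95, 10)), far(1))
  aa$id <- seq_len(nrow(aa))
  bb <- dplyr::bind_rows(toy_particles(seq(5, 95, 10), seq(5, 95, 10)), far(2))
  bb$id <- seq_len(nrow(bb))
  r2 <- classify_positivity(match_particles(aa, bb, 1))
  expect_equal(r2$pct_double, 100 / 3, tolerance = 1e-9)

  expect_error(
    classify_positivity(match_particles(
      toy_particles(numeric(0), numeric(0)),
      toy_particles(numeric(0), numeric(0)), 3
    )),
    "no particles"
  )
})

test_that("normalized counts reference the complete protocol at 100%", {
  counts <- tibble::tibble(
    condition = rep(c("complete", "probe_only"), each = 4),
    fov = rep(1:4, 2),
    count = c(1000, 1100, 900, 1000, 200, 210, 190, 200)
  )
  norm <- normalized_counts_percent(counts)
  expect_equal(mean(norm$normalized_pct[norm$condition == "complete"]), 100)
  expect_equal(attr(norm, "cross_react_pct"), 20)
  expect_equal(attr(norm, "reference_mean"), 1000)
  expect_error(
    normalized_counts_percent(counts, reference = "missing"),
    "no FOVs"
  )
})

test_that("cross-reactivity estimation is unbiased at the model level", {
  cfg <- field_config(
    ev_per_fov = 400, nsb_per_fov = 0,
    markers = list(A = copy_lognormal(), B = copy_lognormal())
  )
  tsa <- stain_method("TSA")
  for (f_true in c(0.03, 0.20)) {
    tp <- twoplex_config(
      channel_a_marker = "A", channel_b_marker = "B",
      cross_react_fraction = f_true, quench_applied = FALSE
    )
    est <- vapply(1:50, function(s) {
      fld <- sample_field(cfg, seed = s)
      tr <- simulate_twoplex(fld, tsa, tsa, tp,
        seed = s,
        render = FALSE
      )$truth
      stained <- tr$kind == "EV" & tr$rate_a > 0
      mean(tr$spurious[stained])
    }, numeric(1))
    expect_lt(abs(mean(est) - f_true), 0.01)
  }
})

test_that("intensity correlation recovers the generative correlation", {
  expect_equal(intensity_correlation(exp(1:10), exp(1:10)), 1)
  expect_equal(intensity_correlation(exp(1:10), exp(10:1)), -1)
  expect_error(intensity_correlation(1:2, 1:2), "at least 3")
  expect_warning(
    intensity_correlation(rep(2, 5), c(1, 2, 3, 4, 5)),
    "zero variance"
  )

  # bivariate log-normal at r = 0.73, n = 500
  set.seed(123)
  r_true <- 0.73
  z1 <- rnorm(500)
  z2 <- r_true * z1 + sqrt(1 - r_true^2) * rnorm(500)
  int_a <- exp(5 + 0.8 * z1)
  int_b <- exp(6 + 0.8 * z2)
  expect_lt(abs(intensity_correlation(int_a, int_b) - r_true), 0.05)
})
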