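#' Multi-channel, multi-timepoint image stack
#'
#' Lightweight container for rendered or loaded images: a numeric array with
#' dimensions `(height, width, channel, time)` plus acquisition metadata.
#'
#' @param data Numeric array `(H, W, C, T)`, or a matrix (promoted to
#'   `C = T = 1`).
#' @param channels Channel names, length `C`.
#' @param timepoints Acquisition timepoints in minutes, length `T`.
#' @param pixel_size Pixel pitch, nm/px.
#' @param exposure Exposure time in ms (per channel acquisition).
#' @return An `ev_image_stack`.
#' @export
image_stack <- function(data, channels = NULL, timepoints = 0,
                        pixel_size = NA_real_, exposure = NA_real_) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1, 1)
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[3]))
  stopifnot(
    length(channels) == dim(data)[3],
    length(timepoints) == dim(data)[4]
  )
  structure(
    list(
      data = data, channels = channels, timepoints = timepoints,
      pixel_size = pixel_size, exposure = exposure
    ),
    class = "ev_image_stack"
  )
}

#' @export
print.ev_image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(
    "<ev_image_stack> ", d[1], "x", d[2], " px, ", d[3], " channel(s) [",
    paste(x$channels, collapse = ", "), "], ", d[4], " timepoint(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Extract one frame of a stack as a matrix
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param time Timepoint index (not minutes).
#' @return A numeric matrix `(H, W)`.
#' @export
frame <- function(stack, channel = 1, time = 1) {
  stopifnot(inherits(stack, "ev_image_stack"))
  if (is.character(channel)) channel <- match(channel, stack$channels)
  stack$data[, , channel, time]
}

# Add PSF-blurred point sources to a photon-mean image.
# x = column, y = row (1-based pixel-centred); photons = total expected
# photons per source. Pixel-integrated Gaussian, kernel renormalised so the
# stamped flux equals `photons` exactly (photon conservation).
stamp_points <- function(mean_img, x, y, photons, sigma) {
  h <- nrow(mean_img)
  w <- ncol(mean_img)
  r <- max(2L, ceiling(4 * sigma))
  for (i in seq_along(x)) {
    if (photons[i] <= 0) next
    cx <- x[i]
    cy <- y[i]
    cols <- max(1L, floor(cx) - r):min(w, floor(cx) + r)
    rows <- max(1L, floor(cy) - r):min(h, floor(cy) + r)
    kx <- stats::pnorm(cols + 0.5, cx, sigma) - stats::pnorm(cols - 0.5, cx, sigma)
    ky <- stats::pnorm(rows + 0.5, cy, sigma) - stats::pnorm(rows - 0.5, cy, sigma)
    k <- outer(ky, kx)
    s <- sum(k)
    if (s <= 0) next
    mean_img[rows, cols] <- mean_img[rows, cols] + photons[i] * (k / s)
  }
  mean_img
}

# Emission-density image (photons/ms/px) for extended cell objects.
# kind = "ring": emission over the membrane annulus; "nucleus": over the
# nuclear disk. Rates are per-particle totals for rings, per-pixel for nuclei.
cell_emission <- function(h, w, cells, kind = c("ring", "nucleus"),
                          dapi_rate = 1) {
  kind <- match.arg(kind)
  img <- matrix(0, h, w)
  if (nrow(cells) == 0) {
    return(img)
  }
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x[i]
    cy <- cells$y[i]
    r_out <- if (kind == "ring") cells$cell_r_px[i] else cells$nucleus_r_px[i]
    r_in <- if (kind == "ring") cells$nucleus_r_px[i] else 0
    cols <- max(1L, floor(cx - r_out)):min(w, ceiling(cx + r_out))
    rows <- max(1L, floor(cy - r_out)):min(h, ceiling(cy + r_out))
    d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
    sel <- d2 <= r_out^2 & d2 >= r_in^2
    npx <- sum(sel)
    if (npx == 0) next
    dens <- if (kind == "ring") cells$rate[i] / npx else dapi_rate
    img[rows, cols][sel] <- img[rows, cols][sel] + dens
  }
  img
}

# Core renderer: photon means -> Poisson photons -> integer ADU.
render_frame <- function(field, optics, pixel_size, rate_col = "rate",
                         channel = c("marker", "dapi"), decay = 1) {
  channel <- match.arg(channel)
  config <- attr(field, "config")
  h <- config$fov_px[1]
  w <- config$fov_px[2]
  sg <- sigma_px(optics, pixel_size)
  mean_img <- matrix(optics$background_rate * optics$exposure, h, w)

  if (channel == "marker") {
    pts <- field[field$kind %in% c("EV", "NSB"), , drop = FALSE]
    if (nrow(pts) > 0) {
      mean_img <- stamp_points(
        mean_img, pts$x, pts$y,
        pts[[rate_col]] * decay * optics$exposure, sg
      )
    }
    cells <- field[field$kind == "CELL", , drop = FALSE]
    if (nrow(cells) > 0) {
      cells$rate <- cells[[rate_col]]
      em <- cell_emission(h, w, cells, "ring") * decay * optics$exposure
      mean_img <- mean_img + EBImage::gblur(em, sigma = max(sg, 0.5))
    }
  } else {
    cells <- field[field$kind == "CELL", , drop = FALSE]
    if (nrow(cells) > 0) {
      dr <- if (!is.null(config$cells)) config$cells$dapi_rate else 1.5
      em <- cell_emission(h, w, cells, "nucleus", dapi_rate = dr) *
        optics$exposure
      mean_img <- mean_img + EBImage::gblur(em, sigma = max(sg, 0.5))
    }
  }

  photons <- matrix(
    stats::rpois(length(mean_img), pmax(mean_img, 0)), h, w
  )
  adu <- optics$gain * photons + optics$offset
  if (optics$read_noise_sd > 0) {
    adu <- adu + stats::rnorm(length(adu), 0, optics$read_noise_sd)
  }
  matrix(pmax(round(adu), 0), h, w)
}

#' Render a single-timepoint image from a stained field
#'
#' Each sub-diffraction particle (EV, NSB) is rendered as a pixel-integrated
#' Gaussian PSF spot whose total expected photon count is
#' `rate * exposure`; cells are rendered as extended objects (membrane ring
#' in marker channels, nuclear disk in the DAPI channel) convolved with the
#' PSF. Photon shot noise is Poisson, then camera gain, offset and Gaussian
#' read noise are applied and pixel values are rounded to non-negative
#' integer ADU.
#'
#' @param field A stained field from [simulate_staining()] (must carry a
#'   `rate` column).
#' @param optics An [optics_config()].
#' @param seed Integer seed.
#' @param channel `"marker"` (default) or `"dapi"`.
#' @return A numeric matrix `(H, W)` of integer ADU.
#' @export
render_image <- function(field, optics = optics_config(), seed = 1,
                         channel = "marker") {
  stopifnot(inherits(field, "ev_field"))
  if (!"rate" %in% names(field) && channel == "marker") {
    stop("field has no `rate` column; run simulate_staining() first",
      call. = FALSE
    )
  }
  if ("rate" %in% names(field)) {
    stopifnot(all(is.finite(field$rate)), all(field$rate >= 0))
  }
  config <- attr(field, "config")
  set.seed(derive_seed(seed, 3))
  render_frame(field, optics, config$pixel_size, channel = channel)
}

#' Render a photobleaching time series
#'
#' Renders the same stained field at several acquisition timepoints under
#' continuous excitation. Emission rates decay as
#' `rate(t) = rate(0) * exp(-bleach_rate * t)` with the stain's per-minute
#' bleach constant; each frame is otherwise rendered as [render_image()].
#'
#' @param field A stained field (from [simulate_staining()]).
#' @param optics An [optics_config()].
#' @param timepoints Minutes, sorted ascending, first must be 0 (default
#'   `c(0, 1, 3, 5)`).
#' @param seed Integer seed.
#' @return An [image_stack()] with one channel and `length(timepoints)`
#'   frames.
#' @export
render_timeseries <- function(field, optics = optics_config(),
                              timepoints = c(0, 1, 3, 5), seed = 1) {
  stopifnot(inherits(field, "ev_field"), "rate" %in% names(field))
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1] != 0) {
    stop("timepoints must be strictly ascending and start at 0", call. = FALSE)
  }
  stain <- attr(field, "stain")
  k <- if (!is.null(stain)) stain$bleach_rate else 0
  config <- attr(field, "config")
  h <- config$fov_px[1]
  w <- config$fov_px[2]
  arr <- array(0, c(h, w, 1, length(timepoints)))
  for (j in seq_along(timepoints)) {
    set.seed(derive_seed(seed, 10 + j))
    arr[, , 1, j] <- render_frame(
      field, optics, config$pixel_size,
      decay = exp(-k * timepoints[j])
    )
  }
  image_stack(arr,
    channels = attr(field, "marker") %||% "ch1",
    timepoints = timepoints,
    pixel_size = config$pixel_size, exposure = optics$exposure
  )
}

#' Simulate a sequential two-plex staining experiment
#'
#' Stains a field for two markers in sequence (channel A first, channel B
#' second) and models residual-HRP cross-reactivity: each A-stained particle
#' additionally receives spurious channel-B probe signal with probability
#' [effective_cross_reaction()] of the [twoplex_config()]; the spurious
#' signal magnitude is B-typical (drawn from the channel-B staining model at
#' a copy count sampled from the field's B-marker copy distribution). The
#' `condition` argument reproduces the cross-reactivity control experiment:
#' `"complete"` performs both staining cycles, `"probe_only"` performs the
#' A cycle and then exposes the substrate to the channel-B probe with no
#' channel-B antibodies, so all specific B signal is absent and only
#' cross-reacting (plus NSB) signal remains in channel B.
#'
#' @param field An `ev_field`.
#' @param stain_a,stain_b [stain_method()]s for the two cycles.
#' @param twoplex A [twoplex_config()] naming the two markers.
#' @param optics An [optics_config()].
#' @param seed Integer seed.
#' @param condition `"complete"` or `"probe_only"`.
#' @param render If `FALSE`, skip image rendering and return the truth table
#'   only (fast path for model-level checks).
#' @return A list with `stack` (two-channel [image_stack()], `NULL` when
#'   `render = FALSE`), `truth` (tibble: particle id, kind, position, both
#'   rates, `spurious` flag) and `field`.
#' @export
simulate_twoplex <- function(field, stain_a, stain_b,
                             twoplex = twoplex_config(),
                             optics = optics_config(), seed = 1,
                             condition = c("complete", "probe_only"),
                             render = TRUE) {
  condition <- match.arg(condition)
  stopifnot(inherits(field, "ev_field"), inherits(twoplex, "twoplex_config"))
  markers <- field_markers(field)
  for (m in c(twoplex$channel_a_marker, twoplex$channel_b_marker)) {
    if (!m %in% markers) {
      stop("unknown marker '", m, "' in twoplex config", call. = FALSE)
    }
  }
  config <- attr(field, "config")

  fa <- simulate_staining(field, stain_a, twoplex$channel_a_marker,
    seed = derive_seed(seed, 21)
  )
  rate_a <- fa$rate

  if (condition == "complete") {
    fb <- simulate_staining(field, stain_b, twoplex$channel_b_marker,
      seed = derive_seed(seed, 22)
    )
    rate_b_true <- fb$rate
  } else {
    rate_b_true <- numeric(nrow(field))
    # NSB contaminates whichever channel is imaged, antibodies or not
    is_nsb <- field$kind == "NSB"
    if (any(is_nsb)) {
      set.seed(derive_seed(seed, 23))
      rate_b_true[is_nsb] <- stats::rexp(sum(is_nsb), 1 / config$nsb_rate_mean)
    }
  }

  set.seed(derive_seed(seed, 24))
  f_eff <- effective_cross_reaction(twoplex)
  a_stained <- field$kind == "EV" & rate_a > 0
  spurious <- a_stained & stats::runif(nrow(field)) < f_eff
  rate_b_spur <- numeric(nrow(field))
  if (any(spurious)) {
    bdist <- config$markers[[twoplex$channel_b_marker]]
    spur_copies <- draw_copies(bdist, sum(spurious))
    rate_b_spur[spurious] <- staining_rate(spur_copies, stain_b)
  }

  truth <- tibble::tibble(
    id = field$id, kind = field$kind, x = field$x, y = field$y,
    rate_a = rate_a, rate_b_true = rate_b_true,
    rate_b_spurious = rate_b_spur, spurious = spurious
  )

  stack <- NULL
  if (render) {
    fr <- field
    fr$rate <- rate_a
    set.seed(derive_seed(seed, 25))
    img_a <- render_frame(fr, optics, config$pixel_size)
    fr$rate <- rate_b_true + rate_b_spur
    set.seed(derive_seed(seed, 26))
    img_b <- render_frame(fr, optics, config$pixel_size)
    arr <- array(0, c(dim(img_a), 2, 1))
    arr[, , 1, 1] <- img_a
    arr[, , 2, 1] <- img_b
    stack <- image_stack(arr,
      channels = c(twoplex$channel_a_marker, twoplex$channel_b_marker),
      pixel_size = config$pixel_size, exposure = optics$exposure
    )
  }
  list(stack = stack, truth = truth, field = field)
}

#' Simulate a single-antibody calibration substrate
#'
#' Emulates the limit-of-detection calibration experiment: diluted
#' HRP-conjugated secondary antibodies are immobilised on an EV-free
#' substrate (spatially separated) and exposed to the tyramide probe, so
#' each fluorescent spot is the amplified output of a single antibody. Under
#' TSA each event's fluorophore count is `Poisson(tyramide_mean)`; under
#' PSS/DS it is the per-antibody conjugation count.
#'
#' @param optics An [optics_config()].
#' @param stain A [stain_method()].
#' @param n_events Number of immobilised antibodies.
#' @param fov_px FOV size `c(h, w)` in pixels.
#' @param pixel_size Pixel pitch, nm/px.
#' @param seed Integer seed.
#' @return A list with `image` (matrix) and `truth` (tibble of event
#'   positions and rates).
#' @export
make_calibration_substrate <- function(optics = optics_config(),
                                       stain = stain_method("TSA"),
                                       n_events = 300,
                                       fov_px = c(256, 256),
                                       pixel_size = 50,
                                       seed = 1) {
  stopifnot(n_events >= 0)
  h <- fov_px[1]
  w <- fov_px[2]
  sg <- sigma_px(optics, pixel_size)
  if (n_events > 0) {
    expected_nn <- 0.5 / sqrt(n_events / (h * w))
    if (expected_nn <= 4 * sg) {
      warning(
        "expected nearest-neighbour spacing (", round(expected_nn, 1),
        " px) is below 4 x PSF sigma; events may overlap"
      )
    }
  }
  set.seed(derive_seed(seed, 31))
  fluors <- switch(stain$name,
    TSA = stats::rpois(n_events, stain$tyramide_mean),
    PSS = rep(stain$fluors_per_secondary, n_events),
    DS = rep(stain$fluors_per_primary, n_events)
  )
  truth <- tibble::tibble(
    id = seq_len(n_events),
    kind = rep("EV", n_events), # point-source rendering path
    x = stats::runif(n_events, 0.5, w + 0.5),
    y = stats::runif(n_events, 0.5, h + 0.5),
    rate = fluors * stain$photon_rate_per_fluor
  )
  cfg <- field_config(
    fov_px = fov_px, pixel_size = pixel_size, ev_per_fov = 0,
    nsb_per_fov = 0
  )
  fld <- truth
  attr(fld, "config") <- cfg
  class(fld) <- c("ev_field", class(fld))
  set.seed(derive_seed(seed, 32))
  img <- render_frame(fld, optics, pixel_size)
  list(image = img, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
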