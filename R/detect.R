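#' Label connected components of a binary mask (8-connectivity)
#'
#' Union-find connected-component labelling over the foreground pixels of a
#' logical matrix, with 8-connectivity (diagonal neighbours connect). Labels
#' are positive integers in raster order of each component's first pixel.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (length(idx) == 0) {
    return(lab)
  }
  parent <- seq_along(idx)
  pos <- integer(h * w) # map linear pixel index -> rank in idx
  pos[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L

  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  # scan: union each pixel with its already-visited neighbours
  # (up-left, up, up-right, left in column-major raster order)
  for (k in seq_along(idx)) {
    r <- rows[k]
    cc <- cols[k]
    for (d in 1:4) {
      nr <- r + c(-1L, 0L, 1L, -1L)[d]
      nc <- cc + c(-1L, -1L, -1L, 0L)[d]
      if (nr < 1L || nr > h || nc < 1L || nc > w) next
      nk <- pos[(nc - 1L) * h + nr]
      if (nk == 0L) next
      ra <- find(k)
      rb <- find(nk)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# Dilate a set of linear pixel indices by a disc of radius r (px), clipped
# to the image. Used for photometry apertures and background exclusion.
dilate_indices <- function(idx, h, w, r) {
  if (r <= 0 || length(idx) == 0) {
    return(idx)
  }
  dr <- -r:r
  offs <- expand.grid(dr = dr, dc = dr)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2 + 1e-9, ]
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  nr <- outer(rows, offs$dr, "+")
  nc <- outer(cols, offs$dc, "+")
  keep <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
  unique((nc[keep] - 1L) * h + nr[keep])
}

#' Detect and segment particles in a fluorescence image
#'
#' Implements the control-calibrated single-particle segmentation pipeline:
#' binarise strictly above `threshold`, fill interior holes, separate
#' touching objects by intensity watershed (applied only to components whose
#' area exceeds 4x the median component area, to avoid splitting
#' sub-diffraction spots), label with 8-connectivity, and drop components
#' smaller than `min_size_px` (and, optionally, border-touching components
#' or over-large aggregates). Per-particle intensities are measured on the
#' original image over the detection mask dilated by `measure_dilate_px`
#' pixels, with the per-image median of non-particle pixels subtracted as
#' background.
#'
#' @param image Numeric matrix (ADU).
#' @param params A [detection_params()] with a non-`NULL` `threshold`.
#' @return A tibble with class `ev_particles`: `id`, `x`, `y` (centroid),
#'   `area_px`, `integrated` (background-subtracted ADU over the aperture),
#'   `mean_int`, `max_int` (background-subtracted, over the raw mask),
#'   `border` flag, and a `mask` list-column of linear pixel indices.
#'   The background level used is stored in `attr(, "background")`.
#' @examples
#' img <- matrix(0, 32, 32)
#' img[5:8, 5:8] <- 50
#' detect_particles(img, detection_params(threshold = 10))
#' @export
detect_particles <- function(image, params = detection_params()) {
  stopifnot(is.matrix(image))
  if (nrow(image) == 0 || ncol(image) == 0) {
    stop("image has empty dimensions", call. = FALSE)
  }
  if (is.null(params$threshold)) {
    stop("detection threshold is not set; run calibrate_threshold() first",
      call. = FALSE
    )
  }
  h <- nrow(image)
  w <- ncol(image)
  seg_img <- image
  if ((params$presmooth_sigma %||% 0) > 0 && min(h, w) >= 8) {
    seg_img <- EBImage::gblur(image, sigma = params$presmooth_sigma)
  }
  bw <- seg_img > params$threshold
  if (params$fill_holes && any(bw)) {
    bw <- EBImage::fillHull(bw) > 0
  }
  lab <- label_components(bw)

  if (params$separate_touching && max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    cutoff <- 4 * stats::median(areas)
    big <- which(areas > cutoff)
    if (length(big) > 0) {
      tol <- params$noise_tolerance %||% 1
      big_mask <- lab %in% big
      dim(big_mask) <- dim(lab)
      ws_in <- (image + 1) * big_mask # +1 keeps in-mask pixels nonzero
      ws <- EBImage::watershed(EBImage::as.Image(ws_in), tolerance = tol)
      ws <- as.integer(EBImage::imageData(ws))
      dim(ws) <- dim(lab)
      lab[big_mask] <- max(lab) + ws[big_mask]
      lab <- matrix(match(lab, sort(unique(lab[lab > 0])), nomatch = 0L), h, w)
    }
  }

  n <- max(lab)
  if (n == 0) {
    return(empty_particles(image))
  }
  members <- split(which(lab > 0), lab[lab > 0])
  areas <- lengths(members)
  keep <- areas >= params$min_size_px & areas <= params$aggregate_area_px
  members <- members[keep]
  if (length(members) == 0) {
    return(empty_particles(image))
  }

  # background: median over pixels away from any foreground
  excl <- dilate_indices(which(bw), h, w, max(2L, params$measure_dilate_px))
  bg_px <- image[-excl]
  bg <- if (length(bg_px) > 0) stats::median(bg_px) else stats::median(image)

  res <- purrr::map_dfr(members, function(m) {
    rows <- ((m - 1L) %% h) + 1L
    cols <- ((m - 1L) %/% h) + 1L
    ap <- dilate_indices(m, h, w, params$measure_dilate_px)
    tibble::tibble(
      x = mean(cols), y = mean(rows),
      area_px = length(m),
      integrated = sum(image[ap]) - bg * length(ap),
      mean_int = mean(image[m]) - bg,
      max_int = max(image[m]) - bg,
      border = any(rows == 1L | rows == h | cols == 1L | cols == w),
      mask = list(m)
    )
  })
  if (params$exclude_border) res <- res[!res$border, , drop = FALSE]
  res <- dplyr::mutate(res, id = dplyr::row_number(), .before = 1)
  attr(res, "background") <- bg
  class(res) <- c("ev_particles", class(res))
  res
}

empty_particles <- function(image) {
  res <- tibble::tibble(
    id = integer(), x = numeric(), y = numeric(), area_px = integer(),
    integrated = numeric(), mean_int = numeric(), max_int = numeric(),
    border = logical(), mask = list()
  )
  attr(res, "background") <- stats::median(image)
  class(res) <- c("ev_particles", class(res))
  res
}

#' Measure existing particle masks on another image
#'
#' Re-measures the (dilated) masks of a detected particle set on a different
#' image of the same geometry — e.g. a later timepoint or another channel —
#' with that image's own background level subtracted.
#'
#' @param particles An `ev_particles` tibble from [detect_particles()].
#' @param image Numeric matrix with the same dimensions as the detection
#'   image.
#' @param dilate_px Photometry aperture dilation (px).
#' @return The particle tibble with `integrated`, `mean_int`, `max_int`
#'   recomputed on `image`.
#' @export
measure_particles <- function(particles, image, dilate_px = 2) {
  stopifnot(is.matrix(image))
  h <- nrow(image)
  w <- ncol(image)
  if (nrow(particles) == 0) {
    return(particles)
  }
  all_idx <- unlist(particles$mask)
  if (any(all_idx < 1 | all_idx > h * w)) {
    stop("particle masks fall outside the image", call. = FALSE)
  }
  excl <- dilate_indices(all_idx, h, w, max(2L, dilate_px))
  bg <- stats::median(image[-excl])
  out <- particles
  meas <- purrr::map_dfr(particles$mask, function(m) {
    ap <- dilate_indices(m, h, w, dilate_px)
    tibble::tibble(
      integrated = sum(image[ap]) - bg * length(ap),
      mean_int = mean(image[m]) - bg,
      max_int = max(image[m]) - bg
    )
  })
  out$integrated <- meas$integrated
  out$mean_int <- meas$mean_int
  out$max_int <- meas$max_int
  attr(out, "background") <- bg
  out
}

#' Calibrate the detection threshold on EV-free control images
#'
#' Reproduces the control-substrate calibration rule: the intensity
#' threshold is set so that EV-free control substrates yield fewer than
#' `max_control_detections` particles. Candidate thresholds are the unique
#' intensity quantiles of the pooled control images, coarsened to at most
#' `grid_levels` values. Scanning the grid from the highest candidate
#' downwards, the calibrated threshold is the smallest value of the
#' contiguous top block for which **every** control image (or the pooled
#' count, with `pooled = TRUE`) stays strictly below the bound; the scan
#' stops at the first violation, which keeps the choice on the
#' monotone branch of the count-vs-threshold curve.
#'
#' @param control_images A matrix or list of matrices (EV-free controls).
#' @param params A [detection_params()]; its `threshold` is ignored.
#' @param grid_levels Maximum number of candidate thresholds.
#' @param pooled If `TRUE` (default), the "fewer than" bound applies to the
#'   control substrate as a whole, i.e. to the summed count over its FOVs;
#'   with `FALSE` it is enforced strictly per control image. Pooling keeps
#'   the calibrated threshold away from the razor edge where per-FOV counts
#'   sit just under the bound, so it transfers stably to unseen control
#'   FOVs.
#' @return An `ev_calibration` list: `threshold`, `control_counts` at the
#'   chosen threshold, `grid`, `params`.
#' @export
calibrate_threshold <- function(control_images, params = detection_params(),
                                grid_levels = 256, pooled = TRUE) {
  if (is.matrix(control_images)) control_images <- list(control_images)
  stopifnot(length(control_images) >= 1, grid_levels >= 2)
  pool <- unlist(lapply(control_images, as.numeric))
  # candidate grid: pooled intensity quantiles, with geometric resolution
  # in the upper tail where admissible thresholds live (bright outlier
  # pixels are a vanishing quantile fraction, so uniform probs would leave
  # the tail almost unsampled)
  n_bulk <- floor(grid_levels / 4)
  n_tail <- grid_levels - n_bulk
  probs <- c(
    seq(0, 0.9, length.out = n_bulk),
    1 - 10^seq(-1, -7, length.out = n_tail)
  )
  grid <- sort(unique(stats::quantile(
    pool,
    probs = probs, names = FALSE, type = 1
  )))
  # thresholds below the background level are degenerate (the whole image
  # binarises into one giant component, trivially passing the count bound);
  # candidates start at the pooled median
  grid <- grid[grid >= stats::median(pool)]

  count_at <- function(thr) {
    p <- params
    p$threshold <- thr
    vapply(
      control_images,
      function(im) nrow(detect_particles(im, p)), integer(1)
    )
  }
  ok <- function(counts) {
    if (pooled) {
      sum(counts) < params$max_control_detections
    } else {
      all(counts < params$max_control_detections)
    }
  }

  # control detections are non-increasing in the threshold (sparse NSB, no
  # merging regime), so the admissible set is the top block of the grid;
  # binary search its lower edge
  if (!ok(count_at(grid[length(grid)]))) {
    stop(
      "no candidate threshold keeps the controls below ",
      params$max_control_detections,
      " detections; inspect the controls or enlarge the threshold grid",
      call. = FALSE
    )
  }
  lo <- 1L
  hi <- length(grid)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (ok(count_at(grid[mid]))) hi <- mid else lo <- mid + 1L
  }
  chosen <- grid[lo]
  chosen_counts <- count_at(chosen)
  structure(
    list(
      threshold = chosen, control_counts = chosen_counts,
      grid = grid, params = params, pooled = pooled
    ),
    class = "ev_calibration"
  )
}

#' @export
print.ev_calibration <- function(x, ...) {
  cat(
    "<ev_calibration> threshold ", x$threshold, " ADU; control counts: ",
    paste(x$control_counts, collapse = ", "),
    " (bound < ", x$params$max_control_detections, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Topographic persistences of all intensity maxima
#'
#' Descending-intensity region growing with union-find (the watershed-by-
#' flooding dual): every local summit is born a region; when two regions
#' meet at a saddle, the lower summit dies and its persistence
#' (summit minus saddle level) is recorded; the global summit's persistence
#' is the image relief (max minus min). Plateaus yield a single summit.
#' Tolerance-based maxima counting is then a simple comparison against this
#' vector, so one pass serves every candidate tolerance.
#'
#' @param image Numeric matrix.
#' @return Numeric vector of summit persistences (empty for a constant
#'   image).
#' @export
maxima_persistences <- function(image) {
  stopifnot(is.matrix(image))
  storage.mode(image) <- "double"
  .maxima_persistences_cpp(image)
}

#' Count intensity maxima with a noise tolerance
#'
#' ImageJ Find-Maxima-style counting: a local maximum is counted when it
#' stands out from the saddle connecting it to higher ground by strictly
#' more than `noise_tolerance` (topographic prominence / persistence, see
#' [maxima_persistences()]). A constant image has no maxima; plateaus count
#' once. This is the rapid per-FOV particle counting route, robust to
#' touching spots that threshold segmentation would merge.
#'
#' @param image Numeric matrix, or a precomputed [maxima_persistences()]
#'   vector.
#' @param noise_tolerance Non-negative prominence tolerance.
#' @return Integer count of accepted maxima.
#' @export
count_maxima <- function(image, noise_tolerance = 0) {
  stopifnot(noise_tolerance >= 0)
  pers <- if (is.matrix(image)) maxima_persistences(image) else image
  sum(pers > noise_tolerance)
}

#' Calibrate the maxima-counting noise tolerance on control images
#'
#' Chooses the smallest noise tolerance for [count_maxima()] such that
#' every EV-free control image yields strictly fewer than
#' `max_control_detections` maxima (the counting analogue of
#' [calibrate_threshold()]). Maxima counts are non-increasing in the
#' tolerance, so the smallest admissible value on the candidate grid (the
#' unique persistences observed in the controls) is returned.
#'
#' @param control_images A matrix or list of matrices.
#' @param params A [detection_params()] (supplies the control bound).
#' @param pooled As in [calibrate_threshold()]: bound the pooled control
#'   count (default) or each image separately.
#' @return An `ev_calibration`-style list: `noise_tolerance`,
#'   `control_counts`, `params`.
#' @export
calibrate_noise_tolerance <- function(control_images,
                                      params = detection_params(),
                                      pooled = TRUE) {
  if (is.matrix(control_images)) control_images <- list(control_images)
  stopifnot(length(control_images) >= 1)
  pers <- lapply(control_images, maxima_persistences)
  grid <- sort(unique(unlist(pers)))
  counts_at <- function(tol) {
    vapply(pers, function(p) sum(p > tol), integer(1))
  }
  ok <- function(counts) {
    if (pooled) {
      sum(counts) < params$max_control_detections
    } else {
      all(counts < params$max_control_detections)
    }
  }
  # counts are non-increasing in tolerance: binary search the grid
  lo <- 1L
  hi <- length(grid)
  if (!ok(counts_at(grid[hi]))) {
    stop("no tolerance keeps the controls below the bound", call. = FALSE)
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (ok(counts_at(grid[mid]))) {
      hi <- mid
    } else {
      lo <- mid + 1L
    }
  }
  structure(
    list(
      noise_tolerance = grid[lo],
      control_counts = counts_at(grid[lo]),
      params = params
    ),
    class = "ev_tolerance_calibration"
  )
}
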