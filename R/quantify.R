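#' Summarise an intensity distribution
#'
#' Wraps a vector of per-particle integrated intensities (IntI) or per-pixel
#' intensities (PixI) with its summary statistics and dynamic range
#' (max - min), optionally after quantile truncation. Truncation mirrors the
#' practice of reporting ranges of truncated violin plots; the default is no
#' truncation.
#'
#' @param values Numeric vector (ADU).
#' @param truncation Optional `c(lo, hi)` quantile bounds in \[0, 1\] applied
#'   before the range is computed (e.g. `c(0.01, 0.99)`).
#' @return An `ev_intensity_dist` list: `values`, `n`, `mean`, `median`,
#'   `min`, `max`, `dynamic_range`, `truncation`.
#' @examples
#' d <- intensity_distribution(c(48, 60, 96))
#' d$dynamic_range
#' @export
intensity_distribution <- function(values, truncation = NULL) {
  stopifnot(is.numeric(values), length(values) >= 1)
  kept <- values
  if (!is.null(truncation)) {
    stopifnot(length(truncation) == 2, truncation[1] < truncation[2])
    q <- stats::quantile(values, truncation, names = FALSE)
    kept <- values[values >= q[1] & values <= q[2]]
  }
  structure(
    list(
      values = values, n = length(values),
      mean = mean(kept), median = stats::median(kept),
      min = min(kept), max = max(kept),
      dynamic_range = max(kept) - min(kept),
      truncation = truncation
    ),
    class = "ev_intensity_dist"
  )
}

#' @export
print.ev_intensity_dist <- function(x, ...) {
  cat(
    "<ev_intensity_dist> n = ", x$n, ", mean ", signif(x$mean, 4),
    ", range [", signif(x$min, 4), ", ", signif(x$max, 4),
    "], dynamic range ", signif(x$dynamic_range, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Dynamic range of an intensity distribution
#'
#' The difference between the highest and lowest intensity values (after any
#' quantile truncation configured on the distribution).
#'
#' @param dist An [intensity_distribution()] or a numeric vector.
#' @return Non-negative scalar, ADU.
#' @export
dynamic_range <- function(dist) {
  if (is.numeric(dist)) dist <- intensity_distribution(dist)
  stopifnot(inherits(dist, "ev_intensity_dist"))
  dist$dynamic_range
}

#' Normalised mean intensity
#'
#' Divides an object's integrated intensity by its two-dimensional area and
#' by the acquisition time, compensating for object size and per-sample
#' exposure differences.
#'
#' @param integrated Integrated intensity, ADU.
#' @param area Object area, px^2.
#' @param acquisition_time Acquisition time, ms.
#' @return ADU / px^2 / ms.
#' @examples
#' normalized_mean_intensity(100, 10, 2) # 5
#' @export
normalized_mean_intensity <- function(integrated, area, acquisition_time) {
  if (any(area <= 0) || any(acquisition_time <= 0)) {
    stop("area and acquisition_time must be positive", call. = FALSE)
  }
  integrated / area / acquisition_time
}

#' Fold change between two summary values
#'
#' `a / b`, reported by default to one decimal (the precision at which
#' population amplification factors are quoted). Use `digits = NULL` for the
#' exact ratio.
#'
#' @param a,b Summary values (e.g. population mean intensities); `b > 0`.
#' @param digits Decimal places for rounding, or `NULL`.
#' @return The (optionally rounded) ratio.
#' @examples
#' fold_change(607, 95) # 6.4
#' @export
fold_change <- function(a, b, digits = 1) {
  if (any(b <= 0)) stop("fold_change denominator must be positive", call. = FALSE)
  r <- a / b
  if (!is.null(digits)) r <- round(r, digits)
  r
}

#' Signal-stability profile over a photobleaching time series
#'
#' Quantifies signal stability under continuous excitation from a rendered
#' or acquired time series. Particle masks detected at time 0 are used at
#' every timepoint (no re-detection, avoiding survivorship bias as dim
#' particles bleach below threshold). Per timepoint the profile records the
#' histogram of background-subtracted pixel intensities over the t = 0
#' masks (shared bin edges across timepoints) and the mean signal; retention
#' is `mean(t) / mean(0)`.
#'
#' @param stack A single-channel [image_stack()] with >= 2 timepoints.
#' @param particles Particles detected on the t = 0 frame, or `NULL` to
#'   detect them with `params`.
#' @param params [detection_params()] used when `particles` is `NULL`.
#' @param n_bins Number of shared histogram bins.
#' @return An `ev_stability` list: `summary` tibble (`timepoint`,
#'   `mean_signal`, `retention`), `histograms` tibble (`timepoint`,
#'   `bin_mid`, `count`), `bin_edges`, `n_particles`.
#' @export
stability_profile <- function(stack, particles = NULL,
                              params = detection_params(), n_bins = 50) {
  stopifnot(inherits(stack, "ev_image_stack"))
  nt <- dim(stack$data)[4]
  if (nt < 2) stop("need at least two timepoints", call. = FALSE)
  img0 <- frame(stack, 1, 1)
  if (is.null(particles)) particles <- detect_particles(img0, params)
  if (nrow(particles) == 0) {
    stop("no particles detected at time 0", call. = FALSE)
  }
  idx <- unique(unlist(particles$mask))

  frames <- lapply(seq_len(nt), function(j) frame(stack, 1, j))
  bgs <- vapply(
    frames, function(im) stats::median(im[-idx]), numeric(1)
  )
  pix <- lapply(seq_len(nt), function(j) frames[[j]][idx] - bgs[j])

  rng <- range(unlist(pix))
  edges <- seq(rng[1], rng[2] + 1e-9, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2

  hists <- purrr::map_dfr(seq_len(nt), function(j) {
    cts <- graphics::hist(pix[[j]], breaks = edges, plot = FALSE)$counts
    tibble::tibble(
      timepoint = stack$timepoints[j], bin_mid = mids, count = cts
    )
  })
  means <- vapply(pix, mean, numeric(1))
  summary <- tibble::tibble(
    timepoint = stack$timepoints,
    mean_signal = means,
    retention = means / means[1]
  )
  structure(
    list(
      summary = summary, histograms = hists, bin_edges = edges,
      n_particles = nrow(particles)
    ),
    class = "ev_stability"
  )
}

#' @export
print.ev_stability <- function(x, ...) {
  cat("<ev_stability> ", x$n_particles, " particles, retention:\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Per-FOV particle counts with summary statistics
#'
#' @param counts Either a named/unnamed integer vector of per-FOV counts, a
#'   list of `ev_particles` tibbles (counted by rows), or a data frame with
#'   columns `fov` and `count`.
#' @return An `ev_fov_counts` tibble (`fov`, `count`) whose
#'   `attr(, "summary")` holds `mean`, `sd` (standard sample formula) and
#'   `n_fov`; see [glance.ev_fov_counts()].
#' @examples
#' counts_per_fov(c(2300, 2200, 2400, 2100))
#' @export
counts_per_fov <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("fov", "count") %in% names(counts)))
    tab <- tibble::as_tibble(counts[c("fov", "count")])
  } else if (is.list(counts)) {
    tab <- tibble::tibble(
      fov = seq_along(counts),
      count = vapply(counts, nrow, integer(1))
    )
  } else {
    tab <- tibble::tibble(fov = seq_along(counts), count = as.numeric(counts))
  }
  stopifnot(nrow(tab) >= 1)
  attr(tab, "summary") <- tibble::tibble(
    mean = mean(tab$count),
    sd = if (nrow(tab) > 1) stats::sd(tab$count) else 0,
    n_fov = nrow(tab)
  )
  class(tab) <- c("ev_fov_counts", class(tab))
  tab
}
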