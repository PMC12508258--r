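#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a colocalization result
#'
#' @param x An `ev_coloc` from [classify_positivity()].
#' @param ... Unused.
#' @return The matched-pair tibble (`a_id`, `b_id`, `distance`, `int_a`,
#'   `int_b`).
#' @export
tidy.ev_coloc <- function(x, ...) {
  x$pairs %||% tibble::tibble()
}

#' One-row summary of a colocalization result
#'
#' @param x An `ev_coloc`.
#' @param ... Unused.
#' @return One-row tibble with counts, percentages and `r`.
#' @export
glance.ev_coloc <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total, n_a_only = x$n_a_only, n_b_only = x$n_b_only,
    n_double = x$n_double, pct_a_only = x$pct_a_only,
    pct_b_only = x$pct_b_only, pct_double = x$pct_double, r = x$r
  )
}

#' Tidy a stability profile
#'
#' @param x An `ev_stability` from [stability_profile()].
#' @param ... Unused.
#' @return Per-timepoint tibble (`timepoint`, `mean_signal`, `retention`).
#' @export
tidy.ev_stability <- function(x, ...) x$summary

#' Tidy a limit-of-detection result
#'
#' @param x An `ev_lod` from [min_detectable_copies()].
#' @param ... Unused.
#' @return One-row tibble with both peaks and the copy estimate.
#' @export
tidy.ev_lod <- function(x, ...) {
  tibble::tibble(
    antibody_peak = x$antibody_peak, ev_first_peak = x$ev_first_peak,
    min_copies = x$min_copies, bandwidth = x$bandwidth, method = x$method
  )
}

#' @rdname tidy.ev_lod
#' @export
glance.ev_lod <- function(x, ...) tidy.ev_lod(x)

#' One-row summary of a threshold calibration
#'
#' @param x An `ev_calibration` from [calibrate_threshold()].
#' @param ... Unused.
#' @return One-row tibble: threshold, worst control count, bound, grid size.
#' @export
glance.ev_calibration <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    max_control_count = max(x$control_counts),
    bound = x$params$max_control_detections,
    grid_size = length(x$grid),
    pooled = x$pooled
  )
}

#' One-row summary of per-FOV counts
#'
#' @param x An `ev_fov_counts` from [counts_per_fov()].
#' @param ... Unused.
#' @return One-row tibble: `mean`, `sd`, `n_fov`.
#' @export
glance.ev_fov_counts <- function(x, ...) attr(x, "summary")

#' Tidy a cohort table
#'
#' @param x An `ev_cohort` from [cohort_table()].
#' @param ... Unused.
#' @return The cohort tibble as a plain tibble.
#' @export
tidy.ev_cohort <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ev_cohort")
  tibble::as_tibble(out)
}

#' One-row summary of a cohort
#'
#' @param x An `ev_cohort`.
#' @param threshold Positivity threshold forwarded to [detection_rate()].
#' @param ... Unused.
#' @return One-row tibble: sample numbers, detection rate, mean/max
#'   CTCs/mL, healthy baseline.
#' @export
glance.ev_cohort <- function(x, threshold = NULL, ...) {
  pat <- x[x$group == "patient", , drop = FALSE]
  tibble::tibble(
    n_patients = nrow(pat),
    n_healthy = sum(x$group == "healthy"),
    detection_rate_pct = detection_rate(x, threshold),
    mean_ctcs_per_ml = mean(pat$ctcs_per_ml),
    max_ctcs_per_ml = max(pat$ctcs_per_ml),
    healthy_baseline_pct = attr(x, "healthy_baseline_pct")
  )
}
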