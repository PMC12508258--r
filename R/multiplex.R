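#' Match particles across two channels by centroid distance
#'
#' Greedy mutual-nearest-neighbour colocalization: candidate pairs are all
#' (a, b) particle pairs with centroid distance at most `match_radius_px`;
#' pairs are accepted in order of increasing distance (ties broken by
#' smaller a id, then smaller b id), each particle used at most once. The
#' default radius of twice the PSF sigma reflects that sub-diffraction EV
#' positions are PSF-limited.
#'
#' @param particles_a,particles_b `ev_particles` tibbles from the same FOV
#'   (channels assumed registered).
#' @param match_radius_px Matching radius, px.
#' @return An `ev_match` list: `pairs` tibble (`a_id`, `b_id`, `distance`,
#'   `int_a`, `int_b`), `unmatched_a`, `unmatched_b` (id vectors), and the
#'   input tables.
#' @export
match_particles <- function(particles_a, particles_b, match_radius_px = 3) {
  if (match_radius_px < 0) stop("match radius must be >= 0", call. = FALSE)
  na <- nrow(particles_a)
  nb <- nrow(particles_b)
  pairs <- tibble::tibble(
    a_id = integer(), b_id = integer(), distance = numeric(),
    int_a = numeric(), int_b = numeric()
  )
  if (na > 0 && nb > 0) {
    d <- sqrt(
      outer(particles_a$x, particles_b$x, "-")^2 +
        outer(particles_a$y, particles_b$y, "-")^2
    )
    cand <- which(d <= match_radius_px, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ai <- cand[, 1]
      bi <- cand[, 2]
      ord <- order(d[cand], particles_a$id[ai], particles_b$id[bi])
      used_a <- logical(na)
      used_b <- logical(nb)
      keep <- integer(0)
      for (k in ord) {
        if (used_a[ai[k]] || used_b[bi[k]]) next
        used_a[ai[k]] <- TRUE
        used_b[bi[k]] <- TRUE
        keep <- c(keep, k)
      }
      pairs <- tibble::tibble(
        a_id = particles_a$id[ai[keep]],
        b_id = particles_b$id[bi[keep]],
        distance = d[cand][keep],
        int_a = particles_a$integrated[ai[keep]],
        int_b = particles_b$integrated[bi[keep]]
      )
    }
  }
  structure(
    list(
      pairs = pairs,
      unmatched_a = setdiff(particles_a$id, pairs$a_id),
      unmatched_b = setdiff(particles_b$id, pairs$b_id),
      particles_a = particles_a, particles_b = particles_b
    ),
    class = "ev_match"
  )
}

#' Classify matched particles into single/double positives
#'
#' Partitions the union of the two channels' detections into A-only, B-only
#' and double-positive classes and reports their percentages of the total.
#' The inter-channel intensity correlation `r` (see
#' [intensity_correlation()]) is computed over double positives when at
#' least three pairs exist.
#'
#' @param match An `ev_match` from [match_particles()].
#' @return An `ev_coloc` list: `n_total`, `n_a_only`, `n_b_only`,
#'   `n_double`, `pct_a_only`, `pct_b_only`, `pct_double`, `r`, `pairs`.
#' @export
classify_positivity <- function(match) {
  stopifnot(inherits(match, "ev_match"))
  n_double <- nrow(match$pairs)
  n_a_only <- length(match$unmatched_a)
  n_b_only <- length(match$unmatched_b)
  n_total <- n_double + n_a_only + n_b_only
  if (n_total == 0) {
    stop("no particles detected in either channel", call. = FALSE)
  }
  r <- if (n_double >= 3) {
    suppressWarnings(
      intensity_correlation(match$pairs$int_a, match$pairs$int_b)
    )
  } else {
    NA_real_
  }
  structure(
    list(
      n_total = n_total, n_a_only = n_a_only, n_b_only = n_b_only,
      n_double = n_double,
      pct_a_only = 100 * n_a_only / n_total,
      pct_b_only = 100 * n_b_only / n_total,
      pct_double = 100 * n_double / n_total,
      r = r, pairs = match$pairs
    ),
    class = "ev_coloc"
  )
}

#' @export
print.ev_coloc <- function(x, ...) {
  cat(
    "<ev_coloc> n = ", x$n_total, ": A-only ", round(x$pct_a_only, 1),
    "%, B-only ", round(x$pct_b_only, 1), "%, double ",
    round(x$pct_double, 1), "% (r = ", round(x$r, 2), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Normalise per-FOV counts to a complete-protocol reference
#'
#' Implements the normalized-EV-count comparison used to quantify
#' cross-reactivity: raw per-FOV counts of every condition are divided by
#' the mean count of the complete-protocol condition and multiplied by 100,
#' so the complete protocol normalises to a mean of 100%. The mean
#' normalised percentage of the probe-only condition estimates the fraction
#' of second-channel detections caused by residual-HRP cross-reaction.
#'
#' @param counts A data frame with columns `condition`, `fov`, `count`.
#' @param reference Name of the complete-protocol condition.
#' @param probe_only Name of the probe-only condition (for the
#'   cross-reactivity estimate; `NA` is returned if absent).
#' @return An `ev_normcounts` tibble (`condition`, `fov`, `count`,
#'   `normalized_pct`) with attributes `reference_mean` and
#'   `cross_react_pct`.
#' @export
normalized_counts_percent <- function(counts, reference = "complete",
                                      probe_only = "probe_only") {
  stopifnot(all(c("condition", "fov", "count") %in% names(counts)))
  ref <- counts$count[counts$condition == reference]
  if (length(ref) < 1) {
    stop("reference condition '", reference, "' has no FOVs", call. = FALSE)
  }
  ref_mean <- mean(ref)
  if (ref_mean <= 0) {
    stop("reference condition has zero mean count", call. = FALSE)
  }
  out <- tibble::as_tibble(counts)
  out$normalized_pct <- 100 * out$count / ref_mean
  xr <- out$normalized_pct[out$condition == probe_only]
  attr(out, "reference_mean") <- ref_mean
  attr(out, "cross_react_pct") <- if (length(xr) > 0) mean(xr) else NA_real_
  class(out) <- c("ev_normcounts", class(out))
  out
}

#' Inter-channel intensity correlation of double positives
#'
#' Pearson correlation of the two channels' background-subtracted integrated
#' intensities over double-positive particles, computed on the log scale by
#' default (single-particle intensity distributions are strongly
#' right-skewed). Non-positive intensities are dropped before the log
#' transform.
#'
#' @param int_a,int_b Paired intensity vectors (double positives).
#' @param log Use log-transformed intensities (default `TRUE`).
#' @return Pearson `r`; `NA` with a warning if either vector has zero
#'   variance.
#' @export
intensity_correlation <- function(int_a, int_b, log = TRUE) {
  stopifnot(length(int_a) == length(int_b))
  if (log) {
    keep <- int_a > 0 & int_b > 0
    int_a <- base::log(int_a[keep])
    int_b <- base::log(int_b[keep])
  }
  if (length(int_a) < 3) {
    stop("need at least 3 double-positive pairs", call. = FALSE)
  }
  if (stats::sd(int_a) == 0 || stats::sd(int_b) == 0) {
    warning("zero variance in intensities; correlation undefined")
    return(NA_real_)
  }
  stats::cor(int_a, int_b)
}
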