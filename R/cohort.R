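#' Circulating tumour cells per millilitre of blood
#'
#' Whole-slide CTC count divided by the initial blood volume.
#'
#' @param ctc_count Non-negative CTC count (whole slide).
#' @param blood_volume_ml Blood volume, mL (> 0).
#' @return CTCs/mL.
#' @examples
#' ctcs_per_ml(45, 7.5) # 6
#' @export
ctcs_per_ml <- function(ctc_count, blood_volume_ml) {
  if (any(blood_volume_ml <= 0)) {
    stop("blood volume must be positive", call. = FALSE)
  }
  ctc_count / blood_volume_ml
}

#' Cohort CTC detection rate
#'
#' Percentage of patient samples whose CTC rate exceeds the positivity
#' threshold, rounded to an integer. The default threshold is the maximum
#' CTC rate observed across healthy-control samples (0 when controls are
#' clean, so any patient CTC counts as positive).
#'
#' @param cohort A cohort tibble (see [cohort_table()]) with columns `group`
#'   (`"patient"`/`"healthy"`) and `ctcs_per_ml`.
#' @param threshold Positivity threshold in CTCs/mL, or `NULL` to use the
#'   healthy-control maximum (0 if there are no controls).
#' @return Integer percentage in \[0, 100\].
#' @export
detection_rate <- function(cohort, threshold = NULL) {
  stopifnot(all(c("group", "ctcs_per_ml") %in% names(cohort)))
  patients <- cohort$ctcs_per_ml[cohort$group == "patient"]
  if (length(patients) == 0) {
    stop("cohort contains no patient samples", call. = FALSE)
  }
  if (is.null(threshold)) {
    healthy <- cohort$ctcs_per_ml[cohort$group == "healthy"]
    threshold <- if (length(healthy) > 0) max(healthy) else 0
  }
  as.integer(round(100 * mean(patients > threshold)))
}

#' Baseline-adjusted tumour-EV percentage
#'
#' Percentage of tetraspanin-positive EVs that are also tumour-marker
#' positive, with the corresponding percentage measured in the paired
#' healthy control subtracted and the result clipped at zero (samples whose
#' raw percentage falls below the healthy baseline are reported as zero).
#'
#' @param ev_double Double-positive (tumour + tetraspanin) EV count.
#' @param ev_total Total tetraspanin-positive EV count (> 0).
#' @param healthy_baseline_pct Healthy-control double-positive percentage,
#'   in \[0, 100\].
#' @return Percentage >= 0.
#' @examples
#' gbm_ev_percent(30, 100, 5) # 25
#' gbm_ev_percent(3, 100, 5) # 0 (clipped)
#' @export
gbm_ev_percent <- function(ev_double, ev_total, healthy_baseline_pct) {
  if (any(ev_total <= 0)) {
    stop("ev_total must be positive (sample not evaluable)", call. = FALSE)
  }
  stopifnot(all(healthy_baseline_pct >= 0), all(healthy_baseline_pct <= 100))
  pmax(0, 100 * ev_double / ev_total - healthy_baseline_pct)
}

#' Assemble a cohort enumeration table
#'
#' Derives per-sample CTCs/mL and baseline-adjusted tumour-EV percentages
#' from raw enumeration results. The healthy EV baseline is the mean (or
#' maximum, with `baseline_mode = "max"`) raw double-positive percentage
#' over healthy-control samples; a single paired control is the typical
#' design, in which case the two modes coincide.
#'
#' @param samples A data frame with columns `sample_id`, `group`
#'   (`"patient"` or `"healthy"`), `ctc_count`, `blood_volume_ml`,
#'   `ev_total`, `ev_double`, and optionally `fovs_sampled`.
#' @param baseline_mode `"mean"` or `"max"` over healthy controls.
#' @return An `ev_cohort` tibble: the input plus `ctcs_per_ml` and
#'   `pct_gbm_ev`, with `attr(, "healthy_baseline_pct")`.
#' @export
cohort_table <- function(samples, baseline_mode = c("mean", "max")) {
  baseline_mode <- match.arg(baseline_mode)
  need <- c(
    "sample_id", "group", "ctc_count", "blood_volume_ml",
    "ev_total", "ev_double"
  )
  stopifnot(all(need %in% names(samples)))
  stopifnot(all(samples$group %in% c("patient", "healthy")))
  out <- tibble::as_tibble(samples)
  out$ctcs_per_ml <- ctcs_per_ml(out$ctc_count, out$blood_volume_ml)

  healthy <- out[out$group == "healthy" & out$ev_total > 0, , drop = FALSE]
  baseline <- if (nrow(healthy) > 0) {
    raw <- 100 * healthy$ev_double / healthy$ev_total
    if (baseline_mode == "mean") mean(raw) else max(raw)
  } else {
    0
  }
  out$pct_gbm_ev <- ifelse(
    out$ev_total > 0,
    gbm_ev_percent(pmax(out$ev_double, 0), pmax(out$ev_total, 1), baseline),
    NA_real_
  )
  attr(out, "healthy_baseline_pct") <- baseline
  class(out) <- c("ev_cohort", class(out))
  out
}

#' Simulate a cohort of patient and control samples
#'
#' Generates per-sample enumeration data with known ground truth for
#' validating the cohort statistics: patient CTC densities are zero with
#' probability `p_negative` and log-normal otherwise; whole-slide CTC counts
#' are Poisson around density x volume; healthy controls have zero CTCs
#' (imaging conditions are assumed calibrated to that end). EV totals are
#' Poisson; double-positive EVs are binomial at a per-sample tumour-EV
#' fraction on top of a shared healthy baseline fraction.
#'
#' @param n_patients,n_healthy Sample numbers.
#' @param blood_volume_ml Blood volume per sample, mL.
#' @param p_negative Probability a patient has no CTCs.
#' @param density_meanlog,density_sdlog Log-normal parameters of positive
#'   patients' CTC densities (CTCs/mL).
#' @param ev_total_mean Mean tetraspanin-positive EVs sampled per sample.
#' @param baseline_pct Healthy-control double-positive percentage.
#' @param tumour_pct_range Range of patients' true added tumour-EV
#'   percentages.
#' @param seed Integer seed.
#' @return A list: `samples` (input for [cohort_table()]) and `truth`
#'   (per-sample true densities and tumour-EV percentages).
#' @export
simulate_cohort <- function(n_patients = 29, n_healthy = 11,
                            blood_volume_ml = 7.5,
                            p_negative = 0.4,
                            density_meanlog = log(6), density_sdlog = 1,
                            ev_total_mean = 2000,
                            baseline_pct = 3,
                            tumour_pct_range = c(5, 40),
                            seed = 1) {
  set.seed(derive_seed(seed, 41))
  n <- n_patients + n_healthy
  group <- c(rep("patient", n_patients), rep("healthy", n_healthy))
  density <- numeric(n)
  pos <- stats::runif(n_patients) >= p_negative
  density[seq_len(n_patients)][pos] <-
    stats::rlnorm(sum(pos), density_meanlog, density_sdlog)
  ctc_count <- stats::rpois(n, density * blood_volume_ml)
  tumour_pct <- numeric(n)
  tumour_pct[seq_len(n_patients)] <-
    stats::runif(n_patients, tumour_pct_range[1], tumour_pct_range[2])
  ev_total <- stats::rpois(n, ev_total_mean)
  p_double <- pmin(1, (baseline_pct + tumour_pct) / 100)
  ev_double <- stats::rbinom(n, ev_total, p_double)
  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = group,
    ctc_count = ctc_count,
    blood_volume_ml = blood_volume_ml,
    ev_total = ev_total,
    ev_double = ev_double,
    fovs_sampled = 4L
  )
  truth <- tibble::tibble(
    sample_id = samples$sample_id, group = group,
    true_density = density, true_tumour_pct = tumour_pct
  )
  list(samples = samples, truth = truth)
}
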