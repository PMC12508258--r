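#' Describe a staining chemistry
#'
#' Builds the generative parameters of one of the three immunofluorescence
#' staining strategies compared throughout the package:
#'
#' * `"DS"` (direct staining): fluorophore-conjugated primary antibody, one
#'   labelling step, no amplification.
#' * `"PSS"` (primary + secondary staining): unconjugated primary plus a
#'   fluorophore-conjugated secondary; modest amplification through the
#'   secondary-to-primary stoichiometry.
#' * `"TSA"` (tyramide signal amplification): unconjugated primary plus an
#'   HRP-conjugated secondary that enzymatically deposits many fluorescent
#'   tyramide molecules, giving the strongest amplification.
#'
#' Per particle carrying `c` protein copies, the number of bound primaries is
#' `Binomial(c, label_efficiency)`. The expected number of fluorophores per
#' bound primary is `fluors_per_primary` (DS),
#' `secondaries_per_primary * fluors_per_secondary` (PSS), or a Poisson draw
#' with mean `secondaries_per_primary * tyramide_mean` (TSA, the stochastic
#' tyramide deposition summed over secondaries). The photon emission rate is
#' the fluorophore count times `photon_rate_per_fluor`.
#'
#' Default amplification parameters are calibrated once so that the expected
#' per-fluorophore ratios are DS : PSS : TSA = 1 : 1.5 : 6.4, matching the
#' population mean intensity ratios observed for tetraspanin staining of
#' single EVs with the three chemistries. Default bleach rates encode the
#' observed stability contrast: direct staining of EVs bleaches within a
#' minute under continuous excitation, while PSS and TSA signals are stable
#' over a 5-minute acquisition.
#'
#' @param name One of `"TSA"`, `"DS"`, `"PSS"`.
#' @param label_efficiency Probability in \[0, 1\] that a protein copy is bound
#'   by a primary antibody.
#' @param fluors_per_primary Fluorophores conjugated per primary (DS).
#' @param fluors_per_secondary Fluorophores conjugated per secondary (PSS).
#' @param secondaries_per_primary Expected secondaries bound per primary
#'   (PSS, TSA).
#' @param tyramide_mean Expected tyramide depositions per HRP secondary
#'   (TSA only).
#' @param photon_rate_per_fluor Photons per millisecond emitted per
#'   fluorophore under the reference excitation.
#' @param bleach_rate Per-minute exponential photobleaching constant; `NULL`
#'   selects the method default (DS 1.5, PSS 0.02, TSA 0.01).
#' @return A `stain_method` object (a validated list).
#' @examples
#' tsa <- stain_method("TSA")
#' ds <- stain_method("DS")
#' # expected amplification of TSA over DS:
#' tsa$secondaries_per_primary * tsa$tyramide_mean / ds$fluors_per_primary
#' @export
stain_method <- function(name = c("TSA", "DS", "PSS"),
                         label_efficiency = 0.8,
                         fluors_per_primary = 1,
                         fluors_per_secondary = 1,
                         secondaries_per_primary = 1.5,
                         tyramide_mean = 6.4 / 1.5,
                         photon_rate_per_fluor = 0.1,
                         bleach_rate = NULL) {
  name <- match.arg(name)
  if (is.null(bleach_rate)) {
    bleach_rate <- switch(name, DS = 1.5, PSS = 0.02, TSA = 0.01)
  }
  stopifnot(
    label_efficiency >= 0, label_efficiency <= 1,
    fluors_per_primary >= 0, fluors_per_secondary >= 0,
    secondaries_per_primary >= 0, tyramide_mean >= 0,
    photon_rate_per_fluor > 0, bleach_rate >= 0
  )
  structure(
    list(
      name = name,
      label_efficiency = label_efficiency,
      fluors_per_primary = fluors_per_primary,
      fluors_per_secondary = fluors_per_secondary,
      secondaries_per_primary = secondaries_per_primary,
      tyramide_mean = if (name == "TSA") tyramide_mean else NA_real_,
      photon_rate_per_fluor = photon_rate_per_fluor,
      bleach_rate = bleach_rate
    ),
    class = "stain_method"
  )
}

#' @export
print.stain_method <- function(x, ...) {
  cat("<stain_method> ", x$name,
    " | label efficiency ", x$label_efficiency,
    " | bleach ", x$bleach_rate, "/min\n",
    sep = ""
  )
  invisible(x)
}

#' Optics and camera acquisition parameters
#'
#' Describes the microscope point-spread function (2D Gaussian approximation
#' to the Airy disk, `psf_sigma = 0.21 * lambda / NA` by default, i.e. about
#' 78 nm for 520 nm emission through an NA 1.4 oil objective) and a
#' photon-counting camera model: expected photons are converted to ADU with
#' `gain`, offset by `offset`, perturbed by Gaussian read noise, and rounded
#' to integer ADU.
#'
#' @param psf_sigma Gaussian PSF sigma in nm.
#' @param exposure Acquisition (integration) time in ms.
#' @param gain Camera gain, ADU per photon.
#' @param offset Camera baseline offset, ADU.
#' @param read_noise_sd Read noise standard deviation, ADU.
#' @param background_rate Diffuse background, photons per pixel per ms.
#' @return An `optics_config` object.
#' @export
optics_config <- function(psf_sigma = 0.21 * 520 / 1.4,
                          exposure = 300,
                          gain = 2,
                          offset = 100,
                          read_noise_sd = 1.5,
                          background_rate = 0.02) {
  stopifnot(
    psf_sigma > 0, exposure > 0, gain > 0,
    read_noise_sd >= 0, offset >= 0, background_rate >= 0
  )
  structure(
    list(
      psf_sigma = psf_sigma, exposure = exposure, gain = gain,
      offset = offset, read_noise_sd = read_noise_sd,
      background_rate = background_rate
    ),
    class = "optics_config"
  )
}

#' Log-normal protein copy-number model
#'
#' Per-particle protein copies are drawn from a log-normal distribution
#' rounded to integers, reflecting the broad right-skewed intensity
#' distributions seen on single vesicles. The default (median 50 copies,
#' sdlog 0.5) represents an abundant tetraspanin-class surface marker.
#'
#' @param meanlog,sdlog Log-normal parameters.
#' @return A `copy_dist` object usable in [field_config()]'s `markers` list.
#' @export
copy_lognormal <- function(meanlog = log(50), sdlog = 0.5) {
  stopifnot(sdlog >= 0)
  structure(list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog),
    class = "copy_dist"
  )
}

#' Fixed protein copy-number model
#'
#' Every particle carries exactly `copies` protein copies. Used for
#' calibration-style experiments (e.g. limit-of-detection substrates where
#' each vesicle bears a known low copy number).
#'
#' @param copies Non-negative integer copy count.
#' @return A `copy_dist` object.
#' @export
copy_fixed <- function(copies) {
  stopifnot(copies >= 0)
  structure(list(kind = "fixed", copies = as.integer(round(copies))),
    class = "copy_dist"
  )
}

draw_copies <- function(dist, n) {
  stopifnot(inherits(dist, "copy_dist"))
  if (dist$kind == "fixed") {
    return(rep(dist$copies, n))
  }
  as.integer(round(stats::rlnorm(n, dist$meanlog, dist$sdlog)))
}

#' Ground-truth field configuration
#'
#' Describes the simulated substrate: field-of-view size, pixel pitch,
#' expected particle numbers and the per-marker protein copy distributions.
#' Expected EV count scales with `concentration_scale` (the relative plating
#' factor, e.g. 1 for a \[1x\] substrate and 8 for \[8x\]). Non-specific
#' background (NSB) particles model the faint contaminating spots present
#' even on EV-free control substrates; their expected number per FOV does not
#' scale with EV concentration and their emission is drawn from an
#' exponential distribution with mean `nsb_rate_mean` photons/ms,
#' marker-independent.
#'
#' @param fov_px Integer vector `c(height, width)` in pixels.
#' @param pixel_size Pixel pitch in nm/px.
#' @param ev_per_fov Expected EV count per FOV at `concentration_scale = 1`.
#' @param concentration_scale Relative plating factor (>= 0).
#' @param markers Named list of [copy_lognormal()] / [copy_fixed()] copy
#'   models, one per marker.
#' @param nsb_per_fov Expected non-specific background particles per FOV.
#' @param nsb_rate_mean Mean photon emission rate (photons/ms) of NSB
#'   particles.
#' @param ev_diameter_meanlog,ev_diameter_sdlog Log-normal parameters of the
#'   EV diameter in nm (ground-truth bookkeeping; sub-diffraction EVs render
#'   as point sources regardless).
#' @param cells Optional [cell_population()] describing plated cells.
#' @return A `field_config` object.
#' @export
field_config <- function(fov_px = c(256, 256),
                         pixel_size = 50,
                         ev_per_fov = 300,
                         concentration_scale = 1,
                         markers = list(CD63 = copy_lognormal()),
                         nsb_per_fov = 20,
                         nsb_rate_mean = 0.6,
                         ev_diameter_meanlog = log(120),
                         ev_diameter_sdlog = 0.35,
                         cells = NULL) {
  stopifnot(
    length(fov_px) == 2, all(fov_px >= 8),
    pixel_size > 0, ev_per_fov >= 0, concentration_scale >= 0,
    nsb_per_fov >= 0, nsb_rate_mean >= 0
  )
  if (length(markers) > 0 && (is.null(names(markers)) || any(names(markers) == ""))) {
    stop("`markers` must be a named list of copy distributions", call. = FALSE)
  }
  structure(
    list(
      fov_px = as.integer(fov_px), pixel_size = pixel_size,
      ev_per_fov = ev_per_fov, concentration_scale = concentration_scale,
      markers = markers, nsb_per_fov = nsb_per_fov,
      nsb_rate_mean = nsb_rate_mean,
      ev_diameter_meanlog = ev_diameter_meanlog,
      ev_diameter_sdlog = ev_diameter_sdlog,
      cells = cells
    ),
    class = "field_config"
  )
}

#' Plated cell population for cell-level simulations
#'
#' Describes tumour cells (CTC class, larger nuclei) and white blood cells
#' (WBC class, smaller nuclei) spiked onto a substrate. Marker copy counts
#' are area-proportional: each cell's copies for a marker are
#' `round(density * cell area in px)` for its own class and (near) zero for
#' the other, which is what makes rule-based classification possible.
#'
#' @param n_ctc,n_wbc Cell numbers per FOV (fixed, cells are plated not
#'   Poisson-sampled).
#' @param ctc_nucleus_px,wbc_nucleus_px Nucleus radii in px.
#' @param ring_px Width of the cytoplasm/membrane ring outside the nucleus,
#'   px.
#' @param ctc_marker,wbc_marker Marker names carried by each class (e.g. the
#'   STEAM tumour cocktail vs CD45/CD11c).
#' @param copies_per_px Marker copy density per cell-mask pixel.
#' @param dapi_rate Nuclear DAPI emission, photons/ms per nucleus pixel.
#' @return A `cell_population` object.
#' @export
cell_population <- function(n_ctc = 5, n_wbc = 5,
                            ctc_nucleus_px = 7, wbc_nucleus_px = 4,
                            ring_px = 3,
                            ctc_marker = "STEAM", wbc_marker = "CD45",
                            copies_per_px = 3,
                            dapi_rate = 1.5) {
  stopifnot(
    n_ctc >= 0, n_wbc >= 0, ctc_nucleus_px > 0, wbc_nucleus_px > 0,
    ring_px >= 1, copies_per_px >= 0, dapi_rate >= 0
  )
  structure(
    list(
      n_ctc = n_ctc, n_wbc = n_wbc,
      ctc_nucleus_px = ctc_nucleus_px, wbc_nucleus_px = wbc_nucleus_px,
      ring_px = ring_px, ctc_marker = ctc_marker, wbc_marker = wbc_marker,
      copies_per_px = copies_per_px, dapi_rate = dapi_rate
    ),
    class = "cell_population"
  )
}

#' Two-plex staining configuration
#'
#' Parameters of a sequential two-colour TSA protocol. Residual active HRP
#' left by the first staining cycle can react with the second tyramide probe,
#' creating spurious second-channel signal on first-channel particles; a
#' peroxide quench step between the cycles deactivates a fraction
#' `quench_efficiency` of that residual HRP. The effective cross-reaction
#' probability is `cross_react_fraction * (1 - quench_efficiency)` when
#' `quench_applied`, else `cross_react_fraction`.
#'
#' Defaults encode the measured cross-reactivity of the two-plex EV protocol:
#' about 20% of second-channel detections are spurious without quenching,
#' and 3% with the peroxide quench (so `quench_efficiency = 0.85`).
#'
#' @param channel_a_marker,channel_b_marker Marker names for the first and
#'   second staining cycles.
#' @param cross_react_fraction Probability that an A-stained particle
#'   receives spurious channel-B probe signal via residual HRP.
#' @param quench_applied Whether the peroxide quench step is performed.
#' @param quench_efficiency Fraction of residual HRP deactivated by the
#'   quench.
#' @return A `twoplex_config` object.
#' @export
twoplex_config <- function(channel_a_marker = "STEAM",
                           channel_b_marker = "CD9CD81",
                           cross_react_fraction = 0.20,
                           quench_applied = TRUE,
                           quench_efficiency = 0.85) {
  stopifnot(
    cross_react_fraction >= 0, cross_react_fraction <= 1,
    quench_efficiency >= 0, quench_efficiency <= 1
  )
  if (identical(channel_a_marker, channel_b_marker)) {
    stop("the two channels must target distinct markers", call. = FALSE)
  }
  structure(
    list(
      channel_a_marker = channel_a_marker,
      channel_b_marker = channel_b_marker,
      cross_react_fraction = cross_react_fraction,
      quench_applied = quench_applied,
      quench_efficiency = quench_efficiency
    ),
    class = "twoplex_config"
  )
}

#' Effective cross-reaction fraction of a two-plex configuration
#'
#' @param twoplex A [twoplex_config()].
#' @return The probability that an A-stained particle shows spurious
#'   channel-B signal, after accounting for quenching.
#' @export
effective_cross_reaction <- function(twoplex) {
  stopifnot(inherits(twoplex, "twoplex_config"))
  if (isTRUE(twoplex$quench_applied)) {
    twoplex$cross_react_fraction * (1 - twoplex$quench_efficiency)
  } else {
    twoplex$cross_react_fraction
  }
}

#' Particle detection parameters
#'
#' Encodes the control-calibrated image-analysis rules used for single-EV
#' segmentation: an intensity threshold chosen so that EV-free control
#' substrates yield fewer than `max_control_detections` particles, a minimum
#' particle size of 10 pixels, hole filling, and morphological separation of
#' touching objects.
#'
#' @param threshold Absolute intensity threshold in ADU (pixels strictly
#'   above are foreground); usually set by [calibrate_threshold()].
#' @param min_size_px Minimum particle area in pixels (default 10).
#' @param fill_holes Fill interior holes of binarised objects.
#' @param separate_touching Watershed-separate components much larger than
#'   the median spot.
#' @param max_control_detections Strict upper bound on detections allowed per
#'   control image during calibration (default 10, i.e. "fewer than 10").
#' @param noise_tolerance Prominence tolerance for [count_maxima()]; also
#'   used to seed watershed separation.
#' @param exclude_border Drop particles touching the image border.
#' @param measure_dilate_px Photometry aperture: the detection mask is
#'   dilated by this many pixels before intensities are integrated, so the
#'   measured flux fraction does not depend on spot brightness.
#' @param aggregate_area_px Optional area cutoff above which objects are
#'   excluded as putative aggregates (`Inf` disables).
#' @param presmooth_sigma Gaussian sigma (px) of the pre-segmentation
#'   smoothing applied before binarisation (0 disables). Smoothing
#'   suppresses single-pixel shot-noise clusters that would otherwise pass
#'   the size filter at permissive thresholds and make control counts
#'   unstable; intensities are always measured on the raw image.
#' @return A `detection_params` object.
#' @export
detection_params <- function(threshold = NULL,
                             min_size_px = 10,
                             fill_holes = TRUE,
                             separate_touching = TRUE,
                             max_control_detections = 10,
                             noise_tolerance = NULL,
                             exclude_border = FALSE,
                             measure_dilate_px = 2,
                             aggregate_area_px = Inf,
                             presmooth_sigma = 1) {
  stopifnot(
    is.null(threshold) || threshold >= 0,
    min_size_px >= 1, max_control_detections >= 1,
    is.null(noise_tolerance) || noise_tolerance >= 0,
    measure_dilate_px >= 0, aggregate_area_px > 0,
    presmooth_sigma >= 0
  )
  structure(
    list(
      threshold = threshold, min_size_px = as.integer(min_size_px),
      fill_holes = isTRUE(fill_holes),
      separate_touching = isTRUE(separate_touching),
      max_control_detections = as.integer(max_control_detections),
      noise_tolerance = noise_tolerance,
      exclude_border = isTRUE(exclude_border),
      measure_dilate_px = as.integer(measure_dilate_px),
      aggregate_area_px = aggregate_area_px,
      presmooth_sigma = presmooth_sigma
    ),
    class = "detection_params"
  )
}

#' Cell segmentation and classification parameters
#'
#' Rule-based replacement for a trained cell classifier: nuclei are DAPI
#' regions passing a Michelson local-contrast threshold and a minimum mean
#' intensity over background; the membrane/cytoplasm ring is a fixed-width
#' dilation band outside the nucleus; a cell is retained only if its
#' membrane-ring "completeness" (positive fraction of ring pixels) exceeds
#' `cytoplasm_completeness_min`.
#'
#' @param nuclear_contrast_threshold Minimum Michelson contrast
#'   `(peak - local background) / (peak + local background)` of a nucleus.
#' @param nuclear_min_intensity Minimum background-subtracted mean DAPI
#'   intensity of a nucleus, ADU.
#' @param cytoplasm_completeness_min Minimum positive membrane-ring fraction
#'   for a cell to be retained (default 0.30).
#' @param membrane_ring_px Ring width in px.
#' @param min_nucleus_px Minimum nucleus area in px.
#' @param tumour_channel Membrane channel name identifying tumour cells (the
#'   STEAM cocktail channel).
#' @param wbc_channels Membrane channel name(s) identifying white blood cells
#'   (CD45/CD11c).
#' @param positivity_thresholds Named numeric vector of per-channel
#'   background-subtracted mean ring intensity thresholds, ADU.
#' @return A `cell_params` object.
#' @export
cell_params <- function(nuclear_contrast_threshold = 0.5,
                        nuclear_min_intensity = 10,
                        cytoplasm_completeness_min = 0.30,
                        membrane_ring_px = 3,
                        min_nucleus_px = 12,
                        tumour_channel = "STEAM",
                        wbc_channels = "CD45",
                        positivity_thresholds = NULL) {
  stopifnot(
    cytoplasm_completeness_min >= 0, cytoplasm_completeness_min <= 1,
    nuclear_min_intensity >= 0, membrane_ring_px >= 1, min_nucleus_px >= 1
  )
  if (!is.null(positivity_thresholds)) {
    stopifnot(all(positivity_thresholds >= 0), !is.null(names(positivity_thresholds)))
  }
  structure(
    list(
      nuclear_contrast_threshold = nuclear_contrast_threshold,
      nuclear_min_intensity = nuclear_min_intensity,
      cytoplasm_completeness_min = cytoplasm_completeness_min,
      membrane_ring_px = as.integer(membrane_ring_px),
      min_nucleus_px = as.integer(min_nucleus_px),
      tumour_channel = tumour_channel,
      wbc_channels = wbc_channels,
      positivity_thresholds = positivity_thresholds
    ),
    class = "cell_params"
  )
}

# Derive a stage seed from a pipeline seed; keeps results < 2^31 and stable.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

sigma_px <- function(optics, pixel_size) optics$psf_sigma / pixel_size
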