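#' Segment cells from a DAPI image and membrane marker channels
#'
#' Nuclear detection on the DAPI channel followed by rule-based membrane
#' analysis:
#'
#' 1. Candidate nuclei are connected regions (8-connectivity, holes filled)
#'    strictly above `background + nuclear_min_intensity` of at least
#'    `min_nucleus_px` pixels.
#' 2. Each nucleus must pass a Michelson local-contrast test
#'    `(peak - local background) / (peak + local background) >=
#'    nuclear_contrast_threshold` (local background is the median in a
#'    5-px ring around the nucleus) and a background-subtracted mean DAPI
#'    intensity above `nuclear_min_intensity`.
#' 3. The cell mask is the nucleus dilated by `membrane_ring_px`; the
#'    membrane ring is the dilation band outside the nucleus. Per membrane
#'    channel, "completeness" is the fraction of ring pixels whose
#'    background-subtracted intensity exceeds that channel's positivity
#'    threshold.
#'
#' @param dapi Numeric matrix, DAPI channel.
#' @param marker_images Named list of numeric matrices (membrane channels),
#'   same dimensions as `dapi`.
#' @param params A [cell_params()]. Channels named in `tumour_channel` /
#'   `wbc_channels` must be present in `marker_images`.
#' @return An `ev_cells` tibble: `id`, `x`, `y`, `nucleus_area`,
#'   `cell_area`, `contrast`, `dapi_mean`, and per channel `ch`:
#'   `completeness_<ch>`, `ring_mean_<ch>`, `integrated_<ch>`; plus mask
#'   list-columns `nucleus_mask` and `cell_mask`.
#' @export
segment_cells <- function(dapi, marker_images = list(),
                          params = cell_params()) {
  stopifnot(is.matrix(dapi))
  for (ch in c(params$tumour_channel, params$wbc_channels)) {
    if (!ch %in% names(marker_images)) {
      stop("configured channel '", ch, "' is missing from marker_images",
        call. = FALSE
      )
    }
  }
  h <- nrow(dapi)
  w <- ncol(dapi)
  bg <- stats::median(dapi)
  bw <- dapi > bg + params$nuclear_min_intensity
  if (any(bw)) bw <- EBImage::fillHull(bw) > 0
  lab <- label_components(bw)
  if (max(lab) == 0) {
    return(empty_cells(marker_images))
  }
  members <- split(which(lab > 0), lab[lab > 0])
  members <- members[lengths(members) >= params$min_nucleus_px]
  if (length(members) == 0) {
    return(empty_cells(marker_images))
  }

  mk_bg <- lapply(marker_images, stats::median)
  thr <- params$positivity_thresholds
  default_thr <- params$nuclear_min_intensity

  rows <- purrr::map_dfr(members, function(m) {
    rr <- ((m - 1L) %% h) + 1L
    cc <- ((m - 1L) %/% h) + 1L
    cell <- dilate_indices(m, h, w, params$membrane_ring_px)
    ring <- setdiff(cell, m)
    # local background ring 5 px beyond the cell mask
    lb_ring <- setdiff(dilate_indices(cell, h, w, 5L), cell)
    local_bg <- if (length(lb_ring) > 0) stats::median(dapi[lb_ring]) else bg
    peak <- max(dapi[m])
    contrast <- (peak - local_bg) / (peak + local_bg)
    out <- tibble::tibble(
      x = mean(cc), y = mean(rr),
      nucleus_area = length(m), cell_area = length(cell),
      contrast = contrast,
      dapi_mean = mean(dapi[m]) - local_bg,
      nucleus_mask = list(m), cell_mask = list(cell)
    )
    for (ch in names(marker_images)) {
      im <- marker_images[[ch]]
      t_ch <- if (!is.null(thr) && ch %in% names(thr)) thr[[ch]] else default_thr
      ring_vals <- im[ring] - mk_bg[[ch]]
      out[[paste0("completeness_", ch)]] <-
        if (length(ring_vals) > 0) mean(ring_vals > t_ch) else 0
      out[[paste0("ring_mean_", ch)]] <-
        if (length(ring_vals) > 0) mean(ring_vals) else 0
      out[[paste0("integrated_", ch)]] <-
        sum(im[cell]) - mk_bg[[ch]] * length(cell)
    }
    out
  })

  keep <- rows$contrast >= params$nuclear_contrast_threshold &
    rows$dapi_mean > params$nuclear_min_intensity
  rows <- rows[keep, , drop = FALSE]
  rows <- dplyr::mutate(rows, id = dplyr::row_number(), .before = 1)
  class(rows) <- c("ev_cells", class(rows))
  rows
}

empty_cells <- function(marker_images) {
  out <- tibble::tibble(
    id = integer(), x = numeric(), y = numeric(),
    nucleus_area = integer(), cell_area = integer(),
    contrast = numeric(), dapi_mean = numeric(),
    nucleus_mask = list(), cell_mask = list()
  )
  for (ch in names(marker_images)) {
    out[[paste0("completeness_", ch)]] <- numeric()
    out[[paste0("ring_mean_", ch)]] <- numeric()
    out[[paste0("integrated_", ch)]] <- numeric()
  }
  class(out) <- c("ev_cells", class(out))
  out
}

#' Classify segmented cells into CTC / WBC / excluded
#'
#' Rule-based classification replacing a trained classifier: a cell positive
#' for the tumour-cocktail channel with membrane completeness above the
#' cytoplasmic-completeness minimum (and negative for the WBC channels) is a
#' CTC; a cell positive for a WBC channel (CD45/CD11c) and tumour-negative
#' is a WBC; cells positive for both are excluded and flagged
#' `double_positive`; everything else is excluded. Channel positivity means
#' the background-subtracted mean membrane-ring intensity exceeds the
#' channel's positivity threshold.
#'
#' @param cells An `ev_cells` tibble from [segment_cells()].
#' @param params The [cell_params()] used for segmentation.
#' @return The tibble with added `classification`
#'   (`"CTC"`/`"WBC"`/`"excluded"`) and `double_positive` columns.
#' @export
classify_cell <- function(cells, params = cell_params()) {
  tum <- params$tumour_channel
  thr <- params$positivity_thresholds
  default_thr <- params$nuclear_min_intensity
  get_thr <- function(ch) {
    if (!is.null(thr) && ch %in% names(thr)) thr[[ch]] else default_thr
  }
  positive <- function(ch) {
    col <- paste0("ring_mean_", ch)
    if (!col %in% names(cells)) {
      stop("channel '", ch, "' was not measured", call. = FALSE)
    }
    cells[[col]] > get_thr(ch)
  }
  tum_pos <- positive(tum)
  wbc_pos <- Reduce(`|`, lapply(params$wbc_channels, positive), logical(nrow(cells)))
  complete <- cells[[paste0("completeness_", tum)]] >
    params$cytoplasm_completeness_min

  cls <- rep("excluded", nrow(cells))
  cls[tum_pos & !wbc_pos & complete] <- "CTC"
  cls[wbc_pos & !tum_pos] <- "WBC"
  cells$classification <- cls
  cells$double_positive <- tum_pos & wbc_pos
  cells
}
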