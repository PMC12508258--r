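#' Sample a ground-truth particle field
#'
#' Draws the latent particle population of one field of view: EV numbers are
#' `Poisson(ev_per_fov * concentration_scale)`, positions uniform over the
#' FOV, diameters log-normal, and per-marker protein copies drawn from the
#' configured copy models. Non-specific background (NSB) particles are added
#' at a Poisson rate independent of the EV concentration and carry no marker
#' copies. Cells, if configured, are placed uniformly with at least one cell
#' diameter of clearance from the border.
#'
#' @param config A [field_config()].
#' @param seed Integer seed; identical config + seed give identical fields.
#' @return A tibble with class `ev_field`, one row per particle: `id`,
#'   `kind` (`"EV"`, `"NSB"`, `"CELL"`), `x`, `y` (1-based pixel-centred,
#'   x = column), `diameter_nm`, `cell_class`, `nucleus_r_px`, `cell_r_px`,
#'   and one `copies_<marker>` column per configured marker. The generating
#'   config is kept in `attr(, "config")`.
#' @examples
#' f <- sample_field(field_config(ev_per_fov = 50), seed = 1)
#' dplyr::count(f, kind)
#' @export
sample_field <- function(config = field_config(), seed = 1) {
  stopifnot(inherits(config, "field_config"))
  set.seed(derive_seed(seed, 1))
  h <- config$fov_px[1]
  w <- config$fov_px[2]
  markers <- names(config$markers)

  n_ev <- stats::rpois(1, config$ev_per_fov * config$concentration_scale)
  n_nsb <- stats::rpois(1, config$nsb_per_fov)

  blank_row <- function(n, kind) {
    tibble::tibble(
      kind = rep(kind, n),
      x = stats::runif(n, 0.5, w + 0.5),
      y = stats::runif(n, 0.5, h + 0.5),
      diameter_nm = NA_real_,
      cell_class = "none",
      nucleus_r_px = NA_real_,
      cell_r_px = NA_real_
    )
  }

  evs <- blank_row(n_ev, "EV")
  if (n_ev > 0) {
    evs$diameter_nm <- stats::rlnorm(
      n_ev, config$ev_diameter_meanlog, config$ev_diameter_sdlog
    )
  }
  nsb <- blank_row(n_nsb, "NSB")

  cells <- NULL
  if (!is.null(config$cells)) {
    cp <- config$cells
    n_cells <- cp$n_ctc + cp$n_wbc
    if (n_cells > 0) {
      cls <- c(rep("CTC", cp$n_ctc), rep("WBC", cp$n_wbc))
      nuc <- ifelse(cls == "CTC", cp$ctc_nucleus_px, cp$wbc_nucleus_px)
      margin <- nuc + cp$ring_px + 2
      # plated cells are spatially dispersed: rejection-sample positions so
      # cell masks do not overlap (falls back after 200 tries per cell)
      cx <- numeric(n_cells)
      cy <- numeric(n_cells)
      rr <- nuc + cp$ring_px
      for (i in seq_len(n_cells)) {
        for (try in 1:200) {
          px <- stats::runif(1, margin[i] + 0.5, w - margin[i] + 0.5)
          py <- stats::runif(1, margin[i] + 0.5, h - margin[i] + 0.5)
          if (i == 1) break
          j <- seq_len(i - 1)
          if (all(sqrt((cx[j] - px)^2 + (cy[j] - py)^2) >
            rr[j] + rr[i] + 2)) {
            break
          }
        }
        cx[i] <- px
        cy[i] <- py
      }
      cells <- tibble::tibble(
        kind = rep("CELL", n_cells),
        x = cx,
        y = cy,
        diameter_nm = NA_real_,
        cell_class = cls,
        nucleus_r_px = nuc,
        cell_r_px = rr
      )
    }
  }

  field <- dplyr::bind_rows(evs, nsb, cells)
  n <- nrow(field)
  field <- dplyr::mutate(field, id = seq_len(n), .before = 1)

  for (m in markers) {
    copies <- integer(n)
    is_ev <- field$kind == "EV"
    copies[is_ev] <- draw_copies(config$markers[[m]], sum(is_ev))
    if (!is.null(config$cells)) {
      cp <- config$cells
      is_cell <- field$kind == "CELL"
      if (any(is_cell)) {
        own <- (field$cell_class == "CTC" & m == cp$ctc_marker) |
          (field$cell_class == "WBC" & m == cp$wbc_marker)
        area <- pi * field$cell_r_px^2
        copies[is_cell & own] <-
          as.integer(round(cp$copies_per_px * area[is_cell & own]))
      }
    }
    field[[paste0("copies_", m)]] <- copies
  }

  attr(field, "config") <- config
  class(field) <- c("ev_field", class(field))
  field
}

field_markers <- function(field) {
  sub("^copies_", "", grep("^copies_", names(field), value = TRUE))
}

#' Simulate staining of a field with one chemistry
#'
#' Applies the generative staining model of a [stain_method()] to every
#' particle, producing per-particle photon emission rates (photons/ms) for
#' the channel targeting `marker`:
#'
#' * bound primaries `b ~ Binomial(copies, label_efficiency)`;
#' * DS: fluorophores `= b * fluors_per_primary`;
#' * PSS: fluorophores `= b * secondaries_per_primary * fluors_per_secondary`;
#' * TSA: fluorophores `~ Poisson(b * secondaries_per_primary *
#'   tyramide_mean)` (tyramide depositions summed over secondaries);
#' * NSB particles emit a marker-independent background rate drawn from an
#'   exponential distribution.
#'
#' Cells use the same model on their (area-proportional) copy counts.
#'
#' @param field An `ev_field` from [sample_field()].
#' @param stain A [stain_method()].
#' @param marker Marker name; defaults to the field's first marker.
#' @param seed Integer seed.
#' @return The field with an added `rate` column (photons/ms) and attributes
#'   `stain` and `marker`.
#' @export
simulate_staining <- function(field, stain, marker = NULL, seed = 1) {
  stopifnot(inherits(field, "ev_field"), inherits(stain, "stain_method"))
  markers <- field_markers(field)
  if (is.null(marker)) marker <- markers[1]
  if (!marker %in% markers) {
    stop("unknown marker '", marker, "'; field carries: ",
      paste(markers, collapse = ", "),
      call. = FALSE
    )
  }
  set.seed(derive_seed(seed, 2))
  config <- attr(field, "config")
  copies <- field[[paste0("copies_", marker)]]
  n <- nrow(field)
  rate <- numeric(n)
  if (n > 0) {
    rate <- staining_rate(copies, stain, n)
    is_nsb <- field$kind == "NSB"
    if (any(is_nsb)) {
      rate[is_nsb] <- stats::rexp(sum(is_nsb), 1 / config$nsb_rate_mean)
    }
  }
  field$rate <- rate
  attr(field, "stain") <- stain
  attr(field, "marker") <- marker
  field
}

# Vectorised emission-rate draw (photons/ms) for specific staining.
staining_rate <- function(copies, stain, n = length(copies)) {
  bound <- stats::rbinom(n, copies, stain$label_efficiency)
  fluors <- switch(stain$name,
    DS = bound * stain$fluors_per_primary,
    PSS = bound * stain$secondaries_per_primary * stain$fluors_per_secondary,
    TSA = stats::rpois(
      n, bound * stain$secondaries_per_primary * stain$tyramide_mean
    )
  )
  fluors * stain$photon_rate_per_fluor
}
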