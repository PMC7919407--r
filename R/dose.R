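#' Photon and dose bookkeeping for one beam condition
#'
#' With the exposure time per image taken as 1/`frame_rate` exactly:
#' * `photons_per_image()` = flux x transmission / frame_rate;
#' * `dose_per_image()` = dose_rate / frame_rate, reported in kGy;
#' * `total_photons()` = n_images x photons_per_image.
#'
#' @param beam A beam condition ([beam_condition()]).
#' @return A single number (photons, kGy, or photons respectively).
#' @examples
#' b <- beam_condition(flux = 4.8e12, transmission = 0.194, frame_rate = 100,
#'                     dose_rate = 4.2)
#' photons_per_image(b) # 9.3e9 photons
#' dose_per_image(b)    # 42 kGy
#' @export
photons_per_image <- function(beam) {
  stopifnot(inherits(beam, "ssrox_beam"))
  beam$flux * beam$transmission / beam$frame_rate
}

#' @rdname photons_per_image
#' @export
dose_per_image <- function(beam) {
  stopifnot(inherits(beam, "ssrox_beam"))
  1000 * beam$dose_rate / beam$frame_rate # MGy/s / Hz -> kGy
}

#' @rdname photons_per_image
#' @param n_images Number of merged (indexed) images (>= 0).
#' @param photons_image Photons per image, e.g. from [photons_per_image()].
#' @export
total_photons <- function(n_images, photons_image) {
  if (any(n_images < 0)) abort("`n_images` must be >= 0", class = "ssrox_error_dose")
  n_images * photons_image
}

# Round half away from zero (presentation rounding for percentage tables;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Hit-rate and index-rate summary of data-set counts
#'
#' Computes per-set and overall hit rates (hits / images) and index rates of
#' hits (indexed / hits) as percentages. Overall rates pool the summed
#' numerators and denominators. Columns `hit_rate` and `index_rate` hold the
#' full-precision percentages; `hit_rate_display` / `index_rate_display`
#' round them half-up to `digits` decimals, matching standard reporting. An
#' index rate with zero hits is returned as `NA` and counted in the
#' `n_undefined` attribute rather than raising an error.
#'
#' @param counts A data frame with columns `dataset`, `n_images`, `n_hits`,
#'   `n_indexed` (e.g. read from a counts CSV).
#' @param digits Decimals for the display rounding (default 1).
#' @return A tibble with one row per data set plus a final `overall` row.
#' @examples
#' counts <- tibble::tibble(
#'   dataset = c("x-1", "x-2"), n_images = c(100, 100),
#'   n_hits = c(50, 25), n_indexed = c(40, 20)
#' )
#' rate_summary(counts)
#' @export
rate_summary <- function(counts, digits = 1) {
  counts <- as_tibble(counts)
  need <- c("dataset", "n_images", "n_hits", "n_indexed")
  if (!all(need %in% names(counts))) {
    abort(paste("`counts` needs columns:", paste(need, collapse = ", ")),
      class = "ssrox_error_dose"
    )
  }
  bad <- counts$n_indexed > counts$n_hits | counts$n_hits > counts$n_images |
    counts$n_indexed < 0
  if (any(bad)) {
    abort("count invariants violated: need 0 <= indexed <= hits <= images",
      class = "ssrox_error_dose"
    )
  }
  overall <- tibble(
    dataset = "overall",
    n_images = sum(counts$n_images),
    n_hits = sum(counts$n_hits),
    n_indexed = sum(counts$n_indexed)
  )
  out <- dplyr::bind_rows(counts[, need], overall)
  out$hit_rate <- 100 * out$n_hits / out$n_images
  out$index_rate <- ifelse(out$n_hits > 0, 100 * out$n_indexed / out$n_hits, NA_real_)
  out$hit_rate_display <- round_half_up(out$hit_rate, digits)
  out$index_rate_display <- round_half_up(out$index_rate, digits)
  attr(out, "n_undefined") <- sum(is.na(out$index_rate))
  out
}

#' The standard room-temperature dose ladder
#'
#' The seven-condition dose series used for the radiation-damage experiments:
#' nominal doses 21-1700 kGy obtained from a 4.8e12 photons/s beam by
#' combining attenuator transmission and detector frame rate (100 Hz for the
#' four lowest doses; 54, 27 and 13 Hz at full transmission for the three
#' highest, all at a 23 MGy/s dose rate). The computed dose per image can
#' differ from the nominal label for the reduced-frame-rate rows
#' (e.g. 23 MGy/s at 54 Hz gives 426 kGy against the 420 kGy label); both are
#' carried.
#'
#' @return A tibble with columns `nominal_dose_kgy`, `dose_rate_mgy_s`,
#'   `transmission`, `frame_rate_hz`, `dose_kgy_computed`,
#'   `photons_per_image`, and a list-column `beam` of [beam_condition()]
#'   objects.
#' @export
dose_series_conditions <- function() {
  tbl <- tibble(
    nominal_dose_kgy = c(21, 42, 83, 210, 420, 830, 1700),
    dose_rate_mgy_s = c(2.1, 4.2, 8.3, 21, 23, 23, 23),
    transmission = c(0.0949, 0.194, 0.401, 0.942, 1, 1, 1),
    frame_rate_hz = c(100, 100, 100, 100, 54, 27, 13)
  )
  tbl$beam <- purrr::pmap(tbl, function(nominal_dose_kgy, dose_rate_mgy_s,
                                        transmission, frame_rate_hz, ...) {
    beam_condition(
      flux = 4.8e12, transmission = transmission, frame_rate = frame_rate_hz,
      dose_rate = dose_rate_mgy_s, nominal_dose_kgy = nominal_dose_kgy
    )
  })
  tbl$dose_kgy_computed <- purrr::map_dbl(tbl$beam, dose_per_image)
  tbl$photons_per_image <- purrr::map_dbl(tbl$beam, photons_per_image)
  tbl
}
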