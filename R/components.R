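#' Acquisition geometry of a helical raster scan
#'
#' @param n_scans Number of helical scans (>= 1).
#' @param images_per_scan Images collected per scan (>= 1).
#' @param rotation_step Goniometer rotation per image, degrees (> 0).
#' @param translation_step Horizontal translation per image, micrometre (> 0).
#' @param scan_interval Vertical spacing between scans, micrometre (> 0).
#' @return An object of class `ssrox_geometry` with the fields above plus
#'   `total_images = n_scans * images_per_scan`.
#' @examples
#' scan_geometry()$total_images # 22200
#' @export
scan_geometry <- function(n_scans = 100, images_per_scan = 222,
                          rotation_step = 0.25, translation_step = 9,
                          scan_interval = 20) {
  if (n_scans < 1 || images_per_scan < 1) {
    abort("scan counts must be >= 1", class = "ssrox_error_geometry")
  }
  if (any(c(rotation_step, translation_step, scan_interval) <= 0)) {
    abort("scan steps must be positive", class = "ssrox_error_geometry")
  }
  structure(
    list(
      n_scans = as.integer(n_scans), images_per_scan = as.integer(images_per_scan),
      rotation_step = rotation_step, translation_step = translation_step,
      scan_interval = scan_interval,
      total_images = as.integer(n_scans) * as.integer(images_per_scan)
    ),
    class = "ssrox_geometry"
  )
}

#' Beam and detector condition
#'
#' Describes one exposure condition: unattenuated flux, attenuator
#' transmission, detector frame rate, and the absorbed-dose rate in the
#' illuminated crystal volume. The exposure time per image is taken as
#' 1/`frame_rate` exactly, so photons per image and dose per image follow by
#' pure rate-times-time accounting (see [photons_per_image()] and
#' [dose_per_image()]). `nominal_dose_kgy` carries the label a condition is
#' referred to by, which may differ from the computed `dose_per_image()` by
#' presentation rounding; both are reported.
#'
#' @param flux Unattenuated photon flux, photons per second.
#' @param transmission Attenuator transmission as a fraction in (0, 1].
#' @param frame_rate Detector frame rate in Hz.
#' @param dose_rate Absorbed dose rate in MGy per second.
#' @param nominal_dose_kgy Dose label in kGy (optional; defaults to the
#'   computed dose per image).
#' @param wavelength X-ray wavelength in angstrom (used for the Lorentz
#'   factor).
#' @return An object of class `ssrox_beam`.
#' @examples
#' b <- beam_condition(flux = 4.8e12, transmission = 0.194, frame_rate = 100,
#'                     dose_rate = 4.2)
#' photons_per_image(b)
#' @export
beam_condition <- function(flux = 4.8e12, transmission = 0.194, frame_rate = 100,
                           dose_rate = 4.2, nominal_dose_kgy = NULL,
                           wavelength = 1.0) {
  vals <- c(flux, transmission, frame_rate, dose_rate, wavelength)
  if (any(!is.finite(vals)) || any(vals[-4] <= 0) || dose_rate < 0) {
    abort("beam parameters must be positive (dose rate may be zero)",
      class = "ssrox_error_beam"
    )
  }
  if (transmission > 1) {
    abort("`transmission` is a fraction and cannot exceed 1", class = "ssrox_error_beam")
  }
  obj <- structure(
    list(
      flux = flux, transmission = transmission, frame_rate = frame_rate,
      dose_rate = dose_rate, wavelength = wavelength,
      nominal_dose_kgy = nominal_dose_kgy
    ),
    class = "ssrox_beam"
  )
  if (is.null(obj$nominal_dose_kgy)) obj$nominal_dose_kgy <- dose_per_image(obj)
  obj
}

#' Multi-crystal hit and indexability model
#'
#' The number of crystal lattices illuminated in an image is Poisson with
#' mean `lambda_crystals`; an image is a hit when at least one lattice is in
#' the beam. A hit indexes with probability `q1 * gamma_multi^(n_lattices - 1)`:
#' single-lattice hits index with probability `q1` and every additional
#' lattice multiplies the success probability by `gamma_multi`, reproducing
#' the empirical anti-correlation between hit rate and index rate (dense
#' loading produces multi-hit images that defeat single-lattice indexing).
#'
#' Defaults are matched to an overall hit rate of 41.9% (lambda = 0.543) and
#' an index rate of hits of 66.9% given `gamma_multi = 0.6`.
#'
#' @param lambda_crystals Mean illuminated crystals per image (>= 0).
#' @param q1 Indexing probability of a single-lattice image, in \[0, 1\].
#' @param gamma_multi Per-extra-lattice indexability decay factor, in \[0, 1\].
#' @return An object of class `ssrox_hits`.
#' @export
hit_model <- function(lambda_crystals = 0.543, q1 = 0.75, gamma_multi = 0.6) {
  if (lambda_crystals < 0) abort("`lambda_crystals` must be >= 0", class = "ssrox_error_hits")
  if (q1 < 0 || q1 > 1 || gamma_multi < 0 || gamma_multi > 1) {
    abort("`q1` and `gamma_multi` must lie in [0, 1]", class = "ssrox_error_hits")
  }
  structure(
    list(lambda_crystals = lambda_crystals, q1 = q1, gamma_multi = gamma_multi),
    class = "ssrox_hits"
  )
}

# Analytic hit rate: P(n_lattices >= 1)
hit_rate_expected <- function(hits) {
  1 - exp(-hits$lambda_crystals)
}

# Analytic index rate of hits: sum_{k>=1} P(k) q1 gamma^(k-1) / P(k>=1)
index_rate_expected <- function(hits) {
  lam <- hits$lambda_crystals
  if (lam == 0) return(NA_real_)
  g <- hits$gamma_multi
  p_hit <- 1 - exp(-lam)
  num <- if (g == 0) {
    hits$q1 * lam * exp(-lam) # only single-lattice images index
  } else {
    hits$q1 * exp(-lam) * (exp(lam * g) - 1) / g
  }
  num / p_hit
}

#' Dose-dependent B-factor damage model
#'
#' Radiation damage is modelled as growth of the overall B factor with
#' absorbed dose: an intensity at resolution s observed after absorbing dose
#' D is damped by `exp(-beta * f * D * s / 2)`, where `f` is
#' `dose_fraction_applied`. The default `f = 0.5` encodes a mean-dose
#' convention: intensities integrated while a dose D accumulates experience,
#' on average, half of it.
#'
#' @param beta B-factor growth coefficient, angstrom squared per MGy (>= 0).
#'   The default 15 makes the fitted B factor roughly double between a
#'   low-dose reference and 1.7 MGy for a crystal with B near 13 angstrom
#'   squared.
#' @param dose_fraction_applied Fraction of the per-image dose whose damage
#'   the recorded intensities experience, in \[0, 1\].
#' @return An object of class `ssrox_damage`.
#' @export
damage_model <- function(beta = 15, dose_fraction_applied = 0.5) {
  if (beta < 0) abort("`beta` must be >= 0", class = "ssrox_error_damage")
  if (dose_fraction_applied < 0 || dose_fraction_applied > 1) {
    abort("`dose_fraction_applied` must lie in [0, 1]", class = "ssrox_error_damage")
  }
  structure(
    list(beta = beta, dose_fraction_applied = dose_fraction_applied),
    class = "ssrox_damage"
  )
}

#' Unit-cell drift model
#'
#' Each cell parameter follows a piecewise-linear trajectory over the
#' acquisition: linear from `start` to `end` up to a `knot` (fraction of the
#' acquisition), constant thereafter, plus independent per-image Gaussian
#' jitter. This emulates the drift seen during room-temperature serial
#' collection, where the cell equilibrates partway through the run (e.g. the
#' c axis growing from 38.38 to 38.79 angstrom and then holding steady).
#'
#' @param a,b,c,alpha,beta,gamma Per-parameter specifications. Each is either
#'   a single number (constant) or a list/vector with elements
#'   `start`, `end`, and optionally `knot` (default 0.5) and `jitter`
#'   (Gaussian sigma per image, default 0).
#' @return An object of class `ssrox_drift`: a named list of per-parameter
#'   `(start, end, knot, jitter)` records.
#' @examples
#' dr <- drift_model(
#'   a = list(start = 78.44, end = 78.34),
#'   b = list(start = 78.44, end = 78.34),
#'   c = list(start = 38.38, end = 38.79, knot = 0.5, jitter = 0.01)
#' )
#' cell_at(dr, image_index = 0, total_images = 22200, seed = 1)
#' @export
drift_model <- function(a = 78.44, b = 78.44, c = 38.38,
                        alpha = 90, beta = 90, gamma = 90) {
  spec_one <- function(x, name) {
    if (is.numeric(x) && length(x) == 1) {
      x <- list(start = x, end = x)
    }
    x <- as.list(x)
    rec <- list(
      start = as.numeric(x$start), end = as.numeric(x$end),
      knot = as.numeric(x$knot %||% 0.5), jitter = as.numeric(x$jitter %||% 0)
    )
    if (!is.finite(rec$start) || !is.finite(rec$end)) {
      abort(sprintf("drift for `%s` needs numeric start/end", name),
        class = "ssrox_error_drift"
      )
    }
    if (rec$knot <= 0 || rec$knot > 1) {
      abort(sprintf("drift knot for `%s` must lie in (0, 1]", name),
        class = "ssrox_error_drift"
      )
    }
    if (rec$jitter < 0) {
      abort(sprintf("drift jitter for `%s` must be >= 0", name),
        class = "ssrox_error_drift"
      )
    }
    rec
  }
  params <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  structure(
    purrr::imap(params, spec_one),
    class = "ssrox_drift"
  )
}

#' Observation-noise model
#'
#' Controls how true intensities are corrupted into per-image observations.
#' Each indexed image measures a random subset (`obs_fraction`) of the unique
#' reflections with partiality drawn uniformly on (0, 1], a per-image
#' log-normal linear scale with median 1 and log-sd `scale_sdlog`, and photon
#' counting noise. The expected signal counts for an observation are
#' `gain * photons_per_image * intensity`; on top of them sits a scattering
#' background of `background_per_photon * photons_per_image` expected counts
#' inside the spot integration area. Raw counts are Poisson in
#' (signal + background); the known background expectation is subtracted
#' (so recorded intensities can be negative) and Gaussian read noise of sd
#' `read_noise_sd` counts is added. `sigma_obs` is
#' sqrt(raw counts + read_noise_sd^2) mapped back to the intensity scale.
#' Because the background grows with the photon budget while the diffracted
#' signal is damped by radiation damage, brighter exposure conditions do not
#' improve data quality without bound.
#'
#' @param obs_fraction Fraction of the truth set observed per indexed image,
#'   in (0, 1].
#' @param scale_sdlog Log-sd of the per-image linear scale (>= 0).
#' @param gain Expected detector counts per unit intensity per incident
#'   photon.
#' @param background_per_photon Expected background counts per incident
#'   photon under one reflection's integration area (>= 0).
#' @param read_noise_sd Gaussian read noise, detector counts (>= 0).
#' @return An object of class `ssrox_noise`.
#' @details The defaults (with `sigma0 = 100` truth intensities) are
#'   calibrated so the reference 42 kGy beam condition (9.3e9
#'   photons/image) merged over about 3000 indexed images crosses
#'   CC1/2 = 0.5 near 1.7 angstrom, the data quality of the
#'   room-temperature reference experiment the simulator emulates.
#' @export
noise_model <- function(obs_fraction = 0.04, scale_sdlog = 0.2,
                        gain = 5e-12, background_per_photon = 2e-10,
                        read_noise_sd = 3) {
  if (obs_fraction <= 0 || obs_fraction > 1) {
    abort("`obs_fraction` must lie in (0, 1]", class = "ssrox_error_noise")
  }
  if (scale_sdlog < 0 || read_noise_sd < 0 || gain <= 0 || background_per_photon < 0) {
    abort("`scale_sdlog`, `read_noise_sd`, `background_per_photon` must be >= 0 and `gain` > 0",
      class = "ssrox_error_noise"
    )
  }
  structure(
    list(
      obs_fraction = obs_fraction, scale_sdlog = scale_sdlog,
      gain = gain, background_per_photon = background_per_photon,
      read_noise_sd = read_noise_sd
    ),
    class = "ssrox_noise"
  )
}
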