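#' Simulate a serial rotation-crystallography observation stream
#'
#' Runs the full acquisition model: for each of `geometry$total_images`
#' images (scan-major acquisition order, 0-based indices), the number of
#' illuminated crystal lattices is Poisson(`hits$lambda_crystals`); an image
#' with at least one lattice is a hit, and a hit indexes with probability
#' `q1 * gamma_multi^(n_lattices - 1)`. Each indexed image records
#' observations for a seeded random subset of the truth set with uniform
#' (0, 1] partiality, a per-image log-normal linear scale (median 1), the
#' rotation-geometry Lorentz factor, B-factor damage at the condition's
#' per-image dose, and photon-counting noise (Poisson counts proportional to
#' photons per image, plus Gaussian read noise).
#'
#' The hidden diagnostics (`partiality`, `lorentz` per observation,
#' `scale_true` per image) are carried for validation and are not part of the
#' on-disk stream format.
#'
#' @param truth A truth set from [generate_truth()].
#' @param geometry Acquisition geometry ([scan_geometry()]).
#' @param beam Beam condition ([beam_condition()]).
#' @param hits Hit/indexability model ([hit_model()]).
#' @param drift Unit-cell drift model ([drift_model()]); default holds the
#'   truth cell constant.
#' @param damage Damage model ([damage_model()]).
#' @param noise Observation-noise model ([noise_model()]).
#' @param seed Master seed. Every stochastic stage draws from its own
#'   substream derived from this seed, so identical seeds and configurations
#'   give bit-identical streams.
#' @return An object of class `ssrox_stream`: a list with
#'   * `images`: tibble with one row per image — `image`, `scan`, `angle`,
#'     the drifted cell (`a` ... `gamma`), `n_lattices`, `hit`, `indexed`,
#'     `scale_true`;
#'   * `observations`: tibble `image, h, k, l, i_obs, sigma_obs, partiality,
#'     lorentz` (rows only for indexed images);
#'   * `header`: echo of the configuration (laue tag, reference cell,
#'     geometry, beam, per-image dose in kGy, seed).
#' @examples
#' tr <- generate_truth(tetragonal_cell(30, 20), d_min = 3, b_true = 20, seed = 1)
#' st <- simulate_stream(tr, scan_geometry(n_scans = 2, images_per_scan = 50), seed = 1)
#' stream_summary(st)
#' @export
simulate_stream <- function(truth, geometry = scan_geometry(),
                            beam = beam_condition(), hits = hit_model(),
                            drift = NULL, damage = damage_model(),
                            noise = noise_model(), seed = 1) {
  stopifnot(
    inherits(truth, "ssrox_truth"), inherits(geometry, "ssrox_geometry"),
    inherits(beam, "ssrox_beam"), inherits(hits, "ssrox_hits"),
    inherits(damage, "ssrox_damage"), inherits(noise, "ssrox_noise")
  )
  if (is.null(drift)) {
    drift <- drift_model(
      a = truth$cell$a, b = truth$cell$b, c = truth$cell$c,
      alpha = truth$cell$alpha, beta = truth$cell$beta, gamma = truth$cell$gamma
    )
  }
  stopifnot(inherits(drift, "ssrox_drift"))
  refl <- truth$reflections
  if (nrow(refl) == 0) abort("empty truth set", class = "ssrox_error_simulate")

  photons_img <- photons_per_image(beam)
  if (!is.finite(photons_img) || photons_img <= 0) {
    abort("photons per image must be positive", class = "ssrox_error_simulate")
  }
  dose_mgy <- dose_per_image(beam) / 1000 # per-crystal dose: serial, fresh crystals
  # every truth reflection must sit inside the Ewald sphere for this wavelength
  sin_theta_max <- beam$wavelength * sqrt(max(refl$s)) / 2
  if (sin_theta_max >= 1) {
    abort("truth set extends beyond the diffraction limit of this wavelength",
      class = "ssrox_error_simulate"
    )
  }

  n <- geometry$total_images
  cells <- drift_cells(drift, n, seed)
  n_lattices <- with_substream(seed, "lattices", rpois(n, hits$lambda_crystals))
  hit <- n_lattices >= 1L
  p_index <- ifelse(hit, hits$q1 * hits$gamma_multi^(pmax(n_lattices - 1L, 0L)), 0)
  indexed <- with_substream(seed, "indexing", runif(n) < p_index) & hit
  scale_true <- with_substream(seed, "scale", exp(rnorm(n, 0, noise$scale_sdlog)))

  within_scan <- (seq_len(n) - 1L) %% geometry$images_per_scan
  images <- tibble(
    image = seq_len(n) - 1L,
    scan = (seq_len(n) - 1L) %/% geometry$images_per_scan,
    angle = (within_scan - (geometry$images_per_scan - 1) / 2) * geometry$rotation_step,
    a = cells$a, b = cells$b, c = cells$c,
    alpha = cells$alpha, beta = cells$beta, gamma = cells$gamma,
    n_lattices = as.integer(n_lattices), hit = hit, indexed = indexed,
    scale_true = scale_true
  )

  n_refl <- nrow(refl)
  m_obs <- max(1L, as.integer(round(noise$obs_fraction * n_refl)))
  idx_images <- which(indexed)

  lorentz <- lorentz_factor(refl$s, beam$wavelength)
  damage_factor <- apply_damage(rep(1, n_refl), refl$s, dose_mgy, damage)

  if (length(idx_images) > 0) {
    picks <- lapply(idx_images, function(i) {
      with_substream(seed, c("obs", format(i - 1L)), {
        ridx <- sample.int(n_refl, m_obs)
        part <- 1 - runif(m_obs) # uniform on (0, 1]: never exactly zero
        list(ridx = ridx, part = part)
      })
    })
    ridx <- unlist(lapply(picks, `[[`, "ridx"), use.names = FALSE)
    part <- unlist(lapply(picks, `[[`, "part"), use.names = FALSE)
    img0 <- rep(idx_images - 1L, each = m_obs)
    g_img <- rep(scale_true[idx_images], each = m_obs)

    i_model <- refl$i_true[ridx] * part * g_img * lorentz[ridx] * damage_factor[ridx]
    mu_signal <- i_model * noise$gain * photons_img
    mu_bg <- noise$background_per_photon * photons_img
    raw_counts <- with_substream(seed, "counts", {
      rpois(length(mu_signal), mu_signal + mu_bg) +
        rnorm(length(mu_signal), 0, noise$read_noise_sd)
    })
    net_counts <- raw_counts - mu_bg # background expectation subtracted
    to_intensity <- 1 / (noise$gain * photons_img)
    observations <- tibble(
      image = img0,
      h = refl$h[ridx], k = refl$k[ridx], l = refl$l[ridx],
      i_obs = net_counts * to_intensity,
      sigma_obs = sqrt(pmax(raw_counts, 0) + noise$read_noise_sd^2) * to_intensity,
      partiality = part,
      lorentz = lorentz[ridx]
    )
  } else {
    observations <- tibble(
      image = integer(), h = integer(), k = integer(), l = integer(),
      i_obs = double(), sigma_obs = double(),
      partiality = double(), lorentz = double()
    )
  }

  structure(
    list(
      images = images,
      observations = observations,
      header = list(
        format_version = 1L,
        cell_convention = "lengths in angstrom, angles in degrees",
        laue = truth$laue,
        cell = truth$cell,
        geometry = geometry,
        beam = beam,
        dose_per_image_kgy = dose_per_image(beam),
        seed = seed
      ),
      truth = truth
    ),
    class = "ssrox_stream"
  )
}

#' @export
print.ssrox_stream <- function(x, ...) {
  cs <- stream_summary(x)
  cat(sprintf(
    "<ssrox stream> %d images, %d hits, %d indexed, %d observations (%s)\n",
    cs$n_images, cs$n_hits, cs$n_indexed, nrow(x$observations), x$header$laue
  ))
  invisible(x)
}

#' Count images, hits and indexed images of a stream
#'
#' @param stream An observation stream ([simulate_stream()] or
#'   [read_stream()]).
#' @return A one-row tibble with `n_images`, `n_hits`, `n_indexed`.
#' @export
stream_summary <- function(stream) {
  stopifnot(inherits(stream, "ssrox_stream"))
  tibble(
    n_images = nrow(stream$images),
    n_hits = sum(stream$images$hit),
    n_indexed = sum(stream$images$indexed)
  )
}

# Restrict a stream to its first `n_indexed` indexed images (plus all earlier
# non-indexed ones) -- mirrors assembling data sets from a prefix of a run.
head_indexed <- function(stream, n_indexed) {
  stopifnot(inherits(stream, "ssrox_stream"))
  idx <- which(stream$images$indexed)
  if (length(idx) < n_indexed) {
    abort(sprintf(
      "stream holds %d indexed images, %d requested", length(idx), n_indexed
    ), class = "ssrox_error_simulate")
  }
  cut <- idx[n_indexed]
  out <- stream
  out$images <- stream$images[stream$images$image <= stream$images$image[cut], ]
  keep_img <- out$images$image[out$images$indexed]
  out$observations <- stream$observations[stream$observations$image %in% keep_img, ]
  out
}
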