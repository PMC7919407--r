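# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

lyso_cell <- function() tetragonal_cell(a = 78.4, c = 38.4)

# moderate-size truth set for merging tests (~2400 reflections)
small_truth <- function() {
  fixture("small_truth", function() {
    generate_truth(lyso_cell(), d_min = 2.2, b_true = 13, sigma0 = 100, seed = 11)
  })
}

# default-noise stream over the small truth, ~950 indexed images
small_stream <- function() {
  fixture("small_stream", function() {
    simulate_stream(
      small_truth(),
      scan_geometry(n_scans = 10, images_per_scan = 100),
      hits = hit_model(3, 1, 1),
      damage = damage_model(beta = 0), # undamaged: merged mean estimates i_true/2
      noise = noise_model(obs_fraction = 0.1),
      seed = 21
    )
  })
}

# Hand-built stream: every image carries the full reflection list at
# partiality 1, intensity i_true * image_scale * lorentz, no noise.
make_exact_stream <- function(truth, image_scales, wavelength = 1) {
  n <- length(image_scales)
  refl <- truth$reflections
  L <- lorentz_factor(refl$s, wavelength)
  imgs <- tibble::tibble(
    image = seq_len(n) - 1L, scan = 0L, angle = 0,
    a = truth$cell$a, b = truth$cell$b, c = truth$cell$c,
    alpha = truth$cell$alpha, beta = truth$cell$beta, gamma = truth$cell$gamma,
    n_lattices = 1L, hit = TRUE, indexed = TRUE,
    scale_true = image_scales
  )
  obs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(
      image = i - 1L, h = refl$h, k = refl$k, l = refl$l,
      i_obs = refl$i_true * image_scales[i] * L,
      sigma_obs = 1, partiality = 1, lorentz = L
    )
  }))
  structure(
    list(
      images = imgs, observations = obs,
      header = list(
        format_version = 1L,
        cell_convention = "lengths in angstrom, angles in degrees",
        laue = truth$laue, cell = truth$cell,
        geometry = scan_geometry(1, n),
        beam = beam_condition(wavelength = wavelength),
        dose_per_image_kgy = dose_per_image(beam_condition()),
        seed = 0
      ),
      truth = truth
    ),
    class = "ssrox_stream"
  )
}
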