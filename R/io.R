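fmt_num <- function(x) {
  formatC(x, digits = 17, format = "g", width = 1)
}

#' Write / read an observation stream as text
#'
#' The on-disk stream format is a plain-text analogue of a serial
#' crystallography stream: a header of `# key<TAB>value` lines (format
#' version, cell convention, Laue tag, reference cell, geometry and beam
#' echo, master seed), then one block per image in acquisition order --
#' a tab-separated image line
#' `index scan angle a b c alpha beta gamma n_lattices hit indexed`,
#' zero or more observation lines `h k l i_obs sigma_obs`, and a blank-line
#' terminator. Numbers are written with 17 significant digits so
#' `read_stream(write_stream(x))` reproduces every stored numeric field
#' exactly. Unknown header keys are preserved on rewrite. The hidden
#' simulation diagnostics (partiality, Lorentz factor, true scale) are not
#' part of the format.
#'
#' @param stream An observation stream.
#' @param path File path.
#' @return `write_stream()` returns `path` invisibly; `read_stream()`
#'   returns a `ssrox_stream`.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "ssrox_stream"))
  h <- stream$header
  geom <- h$geometry
  beam <- h$beam
  header_kv <- c(
    format_version = as.character(h$format_version %||% 1L),
    cell_convention = h$cell_convention %||% "lengths in angstrom, angles in degrees",
    laue = h$laue,
    cell_a = fmt_num(h$cell$a), cell_b = fmt_num(h$cell$b), cell_c = fmt_num(h$cell$c),
    cell_alpha = fmt_num(h$cell$alpha), cell_beta = fmt_num(h$cell$beta),
    cell_gamma = fmt_num(h$cell$gamma),
    geometry_n_scans = as.character(geom$n_scans),
    geometry_images_per_scan = as.character(geom$images_per_scan),
    geometry_rotation_step = fmt_num(geom$rotation_step),
    geometry_translation_step = fmt_num(geom$translation_step),
    geometry_scan_interval = fmt_num(geom$scan_interval),
    beam_flux = fmt_num(beam$flux),
    beam_transmission = fmt_num(beam$transmission),
    beam_frame_rate = fmt_num(beam$frame_rate),
    beam_dose_rate = fmt_num(beam$dose_rate),
    beam_wavelength = fmt_num(beam$wavelength),
    beam_nominal_dose_kgy = fmt_num(beam$nominal_dose_kgy),
    seed = fmt_num(h$seed)
  )
  extra <- h$extra_keys
  if (!is.null(extra)) header_kv <- c(header_kv, extra)
  header_lines <- paste0("# ", names(header_kv), "\t", header_kv)

  imgs <- stream$images
  img_lines <- paste(
    imgs$image, imgs$scan, fmt_num(imgs$angle),
    fmt_num(imgs$a), fmt_num(imgs$b), fmt_num(imgs$c),
    fmt_num(imgs$alpha), fmt_num(imgs$beta), fmt_num(imgs$gamma),
    imgs$n_lattices, as.integer(imgs$hit), as.integer(imgs$indexed),
    sep = "\t"
  )
  obs <- stream$observations
  obs_lines <- if (nrow(obs) > 0) {
    split(
      paste(obs$h, obs$k, obs$l, fmt_num(obs$i_obs), fmt_num(obs$sigma_obs), sep = "\t"),
      factor(obs$image, levels = imgs$image)
    )
  } else {
    split(character(0), factor(integer(0), levels = imgs$image))
  }
  blocks <- vector("list", nrow(imgs))
  for (i in seq_len(nrow(imgs))) {
    blocks[[i]] <- c(img_lines[i], obs_lines[[i]], "")
  }
  writeLines(c(header_lines, unlist(blocks)), path)
  invisible(path)
}

parse_error <- function(line_no, what) {
  abort(sprintf("stream parse error at line %d: %s", line_no, what),
    class = "ssrox_error_parse"
  )
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "# ")
  n_header <- if (any(!is_header)) which(!is_header)[1] - 1L else length(lines)
  hdr_raw <- lines[seq_len(n_header)]
  body <- lines[seq_len(length(lines) - n_header) + n_header]
  body_line_no <- seq_along(body) + n_header

  kv <- strsplit(sub("^# ", "", hdr_raw), "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "\t"), character(1))
  header_kv <- setNames(vals, keys)
  num <- function(key, default = NA_real_) {
    if (key %in% keys) as.numeric(header_kv[[key]]) else default
  }
  known <- c(
    "format_version", "cell_convention", "laue",
    paste0("cell_", c("a", "b", "c", "alpha", "beta", "gamma")),
    paste0("geometry_", c(
      "n_scans", "images_per_scan", "rotation_step",
      "translation_step", "scan_interval"
    )),
    paste0("beam_", c(
      "flux", "transmission", "frame_rate", "dose_rate",
      "wavelength", "nominal_dose_kgy"
    )),
    "seed"
  )
  extra_keys <- header_kv[setdiff(keys, known)]
  if (length(extra_keys) == 0) extra_keys <- NULL

  if (length(body) > 0 && body[length(body)] != "") {
    abort("truncated final image block: missing blank-line terminator",
      class = "ssrox_error_parse"
    )
  }
  if (length(body) == 0 || all(body == "")) {
    body <- character(0)
    body_line_no <- integer(0)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  nf[body == ""] <- 0L
  block_id <- if (length(body) > 0) {
    cumsum(c(1L, head(body, -1) == ""))
  } else {
    integer(0)
  }
  block_id[body == ""] <- NA

  img_rows <- which(!duplicated(block_id) & !is.na(block_id))
  obs_rows <- setdiff(which(!is.na(block_id)), img_rows)

  bad_img <- img_rows[nf[img_rows] != 12L]
  if (length(bad_img) > 0) {
    parse_error(body_line_no[bad_img[1]], "image line must have 12 tab-separated fields")
  }
  bad_obs <- obs_rows[nf[obs_rows] != 5L]
  if (length(bad_obs) > 0) {
    parse_error(body_line_no[bad_obs[1]], "observation line must have 5 tab-separated fields")
  }

  parse_block <- function(rows, ncol, label) {
    if (length(rows) == 0) {
      return(matrix(numeric(0), ncol = ncol))
    }
    m <- matrix(
      suppressWarnings(as.numeric(unlist(fields[rows], use.names = FALSE))),
      ncol = ncol, byrow = TRUE
    )
    bad <- rows[which(rowSums(is.na(m)) > 0)]
    if (length(bad) > 0) {
      parse_error(body_line_no[bad[1]], sprintf("non-numeric field in %s line", label))
    }
    m
  }
  im <- parse_block(img_rows, 12, "image")
  ob <- parse_block(obs_rows, 5, "observation")
  int_ok <- function(x) all(x == round(x))
  if (nrow(im) > 0 && !int_ok(im[, c(1, 2, 10, 11, 12)])) {
    parse_error(
      body_line_no[img_rows[1]],
      "image index, scan, n_lattices and flags must be integers"
    )
  }
  if (nrow(ob) > 0 && !int_ok(ob[, 1:3])) {
    bad <- obs_rows[which(apply(ob[, 1:3, drop = FALSE], 1, function(r) any(r != round(r))))]
    parse_error(body_line_no[bad[1]], "Miller indices must be integers")
  }

  images <- tibble(
    image = as.integer(im[, 1]), scan = as.integer(im[, 2]), angle = im[, 3],
    a = im[, 4], b = im[, 5], c = im[, 6],
    alpha = im[, 7], beta = im[, 8], gamma = im[, 9],
    n_lattices = as.integer(im[, 10]),
    hit = im[, 11] == 1, indexed = im[, 12] == 1,
    scale_true = NA_real_
  )
  obs_block <- block_id[obs_rows]
  img_of_block <- setNames(images$image, block_id[img_rows])
  observations <- tibble(
    image = if (length(obs_rows) > 0) {
      as.integer(img_of_block[as.character(obs_block)])
    } else {
      integer(0)
    },
    h = as.integer(ob[, 1]), k = as.integer(ob[, 2]), l = as.integer(ob[, 3]),
    i_obs = ob[, 4], sigma_obs = ob[, 5],
    partiality = NA_real_, lorentz = NA_real_
  )

  cell <- unit_cell(
    num("cell_a"), num("cell_b"), num("cell_c"),
    num("cell_alpha", 90), num("cell_beta", 90), num("cell_gamma", 90)
  )
  geometry <- scan_geometry(
    n_scans = num("geometry_n_scans", 1),
    images_per_scan = num("geometry_images_per_scan", max(1, nrow(images))),
    rotation_step = num("geometry_rotation_step", 0.25),
    translation_step = num("geometry_translation_step", 9),
    scan_interval = num("geometry_scan_interval", 20)
  )
  beam <- beam_condition(
    flux = num("beam_flux", 4.8e12),
    transmission = num("beam_transmission", 0.194),
    frame_rate = num("beam_frame_rate", 100),
    dose_rate = num("beam_dose_rate", 4.2),
    nominal_dose_kgy = num("beam_nominal_dose_kgy", NA),
    wavelength = num("beam_wavelength", 1)
  )
  structure(
    list(
      images = images, observations = observations,
      header = list(
        format_version = as.integer(num("format_version", 1)),
        cell_convention = unname(header_kv["cell_convention"] %||%
          "lengths in angstrom, angles in degrees"),
        laue = unname(header_kv["laue"] %||% "4/mmm"),
        cell = cell, geometry = geometry, beam = beam,
        dose_per_image_kgy = dose_per_image(beam),
        seed = num("seed", NA),
        extra_keys = extra_keys
      ),
      truth = NULL
    ),
    class = "ssrox_stream"
  )
}

#' Write / read a merged reflection table
#'
#' Whitespace-separated table with a header row; columns `h k l i_merged
#' sigma m i_even i_odd n_even n_odd` (undefined sigmas and half means are
#' written as `NA`).
#'
#' @param merged A merged set from [monte_carlo_merge()].
#' @param path File path.
#' @param cell,laue Reattached on read to recompute `d` and `s` (optional;
#'   without them those columns are absent).
#' @return `write_merged()` returns `path` invisibly; `read_merged()` a
#'   tibble.
#' @export
write_merged <- function(merged, path) {
  df <- data.frame(
    h = merged$h, k = merged$k, l = merged$l,
    i_merged = fmt_num(merged$i_merged), sigma = fmt_num(merged$sigma_merged),
    m = merged$m,
    i_even = fmt_num(merged$i_even), i_odd = fmt_num(merged$i_odd),
    n_even = merged$n_even, n_odd = merged$n_odd
  )
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_merged
#' @export
read_merged <- function(path, cell = NULL, laue = "4/mmm") {
  df <- utils::read.table(path, header = TRUE, sep = "")
  names(df)[names(df) == "sigma"] <- "sigma_merged"
  out <- as_tibble(df)
  if (!is.null(cell)) {
    cell <- as_cell(cell)
    out$s <- inv_d2(cell, out$h, out$k, out$l)
    out$d <- 1 / sqrt(out$s)
    out <- structure(out,
      class = c("ssrox_merged", class(out)),
      cell = cell, laue = laue
    )
  }
  out
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (or `key=value`); blank lines and lines
#' starting with `#` are ignored. Values that parse as numbers become
#' numeric.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(list())
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) {
    abort(sprintf("config line without '=': %s", lines[which(eq < 0)[1]]),
      class = "ssrox_error_parse"
    )
  }
  keys <- trimws(substr(lines, 1, eq - 1))
  vals <- trimws(substr(lines, eq + 1, nchar(lines)))
  parsed <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  setNames(parsed, keys)
}
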