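# Plain-text persistence: versioned columnar dataset files, image files,
# grayscale raster export, and run configuration.
#
# DatasetFileV1: '#'-prefixed header lines (key value), then a CSV block
#   freq_hz,tx,rx,phi,re,im covering the full Cartesian index set exactly
#   once, full decimal precision. ImageFileV1 is analogous with one voxel
#   value per row. Both round-trip bit-exactly.

.mwi_fmt <- function(x) sprintf("%.17g", x)

#' Write a scattering dataset to a DatasetFileV1 text file
#'
#' @param ds An `mwi_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "mwi_dataset"))
  g <- ds$geometry
  d <- dim(ds$s)
  hdr <- c(
    "# mwibeam dataset v1",
    sprintf("# n_tx %d", g$n_tx),
    sprintf("# n_rx %d", g$n_rx),
    sprintf("# n_phi %d", g$n_phi),
    sprintf("# phi_step_deg %s", .mwi_fmt(g$phi_step)),
    sprintf("# radius_m %s", .mwi_fmt(g$radius)),
    sprintf("# z_plane_m %s", .mwi_fmt(g$z_plane)),
    sprintf("# n_freq %d", d[1]),
    sprintf("# seed %d", if (is.null(ds$meta$seed)) NA_integer_
            else ds$meta$seed)
  )
  idx <- expand.grid(fi = seq_len(d[1]), tx = seq_len(d[2]),
                     rx = seq_len(d[3]), phi = seq_len(d[4]),
                     KEEP.OUT.ATTRS = FALSE)
  s <- as.vector(ds$s)
  rows <- paste(.mwi_fmt(ds$freqs[idx$fi]), idx$tx, idx$rx, idx$phi,
                .mwi_fmt(Re(s)), .mwi_fmt(Im(s)), sep = ",")
  writeLines(c(hdr, "freq_hz,tx,rx,phi,re,im", rows), path)
  invisible(path)
}

.mwi_read_header <- function(lines, stage) {
  hdr_lines <- grep("^#", lines, value = TRUE)
  .mwi_check(length(hdr_lines) > 0, "mwi_format_error",
             "[%s] file has no '#' header block", stage)
  kv <- list()
  for (ln in hdr_lines[-1]) {
    parts <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
    if (length(parts) >= 2) kv[[parts[1]]] <- parts[2]
  }
  list(magic = hdr_lines[1], kv = kv, n_header = length(hdr_lines))
}

#' Read a DatasetFileV1 text file
#'
#' Validates the format version, the rotation-step consistency
#' (`n_phi * phi_step = 360`), complete Cartesian index coverage with no
#' duplicates, and reconstructs the dataset (bit-exact round trip).
#'
#' @param path Path to a file written by [write_dataset()].
#' @return An `mwi_dataset`.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  h <- .mwi_read_header(lines, "read_dataset")
  .mwi_check(grepl("mwibeam dataset v1", h$magic), "mwi_format_error",
             "[read_dataset] unsupported format: %s", h$magic)
  need <- c("n_tx", "n_rx", "n_phi", "phi_step_deg", "radius_m",
            "z_plane_m", "n_freq")
  for (k in need) {
    .mwi_check(!is.null(h$kv[[k]]), "mwi_format_error",
               "[read_dataset] missing header key %s", k)
  }
  n_tx <- as.integer(h$kv$n_tx); n_rx <- as.integer(h$kv$n_rx)
  n_phi <- as.integer(h$kv$n_phi)
  phi_step <- as.numeric(h$kv$phi_step_deg)
  .mwi_check(abs(n_phi * phi_step - 360) <= 360 * 1e-9, "mwi_format_error",
             "[read_dataset] n_phi (%d) x phi_step (%g) != 360 degrees",
             n_phi, phi_step)
  n_freq <- as.integer(h$kv$n_freq)

  body <- lines[!grepl("^#", lines)]
  .mwi_check(length(body) >= 1 && body[1] == "freq_hz,tx,rx,phi,re,im",
             "mwi_format_error", "[read_dataset] missing column header row")
  dat <- utils::read.csv(textConnection(body), header = TRUE)
  n_expected <- n_freq * n_tx * n_rx * n_phi
  .mwi_check(nrow(dat) == n_expected, "mwi_format_error",
             "[read_dataset] expected %d rows, found %d",
             n_expected, nrow(dat))
  freqs <- sort(unique(dat$freq_hz))
  .mwi_check(length(freqs) == n_freq, "mwi_format_error",
             "[read_dataset] found %d distinct frequencies, header says %d",
             length(freqs), n_freq)
  fi <- match(dat$freq_hz, freqs)
  .mwi_check(all(dat$tx >= 1 & dat$tx <= n_tx & dat$rx >= 1 &
                   dat$rx <= n_rx & dat$phi >= 1 & dat$phi <= n_phi),
             "mwi_format_error", "[read_dataset] index out of range")
  key <- fi + n_freq * ((dat$tx - 1) + n_tx * ((dat$rx - 1) +
                                                 n_rx * (dat$phi - 1)))
  dup <- duplicated(key)
  if (any(dup)) {
    r <- which(dup)[1]
    .mwi_stop("mwi_format_error",
              "[read_dataset] duplicate record for (f=%g, tx=%d, rx=%d, phi=%d)",
              dat$freq_hz[r], dat$tx[r], dat$rx[r], dat$phi[r])
  }
  missing_key <- setdiff(seq_len(n_expected), key)
  if (length(missing_key)) {
    k <- missing_key[1] - 1
    .mwi_stop("mwi_format_error",
              "[read_dataset] missing record for (f index=%d, tx=%d, rx=%d, phi=%d)",
              k %% n_freq + 1, (k %/% n_freq) %% n_tx + 1,
              (k %/% (n_freq * n_tx)) %% n_rx + 1,
              k %/% (n_freq * n_tx * n_rx) + 1)
  }
  s <- array(0 + 0i, c(n_freq, n_tx, n_rx, n_phi))
  s[key] <- complex(real = dat$re, imaginary = dat$im)
  geom <- build_cylindrical_array(n_tx, n_rx, as.numeric(h$kv$radius_m),
                                  n_phi, phi_step,
                                  z_plane = as.numeric(h$kv$z_plane_m))
  structure(
    list(s = s, freqs = freqs, geometry = geom,
         meta = list(seed = if (is.null(h$kv$seed)) NA_integer_
                     else as.integer(h$kv$seed))),
    class = "mwi_dataset"
  )
}

#' Write a scattering intensity map to an ImageFileV1 text file
#'
#' @param map An `mwi_map`.
#' @param path Output file path.
#' @param state Optional IC-DMAS iteration state; records the iteration
#'   count and convergence history in the header.
#' @return `path`, invisibly.
#' @export
write_image <- function(map, path, state = NULL) {
  stopifnot(inherits(map, "mwi_map"))
  g <- map$grid
  hdr <- c(
    "# mwibeam image v1",
    sprintf("# algorithm %s", map$algorithm),
    sprintf("# n_iter %d", map$n_iter),
    sprintf("# mode %s", g$mode),
    sprintf("# shape %s", paste(g$shape, collapse = ",")),
    sprintf("# spacing_m %s", .mwi_fmt(g$spacing)),
    sprintf("# extent_m %s", paste(.mwi_fmt(g$extent), collapse = ",")),
    sprintf("# z_plane_m %s", .mwi_fmt(g$z[1]))
  )
  if (!is.null(state)) {
    hdr <- c(hdr, sprintf("# e_history %s",
                          paste(.mwi_fmt(state$e_history), collapse = ",")))
  }
  writeLines(c(hdr, "value", .mwi_fmt(map$values)), path)
  invisible(path)
}

#' Read an ImageFileV1 text file
#'
#' @param path Path to a file written by [write_image()].
#' @return An `mwi_map` (with `e_history` attribute when present).
#' @export
read_image <- function(path) {
  lines <- readLines(path)
  h <- .mwi_read_header(lines, "read_image")
  .mwi_check(grepl("mwibeam image v1", h$magic), "mwi_format_error",
             "[read_image] unsupported format: %s", h$magic)
  shape <- as.integer(strsplit(h$kv$shape, ",")[[1]])
  extent <- as.numeric(strsplit(h$kv$extent_m, ",")[[1]])
  grid <- build_imaging_grid(extent, as.numeric(h$kv$spacing_m),
                             mode = h$kv$mode,
                             z_plane = as.numeric(h$kv$z_plane_m))
  .mwi_check(identical(grid$shape, shape), "mwi_format_error",
             "[read_image] header shape (%s) inconsistent with extent/spacing (%s)",
             paste(shape, collapse = "x"), paste(grid$shape, collapse = "x"))
  body <- lines[!grepl("^#", lines)]
  .mwi_check(length(body) >= 1 && body[1] == "value", "mwi_format_error",
             "[read_image] missing column header row")
  values <- as.numeric(body[-1])
  .mwi_check(!anyNA(values), "mwi_format_error",
             "[read_image] non-numeric voxel values")
  .mwi_check(length(values) == prod(shape), "mwi_format_error",
             "[read_image] expected %d voxels, found %d",
             prod(shape), length(values))
  out <- .mwi_map(values, grid, h$kv$algorithm,
                  n_iter = as.integer(h$kv$n_iter))
  if (!is.null(h$kv$e_history)) {
    attr(out, "e_history") <- as.numeric(strsplit(h$kv$e_history, ",")[[1]])
  }
  out
}

#' Export a map as a portable ASCII grayscale raster (PGM "P2")
#'
#' Values are clamped at zero and peak-normalized to 0..255. The brightest
#' pixel coincides with the map's argmax. Plain-text format for visual
#' inspection with any image viewer.
#'
#' @param map An `mwi_map` on a slice2d grid.
#' @param path Output file path (.pgm).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(map, path) {
  stopifnot(inherits(map, "mwi_map"))
  .mwi_check(map$grid$mode == "slice2d", "mwi_config_error",
             "PGM export is implemented for slice2d grids")
  v <- pmax(map$values, 0)
  mx <- max(v)
  pix <- if (mx > 0) as.integer(round(v / mx * 255)) else
    as.integer(rep(0, length(v)))
  nx <- map$grid$shape[1]; ny <- map$grid$shape[2]
  m <- matrix(pix, nrow = nx)
  # PGM scans top row first; grid y ascends, so flip rows.
  rows <- vapply(rev(seq_len(ny)),
                 function(j) paste(m[, j], collapse = " "), character(1))
  writeLines(c("P2", sprintf("%d %d", nx, ny), "255", rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration (structured text, YAML).

#' Default pipeline configuration
#'
#' Returns the full default configuration of the end-to-end pipeline as a
#' nested list; [run_pipeline()] merges a user configuration over it. The
#' defaults are the package's desk-scale study conditions: a 4 Tx x 4 Rx
#' array rotating through 50 positions of 7.2 degrees, 101 frequency points
#' over 2.7-8 GHz, and a 2 mm imaging slice. See the methods vignette for
#' their rationale.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    geometry = list(n_tx = 4L, n_rx = 4L, radius_m = 0.1, n_phi = 50L,
                    phi_step_deg = 7.2, z_plane_m = 0),
    freqs = list(n = 101L, f_start_hz = 2.7e9, f_stop_hz = 8.0e9),
    phantom = list(preset = "B", background_eps = 1.1, noise_sigma = NULL,
                   skin_radius_m = 0.05, skin_reflectivity = 100),
    grid = list(extent_m = c(-0.04, 0.04, -0.04, 0.04), spacing_m = 0.002,
                mode = "slice2d"),
    preprocess = list(window = "hann", pad_factor = 4L),
    reconstruct = list(eps_b = 1, gate = "auto",
                       algorithms = c("das", "dmas", "icdmas")),
    icdmas = list(threshold = 1e-5, max_iter = 7L, path_scale = 0.003),
    metrics = list(mask_radius_m = 0.005, min_separation_m = NULL),
    seed = 1L
  )
}

.mwi_merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- .mwi_merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML configuration merged over [default_config()].
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    .mwi_check(file.exists(path), "mwi_config_error",
               "config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- .mwi_merge_config(cfg, user)
  }
  cfg
}
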