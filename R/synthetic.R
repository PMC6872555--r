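# Synthetic multistatic scattering simulator.
#
# Stands in for the antenna-array/VNA acquisition: a scalar point-scatterer
# Born-type forward model (geometric delays, 1/r spreading, no multiple
# scattering), a rotation-invariant additive skin term, and circularly
# symmetric complex Gaussian noise from one seeded stream.

#' Complex relative permittivity of a lossy dielectric
#'
#' `eps = eps_r + i * sigma / (omega * eps0)` with `omega = 2 * pi * freq`.
#' This is the standard single-frequency parameterization of tissue
#' dielectric properties (dielectric constant plus conductivity loss).
#'
#' @param eps_r Relative permittivity (>= 1).
#' @param sigma Conductivity in S/m (>= 0).
#' @param freq Frequency in Hz (> 0); may be a vector.
#' @return Complex permittivity, same length as `freq`.
#' @examples
#' complex_permittivity(10, 1, 1e9)  # 10 + 17.975i
#' @export
complex_permittivity <- function(eps_r, sigma, freq) {
  .mwi_check(is.numeric(eps_r) && length(eps_r) == 1 && eps_r >= 1,
             "mwi_domain_error", "eps_r must be >= 1")
  .mwi_check(is.numeric(sigma) && length(sigma) == 1 && sigma >= 0,
             "mwi_domain_error", "sigma must be >= 0")
  .mwi_check(is.numeric(freq) && all(freq > 0), "mwi_domain_error",
             "freq must be > 0")
  complex(real = eps_r, imaginary = sigma / (2 * pi * freq * .mwi_eps0))
}

#' Construct a phantom model
#'
#' A phantom is an abstract scattering scene: a homogeneous propagation
#' medium, an optional rotation-invariant skin ring, and point scatterers
#' ("tumors") given as position + reflectivity. Presets mirror a laboratory
#' phantom series: `"A"` has no tumor, `"B"` one, `"C"` two.
#'
#' Preset conditions (chosen once as the package's study conditions, see the
#' methods vignette): propagation permittivity 1.03 (a mild effective-medium
#' slow-down relative to the air background the reconstruction assumes,
#' emulating the under-estimated average dielectric constant that the
#' iterative correction compensates), skin:tumor reflectivity 100:1, tumors
#' of equal reflectivity (the same tumor-mimicking material), preset B
#' noiseless, preset C with `noise_sigma = 0.5` (moderate noise, ~10% of a
#' tumor channel amplitude).
#'
#' @param preset `"A"`, `"B"` or `"C"`, or `NULL` to build a custom phantom
#'   from the remaining arguments.
#' @param seed Integer seed stored with the phantom; drives the simulator's
#'   noise stream.
#' @param background_eps Relative permittivity of the propagation medium.
#' @param scatterers List of `list(position = c(x, y, z), reflectivity = r)`;
#'   overrides the preset's scatterers when given.
#' @param skin `list(radius = , reflectivity = )` or `NULL` for no skin term.
#' @param noise_sigma Standard deviation of the complex Gaussian noise per
#'   sample (total variance; >= 0). Overrides the preset default when given.
#' @param array_radius Radius (m) inside which scatterers must lie.
#' @return An object of class `mwi_phantom`.
#' @examples
#' make_phantom("B", seed = 1)
#' @export
make_phantom <- function(preset = c("B", "A", "C"), seed = 1L,
                         background_eps = 1.03, scatterers = NULL,
                         skin = list(radius = 0.05, reflectivity = 100),
                         noise_sigma = NULL, array_radius = 0.1) {
  if (!is.null(preset)) preset <- match.arg(preset)
  .mwi_check(is.numeric(seed) && length(seed) == 1 && seed == round(seed),
             "mwi_config_error", "seed must be an integer")
  .mwi_check(is.numeric(background_eps) && background_eps >= 1,
             "mwi_domain_error", "background_eps must be >= 1")
  if (is.null(scatterers)) {
    scatterers <- switch(
      if (is.null(preset)) "custom" else preset,
      A = list(),
      B = list(list(position = c(0.010, 0, 0), reflectivity = 1)),
      C = list(list(position = c(0.010, 0, 0), reflectivity = 1),
               list(position = c(-0.010, 0, 0), reflectivity = 1)),
      custom = list()
    )
  }
  if (is.null(noise_sigma)) {
    noise_sigma <- if (!is.null(preset) && preset == "C") 0.5 else 0
  }
  .mwi_check(is.numeric(noise_sigma) && length(noise_sigma) == 1 &&
               noise_sigma >= 0,
             "mwi_domain_error", "noise_sigma must be >= 0")
  for (s in scatterers) {
    .mwi_check(is.numeric(s$position) && length(s$position) == 3 &&
                 all(is.finite(s$position)),
               "mwi_config_error", "scatterer position must be length-3 xyz")
    .mwi_check(is.numeric(s$reflectivity) && is.finite(s$reflectivity),
               "mwi_config_error", "scatterer reflectivity must be finite")
    .mwi_check(sqrt(sum(s$position[1:2]^2)) < array_radius,
               "mwi_config_error",
               "scatterer at (%g, %g, %g) lies outside the array radius %g m",
               s$position[1], s$position[2], s$position[3], array_radius)
  }
  if (!is.null(skin)) {
    .mwi_check(is.numeric(skin$radius) && skin$radius > 0 &&
                 skin$radius < array_radius,
               "mwi_config_error",
               "skin radius must lie inside the array radius")
    .mwi_check(is.numeric(skin$reflectivity) && is.finite(skin$reflectivity),
               "mwi_config_error", "skin reflectivity must be finite")
  }
  structure(
    list(preset = preset, background_eps = background_eps,
         scatterers = scatterers, skin = skin, noise_sigma = noise_sigma,
         seed = as.integer(seed), array_radius = array_radius),
    class = "mwi_phantom"
  )
}

#' @export
print.mwi_phantom <- function(x, ...) {
  cat(sprintf("Phantom%s: %d scatterer(s), %s, eps = %g, noise sigma = %g\n",
              if (is.null(x$preset)) "" else paste0(" (preset ", x$preset, ")"),
              length(x$scatterers),
              if (is.null(x$skin)) "no skin" else
                sprintf("skin ring r = %g m", x$skin$radius),
              x$background_eps, x$noise_sigma))
  invisible(x)
}

#' Simulate a multistatic frequency-domain scattering dataset
#'
#' Forward model per sample (f, tx, rx, phi): sum over scatterers of
#' `reflectivity / d * exp(-i 2 pi f tau)` with `d` the two-way geometric
#' path tx -> scatterer -> rx at rotation `phi` and
#' `tau = sqrt(background_eps) * d / c` (1/r free-space spreading, Born
#' approximation), plus a skin term that is by construction identical across
#' rotation positions (radial two-way path antenna -> skin ring), plus
#' i.i.d. circularly symmetric complex Gaussian noise seeded from the
#' phantom seed.
#'
#' @param phantom An `mwi_phantom`.
#' @param geom An `mwi_geometry`.
#' @param freqs Frequencies in Hz, strictly increasing.
#' @param seed Noise seed; defaults to the phantom's stored seed.
#' @return An object of class `mwi_dataset`: complex array `s` indexed
#'   (freq, tx, rx, phi), plus `freqs`, `geometry`, and provenance `meta`.
#' @export
simulate_scatter_dataset <- function(phantom, geom, freqs,
                                     seed = phantom$seed) {
  stopifnot(inherits(phantom, "mwi_phantom"), inherits(geom, "mwi_geometry"))
  .mwi_check(is.numeric(freqs) && length(freqs) >= 1 && all(freqs > 0),
             "mwi_config_error", "freqs must be positive frequencies")
  .mwi_check(length(freqs) == 1 || all(diff(freqs) > 0),
             "mwi_config_error", "freqs must be strictly increasing")
  n_f <- length(freqs)
  s <- array(0 + 0i, c(n_f, geom$n_tx, geom$n_rx, geom$n_phi))
  sq_eps <- sqrt(phantom$background_eps)

  for (phi in seq_len(geom$n_phi)) {
    pos <- antenna_positions_at_rotation(geom, phi)
    for (sc in phantom$scatterers) {
      q <- sc$position
      d_tx <- sqrt((pos$tx[, 1] - q[1])^2 + (pos$tx[, 2] - q[2])^2 +
                     (pos$tx[, 3] - q[3])^2)
      d_rx <- sqrt((pos$rx[, 1] - q[1])^2 + (pos$rx[, 2] - q[2])^2 +
                     (pos$rx[, 3] - q[3])^2)
      for (a in seq_len(geom$n_tx)) {
        for (b in seq_len(geom$n_rx)) {
          d <- d_tx[a] + d_rx[b]
          tau <- sq_eps * d / .mwi_c0
          s[, a, b, phi] <- s[, a, b, phi] +
            (sc$reflectivity / d) * exp(-2i * pi * freqs * tau)
        }
      }
    }
  }

  if (!is.null(phantom$skin)) {
    # Radial two-way path from the cylinder to the skin ring; independent of
    # rotation and of the antenna index, hence exactly rotation-invariant.
    d_skin <- 2 * (geom$radius - phantom$skin$radius)
    tau_skin <- sq_eps * d_skin / .mwi_c0
    skin_term <- (phantom$skin$reflectivity / d_skin) *
      exp(-2i * pi * freqs * tau_skin)
    for (a in seq_len(geom$n_tx)) {
      for (b in seq_len(geom$n_rx)) {
        for (phi in seq_len(geom$n_phi)) {
          s[, a, b, phi] <- s[, a, b, phi] + skin_term
        }
      }
    }
  }

  if (phantom$noise_sigma > 0) {
    n <- length(s)
    set.seed(seed)
    s <- s + complex(real = rnorm(n, sd = phantom$noise_sigma / sqrt(2)),
                     imaginary = rnorm(n, sd = phantom$noise_sigma / sqrt(2)))
    dim(s) <- c(n_f, geom$n_tx, geom$n_rx, geom$n_phi)
  }

  structure(
    list(s = s, freqs = freqs, geometry = geom,
         meta = list(seed = as.integer(seed),
                     phantom = phantom,
                     n_scatterers = length(phantom$scatterers))),
    class = "mwi_dataset"
  )
}

#' @export
print.mwi_dataset <- function(x, ...) {
  d <- dim(x$s)
  cat(sprintf(
    "Multistatic S-parameter dataset: %d freqs (%.3g-%.3g GHz) x %d tx x %d rx x %d rotations\n",
    d[1], min(x$freqs) / 1e9, max(x$freqs) / 1e9, d[2], d[3], d[4]))
  invisible(x)
}

#' Default acquisition frequency grid
#'
#' Evenly spaced frequency points across the system's operating band,
#' defaulting to 201 points over 2.7-8.0 GHz.
#'
#' @param n Number of frequency points.
#' @param f_start,f_stop Band edges in Hz.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_freqs <- function(n = 201, f_start = 2.7e9, f_stop = 8.0e9) {
  .mwi_check(n >= 2 && f_start > 0 && f_stop > f_start, "mwi_config_error",
             "need n >= 2 and 0 < f_start < f_stop")
  seq(f_start, f_stop, length.out = n)
}
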