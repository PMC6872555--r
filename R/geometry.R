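# Cylindrical array geometry, imaging grid, and distance/delay tables.
#
# Conventions (used consistently by the simulator and the reconstructor):
#   * right-handed Cartesian coordinates in meters, cylinder axis = z;
#   * counter-clockwise rotation positive; rotation index 1 lies one
#     phi_step past the base angles;
#   * antennas and rotation positions are 1-based, grid points are exposed
#     through a 1-based point index i.

#' Build a cylindrical interleaved Tx/Rx antenna array
#'
#' Transmit antennas sit at `k * 360/n_tx` degrees (k = 0..n_tx-1) on a
#' cylinder of the given radius; receive antennas are interleaved, offset by
#' half the transmit spacing. The array rotates in `n_phi` steps of
#' `phi_step` degrees covering a full turn.
#'
#' @param n_tx,n_rx Number of transmit / receive antennas (>= 1).
#' @param radius Cylinder radius in meters (> 0).
#' @param n_phi Number of rotation positions; must be even (the odd/even
#'   rotation split of the skin-removal step pairs consecutive positions).
#' @param phi_step Rotation step in degrees; `n_phi * phi_step` must equal
#'   360 within tolerance.
#' @param z_plane Antenna height (z coordinate) in meters.
#' @return An object of class `mwi_geometry`.
#' @examples
#' geom <- build_cylindrical_array(8, 8, 0.1, 50, 7.2)
#' geom$rx_base_angles[1] - geom$tx_base_angles[1]  # 22.5 degrees
#' @export
build_cylindrical_array <- function(n_tx, n_rx, radius, n_phi, phi_step,
                                    z_plane = 0) {
  .mwi_check(is.numeric(n_tx) && length(n_tx) == 1 && n_tx >= 1,
             "mwi_config_error", "n_tx must be a count >= 1")
  .mwi_check(is.numeric(n_rx) && length(n_rx) == 1 && n_rx >= 1,
             "mwi_config_error", "n_rx must be a count >= 1")
  .mwi_check(is.numeric(radius) && length(radius) == 1 && radius > 0,
             "mwi_config_error", "radius must be > 0")
  .mwi_check(is.numeric(n_phi) && length(n_phi) == 1 && n_phi >= 2 &&
               n_phi == round(n_phi),
             "mwi_config_error", "n_phi must be an integer >= 2")
  .mwi_check(n_phi %% 2 == 0, "mwi_config_error",
             "n_phi must be even (odd/even rotation split), got %g", n_phi)
  .mwi_check(is.numeric(phi_step) && length(phi_step) == 1 && phi_step > 0,
             "mwi_config_error", "phi_step must be > 0")
  .mwi_check(abs(n_phi * phi_step - 360) <= 360 * 1e-9, "mwi_config_error",
             "n_phi * phi_step must equal 360 degrees, got %g",
             n_phi * phi_step)

  tx_base <- (seq_len(n_tx) - 1) * 360 / n_tx
  rx_base <- 180 / n_tx + (seq_len(n_rx) - 1) * 360 / n_rx
  ang <- c(tx_base, rx_base) %% 360
  .mwi_check(!any(duplicated(round(ang / 360 * 1e12))), "mwi_config_error",
             "tx and rx base angles must be pairwise distinct")

  structure(
    list(n_tx = as.integer(n_tx), n_rx = as.integer(n_rx), radius = radius,
         z_plane = z_plane, n_phi = as.integer(n_phi), phi_step = phi_step,
         tx_base_angles = tx_base, rx_base_angles = rx_base),
    class = "mwi_geometry"
  )
}

#' @export
print.mwi_geometry <- function(x, ...) {
  cat(sprintf(
    "Cylindrical array: %d Tx + %d Rx interleaved, radius %g m, z = %g m\n",
    x$n_tx, x$n_rx, x$radius, x$z_plane))
  cat(sprintf("Rotation: %d positions x %g deg (full turn)\n",
              x$n_phi, x$phi_step))
  invisible(x)
}

#' Antenna positions at a rotation index
#'
#' Rotation index `phi_index` places the antennas `phi_index * phi_step`
#' degrees past their base angles. Indices wrap periodically (a full turn
#' reproduces the same positions bit-exactly); indices below 1 are an error.
#'
#' @param geom An `mwi_geometry`.
#' @param phi_index Rotation index (integer >= 1; 1-based, wraps mod n_phi).
#' @return List with `tx` and `rx`, each an n x 3 matrix of positions (m).
#' @export
antenna_positions_at_rotation <- function(geom, phi_index) {
  stopifnot(inherits(geom, "mwi_geometry"))
  .mwi_check(is.numeric(phi_index) && length(phi_index) == 1 &&
               phi_index == round(phi_index) && phi_index >= 1,
             "mwi_index_error", "phi_index must be an integer >= 1, got %s",
             format(phi_index))
  k <- ((phi_index - 1) %% geom$n_phi) + 1
  rot <- k * geom$phi_step
  to_xyz <- function(angles_deg) {
    a <- (angles_deg + rot) * pi / 180
    cbind(x = geom$radius * cos(a), y = geom$radius * sin(a),
          z = rep(geom$z_plane, length(a)))
  }
  list(tx = to_xyz(geom$tx_base_angles), rx = to_xyz(geom$rx_base_angles))
}

#' Build the imaging grid
#'
#' Regular Cartesian grid of focal points. In `slice2d` mode all points lie
#' in the plane `z = z_plane`; in `volume3d` mode the z extent is sampled at
#' the same spacing. Points are ordered with the x index varying fastest,
#' then y, then z.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` (slice2d) or
#'   `c(xmin, xmax, ymin, ymax, zmin, zmax)` (volume3d), in meters.
#' @param spacing Grid spacing in meters (> 0).
#' @param mode `"slice2d"` (default) or `"volume3d"`.
#' @param z_plane Slice height for `slice2d`, meters.
#' @param geom Optional `mwi_geometry`; when supplied, every grid point must
#'   lie inside the array cylinder.
#' @return An object of class `mwi_grid` with fields `points` (n x 3 matrix),
#'   `shape`, `spacing`, `extent`, `mode`.
#' @export
build_imaging_grid <- function(extent, spacing, mode = c("slice2d", "volume3d"),
                               z_plane = 0, geom = NULL) {
  mode <- match.arg(mode)
  .mwi_check(is.numeric(spacing) && length(spacing) == 1 && spacing > 0,
             "mwi_config_error", "spacing must be > 0")
  need <- if (mode == "slice2d") 4L else 6L
  .mwi_check(is.numeric(extent) && length(extent) == need,
             "mwi_config_error",
             "extent must have %d entries for mode %s", need, mode)
  .mwi_check(extent[1] <= extent[2] && extent[3] <= extent[4],
             "mwi_config_error", "extent bounds must be ordered")
  xs <- seq(extent[1], extent[2], by = spacing)
  ys <- seq(extent[3], extent[4], by = spacing)
  if (mode == "slice2d") {
    zs <- z_plane
  } else {
    .mwi_check(extent[5] <= extent[6], "mwi_config_error",
               "extent z bounds must be ordered")
    zs <- seq(extent[5], extent[6], by = spacing)
  }
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  if (!is.null(geom)) {
    r2 <- pts[, 1]^2 + pts[, 2]^2
    .mwi_check(all(r2 < geom$radius^2), "mwi_config_error",
               "imaging grid extends outside the array cylinder")
  }
  structure(
    list(points = pts,
         shape = c(length(xs), length(ys), if (mode == "volume3d") length(zs)),
         spacing = spacing, extent = extent, mode = mode,
         x = xs, y = ys, z = zs),
    class = "mwi_grid"
  )
}

#' @export
print.mwi_grid <- function(x, ...) {
  cat(sprintf("Imaging grid (%s): %s points, spacing %g m\n", x$mode,
              paste(x$shape, collapse = " x "), x$spacing))
  invisible(x)
}

#' Distances from every grid point to every antenna at odd rotations
#'
#' Euclidean distances for every (point, antenna, odd rotation position)
#' triple. Only odd rotation indices (1, 3, ..., n_phi - 1) are tabulated:
#' after rotation subtraction the beamformer treats the differenced data as
#' acquired at the odd positions.
#'
#' @param grid An `mwi_grid`.
#' @param geom An `mwi_geometry`.
#' @return An object of class `mwi_distances` with `tx_to_point` and
#'   `point_to_rx` arrays, indexed (point, antenna, odd-rotation), and
#'   `phi_odd`, the odd rotation indices.
#' @export
compute_distance_tables <- function(grid, geom) {
  stopifnot(inherits(grid, "mwi_grid"), inherits(geom, "mwi_geometry"))
  phi_odd <- seq(1L, geom$n_phi - 1L, by = 2L)
  n_pts <- nrow(grid$points)
  d_tx <- array(NA_real_, c(n_pts, geom$n_tx, length(phi_odd)))
  d_rx <- array(NA_real_, c(n_pts, geom$n_rx, length(phi_odd)))
  pts <- grid$points
  for (m in seq_along(phi_odd)) {
    pos <- antenna_positions_at_rotation(geom, phi_odd[m])
    for (a in seq_len(geom$n_tx)) {
      d_tx[, a, m] <- sqrt((pts[, 1] - pos$tx[a, 1])^2 +
                             (pts[, 2] - pos$tx[a, 2])^2 +
                             (pts[, 3] - pos$tx[a, 3])^2)
    }
    for (b in seq_len(geom$n_rx)) {
      d_rx[, b, m] <- sqrt((pts[, 1] - pos$rx[b, 1])^2 +
                             (pts[, 2] - pos$rx[b, 2])^2 +
                             (pts[, 3] - pos$rx[b, 3])^2)
    }
  }
  structure(list(tx_to_point = d_tx, point_to_rx = d_rx, phi_odd = phi_odd),
            class = "mwi_distances")
}

#' Round-trip propagation delay table
#'
#' Converts the tabulated distances into two-way propagation delays through
#' a homogeneous background of relative permittivity `eps_b`:
#' `tau(i, tx, rx, phi_odd) = sqrt(eps_b) * (P_tx->i + P_i->rx) / c`.
#'
#' @param dist An `mwi_distances` table.
#' @param eps_b Background relative permittivity (>= 1; 1 = air).
#' @return An object of class `mwi_delays` with `tau`, a
#'   (point, tx, rx, odd-rotation) array in seconds, plus `eps_b` and `c`.
#' @export
compute_delay_table <- function(dist, eps_b = 1) {
  stopifnot(inherits(dist, "mwi_distances"))
  .mwi_check(is.numeric(eps_b) && length(eps_b) == 1 && eps_b >= 1,
             "mwi_domain_error", "eps_b must be >= 1, got %g", eps_b)
  d_tx <- dist$tx_to_point
  d_rx <- dist$point_to_rx
  n_pts <- dim(d_tx)[1]; n_tx <- dim(d_tx)[2]
  n_rx <- dim(d_rx)[2]; n_odd <- dim(d_tx)[3]
  tau <- array(NA_real_, c(n_pts, n_tx, n_rx, n_odd))
  scale <- sqrt(eps_b) / .mwi_c0
  for (m in seq_len(n_odd)) {
    for (b in seq_len(n_rx)) {
      tau[, , b, m] <- (d_tx[, , m] + d_rx[, b, m]) * scale
    }
  }
  structure(list(tau = tau, eps_b = eps_b, c = .mwi_c0,
                 phi_odd = dist$phi_odd),
            class = "mwi_delays")
}
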